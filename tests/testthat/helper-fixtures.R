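# Shared fixtures and independent oracles, built in code at test time.

# A methylation_matrix from explicit loci and count matrices.
make_mat <- function(contig, position, meth, total,
                     size_class = rep(c("large", "small"),
                                      length.out = ncol(meth)),
                     feed = rep("Feed1", ncol(meth))) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  samples <- sprintf("s%02d", seq_len(ncol(meth)))
  colnames(meth) <- colnames(total) <- samples
  structure(list(loci = data.frame(contig = contig, position = position,
                                   stringsAsFactors = FALSE),
                 samples = samples, meth = meth, total = total,
                 metadata = data.frame(sample_id = samples,
                                       size_class = size_class, feed = feed,
                                       has_rna = TRUE,
                                       stringsAsFactors = FALSE)),
            class = "methylation_matrix")
}

# Write a tiny GFF3 from a data.frame of 0-based gene models.
write_gff <- function(genes, path, contig_length = 1e6) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     unique(genes$contig), contig_length),
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$contig, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  path
}

# Naive PERMANOVA pseudo-F from raw coordinates (multivariate SS identity),
# independent of the distance-matrix implementation.
oracle_f <- function(x, lab) {
  n <- nrow(x); g <- length(unique(lab))
  ss <- function(m) sum(sweep(m, 2, colMeans(m))^2)
  ss_tot <- ss(x)
  ss_w <- sum(vapply(unique(lab), function(l) ss(x[lab == l, , drop = FALSE]), 0))
  c(f = ((ss_tot - ss_w) / (g - 1)) / (ss_w / (n - g)),
    r2 = (ss_tot - ss_w) / ss_tot)
}

# All permutations of 1..n (small n only).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i)
    lapply(all_perms(n - 1L), function(p) c(i, (seq_len(n))[-i][p]))))
}

# Brute-force Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    j <- which(o == i)                       # rank of p[i]
    q[i] <- min(p[o[j:n]] * n / (j:n))
  }
  pmin(q, 1)
}

# Brute-force all-pairs interval overlap (0-based half-open).
oracle_overlap <- function(dmrs, feats) {
  out <- list()
  for (i in seq_len(nrow(dmrs))) for (j in seq_len(nrow(feats))) {
    if (dmrs$contig[i] == feats$contig[j] &&
        min(dmrs$end[i], feats$end[j]) - max(dmrs$start[i], feats$start[j]) >= 1)
      out[[length(out) + 1L]] <- data.frame(
        dmr_id = dmrs$dmr_id[i], gene_id = feats$gene_id[j],
        feature_class = feats$feature_class[j], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(dmr_id = character(), gene_id = character(),
                      feature_class = character()))
  unique(do.call(rbind, out))
}

# Vectors with an exact sample Pearson correlation r (n points).
make_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1]
  e <- resid(lm(rnorm(n) ~ x))
  e <- e / sd(e)
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}

# Small deterministic simulation for fast end-to-end style tests.
quick_sim <- function(seed = 1, ...) {
  simulate_dataset(sim_config(seed = seed, ...))
}
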