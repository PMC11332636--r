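#' Genome-tiling configuration
#'
#' Fixed non-overlapping windows with CpG-count and coverage filters: a
#' tile is retained iff it holds at least `min_cpgs` CpGs and its mean
#' per-CpG coverage (averaged over CpGs and samples) lies in
#' `[min_cov, max_cov]`. The coverage bounds mitigate low-complexity
#' regions with pile-up coverage.
#'
#' @param window Tile width, bp.
#' @param min_cpgs Minimum CpG count per tile.
#' @param min_cov,max_cov Coverage bounds (X) on the tile mean.
#' @return An object of class `tile_config`.
#' @export
tile_config <- function(window = 10000L, min_cpgs = 100L,
                        min_cov = 1, max_cov = 30) {
  stopifnot(window > 0L, min_cpgs >= 1L, min_cov <= max_cov)
  structure(list(window = as.integer(window), min_cpgs = as.integer(min_cpgs),
                 min_cov = min_cov, max_cov = max_cov),
            class = "tile_config")
}

#' Tile the genome and compute per-tile methylation levels
#'
#' Splits each contig into `[k*window, (k+1)*window)` tiles, applies the
#' CpG-count and mean-coverage filters, and computes the per-sample tile
#' methylation level as the count-weighted `sum(meth)/sum(total)` over the
#' tile's CpGs. Cells with zero coverage get `NA`.
#'
#' @param mat A `methylation_matrix` (assembled; need not be
#'   complete-coverage filtered).
#' @param config A [tile_config()].
#' @return A list of class `tile_matrix` with `tiles` (`contig`, `start`,
#'   `end`, `n_cpgs`, `mean_cov`) and `levels` (tiles x samples matrix in
#'   `[0, 1]`).
#' @export
tile_methylation <- function(mat, config = tile_config()) {
  stopifnot(inherits(config, "tile_config"))
  w <- config$window
  bin <- mat$loci$position %/% w
  key <- paste(mat$loci$contig, bin)
  grp <- match(key, unique(key))
  n_tiles <- max(grp, 0L)
  ns <- length(mat$samples)
  meth_s <- rowsum(mat$meth, grp)
  tot_s <- rowsum(mat$total, grp)
  n_cpgs <- tabulate(grp, n_tiles)
  mean_cov <- rowSums(tot_s) / (n_cpgs * ns)
  first <- !duplicated(grp)
  tiles <- data.frame(contig = mat$loci$contig[first],
                      start = bin[first] * w,
                      end = (bin[first] + 1L) * w,
                      n_cpgs = n_cpgs, mean_cov = mean_cov,
                      stringsAsFactors = FALSE)
  keep <- n_cpgs >= config$min_cpgs &
    mean_cov >= config$min_cov & mean_cov <= config$max_cov
  levels <- meth_s / tot_s
  levels[tot_s == 0] <- NA_real_
  colnames(levels) <- mat$samples
  structure(list(tiles = tiles[keep, , drop = FALSE],
                 levels = levels[keep, , drop = FALSE],
                 samples = mat$samples),
            class = "tile_matrix")
}

#' PCA of tile methylation
#'
#' Principal components of samples in tile space: tiles are centered, not
#' scaled, and tiles with any undefined level are dropped. Scores come
#' from the singular-value decomposition of the centered sample-by-tile
#' matrix; variance fractions sum to 1 when total variance is positive.
#'
#' @param tm A `tile_matrix`.
#' @return A list with `scores` (samples x components), `var_explained`
#'   (fractions; all `NA` when the matrix is constant) and `sdev`.
#' @export
meth_pca <- function(tm) {
  x <- t(tm$levels[stats::complete.cases(tm$levels), , drop = FALSE])
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("PCA needs >= 2 samples and >= 2 complete tiles")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  ve <- if (tot > 0) pc$sdev^2 / tot else rep(NA_real_, length(pc$sdev))
  list(scores = pc$x, var_explained = ve, sdev = pc$sdev)
}

#' PERMANOVA on tile methylation profiles
#'
#' Permutational multivariate ANOVA of between-sample distances against a
#' grouping factor. The pseudo-F is computed from the distance matrix:
#' `SS_total = sum(d_ij^2)/n` over all pairs, `SS_within` the analogous
#' within-group sum, `F = (SS_between/(g-1)) / (SS_within/(n-g))`,
#' `R^2 = SS_between/SS_total`. The p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + N)` under label shuffles; when the
#' number of distinct relabelings (excluding the observed one) is at most
#' `n_perm`, they are enumerated exhaustively.
#'
#' @param tm A `tile_matrix`, or a plain samples x variables numeric matrix.
#' @param labels Group label per sample (2 or more groups).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @param method Distance metric passed to [stats::dist()]; Euclidean on
#'   tile levels by default.
#' @return A list with `r_squared`, `pseudo_f`, `p`, `n_perm` (permutations
#'   actually used) and `exhaustive`.
#' @export
permanova <- function(tm, labels, n_perm = 999L, seed = 1L,
                      method = "euclidean") {
  x <- if (inherits(tm, "tile_matrix"))
    t(tm$levels[stats::complete.cases(tm$levels), , drop = FALSE])
  else as.matrix(tm)
  n <- nrow(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  if (n < 3L) stop("PERMANOVA needs at least 3 samples")
  tab <- table(labels)
  if (length(tab) < 2L || any(tab == 0L)) stop("need >= 2 non-empty groups")
  d2 <- as.matrix(stats::dist(x, method = method))^2
  f_stat <- function(lab) {
    ss_tot <- sum(d2) / (2 * n)
    ss_w <- 0
    for (g in unique(lab)) {
      i <- lab == g
      ss_w <- ss_w + sum(d2[i, i]) / (2 * sum(i))
    }
    ss_b <- ss_tot - ss_w
    g <- length(unique(lab))
    c(f = (ss_b / (g - 1)) / (ss_w / (n - g)), r2 = ss_b / ss_tot)
  }
  obs <- f_stat(labels)
  perms <- enumerate_or_sample_labels(labels, n_perm, seed)
  null_f <- vapply(perms$labelings, function(l) f_stat(l)[["f"]], 0)
  p <- (1 + sum(null_f >= obs[["f"]] - 1e-12)) / (1 + length(null_f))
  list(r_squared = unname(obs[["r2"]]), pseudo_f = unname(obs[["f"]]),
       p = p, n_perm = length(null_f), exhaustive = perms$exhaustive)
}

# All distinct relabelings of `labels` excluding the observed one when
# their number is <= n_perm (two-group case), else n_perm random shuffles.
# Returns list(labelings = list of label vectors, exhaustive = flag).
enumerate_or_sample_labels <- function(labels, n_perm, seed) {
  n <- length(labels)
  tab <- table(labels)
  n_distinct <- if (length(tab) == 2L) choose(n, tab[[1L]]) else Inf
  if (n_distinct - 1 <= n_perm) {
    g1 <- names(tab)[1L]
    combs <- utils::combn(n, tab[[1L]], simplify = FALSE)
    labelings <- lapply(combs, function(i) {
      l <- rep(names(tab)[2L], n)
      l[i] <- g1
      l
    })
    obs <- vapply(labelings, function(l) all(l == labels), TRUE)
    list(labelings = labelings[!obs], exhaustive = TRUE)
  } else {
    rng <- local_rng(seed)
    list(labelings = replicate(n_perm, sample(labels), simplify = FALSE),
         exhaustive = FALSE)
  }
}

# Seeded RNG scoped to the calling frame; restores the global state on exit.
local_rng <- function(seed) {
  env <- parent.frame()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  if (!is.null(old))
    withr::defer(assign(".Random.seed", old, envir = globalenv()), envir = env)
  else
    withr::defer(rm(".Random.seed", envir = globalenv()), envir = env)
  invisible(seed)
}

#' TSS-centred methylation metaprofile
#'
#' Pools every CpG lying within `[-span_up, +span_down)` of any gene's TSS
#' (strand-aware offset; a CpG near several genes contributes once per
#' gene) into fixed bins and reports the count-weighted mean methylation
#' level per bin over all samples. On the minus strand the offset of
#' genomic position `p` is `tss - p - 1`, so profiles are exactly
#' mirror-symmetric under strand flip.
#'
#' @param mat A `methylation_matrix` (destranded).
#' @param genes Gene models from [parse_gene_models()].
#' @param span_up,span_down Window reach upstream/downstream of the TSS, bp.
#' @param bin Bin width, bp.
#' @return A `data.frame` with `bin_start` (offset of the bin's left edge
#'   relative to the TSS), `mean_level` (`NA` where no CpG falls in the
#'   bin) and `n_cpgs` (pooled CpG-gene contributions).
#' @export
tss_metaprofile <- function(mat, genes, span_up = 6000L, span_down = 5000L,
                            bin = 50L) {
  stopifnot((span_up + span_down) %% bin == 0L)
  bin_starts <- seq(-span_up, span_down - bin, by = bin)
  nb <- length(bin_starts)
  meth_sum <- numeric(nb); tot_sum <- numeric(nb); n_cpgs <- integer(nb)
  meth_row <- rowSums(mat$meth)
  tot_row <- rowSums(mat$total)
  for (ctg in unique(genes$contig)) {
    li <- which(mat$loci$contig == ctg)
    if (!length(li)) next
    pos <- mat$loci$position[li]
    for (gi in which(genes$contig == ctg)) {
      tss <- genes$tss[gi]
      off <- if (genes$strand[gi] == "+") pos - tss else tss - pos - 1L
      sel <- off >= -span_up & off < span_down
      if (!any(sel)) next
      b <- (off[sel] + span_up) %/% bin + 1L
      rows <- li[sel]
      agg_m <- rowsum(meth_row[rows], b)
      agg_t <- rowsum(tot_row[rows], b)
      idx <- as.integer(rownames(agg_m))
      meth_sum[idx] <- meth_sum[idx] + agg_m[, 1L]
      tot_sum[idx] <- tot_sum[idx] + agg_t[, 1L]
      n_cpgs <- n_cpgs + tabulate(b, nb)
    }
  }
  mean_level <- meth_sum / tot_sum
  mean_level[tot_sum == 0] <- NA_real_
  data.frame(bin_start = bin_starts, mean_level = mean_level, n_cpgs = n_cpgs)
}
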