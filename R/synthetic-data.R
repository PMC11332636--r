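#' Default feature-class coupling table
#'
#' How planted methylation differences couple to expression, per feature
#' class: `sign = -1` (methylation represses), `+1` (activates) or `0`
#' (mixed: a random sign per gene). Promoter-proximal classes default to
#' repression, gene body and terminal region to mixed coupling.
#' `prob` weights where planted DMRs are placed; `strength` is the
#' log-scale effect per standardized methylation unit.
#'
#' @return A `data.frame` with `feature_class`, `sign`, `prob`, `strength`.
#' @export
default_coupling_table <- function() {
  data.frame(feature_class = c("P1", "GS", "P6", "GB", "TTR"),
             sign = c(-1, -1, -1, 0, 0),
             prob = c(0.3, 0.15, 0.1, 0.4, 0.05),
             strength = 1.2,
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline targets: ~78%
#' background CpG methylation, a hypomethylation dip to 0.2 within
#' +/-500 bp of each TSS, ~5X beta-binomial coverage, 5 vs 5 samples in
#' two feed strata, and 20 planted DMRs with a 0.3 group difference.
#'
#' @param seed Master seed; stages derive their own streams from it.
#' @param n_contigs,contig_length Genome shape.
#' @param n_genes Genes, placed non-overlapping with random strands and
#'   lengths in `gene_length_range` (the lower end below 1500 bp so the
#'   whole-gene gene-start path is exercised).
#' @param gene_length_range Gene length range, bp.
#' @param cpg_rate Expected CpGs per bp (tripled within the TSS dip).
#' @param background_beta,tss_dip_beta,tss_dip_halfwidth Methylation
#'   landscape parameters.
#' @param coverage_mean Mean read coverage per CpG (Poisson).
#' @param bb_precision Beta-binomial concentration; larger is closer to
#'   binomial sampling.
#' @param n_large,n_small Samples per size class.
#' @param feed_split Fraction of each size class in the first feed group.
#' @param n_planted_dmrs,planted_delta Planted regions and their total
#'   between-group methylation difference (large minus small is
#'   `+/- planted_delta`).
#' @param planted_cpgs CpGs per planted region; the default 22 matches
#'   the scale of candidate DMRs reported in gut-methylome data
#'   (~774 bp, 22 CpGs on average).
#' @param coupling_table See [default_coupling_table()].
#' @param nb_mean_log_range Range of per-gene baseline log mean counts.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param n_extra_genes Uncoupled genes added to the count table beyond
#'   the genome's genes, as expression-only noise genes.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_contigs = 2L, contig_length = 500000L,
                       n_genes = 40L, gene_length_range = c(800L, 8000L),
                       cpg_rate = 0.02, background_beta = 0.78,
                       tss_dip_beta = 0.2, tss_dip_halfwidth = 500L,
                       coverage_mean = 5, bb_precision = 30,
                       n_large = 5L, n_small = 5L, feed_split = 0.5,
                       n_planted_dmrs = 20L, planted_delta = 0.3,
                       planted_cpgs = 22L,
                       coupling_table = default_coupling_table(),
                       nb_mean_log_range = log(c(50, 500)),
                       nb_dispersion = 0.05, n_extra_genes = 0L) {
  stopifnot(background_beta > 0, background_beta < 1,
            tss_dip_beta > 0, tss_dip_beta < 1,
            background_beta + planted_delta / 2 < 1,
            tss_dip_beta - planted_delta / 2 > 0,
            n_large >= 1L, n_small >= 1L)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genome annotation and CpG landscape
#'
#' Places non-overlapping genes with random strands and lengths on each
#' contig and draws CpG positions as a thinned point process with
#' elevated density around each TSS. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (gene models as from
#'   [parse_gene_models()]), `cpg` (`data.frame` of `contig`, `position`),
#'   `contig_lengths` and `gff` (GFF3 text lines).
#' @export
simulate_genome <- function(config = sim_config()) {
  local_rng(config$seed)
  L <- config$contig_length
  n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_contigs + 1)))
  contigs <- sprintf("ctg%02d", seq_len(config$n_contigs))
  min_gap <- 8000L
  genes <- list(); cpg <- list()
  gid <- 0L
  for (ci in seq_len(config$n_contigs)) {
    k <- n_per[ci]
    if (k > 0L) {
      len <- as.integer(round(stats::runif(k, config$gene_length_range[1L],
                                           config$gene_length_range[2L])))
      avail <- L - sum(len) - (k + 1L) * min_gap
      if (avail < 0L)
        stop("infeasible packing: ", k, " genes of total length ", sum(len),
             " do not fit on a ", L, " bp contig")
      w <- stats::runif(k + 1L)
      extra <- floor(w / sum(w) * avail)
      gaps <- min_gap + extra[seq_len(k)]          # gap i precedes gene i
      starts <- as.integer(cumsum(gaps) + cumsum(c(0L, len[-k])))
      strand <- sample(c("+", "-"), k, replace = TRUE)
      end <- starts + len
      gdf <- data.frame(gene_id = sprintf("g%03d", gid + seq_len(k)),
                        contig = contigs[ci], start = starts, end = end,
                        strand = strand,
                        tss = ifelse(strand == "-", end - 1L, starts),
                        tts = ifelse(strand == "-", starts, end - 1L),
                        stringsAsFactors = FALSE)
      gid <- gid + k
      genes[[ci]] <- gdf
    }
    p <- rep(config$cpg_rate, L)
    if (k > 0L) {
      for (tss in genes[[ci]]$tss) {
        lo <- max(1L, tss - config$tss_dip_halfwidth + 1L)
        hi <- min(L, tss + config$tss_dip_halfwidth + 1L)
        p[lo:hi] <- config$cpg_rate * 3
      }
    }
    pos <- which(stats::runif(L) < p) - 1L
    pos <- pos[pos <= L - 2L]
    cpg[[ci]] <- data.frame(contig = contigs[ci], position = pos,
                            stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL
  gff <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", contigs, L),
           if (!is.null(genes)) sprintf(
             "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
             genes$contig, genes$start + 1L, genes$end, genes$strand,
             genes$gene_id))
  list(genes = if (is.null(genes)) data.frame(
    gene_id = character(), contig = character(), start = integer(),
    end = integer(), strand = character(), tss = integer(),
    tts = integer()) else genes,
    cpg = do.call(rbind, cpg),
    contig_lengths = stats::setNames(rep(L, config$n_contigs), contigs),
    gff = gff)
}

#' Plant differentially methylated regions
#'
#' Chooses genes, picks one feature class per planted region according to
#' the coupling table's placement weights, and plants the region on a run
#' of `planted_cpgs` consecutive CpGs inside that feature interval (genes
#' whose chosen feature holds fewer CpGs are skipped). Each region gets a
#' random direction: large-fish methylation is shifted by `+delta/2` and
#' small by `-delta/2` (or the reverse).
#'
#' @param genome Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @return A `data.frame` of planted truth: `dmr_id`, `gene_id`,
#'   `feature_class`, `contig`, `start`, `end`, `delta` (large minus
#'   small), `direction`, `n_cpgs`.
#' @export
plant_dmrs <- function(genome, config = sim_config()) {
  local_rng(config$seed + 1L)
  feats <- build_feature_intervals(genome$genes, feature_geometry(),
                                   genome$contig_lengths)
  ct <- config$coupling_table
  n <- config$n_planted_dmrs
  if (n == 0L || nrow(genome$genes) == 0L)
    return(data.frame(dmr_id = character(), gene_id = character(),
                      feature_class = character(), contig = character(),
                      start = integer(), end = integer(), delta = numeric(),
                      direction = character(), n_cpgs = integer()))
  gene_pool <- sample(genome$genes$gene_id)
  out <- list()
  for (g in gene_pool) {
    if (length(out) >= n) break
    cls <- sample(ct$feature_class, 1L, prob = ct$prob)
    fi <- feats[feats$gene_id == g & feats$feature_class == cls, ]
    if (nrow(fi) != 1L) next
    in_feat <- genome$cpg$contig == fi$contig &
      genome$cpg$position >= fi$start & genome$cpg$position < fi$end
    k <- config$planted_cpgs
    if (sum(in_feat) < k) next
    pos <- genome$cpg$position[in_feat]
    first <- sample(length(pos) - k + 1L, 1L)
    pos <- pos[first:(first + k - 1L)]
    out[[length(out) + 1L]] <- data.frame(
      dmr_id = sprintf("planted%03d", length(out) + 1L),
      gene_id = g, feature_class = cls, contig = fi$contig,
      start = min(pos), end = max(pos) + 2L,
      delta = sample(c(-1, 1), 1L) * config$planted_delta,
      direction = NA_character_, n_cpgs = k,
      stringsAsFactors = FALSE)
  }
  if (length(out) < n)
    warning("placed only ", length(out), " of ", n, " planted DMRs")
  truth <- do.call(rbind, out)
  truth$direction <- ifelse(truth$delta > 0, "hyper", "hypo")
  truth
}

# True methylation level per CpG for one group ("large"/"small").
true_beta <- function(genome, truth, config, group) {
  beta <- rep(config$background_beta, nrow(genome$cpg))
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    in_dip <- genome$cpg$contig == g$contig &
      abs(genome$cpg$position - g$tss) <= config$tss_dip_halfwidth
    beta[in_dip] <- config$tss_dip_beta
  }
  if (!is.null(truth) && nrow(truth)) {
    shift <- if (group == "large") 0.5 else -0.5
    for (k in seq_len(nrow(truth))) {
      in_reg <- genome$cpg$contig == truth$contig[k] &
        genome$cpg$position >= truth$start[k] &
        genome$cpg$position < truth$end[k]
      beta[in_reg] <- beta[in_reg] + shift * truth$delta[k]
    }
  }
  pmin(pmax(beta, 0.02), 0.98)
}

#' Simulate per-sample methylation calls
#'
#' Per CpG and sample, total coverage is Poisson with mean
#' `coverage_mean` and the methylated count beta-binomial around the true
#' level (background, lowered in TSS dips, shifted by
#' `+/- planted_delta/2` per group inside planted regions).
#'
#' @param genome Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @param truth Planted regions from [plant_dmrs()] (or `NULL`).
#' @return A list with `calls` (named list of destranded call
#'   `data.frame`s per sample), `metadata`, and `beta_true` (CpGs x 2
#'   matrix of group-level true levels).
#' @export
simulate_methylation <- function(genome, config = sim_config(), truth = NULL) {
  local_rng(config$seed + 2L)
  md <- sim_metadata(config)
  beta_g <- cbind(large = true_beta(genome, truth, config, "large"),
                  small = true_beta(genome, truth, config, "small"))
  n_cpg <- nrow(genome$cpg)
  calls <- lapply(seq_len(nrow(md)), function(si) {
    beta <- beta_g[, md$size_class[si]]
    total <- stats::rpois(n_cpg, config$coverage_mean)
    pr <- stats::rbeta(n_cpg, beta * config$bb_precision,
                       (1 - beta) * config$bb_precision)
    meth <- stats::rbinom(n_cpg, total, pr)
    keep <- total > 0L
    data.frame(contig = genome$cpg$contig[keep],
               position = genome$cpg$position[keep],
               meth = meth[keep], unmeth = total[keep] - meth[keep],
               stringsAsFactors = FALSE)
  })
  names(calls) <- md$sample_id
  list(calls = calls, metadata = md, beta_true = beta_g)
}

sim_metadata <- function(config) {
  ids <- sprintf("s%02d", seq_len(config$n_large + config$n_small))
  size <- rep(c("large", "small"), c(config$n_large, config$n_small))
  feed <- unlist(lapply(c(config$n_large, config$n_small), function(k) {
    n1 <- round(k * config$feed_split)
    c(rep("Feed1", n1), rep("Feed2", k - n1))
  }))
  data.frame(sample_id = ids, size_class = size, feed = feed,
             has_rna = TRUE, stringsAsFactors = FALSE)
}

#' Simulate gene expression coupled to methylation
#'
#' Per gene and sample, a negative-binomial count whose log mean is a
#' per-gene baseline plus, for genes carrying a planted DMR,
#' `strength * sign * z` where `z` is the across-sample standardized true
#' mean methylation of the planted feature's CpGs. Coupling acts through
#' the noise-free methylation, so attenuation of observed correlations by
#' sequencing noise is realistic.
#'
#' @param genome Output of [simulate_genome()].
#' @param meth Output of [simulate_methylation()].
#' @param config A [sim_config()].
#' @param truth Planted regions from [plant_dmrs()].
#' @return A list with `counts` (genes x samples integer matrix) and
#'   `coupling` (`data.frame` of per-gene truth: `gene_id`,
#'   `feature_class`, `sign`, `strength`, `baseline_log_mean`).
#' @export
simulate_expression <- function(genome, meth, config = sim_config(),
                                truth = NULL) {
  local_rng(config$seed + 3L)
  md <- meth$metadata
  gene_ids <- genome$genes$gene_id
  if (config$n_extra_genes > 0L)
    gene_ids <- c(gene_ids, sprintf("x%03d", seq_len(config$n_extra_genes)))
  n_g <- length(gene_ids)
  baseline <- stats::runif(n_g, config$nb_mean_log_range[1L],
                           config$nb_mean_log_range[2L])
  ct <- config$coupling_table
  coupling <- data.frame(gene_id = gene_ids, feature_class = NA_character_,
                         sign = 0, strength = 0, baseline_log_mean = baseline,
                         stringsAsFactors = FALSE)
  logmu <- matrix(rep(baseline, nrow(md)), n_g, nrow(md),
                  dimnames = list(gene_ids, md$sample_id))
  if (!is.null(truth) && nrow(truth)) {
    for (k in seq_len(nrow(truth))) {
      gi <- match(truth$gene_id[k], gene_ids)
      if (is.na(gi)) next
      row <- ct[ct$feature_class == truth$feature_class[k], ]
      sgn <- if (row$sign == 0) sample(c(-1, 1), 1L) else row$sign
      in_reg <- genome$cpg$contig == truth$contig[k] &
        genome$cpg$position >= truth$start[k] &
        genome$cpg$position < truth$end[k]
      mlev <- colMeans(meth$beta_true[in_reg, , drop = FALSE])
      per_sample <- mlev[md$size_class]
      if (stats::sd(per_sample) == 0) {
        warning("planted feature without methylation variation for gene ",
                truth$gene_id[k], "; coupling skipped")
        next
      }
      z <- (per_sample - mean(per_sample)) / stats::sd(per_sample)
      logmu[gi, ] <- baseline[gi] + row$strength * sgn * z
      coupling$feature_class[gi] <- truth$feature_class[k]
      coupling$sign[gi] <- sgn
      coupling$strength[gi] <- row$strength
    }
  }
  counts <- matrix(stats::rnbinom(n_g * nrow(md), mu = exp(logmu),
                                  size = 1 / config$nb_dispersion),
                   n_g, nrow(md), dimnames = dimnames(logmu))
  storage.mode(counts) <- "integer"
  list(counts = counts, coupling = coupling)
}

#' Simulate a complete paired data set
#'
#' Genome, planted DMR truth, per-sample methylomes and a coupled count
#' table, optionally written to disk in the pipeline's input formats
#' (GFF3, Bismark coverage per sample, counts TSV, metadata TSV, truth
#' JSON).
#'
#' @param config A [sim_config()].
#' @param dir Output directory, or `NULL` to keep everything in memory.
#' @return A list with `genome`, `truth`, `meth`, `expr`, `metadata` and
#'   (when written) `paths`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  genome <- simulate_genome(config)
  truth <- plant_dmrs(genome, config)
  meth <- simulate_methylation(genome, config, truth)
  expr <- simulate_expression(genome, meth, config, truth)
  out <- list(genome = genome, truth = truth, meth = meth, expr = expr,
              metadata = meth$metadata)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(gff = file.path(dir, "genes.gff3"),
                  counts = file.path(dir, "counts.tsv"),
                  metadata = file.path(dir, "metadata.tsv"),
                  truth = file.path(dir, "truth.json"),
                  coverage = stats::setNames(
                    file.path(dir, paste0(meth$metadata$sample_id, ".cov")),
                    meth$metadata$sample_id))
    writeLines(genome$gff, paths$gff)
    cdt <- data.table::data.table(gene_id = rownames(expr$counts),
                                  expr$counts)
    data.table::fwrite(cdt, paths$counts, sep = "\t")
    data.table::fwrite(meth$metadata, paths$metadata, sep = "\t")
    jsonlite::write_json(truth, paths$truth, digits = NA)
    for (s in meth$metadata$sample_id) {
      x <- meth$calls[[s]]
      pos1 <- x$position + 1L
      data.table::fwrite(
        data.table::data.table(x$contig, pos1, pos1,
                               100 * x$meth / (x$meth + x$unmeth),
                               x$meth, x$unmeth),
        paths$coverage[[s]], sep = "\t", col.names = FALSE)
    }
    out$paths <- paths
  }
  out
}
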