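#' Filter a gene-count matrix
#'
#' Retains genes passing both a total-count filter (at least `min_total`
#' reads summed across samples) and a prevalence filter (at least
#' `min_count` reads in at least a `min_prevalence` fraction of samples).
#' Either filter can be switched off by passing `NULL`.
#'
#' @param counts Integer matrix, genes x samples, with rownames.
#' @param min_total Minimum total count across samples, or `NULL`.
#' @param min_count,min_prevalence Per-sample count threshold and the
#'   minimum fraction of samples that must reach it, or `min_count = NULL`
#'   to disable.
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, min_total = 10L, min_count = 10L,
                         min_prevalence = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  keep <- rep(TRUE, nrow(counts))
  if (!is.null(min_total))
    keep <- keep & rowSums(counts) >= min_total
  if (!is.null(min_count))
    keep <- keep & rowMeans(counts >= min_count) >= min_prevalence
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per gene in the reference set (genes with positive counts in every
#' sample), the geometric mean across samples is taken; each sample's
#' factor is the median over reference genes of `count / geometric mean`.
#' Factors are rescaled to have geometric mean exactly 1, so normalized
#' counts are on the scale of a typical library.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named numeric vector of positive per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has positive counts in every sample; ",
         "consider a pseudo-reference on a filtered matrix")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- exp(apply(logc - loggeo, 2L, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#'
#' @param counts Genes x samples count matrix.
#' @param sf Size factors from [size_factors()].
#' @return Matrix of `counts[, j] / sf[j]`.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(as.matrix(counts), 2L, sf, "/")
}

#' Covariate-adjusted differential expression
#'
#' Fits, per gene, a linear model of `log2(normalized count + 1)` on the
#' group factor plus stratum indicators, and tests the group coefficient
#' with a two-sided t-test. The log2 fold change is the group coefficient,
#' positive when expression is higher in the non-reference group.
#' Benjamini-Hochberg adjustment is applied across tested genes. Strata
#' in which one group is absent are dropped with a warning.
#'
#' @param counts Genes x samples count matrix (already filtered).
#' @param group Group label per sample (2 groups).
#' @param strata Stratum label per sample, or `NULL`.
#' @param reference Reference group label.
#' @param sf Size factors; computed from `counts` by default.
#' @return A `data.frame` with `gene_id`, `lfc`, `t`, `p`, `q` (BH), and
#'   `mean_norm` (mean normalized count).
#' @export
differential_expression <- function(counts, group, strata = NULL,
                                    reference = "large",
                                    sf = size_factors(counts)) {
  counts <- as.matrix(counts)
  group <- as.character(group)
  stopifnot(length(group) == ncol(counts))
  if (length(unique(group)) != 2L) stop("exactly two groups required")
  if (!reference %in% group) stop("reference group not present: ", reference)
  if (is.null(strata)) strata <- rep("all", ncol(counts))
  strata <- as.character(strata)
  ok_strata <- names(which(tapply(group, strata,
                                  function(g) length(unique(g)) == 2L)))
  drop <- !strata %in% ok_strata
  if (any(drop)) {
    warning("dropping stratum without both groups: ",
            paste(unique(strata[drop]), collapse = ", "))
    if (all(drop)) stop("no stratum contains both groups")
  }
  counts <- counts[, !drop, drop = FALSE]
  sf <- sf[!drop]
  group <- group[!drop]; strata <- strata[!drop]
  norm <- sweep(counts, 2L, sf, "/")
  y <- t(log2(norm + 1))                       # samples x genes
  grp <- factor(group, levels = c(reference, setdiff(unique(group), reference)))
  design <- if (length(unique(strata)) > 1L)
    stats::model.matrix(~ grp + factor(strata))
  else stats::model.matrix(~ grp)
  qr_x <- qr(design)
  coefs <- qr.coef(qr_x, y)
  resid <- y - design %*% coefs
  df <- nrow(design) - qr_x$rank
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtx_inv[2L, 2L])
  lfc <- coefs[2L, ]
  # flat genes: residual variance at rounding-noise scale gives no test
  degenerate <- sigma2 <= 1e-16 * (colMeans(y^2) + 1e-300)
  tstat <- lfc / se
  tstat[degenerate] <- 0
  lfc[degenerate] <- 0
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate] <- 1
  data.frame(gene_id = rownames(counts), lfc = unname(lfc),
             t = unname(tstat), p = unname(p),
             q = stats::p.adjust(p, method = "BH"),
             mean_norm = unname(rowMeans(norm)),
             stringsAsFactors = FALSE)
}

#' MA and volcano tables
#'
#' Per-gene tables for the two standard differential-expression displays:
#' the MA table pairs the average expression signal
#' `A = log2(mean normalized count + 1)` with the log2 fold change `M`,
#' and the volcano table pairs the fold change with `-log10 p`.
#'
#' @param de Result of [differential_expression()].
#' @return A list of two `data.frame`s, `ma` (`gene_id`, `a`, `m`) and
#'   `volcano` (`gene_id`, `lfc`, `neg_log10_p`).
#' @export
ma_volcano_tables <- function(de) {
  list(ma = data.frame(gene_id = de$gene_id,
                       a = log2(de$mean_norm + 1), m = de$lfc),
       volcano = data.frame(gene_id = de$gene_id, lfc = de$lfc,
                            neg_log10_p = -log10(de$p)))
}

#' Read a gene-count table
#'
#' Tab-separated, first column gene ids, remaining columns one per sample.
#'
#' @param path Path to the counts TSV.
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1L])
  rownames(m) <- as.character(dt[[1L]])
  storage.mode(m) <- "integer"
  m
}
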