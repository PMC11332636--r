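#' Intersect DMRs with genomic feature intervals
#'
#' One annotation per (DMR, gene, feature class) triple whose intervals
#' overlap by at least `min_overlap` bp. A DMR may cover several features
#' of one gene, and features of different genes may overlap, so a DMR can
#' carry many annotations. DMRs overlapping no feature are recorded as
#' `Intergenic` (with `gene_id = NA`).
#'
#' @param dmrs A `data.frame` with `contig`, `start`, `end` (0-based
#'   half-open) and optionally `dmr_id` (generated when absent).
#' @param features Feature intervals from [build_feature_intervals()].
#' @param min_overlap Minimum overlap in bp (default 1, the `bedtools
#'   intersect` convention).
#' @return A `data.frame` of annotations: `dmr_id`, `gene_id`,
#'   `feature_class`.
#' @export
intersect_dmrs_features <- function(dmrs, features, min_overlap = 1L) {
  dmrs <- ensure_dmr_ids(dmrs)
  if (nrow(dmrs) == 0L)
    return(data.frame(dmr_id = character(), gene_id = character(),
                      feature_class = character()))
  dmr_gr <- GenomicRanges::GRanges(
    dmrs$contig, IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  hits_df <- if (nrow(features) > 0L) {
    feat_gr <- GenomicRanges::GRanges(
      features$contig, IRanges::IRanges(features$start + 1L, features$end))
    h <- GenomicRanges::findOverlaps(dmr_gr, feat_gr,
                                     minoverlap = min_overlap,
                                     ignore.strand = TRUE)
    unique(data.frame(
      dmr_id = dmrs$dmr_id[S4Vectors::queryHits(h)],
      gene_id = features$gene_id[S4Vectors::subjectHits(h)],
      feature_class = features$feature_class[S4Vectors::subjectHits(h)],
      stringsAsFactors = FALSE))
  } else {
    data.frame(dmr_id = character(), gene_id = character(),
               feature_class = character())
  }
  orphan <- setdiff(dmrs$dmr_id, hits_df$dmr_id)
  if (length(orphan))
    hits_df <- rbind(hits_df,
                     data.frame(dmr_id = orphan, gene_id = NA_character_,
                                feature_class = "Intergenic",
                                stringsAsFactors = FALSE))
  rownames(hits_df) <- NULL
  hits_df
}

ensure_dmr_ids <- function(dmrs) {
  if (!"dmr_id" %in% names(dmrs) && nrow(dmrs) > 0L)
    dmrs$dmr_id <- sprintf("dmr%05d", seq_len(nrow(dmrs)))
  dmrs
}

#' Assign each DMR to a single feature class
#'
#' Resolves multiple annotations with the hierarchy
#' P1 > GS > P6 > GB > TTR > Intergenic, applied across genes: a DMR in
#' gene A's gene body and gene B's proximal promoter is assigned P1.
#'
#' @param annotations Output of [intersect_dmrs_features()].
#' @return A `data.frame` with `dmr_id` and `assigned_class`.
#' @export
assign_primary_feature <- function(annotations) {
  rank <- match(annotations$feature_class, FEATURE_HIERARCHY)
  best <- tapply(rank, annotations$dmr_id, min)
  data.frame(dmr_id = names(best),
             assigned_class = FEATURE_HIERARCHY[as.integer(best)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' DMR density per feature class
#'
#' Number of assigned DMRs divided by the canonical feature length in bp:
#' the geometry spans for P1, GS and TTR; the effective distal window
#' (`p6_span - p1_span` when P6 excludes P1) for P6; and the mean
#' gene-body length over genes longer than `gs_span` for GB. Intergenic
#' has no defined length and gets `NA`.
#'
#' @param n_dmrs Named count vector (names among
#'   P6, P1, GS, GB, TTR, Intergenic).
#' @param geometry A [feature_geometry()].
#' @param mean_gb_length Mean gene-body length in bp (see
#'   [mean_gene_body_length()]).
#' @return Named numeric vector of densities (DMRs per bp).
#' @export
feature_density <- function(n_dmrs, geometry = feature_geometry(),
                            mean_gb_length) {
  if (!is.null(n_dmrs["GB"]) && !is.na(n_dmrs["GB"]) && n_dmrs["GB"] > 0 &&
      (missing(mean_gb_length) || !is.finite(mean_gb_length) ||
       mean_gb_length <= 0))
    stop("mean_gb_length must be positive")
  p6_len <- if (geometry$p6_excludes_p1)
    geometry$p6_span - geometry$p1_span else geometry$p6_span
  lens <- c(P6 = p6_len, P1 = geometry$p1_span, GS = geometry$gs_span,
            GB = if (missing(mean_gb_length)) NA_real_ else mean_gb_length,
            TTR = geometry$ttr_span, Intergenic = NA_real_)
  out <- n_dmrs / lens[names(n_dmrs)]
  stats::setNames(as.numeric(out), names(n_dmrs))
}

#' Mean methylation per DMR per sample
#'
#' Count-weighted `sum(meth)/sum(total)` over the DMR's CpGs for each
#' sample; `NA` where the sample has no coverage over the region.
#'
#' @param mat A `methylation_matrix`.
#' @param dmrs A `data.frame` with `contig`, `start`, `end`
#'   (0-based half-open) and optionally `dmr_id`.
#' @return Numeric matrix, DMRs x samples, rownames = `dmr_id`.
#' @export
dmr_mean_methylation <- function(mat, dmrs) {
  dmrs <- ensure_dmr_ids(dmrs)
  out <- matrix(NA_real_, nrow(dmrs), length(mat$samples),
                dimnames = list(dmrs$dmr_id, mat$samples))
  for (k in seq_len(nrow(dmrs))) {
    i <- mat$loci$contig == dmrs$contig[k] &
      mat$loci$position >= dmrs$start[k] & mat$loci$position < dmrs$end[k]
    if (!any(i)) next
    m <- colSums(mat$meth[i, , drop = FALSE])
    t <- colSums(mat$total[i, , drop = FALSE])
    out[k, ] <- ifelse(t > 0, m / t, NA_real_)
  }
  out
}

#' Pearson correlation with t-based p-value
#'
#' `r = cor(x, y)`; two-sided p from `t = r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom; `|r| = 1` gives `p = 0`. Pairs with a
#' missing value in either vector are dropped.
#'
#' @param x,y Paired numeric vectors.
#' @return A list with `r`, `p` and `n` (complete pairs used).
#' @export
correlate_meth_expr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1 - 1e-12) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Critical Pearson correlation at a two-sided level
#'
#' The significance boundary `|r*|` such that a sample correlation with
#' `|r| > r*` is significant at the given level for `n` pairs.
#'
#' @param n Number of pairs.
#' @param alpha Two-sided level.
#' @return The boundary in `(0, 1)`.
#' @export
critical_r <- function(n, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Correlate DMR methylation with gene expression per annotated pair
#'
#' Builds one link per (DMR, gene) pair that has at least one feature
#' annotation and expression data: the pair's feature class is the
#' highest-ranked class among that gene's annotations for the DMR, the
#' methylation value per sample is the DMR's count-weighted mean level,
#' and the expression value the gene's normalized count. Only samples
#' present in both data sets are used; pairs with fewer than
#' `min_pairs` complete observations or zero variance are recorded with
#' `NA` correlation.
#'
#' @param dmrs DMR records (with `dmr_id` or ids are generated in input
#'   order, matching [intersect_dmrs_features()]).
#' @param annotations Output of [intersect_dmrs_features()].
#' @param mat A `methylation_matrix`.
#' @param norm_expr Normalized expression matrix (genes x samples).
#' @param alpha Significance level on the correlation p-value.
#' @param min_pairs Minimum complete sample pairs per correlation.
#' @return A `data.frame` of links: `dmr_id`, `gene_id`, `assigned_class`,
#'   `r`, `p`, `n`, `significant`, `sign`.
#' @export
build_links <- function(dmrs, annotations, mat, norm_expr, alpha = 0.05,
                        min_pairs = 3L) {
  dmrs <- ensure_dmr_ids(dmrs)
  ann <- annotations[annotations$feature_class != "Intergenic" &
                       annotations$gene_id %in% rownames(norm_expr), ,
                     drop = FALSE]
  if (nrow(ann) == 0L)
    return(data.frame(dmr_id = character(), gene_id = character(),
                      assigned_class = character(), r = numeric(),
                      p = numeric(), n = integer(), significant = logical(),
                      sign = character()))
  shared <- intersect(mat$samples, colnames(norm_expr))
  if (length(shared) < min_pairs)
    stop("fewer than ", min_pairs, " samples with both data types")
  meth <- dmr_mean_methylation(mat, dmrs)[, shared, drop = FALSE]
  pair_key <- paste(ann$dmr_id, ann$gene_id)
  rank <- match(ann$feature_class, FEATURE_HIERARCHY)
  best <- tapply(rank, pair_key, min)
  pairs <- unique(ann[, c("dmr_id", "gene_id")])
  pairs$assigned_class <-
    FEATURE_HIERARCHY[as.integer(best[paste(pairs$dmr_id, pairs$gene_id)])]
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    x <- meth[pairs$dmr_id[k], ]
    y <- norm_expr[pairs$gene_id[k], shared]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < min_pairs || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
    correlate_meth_expr(x, y)
  })
  out <- data.frame(pairs,
                    r = vapply(res, `[[`, 0, "r"),
                    p = vapply(res, `[[`, 0, "p"),
                    n = vapply(res, function(z) as.integer(z$n), 0L),
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p) & out$p < alpha
  out$sign <- ifelse(is.na(out$r), NA,
                     ifelse(out$r > 0, "positive", "negative"))
  rownames(out) <- NULL
  out
}

#' Summarize DMR-gene links per feature class
#'
#' The correlation-integration summary: per feature class the number of
#' annotations (`n_annotations`; from `annotations` restricted to linked
#' pairs when supplied, else the number of link rows), the number of DMRs
#' assigned to the class by the hierarchy across that DMR's linked pairs
#' (`n_dmrs`), the number of those DMRs with at least one significant
#' correlation (`n_significant`), the percentage
#' `100 * n_significant / n_dmrs` to one decimal
#' (`proportion_significant`), and the number of DMRs with a significant
#' negative correlation (`n_negative`). A `Total` row is appended.
#'
#' @param links Output of [build_links()].
#' @param annotations Optional annotations for the `n_annotations` column.
#' @return A `data.frame`, one row per feature class plus `Total`.
#' @export
summarize_links <- function(links, annotations = NULL) {
  classes <- setdiff(FEATURE_HIERARCHY, "Intergenic")
  dmr_class <- if (nrow(links))
    assign_primary_feature(data.frame(dmr_id = links$dmr_id,
                                      feature_class = links$assigned_class))
  else data.frame(dmr_id = character(), assigned_class = character())
  sig_dmrs <- unique(links$dmr_id[links$significant %in% TRUE])
  neg_dmrs <- unique(links$dmr_id[links$significant %in% TRUE &
                                    links$sign == "negative"])
  rows <- lapply(classes, function(cl) {
    in_cl <- dmr_class$dmr_id[dmr_class$assigned_class == cl]
    n_a <- if (!is.null(annotations)) {
      linked <- paste(links$dmr_id, links$gene_id)
      sum(annotations$feature_class == cl &
            paste(annotations$dmr_id, annotations$gene_id) %in% linked)
    } else sum(links$assigned_class == cl)
    n_d <- length(in_cl)
    n_s <- length(intersect(in_cl, sig_dmrs))
    data.frame(feature_class = cl, n_annotations = n_a, n_dmrs = n_d,
               n_significant = n_s,
               proportion_significant =
                 if (n_d > 0) round(100 * n_s / n_d, 1) else NA_real_,
               n_negative = length(intersect(in_cl, neg_dmrs)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(feature_class = "Total",
                      n_annotations = sum(out$n_annotations),
                      n_dmrs = sum(out$n_dmrs),
                      n_significant = sum(out$n_significant),
                      proportion_significant = NA_real_,
                      n_negative = sum(out$n_negative))
  rbind(out, total)
}

#' Summarize DMR annotations per feature class
#'
#' The annotation-bookkeeping summary: per feature class the number of
#' annotations `N_A` (with, for gene start, the count contributed by
#' genes no longer than `gs_span` reported separately in
#' `n_a_short_gene`), the number of DMRs assigned by the hierarchy
#' `N_DMRs` (including Intergenic), and the DMR density per bp. A `Total`
#' row is appended.
#'
#' @param annotations Output of [intersect_dmrs_features()].
#' @param genes Gene models (for short-gene bookkeeping); optional.
#' @param geometry A [feature_geometry()].
#' @param mean_gb_length Mean gene-body length, bp.
#' @return A `data.frame` with one row per class (P6, P1, GS, GB, TTR,
#'   Intergenic) plus `Total`.
#' @export
summarize_annotations <- function(annotations, genes = NULL,
                                  geometry = feature_geometry(),
                                  mean_gb_length = NA_real_) {
  classes <- c("P6", "P1", "GS", "GB", "TTR", "Intergenic")
  assigned <- assign_primary_feature(annotations)
  n_a <- table(factor(annotations$feature_class, levels = classes))
  n_d <- table(factor(assigned$assigned_class, levels = classes))
  short <- rep(NA_integer_, length(classes))
  if (!is.null(genes)) {
    short_genes <- genes$gene_id[genes$end - genes$start <= geometry$gs_span]
    short[classes == "GS"] <-
      sum(annotations$feature_class == "GS" &
            annotations$gene_id %in% short_genes)
  }
  dens <- feature_density(stats::setNames(as.numeric(n_d), classes),
                          geometry, mean_gb_length)
  out <- data.frame(feature_class = classes,
                    n_annotations = as.integer(n_a),
                    n_a_short_gene = short,
                    n_dmrs = as.integer(n_d),
                    density = round(dens, 3),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$n_annotations[classes == "Intergenic"] <- NA_integer_
  rbind(out, data.frame(feature_class = "Total",
                        n_annotations = sum(out$n_annotations, na.rm = TRUE),
                        n_a_short_gene = NA_integer_,
                        n_dmrs = sum(out$n_dmrs),
                        density = NA_real_))
}
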