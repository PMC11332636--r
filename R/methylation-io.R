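#' Read per-sample cytosine methylation calls
#'
#' Supports the two Bismark text dialects: the coverage format
#' (`chrom, start, end, percent, meth, unmeth`; 1-based; already
#' destranded, so calls are read as `+` strand) and the CpG cytosine
#' report (`chrom, pos, strand, meth, unmeth, context, trinucleotide`;
#' 1-based; rows outside CpG context are dropped). Positions are converted
#' to 0-based.
#'
#' @param path Path to a tab-separated file.
#' @param format `"coverage"` or `"cytosine_report"`.
#' @return A `data.frame` of calls in file order with columns `contig`,
#'   `position` (0-based), `strand`, `meth`, `unmeth`.
#' @export
read_cytosine_report <- function(path, format = c("coverage", "cytosine_report")) {
  format <- match.arg(format)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1L))
  if (format == "coverage") {
    if (ncol(dt) < 6L) stop("coverage format needs 6 columns, got ", ncol(dt))
    out <- data.frame(contig = dt[[1L]],
                      position = as.integer(dt[[2L]]) - 1L,
                      strand = "+",
                      meth = as.integer(dt[[5L]]),
                      unmeth = as.integer(dt[[6L]]),
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(dt) < 6L) stop("cytosine_report format needs >= 6 columns, got ", ncol(dt))
    keep <- dt[[6L]] %in% c("CpG", "CG")
    dt <- dt[keep, ]
    out <- data.frame(contig = dt[[1L]],
                      position = as.integer(dt[[2L]]) - 1L,
                      strand = as.character(dt[[3L]]),
                      meth = as.integer(dt[[4L]]),
                      unmeth = as.integer(dt[[5L]]),
                      stringsAsFactors = FALSE)
    if (any(!out$strand %in% c("+", "-")))
      stop("cytosine_report strand column must be '+' or '-'")
  }
  if (any(out$meth < 0L) || any(out$unmeth < 0L))
    stop("negative methylation counts in ", path)
  out
}

#' Destrand CpG calls
#'
#' CpG methylation is symmetric across strands: the `-` strand cytosine of
#' a CpG sits one base downstream of the `+` strand cytosine. Calls on the
#' `-` strand at position `p` are re-anchored to `p - 1` and summed into
#' any `+` call there; orphan `-` calls simply move to the `+` anchor.
#' Total read counts are conserved.
#'
#' @param calls Calls from [read_cytosine_report()].
#' @return Destranded calls, one row per CpG locus, sorted by
#'   `(contig, position)`, with columns `contig`, `position`, `meth`,
#'   `unmeth`.
#' @export
merge_strands <- function(calls) {
  pos <- ifelse(calls$strand == "-", calls$position - 1L, calls$position)
  dt <- data.table::data.table(contig = calls$contig, position = pos,
                               meth = calls$meth, unmeth = calls$unmeth)
  out <- dt[, list(meth = sum(meth), unmeth = sum(unmeth)),
            by = c("contig", "position")]
  data.table::setorder(out, contig, position)
  as.data.frame(out)
}

#' Assemble a cross-sample CpG methylation matrix
#'
#' Takes destranded calls per sample and builds the loci-by-samples counts
#' matrix over the union of loci; a locus absent from a sample gets
#' `total = 0`. Duplicate positions within one sample are summed with a
#' warning.
#'
#' @param per_sample_calls Named list (sample id -> destranded calls from
#'   [merge_strands()]).
#' @param metadata A `data.frame` with columns `sample_id`, `size_class`
#'   (`"large"`/`"small"`), `feed`, and optionally `has_rna`; must cover
#'   every sample.
#' @return A `methylation_matrix`: a list with `loci` (`data.frame` of
#'   `contig`, `position`, sorted), `samples`, `meth` and `total`
#'   (loci x samples integer matrices) and `metadata` (rows aligned with
#'   `samples`).
#' @export
assemble_matrix <- function(per_sample_calls, metadata) {
  samples <- names(per_sample_calls)
  if (is.null(samples) || any(!nzchar(samples)))
    stop("per_sample_calls must be a named list")
  missing <- setdiff(samples, metadata$sample_id)
  if (length(missing))
    stop("metadata missing sample id(s): ", paste(missing, collapse = ", "))
  dts <- lapply(samples, function(s) {
    x <- per_sample_calls[[s]]
    dt <- data.table::as.data.table(x[, c("contig", "position", "meth", "unmeth")])
    if (anyDuplicated(dt, by = c("contig", "position"))) {
      warning("duplicate positions in sample ", s, "; counts summed")
      dt <- dt[, list(meth = sum(meth), unmeth = sum(unmeth)),
               by = c("contig", "position")]
    }
    dt$sample <- s
    dt
  })
  all <- data.table::rbindlist(dts)
  loci <- unique(all[, c("contig", "position")])
  data.table::setorder(loci, contig, position)
  key <- paste(loci$contig, loci$position)
  n <- nrow(loci)
  meth <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  total <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  for (k in seq_along(dts)) {
    dt <- dts[[k]]
    if (nrow(dt) == 0L) next
    i <- match(paste(dt$contig, dt$position), key)
    meth[i, samples[k]] <- dt$meth
    total[i, samples[k]] <- dt$meth + dt$unmeth
  }
  md <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  structure(list(loci = as.data.frame(loci), samples = samples,
                 meth = meth, total = total, metadata = md),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d CpG loci x %d samples (%d contigs)\n",
              nrow(x$loci), length(x$samples),
              length(unique(x$loci$contig))))
  invisible(x)
}

#' Subset a methylation matrix to a set of locus rows
#' @param mat A `methylation_matrix`.
#' @param i Logical or integer row index into `mat$loci`.
#' @return The subsetted `methylation_matrix`.
#' @export
subset_loci <- function(mat, i) {
  mat$loci <- mat$loci[i, , drop = FALSE]
  rownames(mat$loci) <- NULL
  mat$meth <- mat$meth[i, , drop = FALSE]
  mat$total <- mat$total[i, , drop = FALSE]
  mat
}

#' Keep only CpGs covered in every sample
#'
#' Retains exactly the loci with `total > 0` in every sample, in order;
#' the filter the DMR analysis requires. Idempotent.
#'
#' @param mat A `methylation_matrix`.
#' @return The filtered `methylation_matrix` (possibly with zero loci).
#' @export
filter_complete_coverage <- function(mat) {
  keep <- rowSums(mat$total > 0L) == length(mat$samples)
  subset_loci(mat, keep)
}

#' Per-sample global mean CpG methylation
#'
#' Count-weighted mean: `sum(meth) / sum(total)` over covered loci per
#' sample (the convention of sequencing-level methylation summaries), not
#' a mean of per-CpG levels. Samples with zero total coverage get `NA`.
#'
#' @param mat A `methylation_matrix`.
#' @return Named numeric vector of per-sample levels in `[0, 1]`.
#' @export
global_methylation_summary <- function(mat) {
  if (nrow(mat$loci) == 0L) stop("empty methylation matrix")
  tot <- colSums(mat$total)
  lev <- colSums(mat$meth) / tot
  lev[tot == 0] <- NA_real_
  lev
}

#' Write a methylation matrix sample to Bismark coverage format
#'
#' Emits the covered loci of one sample as 1-based coverage rows
#' (`chrom, pos, pos, percent, meth, unmeth`); re-reading with
#' [read_cytosine_report()] and [merge_strands()] reproduces the column.
#'
#' @param mat A `methylation_matrix`.
#' @param sample Sample id.
#' @param path Output path.
#' @export
write_coverage <- function(mat, sample, path) {
  j <- match(sample, mat$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  keep <- mat$total[, j] > 0L
  m <- mat$meth[keep, j]
  u <- mat$total[keep, j] - m
  pos1 <- mat$loci$position[keep] + 1L
  dt <- data.table::data.table(mat$loci$contig[keep], pos1, pos1,
                               100 * m / (m + u), m, u)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated with columns `sample_id`, `size_class`, `feed` and
#' optionally `has_rna` (logical).
#'
#' @param path Path to the metadata TSV.
#' @return A `data.frame`.
#' @export
read_sample_metadata <- function(path) {
  md <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  req <- c("sample_id", "size_class", "feed")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (!"has_rna" %in% names(md)) md$has_rna <- TRUE
  md$has_rna <- as.logical(md$has_rna)
  md
}
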