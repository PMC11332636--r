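#' Feature geometry for promoter/gene-body annotation
#'
#' Defines the spans of the five strand-aware genomic features built around
#' each gene: distal promoter (P6), proximal promoter (P1), gene start (GS),
#' gene body (GB) and transcription terminal region (TTR).
#'
#' @param p6_span Distal-promoter reach upstream of the TSS, bp.
#' @param p1_span Proximal-promoter span immediately upstream of the TSS, bp.
#' @param gs_span Gene-start span: the first `gs_span` bp of the gene.
#' @param ttr_span Terminal-region span downstream of the TTS, bp.
#' @param p6_excludes_p1 If `TRUE` (default) P6 covers `[-p6_span, -p1_span)`
#'   relative to the TSS, i.e. the distal window upstream of P1 (effective
#'   length `p6_span - p1_span`); if `FALSE` P6 covers the full
#'   `[-p6_span, 0)` window and overlaps P1.
#' @return An object of class `feature_geometry`.
#' @export
feature_geometry <- function(p6_span = 6000L, p1_span = 1000L,
                             gs_span = 1500L, ttr_span = 1000L,
                             p6_excludes_p1 = TRUE) {
  p6_span <- as.integer(p6_span); p1_span <- as.integer(p1_span)
  gs_span <- as.integer(gs_span); ttr_span <- as.integer(ttr_span)
  stopifnot(p6_span > 0L, p1_span > 0L, gs_span > 0L, ttr_span > 0L)
  if (p6_excludes_p1 && p6_span <= p1_span)
    stop("p6_span must exceed p1_span when p6_excludes_p1 is TRUE")
  structure(list(p6_span = p6_span, p1_span = p1_span, gs_span = gs_span,
                 ttr_span = ttr_span, p6_excludes_p1 = p6_excludes_p1),
            class = "feature_geometry")
}

#' Ranked feature classes
#'
#' Assignment hierarchy used to resolve a DMR touching several feature
#' classes to a single class: P1 > GS > P6 > GB > TTR > Intergenic.
#' @export
FEATURE_HIERARCHY <- c("P1", "GS", "P6", "GB", "TTR", "Intergenic")

#' Parse gene models from a GFF3 file
#'
#' Reads records of type `gene` and returns one gene model per record with
#' coordinates converted from GFF3 1-based inclusive to 0-based half-open.
#' The TSS is the strand-aware 5' terminus of the gene record (`start` on
#' `+`, `end - 1` on `-`) and the TTS the opposite terminus.
#'
#' @param gff_file Path to a GFF3 file. Need not be sorted.
#' @return A `data.frame` with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `tss`, `tts`.
#' @export
parse_gene_models <- function(gff_file) {
  lines <- readLines(gff_file, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(regmatches(lines[body], gregexpr("\t", lines[body], fixed = TRUE)))
  if (any(nfield != 8L)) {
    bad <- which(body)[which(nfield != 8L)[1L]]
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields", bad))
  }
  gr <- rtracklayer::import(gff_file, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L)
    return(data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      tss = integer(), tts = integer()))
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("gene record without an ID attribute")
  if (anyDuplicated(ids))
    stop("duplicate gene ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (any(end0 <= start0))
    stop("gene record with end < start: ", ids[which(end0 <= start0)[1L]])
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("gene record with undefined strand: ",
         ids[which(!strand %in% c("+", "-"))[1L]])
  minus <- strand == "-"
  data.frame(gene_id = ids,
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = start0, end = end0, strand = strand,
             tss = ifelse(minus, end0 - 1L, start0),
             tts = ifelse(minus, start0, end0 - 1L),
             stringsAsFactors = FALSE)
}

#' Build strand-aware feature intervals for each gene
#'
#' Emits up to five intervals per gene: P1 (`p1_span` bp immediately
#' upstream of the TSS), P6 (distal upstream window), GS (first `gs_span`
#' bp of the gene, or the whole gene when shorter), GB (remainder of the
#' gene; omitted when empty) and TTR (`ttr_span` bp downstream of the TTS).
#' Upstream/downstream are strand-aware and all intervals are clipped to
#' `[0, contig_length)`; intervals that vanish after clipping are dropped.
#'
#' @param genes Gene models as returned by [parse_gene_models()].
#' @param geometry A [feature_geometry()].
#' @param contig_lengths Named integer vector of contig lengths covering
#'   every gene's contig.
#' @return A `data.frame` with columns `gene_id`, `feature_class`, `contig`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @export
build_feature_intervals <- function(genes, geometry = feature_geometry(),
                                    contig_lengths) {
  stopifnot(inherits(geometry, "feature_geometry"))
  missing_ctg <- setdiff(unique(genes$contig), names(contig_lengths))
  if (length(missing_ctg))
    stop("contig length unknown for: ", paste(missing_ctg, collapse = ", "))
  if (nrow(genes) == 0L)
    return(data.frame(gene_id = character(), feature_class = character(),
                      contig = character(), start = integer(),
                      end = integer(), strand = character()))
  g <- geometry
  p6_inner <- if (g$p6_excludes_p1) g$p1_span else 0L
  one_gene <- function(i) {
    gn <- genes[i, ]
    len <- gn$end - gn$start
    if (gn$strand == "+") {
      iv <- list(
        P1 = c(gn$start - g$p1_span, gn$start),
        P6 = c(gn$start - g$p6_span, gn$start - p6_inner),
        GS = c(gn$start, gn$start + min(len, g$gs_span)),
        GB = c(gn$start + g$gs_span, gn$end),
        TTR = c(gn$end, gn$end + g$ttr_span))
    } else {
      iv <- list(
        P1 = c(gn$end, gn$end + g$p1_span),
        P6 = c(gn$end + p6_inner, gn$end + g$p6_span),
        GS = c(gn$end - min(len, g$gs_span), gn$end),
        GB = c(gn$start, gn$end - g$gs_span),
        TTR = c(gn$start - g$ttr_span, gn$start))
    }
    clen <- contig_lengths[[gn$contig]]
    keep <- vapply(iv, function(x) min(x[2L], clen) > max(x[1L], 0L), logical(1))
    iv <- iv[keep]
    if (!length(iv)) return(NULL)
    data.frame(gene_id = gn$gene_id,
               feature_class = names(iv),
               contig = gn$contig,
               start = as.integer(pmax(vapply(iv, `[`, 0, 1L), 0L)),
               end = as.integer(pmin(vapply(iv, `[`, 0, 2L), clen)),
               strand = gn$strand, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), one_gene))
  rownames(out) <- NULL
  out
}

#' Write feature intervals as BED6
#'
#' One BED6 file (0-based half-open) with `name = gene_id|feature_class`,
#' score 0 and the gene strand.
#'
#' @param intervals Output of [build_feature_intervals()].
#' @param path Output file path.
#' @export
write_feature_bed <- function(intervals, path) {
  bed <- data.frame(intervals$contig, intervals$start, intervals$end,
                    paste(intervals$gene_id, intervals$feature_class, sep = "|"),
                    0L, intervals$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean gene-body length
#'
#' Mean length of the gene-body (GB) feature over genes longer than
#' `gs_span`; the canonical GB length used for DMR density.
#'
#' @inheritParams build_feature_intervals
#' @return A single number (bp); `NA` if no gene exceeds `gs_span`.
#' @export
mean_gene_body_length <- function(genes, geometry = feature_geometry()) {
  len <- genes$end - genes$start
  gb <- len[len > geometry$gs_span] - geometry$gs_span
  if (!length(gb)) return(NA_real_)
  mean(gb)
}
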