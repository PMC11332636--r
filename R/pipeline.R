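#' Pipeline configuration
#'
#' Collects the file paths and per-stage settings of a full run. All
#' stochastic stages (PERMANOVA, DMR permutation null) derive their
#' streams from `seed`.
#'
#' @param gff Path to the gene annotation (GFF3).
#' @param coverage Named character vector of Bismark coverage files, one
#'   per sample (names are sample ids).
#' @param counts Path to the gene-count TSV, or `NULL` to skip the
#'   expression and integration stages.
#' @param metadata Path to the sample-metadata TSV.
#' @param outdir Output directory.
#' @param tile A [tile_config()].
#' @param geometry A [feature_geometry()].
#' @param dmr A [dmr_config()].
#' @param min_total,min_count,min_prevalence Gene-count filters, see
#'   [filter_genes()].
#' @param link_alpha Significance level for methylation-expression links.
#' @param permanova_n_perm Permutations for the PERMANOVA test.
#' @param reference Reference group (differences are reference minus
#'   other).
#' @param seed Master seed.
#' @param contig_lengths Named vector, or `NULL` to take lengths from the
#'   GFF3 `##sequence-region` pragmas (falling back to the furthest
#'   annotated coordinate plus the distal-promoter span).
#' @param resume If `TRUE` (default) a rerun against an output directory
#'   whose manifest records the same inputs and parameters skips all
#'   stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(gff, coverage, counts = NULL, metadata, outdir,
                            tile = tile_config(),
                            geometry = feature_geometry(),
                            dmr = dmr_config(),
                            min_total = 10L, min_count = 10L,
                            min_prevalence = 0.5,
                            link_alpha = 0.05, permanova_n_perm = 999L,
                            reference = "large", seed = 1L,
                            contig_lengths = NULL, resume = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

contig_lengths_from_gff <- function(gff, genes, geometry) {
  lines <- grep("^##sequence-region", readLines(gff, warn = FALSE),
                value = TRUE)
  if (length(lines)) {
    parts <- strsplit(trimws(lines), "\\s+")
    return(stats::setNames(vapply(parts, function(p) as.numeric(p[4L]), 0),
                           vapply(parts, `[`, "", 2L)))
  }
  tapply(genes$end + geometry$p6_span, genes$contig, max)
}

#' Run the full integration pipeline
#'
#' Stages, in order: methylation io (read, destrand, assemble), gene
#' features, global patterns (tiling, PCA, PERMANOVA, TSS metaprofile),
#' DMR detection, expression (filter, normalize, differential test) and
#' integration (annotation, links, summaries). Every stage writes its
#' tables under `outdir` and a `manifest.json` records input checksums,
#' parameters and stage timings. When `resume` is on and the manifest
#' matches the current inputs and parameters, the run is skipped and the
#' existing outputs returned.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a run report: list with `manifest`, `outputs`
#'   (named paths), `cached` flag and key in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$gff, config$coverage, config$counts, config$metadata))
    if (!file.exists(p)) stop("input file missing: ", p)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$outdir, "manifest.json")
  inputs <- c(config$gff, config$coverage, config$counts, config$metadata)
  params <- config[setdiff(names(config), c("outdir", "resume"))]
  run_hash <- digest_params(list(md5 = unname(tools::md5sum(inputs)),
                                 params = params))
  if (config$resume && file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path)
    if (identical(man$run_hash, run_hash) &&
        all(file.exists(file.path(config$outdir, unlist(man$outputs))))) {
      message("pipeline: inputs and parameters unchanged; using cached run")
      return(invisible(list(manifest = manifest_path,
                            outputs = file.path(config$outdir,
                                                unlist(man$outputs)),
                            cached = TRUE)))
    }
  }
  stages <- list(); outputs <- character()
  tic <- function() proc.time()[["elapsed"]]
  emit <- function(obj, name) {
    path <- file.path(config$outdir, name)
    data.table::fwrite(as.data.frame(obj), path, sep = "\t", quote = FALSE)
    outputs[[name]] <<- name
    path
  }

  t0 <- tic()
  md <- read_sample_metadata(config$metadata)
  calls <- lapply(config$coverage, function(p)
    merge_strands(read_cytosine_report(p, "coverage")))
  mat <- assemble_matrix(calls, md)
  emit(data.frame(sample_id = names(global_methylation_summary(mat)),
                  mean_methylation = unname(global_methylation_summary(mat))),
       "global_methylation.tsv")
  stages$methylation_io <- tic() - t0

  t0 <- tic()
  genes <- parse_gene_models(config$gff)
  clen <- if (is.null(config$contig_lengths))
    contig_lengths_from_gff(config$gff, genes, config$geometry)
  else config$contig_lengths
  feats <- build_feature_intervals(genes, config$geometry, clen)
  write_feature_bed(feats, file.path(config$outdir, "features.bed"))
  outputs[["features.bed"]] <- "features.bed"
  stages$genome_features <- tic() - t0

  t0 <- tic()
  tm <- tile_methylation(mat, config$tile)
  emit(cbind(tm$tiles, tm$levels), "tiles.tsv")
  pca <- tryCatch(meth_pca(tm), error = function(e) NULL)
  if (!is.null(pca))
    emit(data.frame(sample_id = rownames(pca$scores), pca$scores,
                    check.names = FALSE), "pca_scores.tsv")
  pmv <- permanova(tm, md$size_class, n_perm = config$permanova_n_perm,
                   seed = config$seed)
  emit(data.frame(r_squared = pmv$r_squared, pseudo_f = pmv$pseudo_f,
                  p = pmv$p, n_perm = pmv$n_perm), "permanova.tsv")
  prof <- tss_metaprofile(mat, genes)
  emit(prof, "tss_metaprofile.tsv")
  stages$global_patterns <- tic() - t0

  t0 <- tic()
  cc <- filter_complete_coverage(mat)
  dmr_cfg <- config$dmr
  dmr_cfg$seed <- config$seed
  dmrs <- call_dmrs(cc, md$size_class, md$feed, config$reference, dmr_cfg)
  dmrs <- ensure_dmr_ids(dmrs)
  emit(dmrs, "dmrs.tsv")
  emit(dmrs[, c("p", "delta_beta")], "dmr_volcano.tsv")
  stages$dmr_detection <- tic() - t0

  de <- NULL; links <- NULL; link_summary <- NULL; norm <- NULL
  if (!is.null(config$counts)) {
    t0 <- tic()
    counts <- read_counts(config$counts)
    rna_samples <- intersect(colnames(counts),
                             md$sample_id[md$has_rna])
    counts <- counts[, rna_samples, drop = FALSE]
    counts <- filter_genes(counts, config$min_total, config$min_count,
                           config$min_prevalence)
    sf <- size_factors(counts)
    norm <- normalize_counts(counts, sf)
    mdr <- md[match(rna_samples, md$sample_id), ]
    de <- differential_expression(counts, mdr$size_class, mdr$feed,
                                  config$reference, sf)
    emit(de, "differential_expression.tsv")
    mv <- ma_volcano_tables(de)
    emit(mv$ma, "ma_table.tsv")
    emit(mv$volcano, "de_volcano.tsv")
    stages$expression <- tic() - t0
  }

  t0 <- tic()
  cand <- dmrs[dmrs$candidate, , drop = FALSE]
  ann <- intersect_dmrs_features(cand, feats)
  emit(ann, "annotations.tsv")
  ann_summary <- summarize_annotations(ann, genes, config$geometry,
                                       mean_gene_body_length(genes,
                                                             config$geometry))
  emit(ann_summary, "annotation_summary.tsv")
  if (!is.null(norm)) {
    links <- build_links(cand, ann, mat, norm, config$link_alpha)
    emit(links, "links.tsv")
    link_summary <- summarize_links(links, ann)
    emit(link_summary, "link_summary.tsv")
  }
  stages$integration <- tic() - t0

  manifest <- list(run_hash = run_hash,
                   inputs = as.list(unname(tools::md5sum(inputs))),
                   parameters = params_for_manifest(config),
                   stage_seconds = stages,
                   outputs = as.list(unname(outputs)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest_path,
                 outputs = file.path(config$outdir, unname(outputs)),
                 cached = FALSE,
                 matrix = mat, genes = genes, features = feats,
                 tiles = tm, permanova = pmv, metaprofile = prof,
                 dmrs = dmrs, de = de, normalized = norm, links = links,
                 annotation_summary = ann_summary,
                 link_summary = link_summary))
}

digest_params <- function(x) {
  # order-stable structural hash without extra dependencies
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(json, f)
  unname(tools::md5sum(f))
}

params_for_manifest <- function(config) {
  note <- function(x, assumption = FALSE)
    list(value = x, assumption = assumption)
  list(tile = config$tile[names(config$tile) != "class"],
       geometry = unclass(config$geometry),
       dmr = c(unclass(config$dmr)[c("cutoff", "min_cpgs", "candidate_alpha")],
               lapply(unclass(config$dmr)[c("max_gap", "smooth_bw",
                                            "n_perm")],
                      function(v) note(v, assumption = TRUE))),
       expression = list(min_total = config$min_total,
                         min_count = config$min_count,
                         min_prevalence = config$min_prevalence),
       link_alpha = config$link_alpha,
       reference = config$reference,
       seed = config$seed)
}

#' Render the annotation and correlation summary tables
#'
#' Reads the integration outputs under `outdir` and prints the two
#' bookkeeping tables: DMR annotations per feature class (N_A, N_DMRs,
#' density to 3 decimals; Intergenic density rendered as `-`) and the
#' methylation-expression correlation summary (significant counts and
#' percentage to 1 decimal).
#'
#' @param outdir A pipeline output directory.
#' @return Invisibly, a list of the two `data.frame`s.
#' @export
summarize_tables <- function(outdir) {
  fmt <- function(x, digits) ifelse(is.na(x), "-",
                                    formatC(x, digits = digits,
                                            format = "f"))
  ann_path <- file.path(outdir, "annotation_summary.tsv")
  if (!file.exists(ann_path)) stop("integration outputs missing in ", outdir)
  ann <- as.data.frame(data.table::fread(ann_path, sep = "\t"))
  cat("DMR annotation per genomic feature\n")
  print(data.frame(Feature = ann$feature_class,
                   N_A = ifelse(is.na(ann$n_annotations), "-",
                                ifelse(!is.na(ann$n_a_short_gene) &
                                         ann$n_a_short_gene > 0,
                                       sprintf("%d (+%d)",
                                               ann$n_annotations -
                                                 ann$n_a_short_gene,
                                               ann$n_a_short_gene),
                                       as.character(ann$n_annotations))),
                   N_DMRs = ann$n_dmrs,
                   Density = fmt(ann$density, 3)), row.names = FALSE)
  out <- list(annotation_summary = ann)
  link_path <- file.path(outdir, "link_summary.tsv")
  if (file.exists(link_path)) {
    ls <- as.data.frame(data.table::fread(link_path, sep = "\t"))
    cat("\nMethylation-expression correlation per genomic feature\n")
    print(data.frame(Feature = ls$feature_class, N_A = ls$n_annotations,
                     N_DMRs = ls$n_dmrs, Significant = ls$n_significant,
                     Proportion = fmt(ls$proportion_significant, 1),
                     Negative = ls$n_negative), row.names = FALSE)
    out$link_summary <- ls
  }
  invisible(out)
}
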