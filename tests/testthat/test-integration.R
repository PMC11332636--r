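test_that("DMR-feature intersection keeps per-gene, per-class annotations", {
  genes <- data.frame(gene_id = c("A", "B"), contig = "c",
                      start = c(10000L, 11000L), end = c(20000L, 18000L),
                      strand = "+")
  genes$tss <- genes$start; genes$tts <- genes$end - 1L
  feats <- build_feature_intervals(genes, feature_geometry(), c(c = 50000L))
  # DMR spanning A's P1/GS boundary
  dmr1 <- data.frame(dmr_id = "d1", contig = "c", start = 9900L, end = 10100L)
  ann1 <- intersect_dmrs_features(dmr1, feats)
  expect_setequal(ann1$feature_class[ann1$gene_id == "A"], c("P1", "GS"))
  # inside A's GS and B's P1 (cross-gene overlap)
  dmr2 <- data.frame(dmr_id = "d2", contig = "c", start = 10400L,
                     end = 10500L)
  ann2 <- intersect_dmrs_features(dmr2, feats)
  expect_setequal(paste(ann2$gene_id, ann2$feature_class),
                  c("A GS", "B P1"))
  # no overlap -> Intergenic
  dmr3 <- data.frame(dmr_id = "d3", contig = "c", start = 40000L,
                     end = 40100L)
  ann3 <- intersect_dmrs_features(dmr3, feats)
  expect_equal(ann3$feature_class, "Intergenic")
  expect_true(is.na(ann3$gene_id))
})

test_that("sweep intersection equals the quadratic brute-force oracle", {
  set.seed(51)
  for (trial in 1:5) {
    n_f <- 150L; n_d <- 50L
    feats <- data.frame(gene_id = sprintf("g%03d", sample(40, n_f, TRUE)),
                        feature_class = sample(c("P6", "P1", "GS", "GB",
                                                 "TTR"), n_f, TRUE),
                        contig = sample(c("c1", "c2"), n_f, TRUE),
                        start = sample(0:5000, n_f, TRUE))
    feats$end <- feats$start + sample(50:800, n_f, TRUE)
    feats <- unique(feats)
    dmrs <- data.frame(dmr_id = sprintf("d%03d", seq_len(n_d)),
                       contig = sample(c("c1", "c2"), n_d, TRUE),
                       start = sample(0:5000, n_d, TRUE))
    dmrs$end <- dmrs$start + sample(20:600, n_d, TRUE)
    got <- intersect_dmrs_features(dmrs, feats)
    got <- got[got$feature_class != "Intergenic", ]
    want <- oracle_overlap(dmrs, feats)
    key <- function(x) sort(paste(x$dmr_id, x$gene_id, x$feature_class))
    expect_equal(key(got), key(want))
  }
})

test_that("hierarchy assignment picks the highest-ranked class across genes", {
  ann <- data.frame(dmr_id = c("d1", "d1", "d2", "d2", "d3"),
                    gene_id = c("A", "A", "A", "B", NA),
                    feature_class = c("GS", "GB", "GB", "P1", "Intergenic"))
  got <- assign_primary_feature(ann)
  expect_equal(got$assigned_class[got$dmr_id == "d1"], "GS")
  expect_equal(got$assigned_class[got$dmr_id == "d2"], "P1")
  expect_equal(got$assigned_class[got$dmr_id == "d3"], "Intergenic")
})

test_that("DMR density reproduces the published worked-example arithmetic", {
  counts <- c(P6 = 140, P1 = 109, GS = 74, GB = 423, TTR = 33,
              Intergenic = 278)
  dens <- feature_density(counts, feature_geometry(),
                          mean_gb_length = 423 / 0.014)
  expect_equal(round(dens[["P1"]], 3), 0.109)
  expect_equal(round(dens[["GS"]], 3), 0.049)
  expect_equal(round(dens[["P6"]], 3), 0.028)
  expect_equal(round(dens[["TTR"]], 3), 0.033)
  expect_true(is.na(dens[["Intergenic"]]))
  expect_error(feature_density(counts, feature_geometry(),
                               mean_gb_length = -5), "positive")
})

test_that("per-DMR mean methylation is count-weighted with NA on no coverage", {
  mat <- make_mat("c", c(100L, 150L, 400L),
                  meth = cbind(c(4L, 0L, 3L), c(2L, 2L, 0L)),
                  total = cbind(c(4L, 4L, 4L), c(4L, 4L, 0L)))
  dmr <- data.frame(dmr_id = c("d1", "d2"), contig = "c",
                    start = c(90L, 390L), end = c(160L, 410L))
  mm <- dmr_mean_methylation(mat, dmr)
  expect_equal(mm["d1", ], c(s01 = 0.5, s02 = 0.5))
  expect_equal(unname(mm["d2", "s01"]), 0.75)
  expect_true(is.na(mm["d2", "s02"]))
})

test_that("Pearson correlation machinery matches its contracts", {
  x <- c(0.1, 0.4, 0.5, 0.9)
  out <- correlate_meth_expr(x, -x)
  expect_equal(out$r, -1)
  expect_equal(out$p, 0)
  expect_error(correlate_meth_expr(rep(0.5, 4), x), "variance")
  expect_error(correlate_meth_expr(x[1:2], x[1:2]), "3")

  # significance boundary at n = 17 against a t-quantile oracle
  n <- 17L
  tc <- qt(0.975, n - 2)
  r_star <- tc / sqrt(n - 2 + tc^2)
  expect_equal(critical_r(17), r_star)
  above <- make_cor_pair(n, r_star + 0.01, seed = 2)
  below <- make_cor_pair(n, r_star - 0.01, seed = 2)
  expect_lt(correlate_meth_expr(above$x, above$y)$p, 0.05)
  expect_gt(correlate_meth_expr(below$x, below$y)$p, 0.05)
})

test_that("t-based correlation p matches exhaustive permutation p at small n", {
  set.seed(53)
  x <- rnorm(7); y <- 0.6 * x + rnorm(7, sd = 0.8)
  obs <- abs(cor(x, y))
  perms <- all_perms(7)
  perm_p <- mean(vapply(perms, function(pp) abs(cor(x, y[pp])) >= obs - 1e-12,
                        TRUE))
  expect_equal(correlate_meth_expr(x, y)$p, perm_p, tolerance = 0.05)
})

test_that("links carry the per-pair hierarchy class and significance flags", {
  set.seed(54)
  n <- 10L
  pos <- c(seq(9500L, 9580L, by = 20L), seq(10020L, 10100L, by = 20L))
  genes <- data.frame(gene_id = "A", contig = "c", start = 10000L,
                      end = 20000L, strand = "+", tss = 10000L, tts = 19999L)
  feats <- build_feature_intervals(genes, feature_geometry(), c(c = 50000L))
  meth_lv <- matrix(rep(seq(0.2, 0.65, by = 0.05), each = length(pos)),
                    length(pos), n)       # exact multiples of 1/20
  mat <- make_mat("c", pos, meth = round(meth_lv * 20),
                  total = matrix(20L, length(pos), n))
  dmr <- data.frame(dmr_id = "d1", contig = "c", start = 9500L, end = 10102L)
  ann <- intersect_dmrs_features(dmr, feats)
  expect_setequal(ann$feature_class, c("P1", "GS"))
  expr <- matrix(seq(100, 10, length.out = n), 1, n,
                 dimnames = list("A", mat$samples))
  links <- build_links(dmr, ann, mat, expr)
  expect_equal(nrow(links), 1L)            # one link per (DMR, gene) pair
  expect_equal(links$assigned_class, "P1") # hierarchy within the pair
  expect_equal(links$r, -1)
  expect_true(links$significant)
  expect_equal(links$sign, "negative")
})

test_that("link summaries reproduce the published correlation bookkeeping", {
  mk <- function(cls, n, n_sig, n_neg) {
    data.frame(dmr_id = sprintf("%s%03d", cls, 1:n),
               gene_id = sprintf("gene_%s%03d", cls, 1:n),
               assigned_class = cls, r = c(rep(-0.6, n_neg),
                                           rep(0.6, n_sig - n_neg),
                                           rep(0.1, n - n_sig)),
               p = c(rep(0.01, n_sig), rep(0.5, n - n_sig)),
               n = 17L,
               significant = c(rep(TRUE, n_sig), rep(FALSE, n - n_sig)),
               sign = c(rep("negative", n_neg), rep("positive", n - n_neg)))
  }
  links <- rbind(mk("P6", 71, 2, 0), mk("P1", 38, 7, 6), mk("GS", 27, 4, 1),
                 mk("GB", 225, 9, 8), mk("TTR", 35, 0, 0))
  s <- summarize_links(links)
  get <- function(cl, col) s[s$feature_class == cl, col]
  expect_equal(get("P6", "proportion_significant"), 2.8)
  expect_equal(get("P1", "proportion_significant"), 18.4)
  expect_equal(get("GS", "proportion_significant"), 14.8)
  expect_equal(get("GB", "proportion_significant"), 4.0)
  expect_equal(get("TTR", "proportion_significant"), 0)
  expect_equal(get("Total", "n_significant"), 22)
  expect_equal(get("Total", "n_negative"), 15)
  expect_equal(get("Total", "n_dmrs"), 396)
})

test_that("annotation bookkeeping satisfies the partition and N_A inequalities", {
  set.seed(55)
  n <- 25L
  start <- cumsum(sample(12000:20000, n)) + 8000L
  len <- sample(c(800L, 2000L, 5000L), n, TRUE)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:n), contig = "c",
                      start = start, end = start + len,
                      strand = sample(c("+", "-"), n, TRUE))
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  genes$tts <- ifelse(genes$strand == "-", genes$start, genes$end - 1L)
  feats <- build_feature_intervals(genes, feature_geometry(),
                                   c(c = max(genes$end) + 20000L))
  dmrs <- data.frame(dmr_id = sprintf("d%02d", 1:40),
                     contig = "c", start = sample(0:max(genes$end), 40))
  dmrs$end <- dmrs$start + sample(100:2000, 40, TRUE)
  ann <- intersect_dmrs_features(dmrs, feats)
  assigned <- assign_primary_feature(ann)
  # partition: every DMR appears exactly once
  expect_setequal(assigned$dmr_id, dmrs$dmr_id)
  expect_equal(anyDuplicated(assigned$dmr_id), 0L)
  s <- summarize_annotations(ann, genes, feature_geometry(),
                             mean_gene_body_length(genes, feature_geometry()))
  tot <- s[s$feature_class == "Total", ]
  expect_gte(tot$n_annotations, tot$n_dmrs -
               s$n_dmrs[s$feature_class == "Intergenic"])
  expect_equal(tot$n_dmrs, 40L)
})
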