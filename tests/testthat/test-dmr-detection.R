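# Matrix with exact per-sample levels at unit coverage scale.
level_mat <- function(position, levels_by_sample, scale = 10L,
                      size_class, feed = NULL) {
  lv <- as.matrix(levels_by_sample)
  if (is.null(feed)) feed <- rep("Feed1", ncol(lv))
  make_mat("c", position, meth = round(lv * scale),
           total = matrix(scale, nrow(lv), ncol(lv)),
           size_class = size_class, feed = feed)
}

test_that("per-CpG differences are stratified, weighted means", {
  mat <- level_mat(10L, rbind(c(0.8, 0.8, 0.6, 0.6)),
                   size_class = c("large", "large", "small", "small"))
  d <- per_cpg_difference(mat, mat$metadata$size_class, NULL, "large")
  expect_equal(d$d, 0.2)
  expect_equal(d$d_smooth, 0.2)            # isolated CpG: smoothing identity

  # two strata, d = 0.2 and 0.0, equal sizes -> 0.1
  mat2 <- level_mat(10L, rbind(c(0.8, 0.6, 0.7, 0.7)),
                    size_class = c("large", "small", "large", "small"),
                    feed = c("F1", "F1", "F2", "F2"))
  d2 <- per_cpg_difference(mat2, mat2$metadata$size_class,
                           mat2$metadata$feed, "large")
  expect_equal(d2$d, 0.1)

  # stratum with a single group is excluded with a warning
  mat3 <- level_mat(10L, rbind(c(0.8, 0.6, 0.9, 0.9)),
                    size_class = c("large", "small", "large", "large"),
                    feed = c("F1", "F1", "F2", "F2"))
  expect_warning(
    d3 <- per_cpg_difference(mat3, mat3$metadata$size_class,
                             mat3$metadata$feed, "large"),
    "excluded")
  expect_equal(d3$d, 0.2)
  mat4 <- level_mat(10L, rbind(c(0.8, 0.8)), size_class = c("large", "large"),
                    feed = c("F1", "F1"))
  expect_error(per_cpg_difference(mat4, mat4$metadata$size_class, NULL,
                                  "large"))
})

test_that("region construction respects cutoff, sign, gap and size rules", {
  base <- list(loci = data.frame(contig = "c",
                                 position = seq(0L, by = 100L,
                                                length.out = 12L)),
               d = rep(0.08, 12), d_smooth = rep(0.08, 12),
               s2 = rep(0.02, 12))
  class(base) <- "cpg_differences"
  cfg <- dmr_config(smooth_bw = 0L)

  six <- base
  six$d_smooth <- c(rep(0.08, 6), rep(0, 6))
  r <- find_candidate_regions(six, cfg)
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_cpgs, 6L)
  expect_equal(c(r$start, r$end), c(0L, 502L))

  four <- base
  four$d_smooth <- c(rep(0.08, 4), rep(0, 8))
  expect_equal(nrow(find_candidate_regions(four, cfg)), 0L)

  signs <- base
  signs$d_smooth <- c(rep(0.08, 5), rep(-0.08, 5), 0, 0)
  r2 <- find_candidate_regions(signs, cfg)
  expect_equal(nrow(r2), 2L)
  expect_equal(r2$n_cpgs, c(5L, 5L))

  gap <- base
  gap$loci$position[7:12] <- gap$loci$position[7:12] + 2000L
  r3 <- find_candidate_regions(gap, cfg)
  expect_equal(nrow(r3), 2L)
})

test_that("the region statistic is a variance-standardized signed sum", {
  diffs <- list(loci = data.frame(contig = "c", position = 1:6 * 100L),
                d = rep(0, 6), s2 = rep(0.05, 6))
  reg <- data.frame(contig = "c", start = 100L, end = 602L, n_cpgs = 6L,
                    i_first = 1L, i_last = 6L)
  expect_equal(region_statistic(reg, diffs), 0)

  diffs$d <- rep(0.1, 6)
  s6 <- region_statistic(reg, diffs)
  reg3 <- reg; reg3$i_last <- 3L
  expect_equal(s6, 2 * region_statistic(reg3, diffs))  # additivity

  # independent single-pass oracle on a worked toy, 3 samples per group
  lv <- rbind(c(0.9, 0.8, 0.85, 0.55, 0.6, 0.5),
              c(0.7, 0.75, 0.8, 0.5, 0.45, 0.6),
              c(0.95, 0.85, 0.9, 0.6, 0.65, 0.55))
  mat <- level_mat(c(100L, 160L, 220L), lv, scale = 20L,
                   size_class = rep(c("large", "small"), each = 3))
  diffs2 <- per_cpg_difference(mat, mat$metadata$size_class, NULL, "large")
  reg2 <- find_candidate_regions(diffs2, dmr_config(min_cpgs = 3L))
  got <- region_statistic(reg2, diffs2)
  oracle <- 0
  for (i in 1:3) {
    x <- mat$meth[i, ] / mat$total[i, ]
    di <- mean(x[1:3]) - mean(x[4:6])
    s2 <- (sum((x[1:3] - mean(x[1:3]))^2) +
             sum((x[4:6] - mean(x[4:6]))^2)) / 4
    oracle <- oracle + di / sqrt(s2 + 0.01)
  }
  expect_equal(got, oracle)
})

test_that("direction classification and the hyper/hypo summary", {
  expect_equal(classify_direction(c(0.12, -0.07)), c("hyper", "hypo"))
  expect_warning(classify_direction(0), "zero")
  labels <- classify_direction(c(rep(0.1, 576), rep(-0.1, 481)))
  tab <- table(labels)
  expect_equal(round(100 * tab[["hyper"]] / sum(tab), 1), 54.5)
  expect_equal(round(100 * tab[["hypo"]] / sum(tab), 1), 45.5)
})

test_that("permutation p-values equal an exhaustive brute-force oracle", {
  set.seed(31)
  n_cpg <- 40L
  pos <- sort(sample.int(20000L, n_cpg))
  lv <- matrix(runif(n_cpg * 6, 0.55, 0.95), n_cpg, 6)
  lv[11:20, 1:3] <- lv[11:20, 1:3] + 0.04   # modest planted block
  lv <- pmin(lv, 1)
  mat <- level_mat(pos, lv, scale = 20L,
                   size_class = rep(c("large", "small"), each = 3))
  cfg <- dmr_config(cutoff = 0.02, min_cpgs = 3L, max_gap = 20000L,
                    smooth_bw = 300L, n_perm = 100L, seed = 5L)
  got <- call_dmrs(mat, mat$metadata$size_class, NULL, "large", cfg)
  expect_true(attr(got, "exhaustive"))

  # oracle: naive reimplementation over all 20 relabelings of 3v3
  lev <- mat$meth / mat$total
  naive_stats <- function(ref_idx) {
    d <- rowMeans(lev[, ref_idx, drop = FALSE]) -
      rowMeans(lev[, -ref_idx, drop = FALSE])
    dsm <- vapply(seq_len(n_cpg), function(i)
      mean(d[abs(pos - pos[i]) <= 300]), 0)
    s2 <- vapply(seq_len(n_cpg), function(i) {
      a <- lev[i, ref_idx]; b <- lev[i, -ref_idx]
      (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4
    }, 0)
    ok <- abs(dsm) >= cfg$cutoff - 1e-9
    stats <- c(); k <- 1L
    while (k <= n_cpg) {
      if (!ok[k]) { k <- k + 1L; next }
      j <- k
      while (j < n_cpg && ok[j + 1L] && sign(dsm[j + 1L]) == sign(dsm[k]) &&
             pos[j + 1L] - pos[j] <= cfg$max_gap) j <- j + 1L
      if (j - k + 1L >= cfg$min_cpgs)
        stats <- c(stats, sum(d[k:j] / sqrt(s2[k:j] + 0.01)))
      k <- j + 1L
    }
    stats
  }
  combs <- combn(6, 3, simplify = FALSE)
  obs_stats <- naive_stats(1:3)
  null_stats <- unlist(lapply(combs[!vapply(combs, identical, TRUE, 1:3)],
                              naive_stats))
  expect_equal(length(combs), 20L)
  p_oracle <- vapply(obs_stats, function(s)
    (1 + sum(abs(null_stats) >= abs(s) - 1e-12)) / (1 + length(null_stats)), 0)
  expect_equal(got$stat, obs_stats)
  expect_equal(got$p, p_oracle)
})

test_that("label swap negates statistics and deltas, p unchanged; deterministic", {
  set.seed(33)
  ds <- quick_sim(seed = 33, n_contigs = 1L, contig_length = 120000L,
                  n_genes = 4L, n_planted_dmrs = 3L)
  mat <- filter_complete_coverage(assemble_matrix(ds$meth$calls, ds$metadata))
  cfg <- dmr_config(n_perm = 50L, seed = 2L)
  a <- call_dmrs(mat, ds$metadata$size_class, ds$metadata$feed, "large", cfg)
  b <- call_dmrs(mat, ds$metadata$size_class, ds$metadata$feed, "small", cfg)
  expect_equal(a$stat, -b$stat)
  expect_equal(a$delta_beta, -b$delta_beta)
  expect_equal(a$p, b$p)
  a2 <- call_dmrs(mat, ds$metadata$size_class, ds$metadata$feed, "large", cfg)
  expect_identical(a, a2)

  # raising the cutoff never increases the number of candidates
  strict <- dmr_config(cutoff = 0.12, n_perm = 50L, seed = 2L)
  expect_lte(sum(call_dmrs(mat, ds$metadata$size_class, ds$metadata$feed,
                           "large", strict)$candidate),
             sum(a$candidate))
})

test_that("no qualifying region yields an empty record set", {
  mat <- level_mat(c(100L, 200L), rbind(c(0.8, 0.8, 0.8, 0.8),
                                        c(0.7, 0.7, 0.7, 0.7)),
                   size_class = c("large", "large", "small", "small"))
  out <- call_dmrs(mat, mat$metadata$size_class, NULL, "large",
                   dmr_config(n_perm = 10L))
  expect_equal(nrow(out), 0L)
})
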