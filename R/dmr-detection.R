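#' DMR caller configuration
#'
#' Parameters of the smoothed-difference, label-permutation DMR caller.
#'
#' @param cutoff Minimum absolute smoothed methylation difference for a CpG
#'   to seed a region.
#' @param min_cpgs Minimum CpGs per region.
#' @param max_gap Maximum distance (bp) between consecutive CpGs within a
#'   region.
#' @param smooth_bw Half-window (bp) of the running-mean smoother applied
#'   to per-CpG differences.
#' @param n_perm Number of label permutations for the null.
#' @param seed Integer seed for the permutation stream.
#' @param candidate_alpha Permutation p-value below which a region is
#'   flagged a candidate DMR. Raw, not multiplicity-adjusted: the caller
#'   deliberately reports raw permutation p-values.
#' @return An object of class `dmr_config`.
#' @export
dmr_config <- function(cutoff = 0.05, min_cpgs = 5L, max_gap = 1000L,
                       smooth_bw = 500L, n_perm = 1000L, seed = 1L,
                       candidate_alpha = 0.01) {
  stopifnot(cutoff > 0, cutoff < 1, min_cpgs >= 2L, max_gap > 0L,
            smooth_bw >= 0L, n_perm >= 1L)
  structure(list(cutoff = cutoff, min_cpgs = as.integer(min_cpgs),
                 max_gap = as.integer(max_gap),
                 smooth_bw = as.integer(smooth_bw),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 candidate_alpha = candidate_alpha),
            class = "dmr_config")
}

#' Per-CpG raw and smoothed methylation differences
#'
#' Per-sample levels are `meth/total` on a complete-coverage matrix. The
#' raw difference at each CpG is the mean level in the reference group
#' minus the mean in the other group, computed within each stratum (e.g.
#' feed type) and combined across strata weighted by stratum sample count.
#' Strata containing only one group are excluded with a warning. The
#' smoothed difference is the running mean of the raw difference over CpGs
#' within `smooth_bw` bp on the same contig. Also returns the pooled
#' within-group between-sample variance of levels per CpG, used by the
#' region statistic.
#'
#' @param mat A complete-coverage `methylation_matrix`.
#' @param group Group label per sample (exactly 2 groups).
#' @param strata Stratum label per sample, or `NULL` for a single stratum.
#' @param reference Reference group label; differences are reference minus
#'   other.
#' @param smooth_bw Smoothing half-window, bp.
#' @return A list of class `cpg_differences` with `loci`, `d` (raw),
#'   `d_smooth`, `s2` (pooled variance) and the labels used.
#' @export
per_cpg_difference <- function(mat, group, strata = NULL,
                               reference = "large", smooth_bw = 500L) {
  if (any(mat$total == 0L))
    stop("matrix must be complete-coverage filtered (total > 0 everywhere)")
  group <- as.character(group)
  stopifnot(length(group) == length(mat$samples))
  if (length(unique(group)) != 2L) stop("exactly two groups required")
  if (!reference %in% group) stop("reference group not present: ", reference)
  if (is.null(strata)) strata <- rep("all", length(group))
  strata <- as.character(strata)
  lev <- mat$meth / mat$total
  d <- stratified_difference(lev, group, strata, reference)
  d_smooth <- smooth_by_position(d, mat$loci$contig, mat$loci$position,
                                 smooth_bw)
  structure(list(loci = mat$loci, d = d, d_smooth = d_smooth,
                 s2 = pooled_group_variance(lev, group),
                 group = group, strata = strata, reference = reference,
                 levels = lev, smooth_bw = as.integer(smooth_bw)),
            class = "cpg_differences")
}

# Stratum-weighted reference-minus-other mean difference per CpG row.
stratified_difference <- function(lev, group, strata, reference) {
  usable <- intersect(unique(strata),
                      names(which(tapply(group, strata,
                                         function(g) length(unique(g)) == 2L))))
  dropped <- setdiff(unique(strata), usable)
  if (length(dropped)) {
    warning("stratum with a single group excluded: ",
            paste(dropped, collapse = ", "))
    if (!length(usable)) stop("no stratum contains both groups")
  }
  num <- 0; den <- 0
  for (s in usable) {
    in_s <- strata == s
    r <- in_s & group == reference
    o <- in_s & group != reference
    d_s <- rowMeans(lev[, r, drop = FALSE]) - rowMeans(lev[, o, drop = FALSE])
    w <- sum(in_s)
    num <- num + w * d_s
    den <- den + w
  }
  num / den
}

# Pooled within-group sample variance per CpG row (n - 2 denominator).
pooled_group_variance <- function(lev, group) {
  ss <- 0
  n <- length(group)
  for (g in unique(group)) {
    x <- lev[, group == g, drop = FALSE]
    ng <- ncol(x)
    ss <- ss + rowSums(x^2) - rowSums(x)^2 / ng
  }
  ss / (n - 2L)
}

# Running mean of x over entries within +/- bw bp on the same contig.
# Positions must be sorted within contig.
smooth_by_position <- function(x, contig, position, bw) {
  out <- numeric(length(x))
  for (ctg in unique(contig)) {
    i <- which(contig == ctg)
    pos <- position[i]
    cs0 <- c(0, cumsum(x[i]))
    lo <- findInterval(pos - bw - 0.5, pos) + 1L
    hi <- findInterval(pos + bw + 0.5, pos)
    out[i] <- (cs0[hi + 1L] - cs0[lo]) / (hi - lo + 1L)
  }
  out
}

#' Find candidate regions from smoothed differences
#'
#' Maximal runs of consecutive CpGs whose smoothed difference exceeds the
#' cutoff in absolute value with constant sign, with inter-CpG gaps at
#' most `max_gap` bp and at least `min_cpgs` CpGs. Region bounds span the
#' first to last CpG plus the CpG dinucleotide
#' (`[first, last + 2)`).
#'
#' @param diffs A `cpg_differences` object.
#' @param config A [dmr_config()].
#' @return A `data.frame` of raw regions: `contig`, `start`, `end`,
#'   `n_cpgs`, `i_first`, `i_last` (row indices into `diffs$loci`).
#' @export
find_candidate_regions <- function(diffs, config = dmr_config()) {
  d <- diffs$d_smooth
  # the cutoff comparison tolerates summation-order float error
  ok <- !is.na(d) & abs(d) >= config$cutoff - 1e-9
  idx <- which(ok)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      i_first = integer(), i_last = integer())
  if (!length(idx)) return(empty)
  ctg <- diffs$loci$contig[idx]
  pos <- diffs$loci$position[idx]
  brk <- diff(idx) > 1L |
    ctg[-1L] != ctg[-length(ctg)] |
    diff(pos) > config$max_gap |
    sign(d[idx][-1L]) != sign(d[idx][-length(idx)])
  run <- cumsum(c(TRUE, brk))
  first <- idx[!duplicated(run)]
  last <- idx[!duplicated(run, fromLast = TRUE)]
  n <- last - first + 1L
  keep <- n >= config$min_cpgs
  if (!any(keep)) return(empty)
  data.frame(contig = diffs$loci$contig[first[keep]],
             start = diffs$loci$position[first[keep]],
             end = diffs$loci$position[last[keep]] + 2L,
             n_cpgs = n[keep],
             i_first = first[keep], i_last = last[keep],
             stringsAsFactors = FALSE)
}

#' Signed region statistic
#'
#' Variance-standardized sum over the region's CpGs:
#' `stat = sum_i d_i / sqrt(s_i^2 + eps)` with `d_i` the raw per-CpG
#' difference, `s_i^2` the pooled within-group between-sample variance at
#' CpG i, and `eps` a stabilizer for low-variance sites.
#'
#' @param regions Regions from [find_candidate_regions()].
#' @param diffs The `cpg_differences` the regions came from.
#' @param eps Variance stabilizer.
#' @return Numeric vector of signed statistics, one per region.
#' @export
region_statistic <- function(regions, diffs, eps = 0.01) {
  z <- diffs$d / sqrt(diffs$s2 + eps)
  vapply(seq_len(nrow(regions)),
         function(k) sum(z[regions$i_first[k]:regions$i_last[k]]), 0)
}

#' Classify DMR direction relative to the reference group
#'
#' `hyper` iff the raw mean methylation difference (reference minus other)
#' is positive, `hypo` iff negative; exact zeros are returned as `NA` with
#' a warning (they cannot occur for candidate regions, whose smoothed
#' difference clears the cutoff).
#'
#' @param delta_beta Numeric vector of region mean differences.
#' @return Character vector `"hyper"`/`"hypo"` (`NA` for zero).
#' @export
classify_direction <- function(delta_beta) {
  out <- ifelse(delta_beta > 0, "hyper", ifelse(delta_beta < 0, "hypo", NA))
  if (anyNA(out)) warning("zero delta_beta: direction undefined")
  out
}

#' Detect DMRs with a stratified label-permutation null
#'
#' Runs the full caller: observed per-CpG differences, region
#' construction and region statistics; then, for each permutation of
#' group labels (shuffled within strata so feed-type structure is
#' preserved), the entire pipeline is re-run and all resulting region
#' statistics are pooled into one null set. The p-value of an observed
#' region is `(1 + #{|null stat| >= |observed stat|}) / (1 + N_null)`.
#' When the number of distinct relabelings (excluding the observed one)
#' is at most `n_perm` they are enumerated exhaustively. Regions with
#' `p < candidate_alpha` are flagged candidates.
#'
#' @inheritParams per_cpg_difference
#' @param config A [dmr_config()].
#' @return A `data.frame` of DMR records sorted by position: `contig`,
#'   `start`, `end`, `n_cpgs`, `stat`, `p`, `delta_beta` (reference minus
#'   other, mean over region CpGs), `direction`, `candidate`.
#' @export
permutation_pvalues <- function(mat, group, strata = NULL,
                                reference = "large",
                                config = dmr_config()) {
  diffs <- per_cpg_difference(mat, group, strata, reference,
                              smooth_bw = config$smooth_bw)
  obs_regions <- find_candidate_regions(diffs, config)
  if (nrow(obs_regions) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), n_cpgs = integer(), stat = numeric(),
                      p = numeric(), delta_beta = numeric(),
                      direction = character(), candidate = logical()))
  obs_stat <- region_statistic(obs_regions, diffs)
  relab <- stratified_relabelings(diffs$group, diffs$strata, diffs$reference,
                                  config$n_perm, config$seed)
  if (length(relab$labelings) < 1L)
    stop("fewer than 2 distinct relabelings possible")
  null_stats <- unlist(lapply(relab$labelings, function(g) {
    d <- stratified_difference(diffs$levels, g, diffs$strata, diffs$reference)
    dp <- diffs
    dp$d <- d
    dp$d_smooth <- smooth_by_position(d, diffs$loci$contig,
                                      diffs$loci$position, diffs$smooth_bw)
    dp$s2 <- pooled_group_variance(diffs$levels, g)
    reg <- find_candidate_regions(dp, config)
    if (nrow(reg)) region_statistic(reg, dp) else numeric()
  }))
  n_null <- length(null_stats)
  p <- vapply(obs_stat, function(s)
    (1 + sum(abs(null_stats) >= abs(s) - 1e-12)) / (1 + n_null), 0)
  delta_beta <- vapply(seq_len(nrow(obs_regions)), function(k)
    mean(diffs$d[obs_regions$i_first[k]:obs_regions$i_last[k]]), 0)
  out <- data.frame(obs_regions[, c("contig", "start", "end", "n_cpgs")],
                    stat = obs_stat, p = p, delta_beta = delta_beta,
                    direction = classify_direction(delta_beta),
                    candidate = p < config$candidate_alpha,
                    stringsAsFactors = FALSE)
  attr(out, "n_null") <- n_null
  attr(out, "exhaustive") <- relab$exhaustive
  out
}

#' @rdname permutation_pvalues
#' @export
call_dmrs <- permutation_pvalues

# Within-stratum relabelings of a two-group factor. Exhaustive (all
# distinct assignments except the observed one) when their number is
# <= n_perm; otherwise n_perm seeded within-stratum shuffles.
stratified_relabelings <- function(group, strata, reference, n_perm, seed) {
  n <- length(group)
  strat_ids <- unique(strata)
  per_strat <- lapply(strat_ids, function(s) {
    i <- which(strata == s)
    k <- sum(group[i] == reference)
    list(idx = i, k = k,
         n_comb = if (k %in% c(0L, length(i))) 1 else choose(length(i), k))
  })
  total <- prod(vapply(per_strat, `[[`, 0, "n_comb"))
  other <- setdiff(unique(group), reference)
  if (total - 1 <= n_perm) {
    per_strat_labels <- lapply(per_strat, function(ps) {
      if (ps$n_comb == 1)
        return(list(group[ps$idx]))
      lapply(utils::combn(length(ps$idx), ps$k, simplify = FALSE), function(j) {
        l <- rep(other, length(ps$idx))
        l[j] <- reference
        l
      })
    })
    grid <- expand.grid(lapply(per_strat_labels, seq_along))
    labelings <- lapply(seq_len(nrow(grid)), function(r) {
      l <- character(n)
      for (si in seq_along(per_strat))
        l[per_strat[[si]]$idx] <- per_strat_labels[[si]][[grid[r, si]]]
      l
    })
    obs <- vapply(labelings, function(l) all(l == group), TRUE)
    list(labelings = labelings[!obs], exhaustive = TRUE)
  } else {
    local_rng(seed)
    labelings <- replicate(n_perm, {
      l <- group
      for (ps in per_strat) l[ps$idx] <- sample(l[ps$idx])
      l
    }, simplify = FALSE)
    list(labelings = labelings, exhaustive = FALSE)
  }
}
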