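#' Convert a count table to relative abundances
#'
#' Scales every sample (column) to sum to 100, the percent scale on which
#' heavy-versus-light comparisons are made.
#'
#' @param table Taxa x samples numeric matrix, nonnegative.
#' @return Matrix of the same shape with columns summing to 100.
#' @export
to_relative_abundance <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be nonnegative")
  cs <- colSums(table)
  if (any(cs == 0)) {
    bad <- colnames(table)[cs == 0]
    stop("all-zero sample column(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  sweep(table, 2L, cs / 100, "/")
}

# One-way two-group F statistic from the group-1 sum, given fixed data.
# Returns the signed statistic: sign(mean1 - mean2) * F.
signed_f_from_sums <- function(s1, n1, n2, total, ss_total) {
  n <- n1 + n2
  s2 <- total - s1
  ssb <- s1^2 / n1 + s2^2 / n2 - total^2 / n
  ssw <- pmax(ss_total - ssb, 0)
  f <- ifelse(ssw > 0, ssb / (ssw / (n - 2)), ifelse(ssb > 0, Inf, 0))
  sign(s1 / n1 - s2 / n2) * f
}

#' Permutation ANOVA of heavy versus light abundances
#'
#' One-way two-group ANOVA whose null distribution is generated by permuting
#' the density-class labels. The F statistic is between-group over
#' within-group mean squares. With `alternative = "greater"` (the default,
#' matching the one-sided hypothesis that a labeled taxon is *higher* in
#' heavy fractions) the permutation tail is computed on the signed statistic
#' `sign(mean_heavy - mean_light) * F`; `"two.sided"` uses the plain F, which
#' is direction-blind and invariant to swapping the group labels.
#'
#' In `montecarlo` mode the p-value is `(1 + #{S* >= S_obs}) / (n_perm + 1)`
#' over `n_perm` random label permutations (never exactly zero). In `exact`
#' mode all `choose(n_h + n_l, n_h)` assignments are enumerated and the tail
#' proportion returned; ties count as exceedances. Constant data yield F = 0
#' and p = 1 with a warning.
#'
#' @param heavy,light Numeric abundance vectors (>= 2 values each).
#' @param n_perm Number of random permutations (`montecarlo` mode).
#' @param seed Optional integer seed (RNG state restored).
#' @param mode `"montecarlo"` or `"exact"`.
#' @param alternative `"greater"` (heavy above light) or `"two.sided"`.
#' @return Object of class `perm_anova`: list with `mean_heavy`,
#'   `mean_light`, `F_stat`, `p_perm`, `n_permutations`, `exact`,
#'   `alternative`.
#' @export
permutation_anova <- function(heavy, light, n_perm = 2000L, seed = NULL,
                              mode = c("montecarlo", "exact"),
                              alternative = c("greater", "two.sided")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  heavy <- as.numeric(heavy); light <- as.numeric(light)
  if (length(heavy) < 2L || length(light) < 2L)
    stop("at least 2 values per group are required")
  x <- c(heavy, light)
  n1 <- length(heavy); n2 <- length(light); n <- n1 + n2
  total <- sum(x)
  ss_total <- sum(x^2) - total^2 / n

  res <- list(mean_heavy = mean(heavy), mean_light = mean(light),
              alternative = alternative)
  if (ss_total <= 1e-24 * max(1, mean(x)^2)) {
    warning("constant data: F undefined, returning F = 0, p = 1")
    res$F_stat <- 0; res$p_perm <- 1
    res$n_permutations <- if (mode == "exact") choose(n, n1) else n_perm
    res$exact <- mode == "exact"
    class(res) <- "perm_anova"
    return(res)
  }

  stat <- function(s1) signed_f_from_sums(s1, n1, n2, total, ss_total)
  s_obs <- stat(sum(heavy))
  res$F_stat <- abs(s_obs)
  if (alternative == "two.sided") s_obs <- abs(s_obs)
  tailed <- function(s_star) {
    if (alternative == "two.sided") s_star <- abs(s_star)
    eps <- if (is.finite(s_obs)) 1e-10 * max(1, abs(s_obs)) else 0
    s_star >= s_obs - eps
  }

  # permuted statistics depend only on the pooled multiset of values, so
  # draws are taken from the sorted pool: p is then bit-reproducible under
  # group swaps and reorderings for the label-symmetric two-sided tail
  pool <- sort(x)
  if (mode == "exact") {
    comb <- utils::combn(n, n1)
    s_star <- apply(comb, 2L, function(idx) stat(sum(pool[idx])))
    res$p_perm <- mean(tailed(s_star))
    res$n_permutations <- ncol(comb)
    res$exact <- TRUE
  } else {
    run <- function() {
      s_star <- vapply(seq_len(n_perm),
                       function(i) stat(sum(pool[sample.int(n, n1)])),
                       numeric(1L))
      (1 + sum(tailed(s_star))) / (n_perm + 1)
    }
    res$p_perm <- if (is.null(seed)) run() else with_seed(seed, run())
    res$n_permutations <- as.integer(n_perm)
    res$exact <- FALSE
  }
  class(res) <- "perm_anova"
  res
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf(
    "Permutation ANOVA (%s, %s): F = %.4g, p = %.4g (%d permutations)\n",
    if (x$exact) "exact" else "monte-carlo", x$alternative,
    x$F_stat, x$p_perm, x$n_permutations))
  cat(sprintf("  mean heavy = %.4g, mean light = %.4g\n",
              x$mean_heavy, x$mean_light))
  invisible(x)
}

#' Identify isotope-labeled taxa from heavy/light fraction abundances
#'
#' For each taxon, compares its relative abundance in heavy versus light
#' fraction samples at the test timepoint by permutation ANOVA and applies
#' the classification rules:
#' \itemize{
#'   \item `labeled`: p <= `alpha` and mean heavy > mean light;
#'   \item `trend`: `alpha` < p <= `trend` and mean heavy > mean light;
#'   \item `baseline_excluded`: the taxon was already enriched in heavy
#'     fractions at the baseline timepoint (mean heavy > mean light and
#'     baseline p <= `trend`), before any labeled substrate was available —
#'     such apparent enrichment reflects buoyant-density differences (e.g.
#'     GC content), not isotope incorporation, and overrides the test-time
#'     call;
#'   \item `unlabeled`: everything else.
#' }
#' Taxa whose mean relative abundance at the test timepoint falls below
#' `min_mean_abundance` are still reported but flagged `low_abundance`.
#'
#' @param table Taxa x samples count (or relative) matrix.
#' @param meta Data frame with one row per sample: columns `sample`,
#'   `timepoint`, `density_class` (`"heavy"`/`"light"`/other).
#' @param baseline_timepoint,test_timepoint Timepoint labels in `meta`.
#' @param alpha Significance threshold (default 0.05).
#' @param trend Trend threshold (default 0.10).
#' @param min_mean_abundance Percent threshold for the low-abundance flag.
#' @param n_perm,seed,mode,alternative Passed to [permutation_anova()]; with
#'   a seed, each taxon receives its own derived seed.
#' @param p_adjust Multiple-testing correction applied to test p-values
#'   before classification (`"none"`, the default — no correction across
#'   taxa — or any method of [stats::p.adjust()]).
#' @return Data frame of class `labeling_result`, one row per taxon:
#'   means, `F_stat`, `p_perm`, `p_baseline`, `direction`, `class`,
#'   `low_abundance`.
#' @export
identify_labeled_taxa <- function(table, meta,
                                  baseline_timepoint, test_timepoint,
                                  alpha = 0.05, trend = 0.10,
                                  min_mean_abundance = 0.1,
                                  n_perm = 2000L, seed = NULL,
                                  mode = c("montecarlo", "exact"),
                                  alternative = c("greater", "two.sided"),
                                  p_adjust = "none") {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(c("sample", "timepoint", "density_class") %in% names(meta)))
    stop("meta must have columns sample, timepoint, density_class")
  if (!all(colnames(table) %in% meta$sample))
    stop("every feature-table column needs a metadata row")
  meta <- meta[match(colnames(table), meta$sample), ]
  for (tp in c(baseline_timepoint, test_timepoint)) {
    if (!tp %in% meta$timepoint) stop("timepoint absent from metadata: ", tp)
    for (cls in c("heavy", "light")) {
      if (sum(meta$timepoint == tp & meta$density_class == cls) < 2L)
        stop("need >= 2 ", cls, " samples at timepoint ", tp)
    }
  }
  rel <- to_relative_abundance(table)
  sel <- function(tp, cls)
    rel[, meta$timepoint == tp & meta$density_class == cls, drop = FALSE]
  h_test <- sel(test_timepoint, "heavy")
  l_test <- sel(test_timepoint, "light")
  h_base <- sel(baseline_timepoint, "heavy")
  l_base <- sel(baseline_timepoint, "light")

  taxa <- rownames(table)
  run_one <- function(i, hv, lv, seed_off) {
    s <- if (is.null(seed)) NULL else seed + seed_off + i
    suppressWarnings(
      permutation_anova(hv[i, ], lv[i, ], n_perm = n_perm, seed = s,
                        mode = mode, alternative = alternative))
  }
  test_res <- lapply(seq_along(taxa), run_one, hv = h_test, lv = l_test,
                     seed_off = 0L)
  base_res <- lapply(seq_along(taxa), run_one, hv = h_base, lv = l_base,
                     seed_off = 100000L)

  p_test <- stats::p.adjust(vapply(test_res, `[[`, 0, "p_perm"),
                            method = p_adjust)
  p_base <- vapply(base_res, `[[`, 0, "p_perm")
  out <- data.frame(
    taxon = taxa,
    mean_heavy = vapply(test_res, `[[`, 0, "mean_heavy"),
    mean_light = vapply(test_res, `[[`, 0, "mean_light"),
    F_stat = vapply(test_res, `[[`, 0, "F_stat"),
    p_perm = p_test,
    p_baseline = p_base,
    direction = vapply(test_res, function(r) r$mean_heavy > r$mean_light,
                       logical(1L)),
    stringsAsFactors = FALSE
  )
  base_up <- vapply(base_res, function(r) r$mean_heavy > r$mean_light,
                    logical(1L))
  out$class <- ifelse(
    base_up & p_base <= trend, "baseline_excluded",
    ifelse(out$direction & out$p_perm <= alpha, "labeled",
           ifelse(out$direction & out$p_perm <= trend, "trend",
                  "unlabeled")))
  out$low_abundance <-
    rowMeans(cbind(h_test, l_test)) < min_mean_abundance
  rownames(out) <- NULL
  class(out) <- c("labeling_result", "data.frame")
  attr(out, "parameters") <- list(
    baseline_timepoint = baseline_timepoint,
    test_timepoint = test_timepoint, alpha = alpha, trend = trend,
    min_mean_abundance = min_mean_abundance, n_perm = n_perm,
    mode = mode, alternative = alternative, p_adjust = p_adjust,
    seed = seed)
  out
}

#' Cluster fraction-sample community profiles
#'
#' Hierarchical clustering of samples with distances 1 minus the (centered)
#' Pearson correlation between abundance profiles and average linkage
#' (UPGMA). Columns are ordered by sample id before clustering so the merge
#' tree is deterministic for a given sample set.
#'
#' @param table Taxa x samples matrix (counts or relative abundances).
#' @return List with `hclust` (the merge tree), `order` (sample ids in
#'   dendrogram order) and `dist` (the distance object).
#' @export
cluster_profiles <- function(table) {
  table <- as.matrix(table)
  if (ncol(table) < 3L) stop("at least 3 samples are required")
  table <- table[, order(colnames(table)), drop = FALSE]
  sds <- apply(table, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant profile (undefined correlation) in sample(s): ",
         paste(colnames(table)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(table))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = hc$labels[hc$order], dist = d)
}
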