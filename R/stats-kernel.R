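#' @importFrom stats p.adjust pchisq phyper pnorm cor kruskal.test wilcox.test
#'   var
NULL

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control, order-aligned with the input and
#' capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("bh_adjust: p-values must lie in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Fisher's combined probability
#'
#' Combines k p-values through the statistic X2 = -2 * sum(log p), referred to
#' a chi-squared distribution with 2k degrees of freedom (upper tail). With
#' k = 1 the input is returned unchanged. Zero p-values are an error unless
#' `floor_zero = TRUE`, in which case they are floored at the smallest
#' positive double; silent flooring is off by default so upstream problems
#' surface.
#'
#' @param pvalues Numeric vector of p-values in (0,1\].
#' @param floor_zero Replace p = 0 by the smallest positive double instead of
#'   erroring.
#' @return Combined p-value.
#' @export
fisher_combine <- function(pvalues, floor_zero = FALSE) {
  k <- length(pvalues)
  if (k < 1) stop("fisher_combine: need at least one p-value")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("fisher_combine: p-values must lie in [0,1]")
  if (any(pvalues == 0)) {
    if (!floor_zero) stop("fisher_combine: p = 0 gives an infinite statistic; ",
                          "set floor_zero = TRUE to floor")
    pvalues <- pmax(pvalues, .Machine$double.xmin)
  }
  if (k == 1) return(pvalues)
  x2 <- -2 * sum(log(pvalues))
  stats::pchisq(x2, df = 2 * k, lower.tail = FALSE)
}

#' One-sided hypergeometric overlap probability
#'
#' Probability of observing at least `k_overlap` shared elements when a set of
#' size `n_b` is drawn from a universe of `n_universe` elements containing
#' `n_a` successes (the one-sided Fisher exact enrichment test).
#'
#' @param n_a,n_b Sizes of the two sets.
#' @param k_overlap Observed overlap.
#' @param n_universe Universe size.
#' @return P(X >= k_overlap) under the hypergeometric null.
#' @export
hypergeom_overlap <- function(n_a, n_b, k_overlap, n_universe) {
  if (k_overlap > min(n_a, n_b) || n_a > n_universe || n_b > n_universe ||
      any(c(n_a, n_b, k_overlap, n_universe) < 0))
    stop("hypergeom_overlap: inconsistent counts")
  stats::phyper(k_overlap - 1, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (tie-aware). A constant input vector has
#' no defined rank correlation and yields `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1,1\], or `NA` when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("spearman_rho: need equal lengths >= 3")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("spearman_rho: constant vector, correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic referred to chi-squared with g - 1 degrees of
#' freedom. The fully degenerate case (all observations identical) is defined
#' as H = 0, p = 1.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List with `statistic`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1)
    return(list(statistic = 0, p = 1, df = length(groups) - 1))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("groups must be non-empty")
  if (sum(lengths(groups)) < 3) stop("need total N >= 3")
  invisible(groups)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' For each pair of groups computes z = (Ri - Rj) / sqrt((N(N+1)/12 - T) *
#' (1/ni + 1/nj)) on pooled midranks, with tie correction
#' T = sum(t^3 - t) / (12 (N - 1)), a two-sided normal p, and p-values
#' adjusted across all pairs.
#'
#' @param groups List of >= 2 non-empty numeric vectors (named lists keep
#'   their labels).
#' @param adjust_method Multiplicity adjustment across the pairwise family
#'   (any method of [stats::p.adjust()]); default `"holm"`.
#' @return Data frame with `group_a`, `group_b`, `z`, `p`, `padj`.
#' @export
dunn_posthoc <- function(groups, adjust_method = "holm") {
  check_groups(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  idx <- rep(seq_along(groups), lengths(groups))
  r <- rank(values)                      # midranks
  n <- lengths(groups)
  N <- length(values)
  rbar <- tapply(r, idx, mean)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    denom <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    z[k] <- if (denom == 0) 0 else (rbar[i] - rbar[j]) / denom
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group_a = labs[pairs[1, ]], group_b = labs[pairs[2, ]],
             z = z, p = p, padj = stats::p.adjust(p, method = adjust_method),
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Exact two-sided p-value by enumeration when the combined sample size is at
#' most 12 and there are no ties; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return List with `statistic` (U for the first sample) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("wilcoxon_rank_sum: empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = (length(x) + length(y) <= 12) && !ties,
                  exact = TRUE, normal = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1   # degenerate: no rank variation (complete ties)
  list(statistic = unname(wt$statistic), p = p)
}

#' Fit a single-exponential decay constant
#'
#' Fits y = exp(t * tau) by least squares on the log scale through the
#' implied anchor y(0) = 1: tau = sum(t * log(y)) / sum(t^2). Values are
#' floored before the log so ratios that hit zero at late time points do not
#' produce infinities.
#'
#' @param times Time points (> 0), e.g. days.
#' @param values Positive response values (ratios relative to time 0).
#' @param floor Lower floor applied to `values` before the log.
#' @return The decay constant tau (same reciprocal units as `times`).
#' @export
fit_exp_decay <- function(times, values, floor = 1e-6) {
  if (length(times) < 2 || length(times) != length(values))
    stop("fit_exp_decay: need >= 2 (time, value) pairs")
  if (all(times == 0)) stop("fit_exp_decay: all times are zero")
  if (any(times <= 0)) stop("fit_exp_decay: times must be > 0")
  y <- pmax(values, floor)
  sum(times * log(y)) / sum(times^2)
}

#' Half-life from a decay constant
#'
#' @param tau Decay constant (per unit time). Must be negative for a
#'   half-life to exist; non-negative values (no decay / growth) yield `NA`.
#' @return ln(2) / |tau|, or `NA` when `tau >= 0`.
#' @export
half_life <- function(tau) {
  out <- ifelse(!is.na(tau) & tau < 0, log(2) / abs(tau), NA_real_)
  unname(out)
}

#' Relative expression by the delta-delta-Ct method
#'
#' @param ct_target,ct_ref Ct of target and reference gene in the sample.
#' @param ct_target_cal,ct_ref_cal Ct of target and reference in the
#'   calibrator sample.
#' @return 2^-(((ct_target - ct_ref) - (ct_target_cal - ct_ref_cal))).
#' @export
ddct <- function(ct_target, ct_ref, ct_target_cal, ct_ref_cal) {
  2^(-((ct_target - ct_ref) - (ct_target_cal - ct_ref_cal)))
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Bootstrap size-matched gene-set comparison
#'
#' In each replicate two disjoint background subsets S1 and S2 of
#' `subsample_size` genes are drawn without replacement; a Kruskal-Wallis test
#' with Dunn's pairwise comparisons is run over the groups {up, down, S1, S2};
#' and the p-values for (up vs S1), (down vs S1) and the negative control
#' (S1 vs S2) are recorded. The summary reports, per comparison, the fraction
#' of replicates with p below `alpha`.
#'
#' By default the per-replicate Dunn p-values are not multiplicity-adjusted:
#' the three tracked comparisons are planned contrasts and the
#' across-replicate fraction is itself the robustness summary; adjusting
#' within each replicate would leave the S1-vs-S2 negative control with a
#' rejection rate far below `alpha` and remove its calibration value. Holm or
#' BH adjustment across the pairwise family is available via `adjust_method`.
#'
#' @param feature Numeric vector, one value per gene.
#' @param labels Character/factor vector aligned with `feature`; levels
#'   `"up"`, `"down"`, `"background"` (other labels are ignored).
#' @param n_boot Number of bootstrap replicates.
#' @param subsample_size Size of each background subset; default the rounded
#'   mean of the up and down cluster sizes.
#' @param alpha Significance level for the fraction-significant summary.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param adjust_method Per-replicate adjustment across the Dunn family
#'   (default `"none"`; see Details).
#' @return List with `p` (n_boot x 3 data frame of per-replicate p-values for
#'   `up_vs_s1`, `down_vs_s1`, `s1_vs_s2`), `frac_significant` (named vector),
#'   `alpha`, `subsample_size`, `n_boot`.
#' @export
bootstrap_group_comparison <- function(feature, labels, n_boot = 1000,
                                       subsample_size = NULL, alpha = 0.05,
                                       seed, adjust_method = "none") {
  stopifnot(length(feature) == length(labels), n_boot >= 1)
  labels <- as.character(labels)
  up <- feature[labels == "up"]
  down <- feature[labels == "down"]
  bg <- feature[labels == "background"]
  if (!length(up) || !length(down)) stop("need non-empty up and down groups")
  if (is.null(subsample_size))
    subsample_size <- round(mean(c(length(up), length(down))))
  if (length(bg) < 2 * subsample_size)
    stop(sprintf("background too small: %d genes, need >= %d",
                 length(bg), 2 * subsample_size))
  pm <- matrix(NA_real_, n_boot, 3,
               dimnames = list(NULL, c("up_vs_s1", "down_vs_s1", "s1_vs_s2")))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(length(bg), 2 * subsample_size)
      s1 <- bg[idx[seq_len(subsample_size)]]
      s2 <- bg[idx[subsample_size + seq_len(subsample_size)]]
      dn <- dunn_posthoc(list(up = up, down = down, s1 = s1, s2 = s2),
                         adjust_method = adjust_method)
      key <- paste(dn$group_a, dn$group_b, sep = "_vs_")
      pm[b, "up_vs_s1"] <- dn$padj[key == "up_vs_s1"]
      pm[b, "down_vs_s1"] <- dn$padj[key == "down_vs_s1"]
      pm[b, "s1_vs_s2"] <- dn$padj[key == "s1_vs_s2"]
    }
  })
  list(p = as.data.frame(pm), frac_significant = colMeans(pm < alpha),
       alpha = alpha, subsample_size = subsample_size, n_boot = n_boot)
}
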