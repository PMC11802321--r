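test_that("BH adjustment matches brute-force step-up on short vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
  set.seed(3)
  for (i in 1:200) {
    p <- runif(sample(1:6, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("Fisher combination matches the closed-form chi-squared tail", {
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.0174787, tolerance = 1e-5)
  expect_equal(fisher_combine(c(0.1, 1.0)), 0.3302585, tolerance = 1e-5)
  expect_equal(fisher_combine(0.37), 0.37)      # k = 1 identity
  expect_error(fisher_combine(c(0.5, 0)), "infinite")
  expect_lt(fisher_combine(c(0.5, 0), floor_zero = TRUE), 1e-100)
  set.seed(5)
  for (i in 1:500) {
    p <- runif(sample(2:8, 1), min = 1e-6)
    expect_equal(fisher_combine(p), fisher_brute(p), tolerance = 1e-12)
    expect_equal(fisher_combine(p), fisher_combine(rev(p)))  # order invariance
  }
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  expect_equal(hypergeom_overlap(5, 5, 5, 10), 1 / 252)
  expect_equal(hypergeom_overlap(5, 5, 0, 10), 1)
  expect_equal(hypergeom_overlap(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  expect_error(hypergeom_overlap(5, 5, 6, 10), "inconsistent")
  set.seed(9)
  for (i in 1:40) {
    N <- sample(4:12, 1)
    na <- sample(1:(N - 1), 1); nb <- sample(1:(N - 1), 1)
    k <- sample(0:min(na, nb), 1)
    expect_equal(hypergeom_overlap(na, nb, k, N),
                 hypergeom_brute(na, nb, k, N), tolerance = 1e-12)
  }
})

test_that("Spearman correlation is the rank-Pearson with NA for constants", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_warning(r <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
})

test_that("Kruskal-Wallis matches the hand-computed H and handles ties", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 3.8571, tolerance = 1e-4)
  expect_equal(kw$p, 0.0495, tolerance = 1e-3)
  # degenerate: everything identical
  kw0 <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p, 1)
  # permutation symmetry
  g <- list(a = c(1, 5, 3), b = c(2, 2, 8), c = c(9, 4))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(rev(g))$statistic)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("Dunn pairwise z matches the tie-corrected formula", {
  dn <- dunn_posthoc(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(abs(dn$z), 1.9640, tolerance = 1e-4)
  expect_equal(dn$p, 0.0495, tolerance = 1e-3)
  same <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  three <- dunn_posthoc(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(nrow(three), 3)            # C(3,2) comparisons
  expect_true(all(three$padj >= three$p))
  none <- dunn_posthoc(list(a = 1:3, b = 4:6, c = 7:9), adjust_method = "none")
  expect_equal(none$padj, none$p)
})

test_that("Wilcoxon rank-sum matches enumeration in the exact regime", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p, 0.1)
  expect_equal(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))$p, 0.1)  # symmetry
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(13)
  for (i in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(1:100, nx + ny)            # distinct => no ties
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(wilcoxon_rank_sum(x, y)$p, wilcox_brute(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exponential decay fit recovers tau and half-lives exactly", {
  t <- c(7, 14, 28, 56)
  expect_equal(fit_exp_decay(t, rep(1, 4)), 0)
  expect_equal(fit_exp_decay(t, exp(-0.1 * t)), -0.1, tolerance = 1e-12)
  expect_equal(half_life(-0.0770), 9.002, tolerance = 1e-3)
  expect_equal(half_life(-log(2)), 1.0)
  expect_identical(half_life(0.1), NA_real_)
  expect_equal(half_life(-log(2) / 9), 9)
  expect_error(fit_exp_decay(c(0, 0), c(1, 1)), "zero")
  # noise robustness: median relative error under lognormal noise sigma=0.1
  set.seed(21)
  taus <- -runif(300, 0.03, 0.15)
  est <- vapply(taus, function(tau) {
    y <- exp(tau * t) * exp(rnorm(4, 0, 0.1))
    fit_exp_decay(t, y)
  }, numeric(1))
  expect_lt(median(abs(est - taus) / abs(taus)), 0.05)
})

test_that("delta-delta-Ct gives fold-changes on the 2^-ddCt scale", {
  expect_equal(ddct(21, 20, 21, 20), 1)
  expect_equal(ddct(22, 20, 21, 20), 0.5)
  expect_equal(ddct(19, 20, 21, 20), 4)
})
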