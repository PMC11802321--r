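# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# step-up FDR by direct definition: padj_(i) = min_{j >= i} m * p_(j) / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# chi-squared upper tail for even df via the finite series
# P(X2 >= x) = exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!, df = 2k
fisher_brute <- function(pvalues) {
  k <- length(pvalues)
  x <- -2 * sum(log(pvalues))
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# hypergeometric upper tail by exhaustive enumeration of all draws
hypergeom_brute <- function(n_a, n_b, k, n_universe) {
  draws <- utils::combn(n_universe, n_b)
  hits <- apply(draws, 2, function(d) sum(d <= n_a))
  mean(hits >= k)
}

# exact two-sided Mann-Whitney p by enumeration over rank assignments
wilcox_brute <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  all_r <- rank(c(x, y))
  us <- apply(combs, 2, function(idx) sum(all_r[idx]) - nx * (nx + 1) / 2)
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# per-base signal integration
integrate_brute <- function(track, chrom, start, end) {
  total <- 0
  sel <- track[track$chrom == chrom, , drop = FALSE]
  for (b in seq(start, end - 1)) {
    hit <- which(sel$start <= b & sel$end > b)
    if (length(hit)) total <- total + sel$value[hit]
  }
  total
}

# does interval a overlap any interval in df by >= 1 bp
overlap_brute <- function(chrom, start, end, df) {
  any(df$chrom == chrom & df$start < end & df$end > start)
}

random_track <- function(n = 10, chrom = "chr1", max_pos = 200,
                         values = 0:5) {
  bounds <- sort(sample(0:max_pos, 2 * n))
  signal_track(chrom, bounds[seq(1, 2 * n, 2)], bounds[seq(2, 2 * n, 2)],
                   sample(values, n, replace = TRUE))
}

small_sim_config <- function(...) {
  cascade_sim_config(n_genes = 300, n_up = 20, n_down = 30,
                     n_tamoxifen = 15, n_cre = 10, ...)
}

# one shared small dataset per test run (cheap; ~0.5 s)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_experiment(small_sim_config(),
                                                      seed = 42)
    cache
  }
})

# the default-scale study (2000 genes, 93 up / 142 down), seed 1, with its
# DE table and persistence records; simulated once and shared where a
# property is stated at the default conditions
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_experiment(cascade_sim_config(), seed = 1)
      de <- de_timecourse(ds$rna)
      pa <- persistence_analysis(de)
      cache <<- list(ds = ds, de = de, pa = pa)
    }
    cache
  }
})
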