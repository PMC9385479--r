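# Fixture builders shared across test files. All synthetic, all in code.

# noiseless model curve with known truth
make_truth_curve <- function(e_active = 5, k2 = 1.0, k3 = 0.004,
                             times = default_times(), s_total = 100) {
  bp <- burst_params(e_active, k2 = k2, k3 = k3)
  progress_curve(times, burst_product(times, bp), e_nominal = e_active,
                 s_total = s_total)
}

# time grid matched to the burst rate so both phases are sampled
times_for_rate <- function(k_burst, n = 16L) {
  t_burst <- 3 / k_burst             # ~95% of the exponential phase
  early <- seq(0, t_burst, length.out = n - 4L)
  late <- seq(t_burst * 1.5, t_burst * 8, length.out = 4L)
  unique(c(early, late))
}

# random valid rate draws for property-style tests
draw_rates <- function(n, seed, ratio_range = c(5, 500),
                       k_burst_range = c(0.01, 2)) {
  set.seed(seed)
  kb <- exp(stats::runif(n, log(k_burst_range[1]), log(k_burst_range[2])))
  ratio <- exp(stats::runif(n, log(ratio_range[1]), log(ratio_range[2])))
  k3 <- kb / (1 + ratio)
  k2 <- kb - k3
  data.frame(k2 = k2, k3 = k3, k_burst = kb)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# independent midrank Spearman (brute force, used as oracle)
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
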