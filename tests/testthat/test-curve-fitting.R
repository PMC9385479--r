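test_that("fit_burst recovers truth on noiseless curves to < 1e-6 relative", {
  # spec'd reference case
  curve <- make_truth_curve(e_active = 5, k2 = 1.0, k3 = 0.004)
  fit <- fit_burst(curve)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$params$e_active, 5), 1e-6)
  expect_lt(rel_err(fit$params$rates$k2, 1.0), 1e-6)
  expect_lt(rel_err(fit$params$rates$k3, 0.004), 1e-6)
  # derived quantities consistent with params
  dr <- derived_rates(fit$params$rates)
  expect_identical(fit$k_burst, dr$k_burst)
  expect_identical(fit$k_ss, dr$k_ss)

  # property: random draws with k2/k3 in [5, 500], matched time grids
  draws <- draw_rates(12, seed = 23)
  for (i in seq_len(nrow(draws))) {
    e <- runif(1, 0.5, 8)
    tt <- times_for_rate(draws$k_burst[i])
    curve <- progress_curve(tt, burst_product(tt, burst_params(
      e, k2 = draws$k2[i], k3 = draws$k3[i])), s_total = Inf)
    fit <- fit_burst(curve)
    expect_lt(rel_err(fit$params$e_active, e), 1e-6)
    expect_lt(rel_err(fit$params$rates$k2, draws$k2[i]), 1e-6)
    expect_lt(rel_err(fit$params$rates$k3, draws$k3[i]), 1e-6)
    expect_lte(fit$k_ss, fit$k_burst / 4 + 1e-14)
  }
})

test_that("fit_burst reparameterisation is self-consistent", {
  curve <- make_truth_curve(e_active = 3, k2 = 0.4, k3 = 0.02)
  fit <- fit_burst(curve)
  E <- fit$params$e_active; k2 <- fit$params$rates$k2
  k3 <- fit$params$rates$k3; lam <- k2 + k3
  # (A, lambda, m) computed from returned params reproduce the fitted curve
  A <- E * (k2 / lam)^2
  m <- E * k2 * k3 / lam
  mu <- A * (1 - exp(-lam * curve$times)) + m * curve$times
  expect_equal(mu, fit$fitted, tolerance = 1e-9)
})

test_that("fit_burst error taxonomy", {
  tt <- default_times()
  flat0 <- progress_curve(tt, rep(0, length(tt)))
  expect_error(fit_burst(flat0), "no detectable product")
  flat3 <- progress_curve(tt, rep(3, length(tt)))
  expect_error(fit_burst(flat3), "no detectable product")
  expect_error(progress_curve(c(0, 1, 2), c(0, 1, 2)), ">= 4 time points")
  expect_error(progress_curve(c(0, 2, 1, 3), c(0, 1, 2, 3)),
               "strictly increasing")
  expect_error(progress_curve(tt, rep(-1, length(tt))), "non-negative")
})

test_that("fit_burst with a fixed active-enzyme concentration", {
  curve <- make_truth_curve(e_active = 5, k2 = 0.5, k3 = 0.01)
  fit <- fit_burst(curve, fit_opts(fix_e_active = 5))
  expect_identical(fit$params$e_active, 5)
  expect_lt(rel_err(fit$params$rates$k2, 0.5), 1e-4)
  expect_lt(rel_err(fit$params$rates$k3, 0.01), 1e-4)
})

test_that("pooled and averaged replicate fits both work", {
  des <- assay_design(s_total = 100)
  sc <- gen_progress_curve(des, rate_constants(0.5, 0.01),
                           noise_model(0.05, 0.05, seed = 42))
  f_avg <- fit_burst(sc$curve, fit_opts(replicates = "average"))
  f_pool <- fit_burst(sc$curve, fit_opts(replicates = "pooled"))
  expect_equal(f_pool$n_points, 3L * f_avg$n_points)
  # both land near truth under 5% cv noise
  expect_lt(rel_err(f_avg$k_burst, 0.51), 0.2)
  expect_lt(rel_err(f_pool$k_burst, 0.51), 0.2)
})

test_that("grid oracle: fit_burst is at least grid-optimal", {
  curve <- make_truth_curve(e_active = 5, k2 = 1.0, k3 = 0.004)
  fit <- fit_burst(curve)
  # coarse grid bracketing the truth
  g <- grid_oracle_fit(curve,
                       e_grid = seq(3, 7, length.out = 9),
                       k2_grid = seq(0.5, 1.5, length.out = 11),
                       k3_grid = seq(0.001, 0.01, length.out = 10))
  expect_lte(fit$ssr, g$ssr + 1e-12)
  expect_lt(abs(g$params$rates$k2 - fit$params$rates$k2), 0.1 + 1e-9)
  # grid excluding the truth region can't beat the free fit
  g_off <- grid_oracle_fit(curve, e_grid = c(1, 2), k2_grid = c(0.1, 0.2),
                           k3_grid = c(0.2, 0.3))
  expect_gt(g_off$ssr, fit$ssr)
  # single-cell grid returns that cell
  g1 <- grid_oracle_fit(curve, 4, 0.9, 0.005)
  expect_equal(g1$params$e_active, 4)
  expect_equal(g1$params$rates$k2, 0.9)
  expect_error(grid_oracle_fit(curve, numeric(), 1, 1), "non-empty")
})

test_that("fit_titration recovers hyperbola truth and errors correctly", {
  concs <- c(1, 3, 8, 30, 100, 500, 5000)
  wt <- hyperbola_params(1.1, 8)
  series <- titration_series(concs, hyperbolic_rate(concs, wt))
  fit <- fit_titration(series)
  expect_lt(rel_err(fit$params$kd, 8), 1e-6)
  expect_lt(rel_err(fit$params$k_pot, 1.1), 1e-6)

  mut <- hyperbola_params(0.8, 500)
  concs2 <- 10^seq(0, 4, length.out = 8)
  s2 <- titration_series(concs2, hyperbolic_rate(concs2, mut))
  f2 <- fit_titration(s2)
  expect_lt(rel_err(f2$params$kd, 500), 1e-6)

  expect_error(titration_series(c(1, 10), c(0.1, 0.2)), "3 distinct")
  flat <- titration_series(c(1, 10, 100), c(0.5, 0.5, 0.5))
  expect_error(fit_titration(flat), "saturated or flat")
  # kd outside the sampled range draws a warning
  narrow <- titration_series(c(1000, 2000, 5000),
                             hyperbolic_rate(c(1000, 2000, 5000), wt))
  expect_warning(fit_titration(narrow), "poorly constrained")
})

test_that("optional basal offset augments the hyperbola", {
  concs <- c(0, 1, 3, 8, 30, 100, 500, 5000)
  y <- hyperbolic_rate(concs, hyperbola_params(1.0, 8)) + 0.033
  s <- titration_series(concs, y)
  f <- fit_titration(s, fit_opts(basal_offset = TRUE))
  expect_lt(rel_err(f$params$kd, 8), 1e-6)
  expect_lt(rel_err(f$k0, 0.033), 1e-6)
})

test_that("bootstrap_cis is seeded, degenerate-aware and ordered", {
  curve <- make_truth_curve(e_active = 5, k2 = 0.5, k3 = 0.01)
  fit <- fit_burst(curve)
  # noiseless data -> degenerate residuals -> zero-width intervals
  ci0 <- bootstrap_cis("burst", fit$data, fit, n_boot = 100, seed = 1)
  expect_true(attr(ci0, "degenerate"))
  expect_equal(ci0[, "lower"], ci0[, "upper"])

  sc <- gen_progress_curve(assay_design(s_total = 100),
                           rate_constants(0.5, 0.01),
                           noise_model(0.05, 0.05, seed = 9))
  f <- fit_burst(sc$curve)
  ci1 <- bootstrap_cis("burst", f$data, f, n_boot = 150, seed = 4)
  ci2 <- bootstrap_cis("burst", f$data, f, n_boot = 150, seed = 4)
  expect_identical(ci1, ci2)                     # determinism contract
  ci3 <- bootstrap_cis("burst", f$data, f, n_boot = 150, seed = 5)
  expect_false(identical(ci1, ci3))
  expect_true(all(ci1[, "lower"] <= ci1[, "upper"]))
  expect_error(bootstrap_cis("burst", f$data, f, n_boot = 50, seed = 1),
               ">= 100")
  expect_error(bootstrap_cis("burst", f$data, f, n_boot = 100), "seed")
})

test_that("fold_stimulation reproduces printed stimulation folds", {
  # pi6: 0.0040 -> 0.32 min^-1 (80-fold); slow condition gets a long assay
  mk <- function(kb, times) {
    k2 <- 0.9 * kb; k3 <- 0.1 * kb
    progress_curve(times, burst_product(times, burst_params(1.75, k2 = k2,
                                                            k3 = k3)),
                   s_total = Inf)
  }
  f_alone <- fit_burst(mk(0.0040, slow_times()))
  f_gtsf <- fit_burst(mk(0.32, default_times()))
  expect_equal(fold_stimulation(f_alone, f_gtsf), 80, tolerance = 0.01)
  # pi9: 0.033 -> 0.62 min^-1 (~19-fold)
  f_a9 <- fit_burst(mk(0.033, slow_times()))
  f_g9 <- fit_burst(mk(0.62, default_times()))
  expect_equal(fold_stimulation(f_a9, f_g9), 0.62 / 0.033, tolerance = 0.01)
  # identical fits give 1; errors propagate
  expect_equal(fold_stimulation(f_gtsf, f_gtsf), 1)
})

test_that("fit_single_turnover recovers the exponential", {
  tt <- seq(0, 60, by = 4)
  y <- single_turnover_product(tt, 8, 0.12)
  f <- fit_single_turnover(tt, y)
  expect_lt(rel_err(f$amplitude, 8), 1e-6)
  expect_lt(rel_err(f$k, 0.12), 1e-6)
  expect_gt(f$r_squared, 0.999999)
})
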