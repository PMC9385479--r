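test_that("conservation laws hold along every trajectory", {
  specs <- list(
    scheme_spec("basic", k1 = 10, k_minus1 = 1, k2 = 1, k3 = 0.004),
    scheme_preset("miwi_like"),
    scheme_preset("rapid_equilibrium"))
  for (spec in specs) {
    init <- if (spec$kind == "basic") initial_state(spec, e = 2, s = 50)
            else initial_state(spec, e = 2, s = 50, gtsf = 100)
    traj <- simulate_scheme(spec, init, default_times())
    e_tot <- rowSums(traj$conc[, spec$enzyme_species, drop = FALSE])
    s_tot <- rowSums(traj$conc[, spec$target_species, drop = FALSE])
    expect_lt(diff(range(e_tot)) / max(e_tot), 1e-6)
    expect_lt(diff(range(s_tot)) / max(s_tot), 1e-6)
    expect_true(all(traj$conc >= 0))
    expect_true(all(diff(cleaved_product(traj)) >= -1e-9))
  }
})

test_that("no chemistry step means no product", {
  spec <- scheme_spec("gtsf_extended", kd_target = 1, k_c = 50,
                      k_minus_c = 0.5, k_on = 1, k_off = 8,
                      k_chem = 0, k_prime_minus_c = 0.004)
  init <- initial_state(spec, e = 2, s = 50, gtsf = 500)
  traj <- simulate_scheme(spec, init, default_times())
  expect_true(all(cleaved_product(traj) <= 1e-10))
})

test_that("rapid-binding limit of the basic scheme matches the closed form", {
  # k1*S >> k2+k3 and E << S
  spec <- scheme_spec("basic", k1 = 10, k_minus1 = 1, k2 = 1.0, k3 = 0.004)
  init <- initial_state(spec, e = 2, s = 100)
  tt <- default_times()
  traj <- simulate_scheme(spec, init, tt)
  y <- cleaved_product(traj)
  yc <- burst_product(tt, burst_params(2, k2 = 1.0, k3 = 0.004))
  expect_lt(max(abs(y - yc)) / max(yc), 0.01)
  # apparent rates from refitting are within 2% of (k2+k3, k2 k3/(k2+k3))
  ar <- apparent_rates(traj)
  expect_lt(rel_err(ar$k_burst_app, 1.004), 0.02)
  expect_lt(rel_err(ar$k_ss_app, 1.0 * 0.004 / 1.004), 0.02)
})

test_that("product release limits turnover but not the burst", {
  base <- list(kd_target = 1, k_on_target = 10, k_c = 50, k_minus_c = 0.5,
               k_on = 1, k_off = 8, k_chem = 0.6, k_prime_minus_c = 0.0035)
  doubled <- base; doubled$k_prime_minus_c <- 2 * base$k_prime_minus_c
  rates <- function(r) {
    spec <- do.call(scheme_spec, c(list(kind = "gtsf_extended"), r))
    init <- initial_state(spec, e = 2, s = 100, gtsf = 500)
    apparent_rates(simulate_scheme(spec, init, default_times()))
  }
  a <- rates(base); b <- rates(doubled)
  expect_gt(b$k_ss_app / a$k_ss_app, 1.5)          # k_ss rises
  expect_lt(abs(b$k_burst_app - a$k_burst_app) / a$k_burst_app, 0.05)
})

test_that("simulated activator titration collapses onto the hyperbola", {
  spec <- scheme_preset("rapid_equilibrium")
  init <- initial_state(spec, e = 0.2, s = 100)  # enzyme << activator
  concs <- c(1, 4, 17, 75, 320, 1400, 5000)
  tc <- gtsf_titration_curve(spec, init, concs)
  expect_true(all(diff(tc$k_burst_app) > 0))      # monotone response
  fit <- fit_titration(titration_series(tc$conc_nM, tc$k_burst_app))
  kd_true <- spec$rates[["k_off"]] / spec$rates[["k_on"]]
  expect_lt(rel_err(fit$params$kd, kd_true), 0.10)
  # saturating concentration sits within 5% of the plateau
  expect_lt(abs(tc$k_burst_app[7] - fit$params$k_pot) / fit$params$k_pot,
            0.05)
})

test_that("zero activator reduces to the basal route", {
  spec <- scheme_preset("miwi_like")
  init <- initial_state(spec, e = 1.75, s = 100, gtsf = 0)
  ar0 <- apparent_rates(simulate_scheme(spec, init, slow_times()))
  tc <- gtsf_titration_curve(spec, init, c(0, 500),
                             times = slow_times())
  expect_equal(tc$k_burst_app[1], ar0$k_burst_app, tolerance = 1e-9)
  # basal burst rate is far below the chemistry rate constant
  expect_lt(ar0$k_burst_app, 0.1 * spec$rates[["k_chem"]])
  # and a scheme without the basal route makes no product at all
  spec2 <- scheme_spec("gtsf_extended", kd_target = 1, k_c = 50,
                       k_minus_c = 0.5, k_on = 1, k_off = 8,
                       k_chem = 0.6, k_prime_minus_c = 0.0035)
  traj2 <- simulate_scheme(spec2, initial_state(spec2, e = 2, s = 50),
                           default_times())
  expect_true(all(cleaved_product(traj2) <= 1e-10))
})

test_that("enzyme excess gives single-turnover behaviour", {
  spec <- scheme_spec("basic", k1 = 10, k_minus1 = 1, k2 = 0.2, k3 = 0.01)
  init <- initial_state(spec, e = 50, s = 2)
  tt <- seq(0, 60, by = 2)
  traj <- simulate_scheme(spec, init, tt)
  y <- cleaved_product(traj)
  expect_gt(max(y), 0.99 * 2)                    # product approaches S
  f <- fit_single_turnover(tt, y)
  expect_gt(f$r_squared, 0.99)
})

test_that("scheme validation rejects bad input", {
  expect_error(scheme_spec("basic", k1 = 10, k_minus1 = 1, k2 = 1),
               "requires rate k3")
  expect_error(scheme_spec("gtsf_extended", k_c = 1, k_minus_c = 1,
                           k_on = 1, k_off = 1, k_chem = 1,
                           k_prime_minus_c = 1),
               "kd_target")
  spec <- scheme_spec("basic", k1 = 1, k_minus1 = 1, k2 = 1, k3 = 1)
  expect_error(initial_state(spec, e = -1, s = 5), "non-negative")
  expect_error(initial_state(spec, e = 1, s = 5, XX = 1), "unknown species")
  expect_error(simulate_scheme(spec, initial_state(spec, 1, 5), c(0, 2, 1)),
               "strictly increasing")
})
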