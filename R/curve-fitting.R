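#' A single cleavage time course
#'
#' Container for one gel-quantified progress curve: product formed (nM) at
#' strictly increasing times (min), together with the assay's nominal enzyme
#' and total target concentrations and free-text condition labels.
#'
#' @param times Time points (min), strictly increasing, `times[1] >= 0`.
#' @param product Product concentrations (nM), same length as `times`. When
#'   a replicate matrix is supplied this is the per-time mean.
#' @param e_nominal Nominal enzyme (piRISC) concentration (nM), or `NA`.
#' @param s_total Total target concentration (nM), or `NA`. When known,
#'   product may not exceed it beyond `tol`.
#' @param condition Named list of free-text labels (guide id, guide length,
#'   activator and concentration, ...).
#' @param replicates Optional matrix (time x replicate) of per-replicate
#'   product values; `product` defaults to its row means.
#' @param sd Optional per-time standard deviations (nM).
#' @param tol Relative tolerance for the `product <= s_total` check, to
#'   accommodate quantification noise. Default 0.05.
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(times, product = NULL, e_nominal = NA_real_,
                           s_total = NA_real_, condition = list(),
                           replicates = NULL, sd = NULL, tol = 0.05) {
  stopifnot(is.numeric(times))
  if (!is.null(replicates)) {
    replicates <- as.matrix(replicates)
    if (nrow(replicates) != length(times)) {
      stop("replicate matrix must have one row per time point")
    }
    if (is.null(product)) product <- rowMeans(replicates)
    if (is.null(sd) && ncol(replicates) > 1L) {
      sd <- apply(replicates, 1L, stats::sd)
    }
  }
  stopifnot(is.numeric(product))
  n <- length(times)
  if (n < 4L || length(product) != n) {
    stop("a progress curve needs >= 4 time points with matching product ",
         "values (got ", n, " times, ", length(product), " products)")
  }
  if (any(!is.finite(times)) || times[1] < 0 || any(diff(times) <= 0)) {
    stop("times must be finite, non-negative and strictly increasing")
  }
  if (any(!is.finite(product)) || any(product < 0)) {
    stop("product concentrations must be finite and non-negative")
  }
  if (is.finite(s_total) && any(product > s_total * (1 + tol))) {
    stop("product exceeds total target concentration (s_total = ",
         s_total, " nM) beyond tolerance")
  }
  structure(list(times = as.numeric(times), product = as.numeric(product),
                 e_nominal = as.numeric(e_nominal),
                 s_total = as.numeric(s_total),
                 condition = condition, replicates = replicates,
                 sd = if (is.null(sd)) NULL else as.numeric(sd)),
            class = "progress_curve")
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf(
    "progress curve: %d points, t = %.3g-%.3g min, P up to %.3g nM\n",
    length(x$times), min(x$times), max(x$times), max(x$product)))
  if (is.finite(x$e_nominal))
    cat(sprintf("  nominal enzyme %.3g nM", x$e_nominal))
  if (is.finite(x$s_total)) cat(sprintf(", total target %.3g nM", x$s_total))
  cat("\n")
  invisible(x)
}

#' An activator-titration series
#'
#' @param concs Activator concentrations (nM), `>= 0`; at least 3 distinct.
#' @param k_burst_obs Fitted pre-steady-state rates (min^-1), `>= 0`.
#' @param labels Optional activator identity label(s) (e.g. wild-type or a
#'   PIWI-interaction mutant).
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(concs, k_burst_obs, labels = character()) {
  stopifnot(is.numeric(concs), is.numeric(k_burst_obs))
  if (length(concs) != length(k_burst_obs)) {
    stop("concs and k_burst_obs must have the same length")
  }
  if (length(unique(concs)) < 3L) {
    stop("a titration series needs >= 3 distinct activator concentrations")
  }
  if (any(!is.finite(concs)) || any(concs < 0) ||
      any(!is.finite(k_burst_obs)) || any(k_burst_obs < 0)) {
    stop("concentrations and rates must be finite and non-negative")
  }
  structure(list(concs = as.numeric(concs),
                 k_burst_obs = as.numeric(k_burst_obs),
                 labels = labels),
            class = "titration_series")
}

#' Fit options
#'
#' @param fix_e_active Optional fixed active-enzyme concentration (nM); when
#'   `NULL` (default) the amplitude is a free parameter.
#' @param replicates How replicate columns are used: `"average"` fits the
#'   per-time mean (default, mirroring fitting of mean values), `"pooled"`
#'   fits all replicate points jointly.
#' @param weights Optional per-point weights (e.g. 1/sd^2); default
#'   unweighted.
#' @param basal_offset For titration fits: include a basal-rate intercept k0
#'   in the hyperbola. Off by default (the canonical model has no intercept).
#' @param ci Compute residual-bootstrap confidence intervals.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap; required when `ci = TRUE`.
#' @return A list of class `fit_opts`.
#' @export
fit_opts <- function(fix_e_active = NULL,
                     replicates = c("average", "pooled"),
                     weights = NULL, basal_offset = FALSE,
                     ci = FALSE, n_boot = 1000L, seed = NULL) {
  replicates <- match.arg(replicates)
  if (ci && is.null(seed)) {
    stop("bootstrap confidence intervals require a seed")
  }
  structure(list(fix_e_active = fix_e_active, replicates = replicates,
                 weights = weights, basal_offset = basal_offset,
                 ci = ci, n_boot = as.integer(n_boot), seed = seed),
            class = "fit_opts")
}

## ---- internal: profile least squares for the burst model --------------------
## For fixed lambda = k2 + k3 the model P = A (1 - exp(-lambda t)) + m t is
## linear in the burst amplitude A and steady slope m; both are constrained
## non-negative. Profiling lambda reduces the fit to a 1-D search, which is
## robust and needs no starting guess.

.burst_lin_solve <- function(t, y, lambda, w) {
  xb <- 1 - exp(-lambda * t)
  X <- cbind(xb, t)
  sw <- sqrt(w)
  cf <- tryCatch(stats::lm.fit(X * sw, y * sw)$coefficients,
                 error = function(e) c(NA_real_, NA_real_))
  cf[!is.finite(cf)] <- -1  # force fallback when collinear
  A <- cf[1]; m <- cf[2]
  if (A < 0 || m < 0) {
    # clamp the offending coefficient at 0, re-solve the other
    mA <- sum(w * xb * y) / sum(w * xb * xb)       # m = 0 branch
    mM <- sum(w * t * y) / sum(w * t * t)          # A = 0 branch
    candidates <- list(c(max(mA, 0), 0), c(0, max(mM, 0)))
    ssrs <- vapply(candidates, function(cm) {
      r <- y - (cm[1] * xb + cm[2] * t); sum(w * r * r)
    }, numeric(1))
    best <- candidates[[which.min(ssrs)]]
    A <- best[1]; m <- best[2]
  }
  r <- y - (A * xb + m * t)
  list(A = A, m = m, ssr = sum(w * r * r))
}

## Back-solve (A, lambda, m) -> (E, k2, k3). Unique: A = E (k2/lambda)^2 and
## m = E k2 k3 / lambda give k2 = A lambda^2 / (m + A lambda),
## k3 = lambda m / (m + A lambda), E = A lambda^2 / k2^2.
.burst_backsolve <- function(A, lambda, m) {
  denom <- m + A * lambda
  if (denom <= 0 || lambda <= 0) {
    return(list(e_active = 0, k2 = 0, k3 = 0))
  }
  k2 <- A * lambda^2 / denom
  k3 <- lambda - k2
  e <- if (k2 > 0) A * lambda^2 / k2^2 else 0
  list(e_active = e, k2 = max(k2, 0), k3 = max(k3, 0))
}

.fit_burst_core <- function(t, y, w = NULL, fix_e_active = NULL,
                            lambda_range = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  tp <- t[t > 0]
  if (is.null(lambda_range)) {
    lambda_range <- c(1e-3 / max(t), 5e2 / min(tp))
  }
  lgrid <- 10^seq(log10(lambda_range[1]), log10(lambda_range[2]),
                  length.out = 121L)

  if (is.null(fix_e_active)) {
    obj <- function(l10) .burst_lin_solve(t, y, 10^l10, w)$ssr
    l10g <- log10(lgrid)
    ssr_g <- vapply(l10g, obj, numeric(1))
    i <- which.min(ssr_g)
    lo <- l10g[max(i - 1L, 1L)]
    hi <- l10g[min(i + 1L, length(l10g))]
    opt <- stats::optimize(obj, c(lo, hi), tol = 1e-11)
    # optimize() can stagnate when the bracket edge is the optimum; polish
    lam <- 10^opt$minimum
    sol <- .burst_lin_solve(t, y, lam, w)
    bp <- .burst_backsolve(sol$A, lam, sol$m)
    converged <- is.finite(sol$ssr)
  } else {
    # E fixed: P = E [ phi^2 (1 - e^-lambda t) + phi (1 - phi) lambda t ]
    E <- fix_e_active
    obj2 <- function(p) {
      lam <- 10^p[1]; phi <- p[2]
      mu <- E * (phi^2 * (1 - exp(-lam * t)) + phi * (1 - phi) * lam * t)
      sum(w * (y - mu)^2)
    }
    starts <- expand.grid(l = log10(c(lambda_range[1] * 10, sqrt(prod(lambda_range)),
                                      lambda_range[2] / 10)),
                          phi = c(0.5, 0.9, 0.999))
    best <- NULL
    for (j in seq_len(nrow(starts))) {
      o <- stats::optim(as.numeric(starts[j, ]), obj2, method = "L-BFGS-B",
                        lower = c(log10(lambda_range[1]), 1e-8),
                        upper = c(log10(lambda_range[2]), 1),
                        control = list(factr = 1e4))
      if (is.null(best) || o$value < best$value) best <- o
    }
    lam <- 10^best$par[1]; phi <- best$par[2]
    bp <- list(e_active = E, k2 = phi * lam, k3 = (1 - phi) * lam)
    sol <- list(A = E * phi^2,
                m = E * phi * (1 - phi) * lam,
                ssr = best$value)
    converged <- best$convergence == 0
  }
  fitted <- sol$A * (1 - exp(-lam * t)) + sol$m * t
  list(params = burst_params(bp$e_active,
                             rate_constants(bp$k2, bp$k3)),
       A = sol$A, lambda = lam, m = sol$m, ssr = sol$ssr,
       fitted = fitted, residuals = y - fitted, converged = converged)
}

#' Fit the burst-and-steady-state model to a progress curve
#'
#' Estimates the apparent active-enzyme concentration and the rate constants
#' (k2, k3) by nonlinear least squares. Internally the identifiable
#' reparameterisation (A, lambda, m) — burst amplitude, burst rate
#' lambda = k2 + k3, and steady-state slope — is used: for fixed lambda the
#' model is linear in (A, m), so lambda is profiled over a log grid and
#' refined by 1-D optimisation, then (E, k2, k3) are recovered by the unique
#' back-solution k2 = A lambda^2 / (m + A lambda). This sidesteps the
#' near-symmetric k2/k3 ill-conditioning of a direct 3-parameter search.
#'
#' @param curve A [progress_curve()].
#' @param opts A [fit_opts()] object.
#' @return An object of class `burst_fit` with components `params`
#'   ([burst_params()]), `k_burst`, `k_ss`, `ssr`, `fitted`, `residuals`,
#'   `converged`, `n_points` and, when requested, `ci` (95% bootstrap
#'   percentile intervals per quantity).
#' @export
fit_burst <- function(curve, opts = fit_opts()) {
  stopifnot(inherits(curve, "progress_curve"), inherits(opts, "fit_opts"))
  if (opts$replicates == "pooled" && !is.null(curve$replicates)) {
    t <- rep(curve$times, ncol(curve$replicates))
    y <- as.numeric(curve$replicates)
  } else {
    t <- curve$times
    y <- curve$product
  }
  if (length(y) < 4L) stop("fewer data points than model parameters")
  scale <- max(abs(y))
  if (scale <= 0 || (max(y) - min(y)) <= 1e-12 * max(scale, 1)) {
    stop("no detectable product: signal is all-zero or flat")
  }
  w <- opts$weights
  core <- .fit_burst_core(t, y, w, fix_e_active = opts$fix_e_active)
  dr <- derived_rates(core$params$rates)
  res <- structure(list(params = core$params,
                        k_burst = dr$k_burst, k_ss = dr$k_ss,
                        ssr = core$ssr, fitted = core$fitted,
                        residuals = core$residuals,
                        converged = core$converged,
                        n_points = length(y), ci = NULL,
                        data = list(times = t, product = y),
                        opts = opts),
                   class = "burst_fit")
  if (isTRUE(opts$ci)) {
    res$ci <- bootstrap_cis("burst", list(times = t, product = y), res,
                            n_boot = opts$n_boot, seed = opts$seed,
                            opts = opts)
  }
  res
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf(
    "burst fit (%d points, converged = %s):\n", x$n_points, x$converged))
  cat(sprintf("  E_active = %.4g nM, k2 = %.4g, k3 = %.4g min^-1\n",
              x$params$e_active, x$params$rates$k2, x$params$rates$k3))
  cat(sprintf("  k_burst = %.4g min^-1, k_ss = %.4g min^-1, SSR = %.4g nM^2\n",
              x$k_burst, x$k_ss, x$ssr))
  invisible(x)
}

## ---- internal: profile least squares for the hyperbola ----------------------
.fit_titration_core <- function(conc, y, w = NULL, basal_offset = FALSE,
                                kd_range = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  cp <- conc[conc > 0]
  if (is.null(kd_range)) kd_range <- c(min(cp) * 1e-3, max(cp) * 1e3)

  lin <- function(kd) {
    x <- conc / (kd + conc)
    if (basal_offset) {
      X <- cbind(x, 1)
      cf <- stats::lm.fit(X * sqrt(w), y * sqrt(w))$coefficients
      cf[!is.finite(cf)] <- 0
      kpot <- max(cf[1], 0); k0 <- max(cf[2], 0)
    } else {
      kpot <- max(sum(w * x * y) / sum(w * x * x), 0); k0 <- 0
    }
    r <- y - (kpot * x + k0)
    list(k_pot = kpot, k0 = k0, ssr = sum(w * r * r))
  }
  obj <- function(l10) lin(10^l10)$ssr
  l10g <- seq(log10(kd_range[1]), log10(kd_range[2]), length.out = 81L)
  ssr_g <- vapply(l10g, obj, numeric(1))
  i <- which.min(ssr_g)
  opt <- stats::optimize(obj, c(l10g[max(i - 1L, 1L)],
                                l10g[min(i + 1L, length(l10g))]),
                         tol = 1e-11)
  kd <- 10^opt$minimum
  sol <- lin(kd)
  x <- conc / (kd + conc)
  fitted <- sol$k_pot * x + sol$k0
  list(params = hyperbola_params(sol$k_pot, kd), k0 = sol$k0,
       ssr = sol$ssr, fitted = fitted, residuals = y - fitted,
       converged = is.finite(sol$ssr))
}

#' Fit the hyperbolic activation model to a titration series
#'
#' Least-squares estimate of (k_pot, kd) for
#' k_burst = k_pot * conc / (kd + conc). kd is profiled on a log grid (for
#' fixed kd the model is linear in k_pot) and refined by 1-D optimisation.
#'
#' @param series A [titration_series()].
#' @param opts A [fit_opts()]; `basal_offset = TRUE` adds an intercept k0
#'   (off by default).
#' @return An object of class `titration_fit` with `params`
#'   ([hyperbola_params()]), `ssr`, `converged`, optional `ci`.
#' @export
fit_titration <- function(series, opts = fit_opts()) {
  stopifnot(inherits(series, "titration_series"), inherits(opts, "fit_opts"))
  conc <- series$concs
  y <- series$k_burst_obs
  if (length(unique(conc)) < 3L) {
    stop("titration fit needs >= 3 distinct concentrations")
  }
  if (max(y) - min(y) <= 1e-12 * max(max(abs(y)), 1)) {
    stop("saturated or flat series: observed rates do not vary with ",
         "concentration; the series cannot constrain kd")
  }
  core <- .fit_titration_core(conc, y, opts$weights,
                              basal_offset = opts$basal_offset)
  kd <- core$params$kd
  if (kd < min(conc[conc > 0]) || kd > max(conc)) {
    warning("fitted kd (", signif(kd, 3),
            " nM) lies outside the sampled concentration range; ",
            "the estimate is poorly constrained")
  }
  res <- structure(list(params = core$params, k0 = core$k0,
                        ssr = core$ssr, fitted = core$fitted,
                        residuals = core$residuals,
                        converged = core$converged,
                        n_points = length(y), ci = NULL,
                        data = list(concs = conc, k_burst_obs = y),
                        opts = opts),
                   class = "titration_fit")
  if (isTRUE(opts$ci)) {
    res$ci <- bootstrap_cis("titration",
                            list(concs = conc, k_burst_obs = y), res,
                            n_boot = opts$n_boot, seed = opts$seed,
                            opts = opts)
  }
  res
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("titration fit (%d points, converged = %s):\n",
              x$n_points, x$converged))
  cat(sprintf("  k_pot = %.4g min^-1, Kd = %.4g nM, SSR = %.4g\n",
              x$params$k_pot, x$params$kd, x$ssr))
  if (!is.null(x$ci)) {
    for (nm in rownames(x$ci)) {
      cat(sprintf("  %s 95%% CI: [%.4g, %.4g]\n",
                  nm, x$ci[nm, 1], x$ci[nm, 2]))
    }
  }
  invisible(x)
}

#' Residual-resampling bootstrap confidence intervals
#'
#' Percentile intervals from refitting `n_boot` pseudo-datasets formed as
#' fitted + resampled residuals. Deterministic given the seed.
#'
#' @param kind `"burst"` or `"titration"`.
#' @param data For `"burst"`, a list with `times` and `product`; for
#'   `"titration"`, a list with `concs` and `k_burst_obs`.
#' @param fit The converged point fit ([fit_burst()] / [fit_titration()]).
#' @param n_boot Number of bootstrap replicates, `>= 100`.
#' @param seed Integer seed (required).
#' @param opts Fit options forwarded to the refits.
#' @return A matrix with one row per quantity (`e_active`, `k2`, `k3`,
#'   `k_burst`, `k_ss` or `k_pot`, `kd`) and columns `lower`, `upper`.
#'   Attribute `degenerate` flags an all-zero-residual fit (zero-width
#'   intervals).
#' @export
bootstrap_cis <- function(kind = c("burst", "titration"), data, fit,
                          n_boot = 1000L, seed, opts = fit_opts()) {
  kind <- match.arg(kind)
  if (!isTRUE(fit$converged)) stop("point fit did not converge")
  if (n_boot < 100L) stop("n_boot must be >= 100")
  if (missing(seed) || is.null(seed)) stop("bootstrap requires a seed")
  res <- fit$residuals
  fitted <- fit$fitted
  degenerate <- all(abs(res) <= 1e-8 * max(max(abs(fitted)), 1))

  qnames <- if (kind == "burst") {
    c("e_active", "k2", "k3", "k_burst", "k_ss")
  } else c("k_pot", "kd")

  if (degenerate) {
    pt <- if (kind == "burst") {
      dr <- derived_rates(fit$params$rates)
      c(fit$params$e_active, fit$params$rates$k2, fit$params$rates$k3,
        dr$k_burst, dr$k_ss)
    } else c(fit$params$k_pot, fit$params$kd)
    ci <- cbind(lower = pt, upper = pt)
    rownames(ci) <- qnames
    attr(ci, "degenerate") <- TRUE
    return(ci)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  n <- length(res)
  draws <- matrix(NA_real_, n_boot, length(qnames))
  for (b in seq_len(n_boot)) {
    yb <- fitted + sample(res, n, replace = TRUE)
    est <- tryCatch({
      if (kind == "burst") {
        cf <- .fit_burst_core(data$times, yb,
                              fix_e_active = opts$fix_e_active)
        dr <- derived_rates(cf$params$rates)
        c(cf$params$e_active, cf$params$rates$k2, cf$params$rates$k3,
          dr$k_burst, dr$k_ss)
      } else {
        cf <- .fit_titration_core(data$concs, yb,
                                  basal_offset = opts$basal_offset)
        c(cf$params$k_pot, cf$params$kd)
      }
    }, error = function(e) rep(NA_real_, length(qnames)))
    draws[b, ] <- est
  }
  ci <- t(apply(draws, 2L, stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE, names = FALSE))
  dimnames(ci) <- list(qnames, c("lower", "upper"))
  attr(ci, "degenerate") <- FALSE
  ci
}

#' Brute-force grid oracle for the burst fit
#'
#' Exhaustive sum-of-squared-residual minimisation over a finite grid of
#' (e_active, k2, k3). Slow and crude by design: it serves as an independent
#' check that [fit_burst()] attains at least grid-level optimality. Ties are
#' broken by smallest k2, then k3, then e_active.
#'
#' @param curve A [progress_curve()].
#' @param e_grid,k2_grid,k3_grid Numeric grids, all non-empty, values `>= 0`.
#' @return A list with `params` ([burst_params()]) and `ssr`.
#' @export
grid_oracle_fit <- function(curve, e_grid, k2_grid, k3_grid) {
  stopifnot(inherits(curve, "progress_curve"))
  if (length(e_grid) == 0L || length(k2_grid) == 0L || length(k3_grid) == 0L) {
    stop("all parameter grids must be non-empty")
  }
  g <- expand.grid(k3 = sort(k3_grid), k2 = sort(k2_grid),
                   e = sort(e_grid))  # order => first min is the tie-break
  g <- g[order(g$k2, g$k3, g$e), ]
  t <- curve$times
  y <- curve$product
  best_ssr <- Inf
  best <- NULL
  for (i in seq_len(nrow(g))) {
    lam <- g$k2[i] + g$k3[i]
    mu <- if (lam == 0) rep(0, length(t)) else {
      g$e[i] * ((g$k2[i] / lam)^2 * (1 - exp(-lam * t)) +
                (g$k2[i] * g$k3[i] / lam) * t)
    }
    ssr <- sum((y - mu)^2)
    if (is.null(best) || ssr < best_ssr) {  # ties keep the earlier
      best_ssr <- ssr                        # (smallest k2, k3, e) entry
      best <- g[i, ]
    }
  }
  list(params = burst_params(best$e, rate_constants(best$k2, best$k3)),
       ssr = best_ssr)
}

#' Fold-stimulation of the burst rate between two conditions
#'
#' @param fit_a Reference (e.g. piRISC alone) [fit_burst()] result.
#' @param fit_b Stimulated (e.g. plus GTSF1) [fit_burst()] result.
#' @return The ratio `k_burst(b) / k_burst(a)`.
#' @export
fold_stimulation <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "burst_fit"), inherits(fit_b, "burst_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    stop("both fits must have converged")
  }
  if (fit_a$k_burst <= 0) stop("reference k_burst is zero; fold undefined")
  fit_b$k_burst / fit_a$k_burst
}

#' Fit a single exponential to a single-turnover trace
#'
#' Fits A (1 - exp(-k t)) by profiling k (A is linear given k). Used to
#' extract single-turnover rates and to check that enzyme-excess simulations
#' collapse to a single exponential.
#'
#' @param times Time points (min).
#' @param product Product values (nM).
#' @return A list with `amplitude`, `k`, `ssr`, `r_squared`, `fitted`.
#' @export
fit_single_turnover <- function(times, product) {
  stopifnot(is.numeric(times), is.numeric(product),
            length(times) == length(product), length(times) >= 3L)
  t <- times; y <- product
  if (max(y) - min(y) <= 0) stop("no detectable product: flat signal")
  lin <- function(k) {
    x <- 1 - exp(-k * t)
    A <- max(sum(x * y) / sum(x * x), 0)
    r <- y - A * x
    list(A = A, ssr = sum(r * r))
  }
  obj <- function(l10) lin(10^l10)$ssr
  tp <- t[t > 0]
  l10g <- seq(log10(1e-3 / max(t)), log10(5e2 / min(tp)), length.out = 101L)
  ssr_g <- vapply(l10g, obj, numeric(1))
  i <- which.min(ssr_g)
  opt <- stats::optimize(obj, c(l10g[max(i - 1L, 1L)],
                                l10g[min(i + 1L, length(l10g))]),
                         tol = 1e-11)
  k <- 10^opt$minimum
  sol <- lin(k)
  fitted <- sol$A * (1 - exp(-k * t))
  ss_tot <- sum((y - mean(y))^2)
  list(amplitude = sol$A, k = k, ssr = sol$ssr,
       r_squared = if (ss_tot > 0) 1 - sol$ssr / ss_tot else NA_real_,
       fitted = fitted)
}
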