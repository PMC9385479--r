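#' Rate constants for the two-step cleavage cycle
#'
#' The minimal multiple-turnover scheme is E + S <-> ES -> EP -> E + P, where
#' the first irreversible step (rate `k2`, min^-1) is the endonucleolytic
#' chemistry and the second (rate `k3`, min^-1) is release of the cleaved
#' products, which regenerates free enzyme.
#'
#' @param k2 First-order cleavage-step rate constant (min^-1), `>= 0`.
#' @param k3 First-order product-release rate constant (min^-1), `>= 0`.
#' @return An object of class `rate_constants`.
#' @seealso [derived_rates()], [burst_params()]
#' @export
rate_constants <- function(k2, k3) {
  stopifnot(is.numeric(k2), length(k2) == 1L, is.finite(k2),
            is.numeric(k3), length(k3) == 1L, is.finite(k3))
  if (k2 < 0 || k3 < 0) {
    stop("rate constants must be non-negative (got k2 = ", k2,
         ", k3 = ", k3, ")")
  }
  structure(list(k2 = as.numeric(k2), k3 = as.numeric(k3)),
            class = "rate_constants")
}

#' Parameters of the burst-and-steady-state progress curve
#'
#' @param e_active Apparent concentration of catalytically active enzyme
#'   (nM), `>= 0`. Estimated from the burst amplitude; often well below the
#'   nominal enzyme concentration.
#' @param rates A [rate_constants()] object, or `k2`/`k3` given separately.
#' @param k2,k3 Convenience scalars used when `rates` is missing.
#' @return An object of class `burst_params` with fields `e_active` and
#'   `rates`.
#' @export
burst_params <- function(e_active, rates = NULL, k2 = NULL, k3 = NULL) {
  if (is.null(rates)) rates <- rate_constants(k2, k3)
  stopifnot(inherits(rates, "rate_constants"),
            is.numeric(e_active), length(e_active) == 1L, is.finite(e_active))
  if (e_active < 0) stop("e_active must be non-negative")
  structure(list(e_active = as.numeric(e_active), rates = rates),
            class = "burst_params")
}

#' @export
print.burst_params <- function(x, ...) {
  dr <- derived_rates(x$rates)
  cat(sprintf(
    "burst params: E_active = %.4g nM, k2 = %.4g, k3 = %.4g min^-1\n",
    x$e_active, x$rates$k2, x$rates$k3))
  cat(sprintf("  k_burst = %.4g min^-1, k_ss = %.4g min^-1\n",
              dr$k_burst, dr$k_ss))
  invisible(x)
}

#' Parameters of the hyperbolic activator-titration model
#'
#' The pre-steady-state rate as a function of activator concentration is
#' modelled as k_burst = k_pot * conc / (kd + conc): a rectangular hyperbola
#' through the origin with asymptote `k_pot`.
#'
#' @param k_pot Maximum observable pre-steady-state rate (min^-1), `>= 0`.
#' @param kd Activator dissociation constant (nM), `> 0`.
#' @return An object of class `hyperbola_params`.
#' @export
hyperbola_params <- function(k_pot, kd) {
  stopifnot(is.numeric(k_pot), length(k_pot) == 1L, is.finite(k_pot),
            is.numeric(kd), length(kd) == 1L, is.finite(kd))
  if (k_pot < 0) stop("k_pot must be non-negative")
  if (kd <= 0) stop("kd must be strictly positive")
  structure(list(k_pot = as.numeric(k_pot), kd = as.numeric(kd)),
            class = "hyperbola_params")
}

#' Burst-and-steady-state progress curve
#'
#' Product formed at time `t` under the multiple-turnover two-step cycle,
#'
#'   P(t) = E * \[ (k2/(k2+k3))^2 * (1 - exp(-(k2+k3) t))
#'                + (k2 k3/(k2+k3)) * t \]
#'
#' where E is the apparent active-enzyme concentration. The curve is a fast
#' exponential burst of rate k_burst = k2 + k3 followed by a linear
#' steady-state phase of slope E * k_ss. "Product" is total cleaved target
#' (enzyme-bound plus released), as measured by a quench-and-gel assay.
#'
#' The expression is unbounded in `t`; it is physically valid only while
#' P <= total substrate. No clamping is applied here — the synthetic-data
#' generator truncates at the substrate ceiling instead.
#'
#' @param t Time(s) in minutes, `>= 0`. Vectorised.
#' @param params A [burst_params()] object.
#' @return Product concentration(s) in nM, same length as `t`. Returns 0
#'   whenever `k2 = 0` (no chemistry) and at `t = 0`.
#' @export
burst_product <- function(t, params) {
  stopifnot(inherits(params, "burst_params"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("time points must be finite and non-negative")
  }
  k2 <- params$rates$k2
  k3 <- params$rates$k3
  lambda <- k2 + k3
  if (lambda == 0) return(rep(0, length(t)))
  amp_frac <- (k2 / lambda)^2
  params$e_active * (amp_frac * (1 - exp(-lambda * t)) +
                     (k2 * k3 / lambda) * t)
}

#' Derived burst and steady-state rates
#'
#' k_burst = k2 + k3 is the observed first-order rate of the pre-steady-state
#' phase; k_cat = k_ss = k2 k3 / (k2 + k3) is the steady-state turnover rate.
#' k_ss <= k_burst / 4 always, with equality iff k2 = k3.
#'
#' @param rates A [rate_constants()] object.
#' @return A list with components `k_burst` and `k_ss` (min^-1). Both are 0
#'   when `k2 = k3 = 0`.
#' @export
derived_rates <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  k2 <- rates$k2
  k3 <- rates$k3
  lambda <- k2 + k3
  list(k_burst = lambda,
       k_ss = if (lambda == 0) 0 else k2 * k3 / lambda)
}

#' Hyperbolic dependence of the burst rate on activator concentration
#'
#' k_burst(conc) = k_pot * conc / (kd + conc). Strictly increasing in `conc`
#' with asymptote `k_pot`; passes through the origin (the model carries no
#' basal-activity intercept).
#'
#' @param conc Activator concentration(s) in nM, `>= 0`. Vectorised.
#' @param params A [hyperbola_params()] object.
#' @return Pre-steady-state rate(s) in min^-1.
#' @export
hyperbolic_rate <- function(conc, params) {
  stopifnot(inherits(params, "hyperbola_params"), is.numeric(conc))
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("activator concentrations must be finite and non-negative")
  }
  params$k_pot * conc / (params$kd + conc)
}

#' Single-turnover progress curve
#'
#' Under enzyme excess (E > S) there is no linear phase; product formation is
#' the single exponential A * (1 - exp(-k t)). This is the standard form used
#' to extract a single-turnover rate when the fitted equation is not
#' otherwise constrained.
#'
#' @param t Time(s) in minutes, `>= 0`. Vectorised.
#' @param amplitude Reaction amplitude (nM), `>= 0`; upper bound of the curve.
#' @param k First-order rate constant (min^-1), `>= 0`.
#' @return Product concentration(s) in nM, bounded above by `amplitude`.
#' @export
single_turnover_product <- function(t, amplitude, k) {
  stopifnot(is.numeric(t), is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(k), length(k) == 1L)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("time points must be finite and non-negative")
  }
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("amplitude must be finite and non-negative")
  }
  if (!is.finite(k) || k < 0) stop("rate constant must be non-negative")
  amplitude * (1 - exp(-k * t))
}
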