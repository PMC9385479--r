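## Seeded synthetic-data generation emulating gel-quantified cleavage assays.
## The defaults encode the assay regime of the slow PIWI slicer: a few nM of
## enzyme (of which only a fraction is catalytically active) acting on a few
## nM of radiolabelled target over an hour, quantified in triplicate by
## densitometry with multiplicative noise.

#' Default assay time grid
#'
#' 16 points over 0-60 min with denser early sampling, so that both the burst
#' and the linear phase are resolved for burst rates down to ~0.05 min^-1.
#' For slower conditions pass a longer grid (see [slow_times()]).
#'
#' @return Numeric vector of times (min).
#' @export
default_times <- function() {
  c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24, 32, 45, 60)
}

#' Extended time grid for slow conditions
#'
#' 16 points over 0-480 min; appropriate when the burst rate is of order
#' 0.005 min^-1 so that the exponential phase develops within the assay.
#'
#' @return Numeric vector of times (min).
#' @export
slow_times <- function() {
  c(0, 2, 5, 10, 20, 30, 45, 60, 90, 120, 160, 200, 260, 320, 400, 480)
}

#' Assay design for synthetic progress curves
#'
#' Defaults emulate the canonical slow-slicer regime: 5 nM nominal enzyme of
#' which ~35% is apparently active, 5 nM target, triplicates, 0-60 min.
#' (With a burst rate of 0.01 min^-1 this design cleaves ~15% of the target
#' in an hour.)
#'
#' @param times Strictly increasing time grid (min).
#' @param e_nominal Nominal enzyme concentration (nM), `> 0`.
#' @param active_fraction Fraction of enzyme that is catalytically active,
#'   in (0, 1]. The generator uses `e_active = e_nominal * active_fraction`.
#' @param s_total Total target concentration (nM), `> 0`.
#' @param replicates Number of replicates (default 3).
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(times = default_times(), e_nominal = 5,
                         active_fraction = 0.35, s_total = 5,
                         replicates = 3L) {
  stopifnot(is.numeric(times), length(times) >= 4L)
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  if (e_nominal <= 0 || s_total <= 0) stop("concentrations must be positive")
  if (active_fraction <= 0 || active_fraction > 1) {
    stop("active_fraction must be in (0, 1]")
  }
  if (replicates < 1L) stop("need at least one replicate")
  structure(list(times = as.numeric(times), e_nominal = e_nominal,
                 active_fraction = active_fraction, s_total = s_total,
                 replicates = as.integer(replicates)),
            class = "assay_design")
}

#' Gel-densitometry noise model
#'
#' Heteroscedastic: observed = max(0, true * (1 + eps_cv) + eps_floor), with
#' eps_cv ~ N(0, cv^2) and eps_floor ~ N(0, floor^2). Defaults (cv = 5%,
#' floor = 0.05 nM) match the scatter of triplicate gel quantification.
#'
#' @param cv Multiplicative coefficient of variation (fraction), `>= 0`.
#' @param floor Additive noise floor standard deviation (nM), `>= 0`.
#' @param seed Integer seed; required whenever `cv > 0` or `floor > 0`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.05, floor = 0.05, seed = NULL) {
  if (cv < 0 || floor < 0) stop("noise parameters must be non-negative")
  if ((cv > 0 || floor > 0) && is.null(seed)) {
    stop("a seed is required for any nonzero noise")
  }
  structure(list(cv = cv, floor = floor, seed = seed), class = "noise_model")
}

#' Noiseless generation shortcut
#' @return A zero-noise [noise_model()].
#' @export
no_noise <- function() noise_model(cv = 0, floor = 0)

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.apply_noise <- function(p, noise) {
  if (noise$cv == 0 && noise$floor == 0) return(p)
  n <- length(p)
  pmax(0, p * (1 + stats::rnorm(n, 0, noise$cv)) +
          stats::rnorm(n, 0, noise$floor))
}

#' Generate a synthetic progress curve with known truth
#'
#' Evaluates the burst-and-steady-state model on the design grid with
#' `e_active = e_nominal * active_fraction`, truncates at the total target
#' concentration (the model-validity boundary the closed form ignores), and
#' applies seeded heteroscedastic noise per replicate.
#'
#' @param design An [assay_design()].
#' @param truth A [rate_constants()] object (the true k2, k3), or a
#'   [burst_params()] whose rates are used (its `e_active` is ignored — the
#'   design determines the active-enzyme concentration).
#' @param noise A [noise_model()].
#' @param seed Optional seed overriding `noise$seed`.
#' @return A list of class `synth_curve`: `curve` ([progress_curve()], with
#'   replicate matrix and per-time means), `truth` (a [burst_params()] with
#'   the design's e_active), `design`, `noise`.
#' @export
gen_progress_curve <- function(design = assay_design(), truth,
                               noise = no_noise(), seed = noise$seed) {
  stopifnot(inherits(design, "assay_design"), inherits(noise, "noise_model"))
  if (inherits(truth, "burst_params")) truth <- truth$rates
  stopifnot(inherits(truth, "rate_constants"))
  e_active <- design$e_nominal * design$active_fraction
  bp <- burst_params(e_active, truth)
  p <- burst_product(design$times, bp)
  if (length(p) >= 2L && p[2] > design$s_total) {
    stop("substrate exhausted before the second time point; ",
         "use denser early sampling")
  }
  p <- pmin(p, design$s_total)
  noisy <- noise$cv > 0 || noise$floor > 0
  if (noisy && is.null(seed)) stop("a seed is required for nonzero noise")
  reps <- if (noisy) {
    .with_seed(seed, {
      vapply(seq_len(design$replicates),
             function(i) pmin(.apply_noise(p, noise), design$s_total),
             numeric(length(p)))
    })
  } else {
    matrix(rep(p, design$replicates), ncol = design$replicates)
  }
  curve <- progress_curve(design$times, replicates = reps,
                          e_nominal = design$e_nominal,
                          s_total = design$s_total)
  structure(list(curve = curve, truth = bp, design = design, noise = noise),
            class = "synth_curve")
}

#' Default 7-point log-spaced activator concentration series (1-5,000 nM)
#' @param n Number of points.
#' @param max_conc Top concentration (nM).
#' @return Numeric vector of concentrations (nM).
#' @export
default_titration_concs <- function(n = 7L, max_conc = 5000) {
  10^seq(0, log10(max_conc), length.out = n)
}

#' Generate a synthetic activator-titration series with known truth
#'
#' @param concs Activator concentrations (nM), within \[0, 1e5\].
#' @param truth A [hyperbola_params()].
#' @param noise A [noise_model()] (multiplicative part applies to the rates;
#'   the additive floor is interpreted in min^-1 here and defaults off).
#' @param seed Optional seed overriding `noise$seed`.
#' @return A list of class `synth_titration`: `series`
#'   ([titration_series()]), `truth`, `meta` (includes
#'   `max_conc_over_kd`).
#' @export
gen_titration <- function(concs = default_titration_concs(), truth,
                          noise = no_noise(), seed = noise$seed) {
  stopifnot(inherits(truth, "hyperbola_params"),
            inherits(noise, "noise_model"))
  if (length(concs) == 0L) stop("empty concentration series")
  if (any(concs < 0) || any(concs > 1e5)) {
    stop("concentrations must lie within [0, 1e5] nM")
  }
  k <- hyperbolic_rate(concs, truth)
  noisy <- noise$cv > 0 || noise$floor > 0
  if (noisy) {
    if (is.null(seed)) stop("a seed is required for nonzero noise")
    k <- .with_seed(seed, .apply_noise(k, noise))
  }
  series <- titration_series(concs, k)
  structure(list(series = series, truth = truth,
                 meta = list(max_conc_over_kd = max(concs) / truth$kd)),
            class = "synth_titration")
}

#' Default guide-length truth map
#'
#' Per-length true (k_burst, k_ss) pairs for the 16/21/26/30-nt panel,
#' calibrated once to the printed fold-relations — shortening the guide from
#' 30 to 16 nt drops k_burst by more than 50-fold (here 60x) and raises k_ss
#' about ninefold (here 10x) — with monotone behaviour at the intermediate
#' lengths. Stored as k_burst/k_ss and converted to (k2, k3) by inverting
#' k2 + k3 = k_burst, k2 k3 = k_ss * k_burst (k2 >= k3 branch).
#'
#' @return A data frame with columns `length`, `k_burst`, `k_ss`, `k2`, `k3`.
#' @export
default_length_truth <- function() {
  map <- data.frame(
    length = c(16L, 21L, 26L, 30L),
    k_burst = c(0.02, 0.15, 0.45, 1.2),
    k_ss = c(0.0045, 0.002, 0.0009, 0.00045))
  disc <- map$k_burst^2 - 4 * map$k_ss * map$k_burst
  map$k2 <- (map$k_burst + sqrt(disc)) / 2
  map$k3 <- map$k_burst - map$k2
  map
}

## fixed synthetic 30-nt guide (1U start, mixed composition); shorter panel
## guides are its 3' truncations, and the shared target is its full
## reverse complement (fully complementary to every truncation).
.PANEL_GUIDE_30 <- "UAGCUUCCGAAGCUGAUUCGGAUCCAGCAU"

#' The synthetic guide-length panel sequences
#'
#' @param lengths Guide lengths (nt), each <= 30.
#' @return A list with `guides` (named character, 5'->3') and `target`
#'   (character, the 30-nt fully complementary target, 5'->3').
#' @export
panel_sequences <- function(lengths = c(16L, 21L, 26L, 30L)) {
  stopifnot(all(lengths >= 10L), all(lengths <= 30L))
  guides <- vapply(lengths, function(L) substr(.PANEL_GUIDE_30, 1L, L), "")
  names(guides) <- paste0("g", lengths, "nt")
  chars <- strsplit(.PANEL_GUIDE_30, "")[[1]]
  target <- paste(rev(unname(.RNA_COMP[chars])), collapse = "")
  list(guides = guides, target = target)
}

#' Generate the synthetic guide-length panel
#'
#' One progress curve per guide length with per-length ground truth, plus the
#' guide/target sequences so the energetics module can compute the pairing
#' free energy of each duplex. The truth map must obey the qualitative law
#' (shorter guide: smaller k_burst, larger k_ss) unless overridden.
#'
#' @param lengths Guide lengths (nt).
#' @param truth_map Data frame like [default_length_truth()], with columns
#'   `length`, `k2`, `k3` covering `lengths`.
#' @param design An [assay_design()]; its time grid is scaled per condition
#'   (slow conditions get the extended grid).
#' @param noise A [noise_model()].
#' @param seed Seed for noise (per-length seeds are derived from it).
#' @param check_monotone Validate the qualitative law (default TRUE).
#' @return A list of class `synth_panel`: `curves` (named list of
#'   `synth_curve`), `truths` (data frame with per-length k_burst/k_ss),
#'   `sequences` ([panel_sequences()]).
#' @export
gen_guide_length_panel <- function(lengths = c(16L, 21L, 26L, 30L),
                                   truth_map = default_length_truth(),
                                   design = assay_design(),
                                   noise = no_noise(),
                                   seed = noise$seed,
                                   check_monotone = TRUE) {
  stopifnot(is.data.frame(truth_map),
            all(c("length", "k2", "k3") %in% names(truth_map)))
  lengths <- sort(as.integer(lengths))
  rows <- match(lengths, truth_map$length)
  if (anyNA(rows)) stop("truth map lacks entries for some requested lengths")
  tm <- truth_map[rows, ]
  kb <- tm$k2 + tm$k3
  kss <- ifelse(kb > 0, tm$k2 * tm$k3 / kb, 0)
  if (check_monotone &&
      (any(diff(kb) <= 0) || any(diff(kss) >= 0))) {
    stop("truth map violates the guide-length law (k_burst must increase ",
         "and k_ss decrease with guide length); set check_monotone = FALSE ",
         "to override")
  }
  seqs <- panel_sequences(lengths)
  noisy <- noise$cv > 0 || noise$floor > 0
  curves <- vector("list", length(lengths))
  names(curves) <- names(seqs$guides)
  for (i in seq_along(lengths)) {
    # slow conditions need a longer assay for the burst to develop
    des <- design
    if (kb[i] < 0.05) des$times <- slow_times() else des$times <- design$times
    sc <- gen_progress_curve(
      des, rate_constants(tm$k2[i], tm$k3[i]), noise,
      seed = if (noisy) seed + i else NULL)
    sc$curve$condition <- list(guide = names(seqs$guides)[i],
                               guide_length_nt = lengths[i])
    curves[[i]] <- sc
  }
  structure(list(
    curves = curves,
    truths = data.frame(length = lengths, k2 = tm$k2, k3 = tm$k3,
                        k_burst = kb, k_ss = kss),
    sequences = seqs),
    class = "synth_panel")
}

#' The potentiated-condition truth used for multiple-turnover checks
#'
#' Activator-saturated burst rate 1.1 min^-1 (the saturating rate of the
#' wild-type titration) combined with the slow product release that leaves
#' the steady-state rate essentially unchanged by the activator; k_ss is set
#' to 0.003 min^-1, within the < 0.005 min^-1 bound observed under
#' multiple-turnover conditions.
#'
#' @return A [rate_constants()] object.
#' @export
potentiated_truth <- function() {
  kb <- 1.1; kss <- 0.003
  k2 <- (kb + sqrt(kb^2 - 4 * kss * kb)) / 2
  rate_constants(k2, kb - k2)
}
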