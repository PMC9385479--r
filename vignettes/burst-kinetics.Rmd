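---
title: "Burst kinetics of piRNA-guided target cleavage: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst kinetics of piRNA-guided target cleavage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstfit)
```

## The kinetic problem

PIWI-clade Argonaute proteins loaded with a piRNA guide (piRISC) are
endoribonucleases that cleave complementary target RNA. Quantified by
quench-and-gel assays, product formation under multiple-turnover conditions
(target in excess over enzyme) is biphasic: a fast pre-steady-state
*burst* — every active enzyme molecule cleaves its first substrate — followed
by a slow linear *steady state* limited by release of the cleaved products.
The minimal scheme is

$$\mathrm{E} + \mathrm{S}
  \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} \mathrm{ES}
  \xrightarrow{k_2} \mathrm{EP} \xrightarrow{k_3} \mathrm{E} + \mathrm{P},$$

and in the rapid-binding, substrate-saturating limit the measured cleaved
target (bound plus free — quenching releases everything on the gel) follows

$$P(t) = E\left[\left(\frac{k_2}{k_2+k_3}\right)^2
  \left(1 - e^{-(k_2+k_3)t}\right) + \frac{k_2 k_3}{k_2+k_3}\,t\right],$$

with $E$ the *apparent active-enzyme concentration* (burst amplitude),
$k_\mathrm{burst} = k_2 + k_3$ and
$k_\mathrm{ss} = k_2 k_3 / (k_2 + k_3)$. Note
$k_\mathrm{ss} \le k_\mathrm{burst}/4$, with equality iff $k_2 = k_3$.
The package implements this model (`burst_product()`), its fitting
(`fit_burst()`), the hyperbolic dependence of $k_\mathrm{burst}$ on an
activator — the small zinc-finger protein GTSF1 —
($k_\mathrm{burst} = k_\mathrm{pot}[\mathrm{A}]/(K_d+[\mathrm{A}])$,
`fit_titration()`), nearest-neighbour guide:target duplex energetics
(`duplex_dg37()`), and a mass-action simulator of the underlying schemes
(`simulate_scheme()`).

Units are fixed package-wide: minutes, nM, min^-1^, kcal·mol^-1^. Column
names encode them (`time_min`, `product_nM`, `conc_nM`, `rate_per_min`); no
unit inference is performed.

## Fitting: reparameterisation and numerics

Direct least squares in $(E, k_2, k_3)$ is ill-conditioned near
$k_2 \approx k_3$. We fit instead in the identifiable observable space
$(A, \lambda, m)$ — burst amplitude $A = E(k_2/\lambda)^2$, burst rate
$\lambda = k_2 + k_3$, steady slope $m = E k_2 k_3 / \lambda$. For fixed
$\lambda$ the model is **linear** in $(A, m)$ (non-negative least squares in
two variables), so $\lambda$ is profiled: a 121-point log-spaced scan
bracketing the data's observable rate range, refined by 1-D optimisation to
an absolute tolerance of $10^{-11}$ in $\log_{10}\lambda$. The scan makes the
fit multi-start by construction; no user-supplied initial guess exists to get
wrong. The back-solution

$$k_2 = \frac{A\lambda^2}{m + A\lambda},\qquad k_3 = \lambda - k_2,\qquad
  E = \frac{A\lambda^2}{k_2^2}$$

is algebraically *unique* — swapping $k_2 \leftrightarrow k_3$ changes the
amplitude, so the two branches are distinguishable from data and no reporting
convention is needed. Curves whose burst is weaker than their linear phase
($A\lambda < m$) legitimately return $k_2 < k_3$. On noiseless
model-generated data the fit recovers all three parameters to better than
$10^{-6}$ relative error (asserted across a randomized grid with
$k_2/k_3 \in [5, 500]$); an exhaustive `grid_oracle_fit()` provides an
independent brute-force check that the profile fit is at least grid-optimal.

Degenerate inputs: an all-zero or flat signal raises a "no detectable
product" error; $k_2 + k_3 = 0$ evaluates the model to zero rather than
raising, so optimizers can traverse the boundary. $P(t)$ is unbounded in $t$
(linear phase); the model itself never clamps — validity ($P \le S_{total}$)
is enforced by the data generator, not the equation.

The titration fit profiles $K_d$ the same way ($k_\mathrm{pot}$ is linear
given $K_d$). The canonical model passes through the origin; a basal-rate
intercept $k_0$ can be enabled (`fit_opts(basal_offset = TRUE)`) but is off
by default for fidelity to the standard form, even though basal (activator
free) activity is nonzero in reality. A fitted $K_d$ outside the sampled
concentration range triggers a warning rather than an error.

Replicates: the default fits per-time means (mirroring legends that state
mean values were fit); `replicates = "pooled"` fits all points jointly.
Weighting is unweighted SSR by default, with optional user weights. The
apparent active-enzyme concentration is always fitted; `fix_e_active` pins
it when an independent titration of active sites is available.

## Confidence intervals

The interval method behind published kinetic CIs is often unstated; we use a
**residual-resampling bootstrap** (percentile, default `n_boot = 1000`, seed
mandatory) for distribution-freeness. Noiseless data yield degenerate
(zero-width) intervals, flagged as such. The test suite verifies empirical
coverage of the 95% interval for $K_d$ on a 500-replicate ensemble of noisy
synthetic titrations (5% cv): coverage must land in [90%, 99%]. For runtime
the coverage test uses `n_boot = 200`; percentile endpoints are stable well
below the 1000 default, and the assertion is on ensemble coverage, not on any
single interval.

## Duplex energetics

Pairing free energy of the guide:target duplex at 37 °C uses the standard
nearest-neighbour decomposition: helix initiation + the sum of dinucleotide
stack terms over the contiguous paired span + a penalty per terminal A-U
pair (+ a symmetry term for self-complementary duplexes). The parameter set
shipped (`nn_rna_wc_1998.tsv`, named `"rna_wc_1998"` in outputs) is the
published INN-HB Watson–Crick RNA/RNA set; the table is versioned by name so
alternatives can be added without changing results silently.

Choices the assay convention dictates:

* g1 never pairs (the guide 5′-monophosphate is anchored in the MID pocket);
  spans start at g2. `pairing_span()` walks the longest contiguous
  Watson–Crick run from g2 against the reverse-complementary register
  (guide position $i$ faces target position $L_t - i + 1$).
* Wobble (G·U) pairs are excluded — panel targets are fully Watson–Crick.
* A 3′-terminal 2′-O-methyl is thermodynamically neutral here (methylated
  and hydroxyl guides are equally functional in cleavage assays).
* Dangling ends and coaxial stacking are ignored.
* Whether published energy-versus-rate plots include initiation/terminal
  terms is typically unstated; both modes are computable
  (`include_ends = FALSE` for stacks only) and every result records its mode.

`energy_rate_table()` sorts entries by ΔG37 and reports Spearman rank
correlations (midranks for ties) of ΔG37 with $k_\mathrm{burst}$ and
$k_\mathrm{ss}$; on the monotone synthetic guide-length panel these are
exactly −1 and +1: stronger pairing, faster burst, slower turnover.

## The scheme simulator

`simulate_scheme()` integrates mass-action rate equations for the basic
scheme and for a two-conformational-change extension in which (1) target
binding lets the guide 3′ end leave the PAZ domain, giving a pre-catalytic
complex, and (2) activator binding converts that complex to the catalytically
competent state, which performs chemistry ($k_\mathrm{chem}$) and then slowly
regenerates free piRISC ($k'_{-c}$), releasing products *and* activator
together (the alternative — activator retained through release — is not
drawn in the qualitative scheme; we chose joint release and note it here).
When only a target dissociation constant is supplied, the on-rate defaults to
a diffusion-scale 10 nM^-1^ min^-1^ and the off-rate follows.

Because the published two-conformation scheme is qualitative (no numeric
rates), the package ships named presets labelled *calibrated, not measured*:
`"miwi_like"` reproduces the regime of the printed apparent rates (basal
burst ~0.03 min^-1^, potentiated ~0.6 min^-1^, activator $K_d$ 8 nM, slow
release) and includes a small activator-independent chemistry rate
`k_chem_basal` — the strictly-drawn scheme has no route to product without
activator, which would contradict the nonzero basal activity; the basal route
defaults to 0 in user-built schemes. `"rapid_equilibrium"` makes every
binding/conformational step fast relative to chemistry so that a simulated
activator titration collapses onto the hyperbolic model and the re-fitted
$K_d$ recovers $k_\mathrm{off}/k_\mathrm{on}$ (asserted within 10%).

The integrator is an adaptive embedded Dormand–Prince RK5(4) pair
implemented in C++ (relative tolerance $10^{-8}$, absolute $10^{-12}$ nM,
step-budget guard). No stiff-implicit solver ships with the allowed
dependency set; the networks here are small and only mildly stiff (fast
binding equilibria up to ~10^4^ min^-1^ against 60-min horizons), well within
an adaptive explicit method's stability budget — the guard raises an error
rather than returning silently wrong trajectories if a user pushes beyond
it. Conservation of total enzyme and total target is checked at every output
time (≤10^-6^ relative drift; violation is an error, not a warning).

The observable compared with the closed form is **total cleaved target**
(product-bound enzyme states + free product), matching what a gel quantifies;
comparing free product alone would show a lag, not a burst. In the
rapid-binding limit ($k_1 S \gg k_2 + k_3$, $E \ll S$) the simulated
observable matches the closed form to <1% everywhere, and re-fitted apparent
rates recover $(k_2+k_3,\; k_2k_3/(k_2+k_3))$ within 2%. Slow-binding
regimes deviate from the closed form (documented limitation; not asserted).

One practical regime note: at low activator concentrations an enzyme excess
over activator sequesters the activator in long-lived product complexes and
distorts the titration's lowest points. Verification runs therefore use
enzyme ≪ activator (0.2 nM enzyme against ≥1 nM activator), which is also
the cleaner experimental design.

## The synthetic-data generator: a stated world

No machine-readable kinetic data accompany the assays the package targets
(gel images only), so every pipeline stage is exercised against generated
data with known ground truth. The generator's defaults are fixed once, from
the stated assay conditions, and are not tuned against test outcomes:

* **Design** (`assay_design()`): 5 nM nominal enzyme, 35% apparently active,
  5 nM target, triplicates, 16 time points over 0–60 min with denser early
  sampling. The active fraction reflects the typical gap between nominal
  piRISC and the fitted burst amplitude; with a basal burst rate of
  0.01 min^-1^ this design cleaves ~15% of the target in 1 h, the canonical
  slow-slicer observation. Conditions with $k_\mathrm{burst} < 0.05$
  min^-1^ use a 0–480 min grid (`slow_times()`) — a slow condition is assayed
  longer, exactly as a bench scientist would.
* **Noise** (`noise_model()`): heteroscedastic, multiplicative cv 5% plus a
  0.05 nM additive floor, clamped to $[0, S_{total}]$ — emulating triplicate
  gel densitometry. No published noise statistics exist; these values were
  chosen once to match the visual scatter of triplicate quantification.
  A seed is mandatory for any nonzero noise; identical seeds give identical
  data.
* **Model-validity truncation**: generated curves are truncated at
  $S_{total}$, implementing the boundary the closed form ignores. A truth
  that exhausts substrate before the second time point is an error advising
  denser sampling.
* **Guide-length panel** (`gen_guide_length_panel()`): per-length truths
  calibrated once to the printed fold relations — 30 nt → 16 nt drops
  $k_\mathrm{burst}$ by 60× (printed: >50×) and raises $k_\mathrm{ss}$ 10×
  (printed: ~9×) — with monotone intermediate lengths, and a fixed synthetic
  30-nt guide (1U start; shorter guides are 3′ truncations; the shared
  target is its full reverse complement). The truth map is validated against
  the qualitative law and can only be violated with an explicit override.
* **Potentiated multiple-turnover truth** (`potentiated_truth()`):
  $k_\mathrm{burst} = 1.1$ min^-1^ (the saturating rate of the wild-type
  activator titration) with $k_\mathrm{ss} = 0.003$ min^-1^, inside the
  stated <0.005 min^-1^ bound for activator-potentiated turnover.

What a green test on this world does **not** establish: robustness to
non-Gaussian densitometry artefacts, exonucleolytic loss of substrate at
long times (observed in lysate, deliberately not modelled), correlated
replicate structure (replicates are i.i.d. here), or temperature/metal-ion
dependence of the rate constants. The single-turnover functional form is the
standard single exponential $A(1-e^{-kt})$ — under enzyme excess there is no
linear phase — because the fitted equation for published single-turnover
rates is not printed; an initial-slope extraction would be the alternative.

## Known limitations

* Global multi-curve fitting with shared parameters and Bayesian posterior
  sampling are out of scope; each curve is fit independently.
* Wobble-containing spans, dangling ends, full secondary-structure
  prediction and melting temperatures are outside the energetics module.
* The simulator is deterministic ODE only; no stochastic small-copy-number
  regime.
* Extended-scheme presets are calibrated worked examples, not estimates of
  physical rate constants.
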