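# burstfit

Kinetic analysis of piRNA-guided target cleavage by PIWI-clade Argonaute
proteins (piRISC), for biochemists quantifying cleavage assays: burst-and-
steady-state progress-curve fitting, activator (GTSF1) titration fitting,
nearest-neighbour guide:target duplex energetics, a mass-action simulator of
the underlying reaction schemes, and a seeded synthetic-data generator that
emulates gel-quantified assays end to end.

## The model

Under multiple-turnover conditions the two-step cycle
E + S ⇌ ES →(k₂) EP →(k₃) E + P produces biphasic progress curves. The
measured cleaved target follows the burst-and-steady-state equation

    P(t) = E [ (k₂/(k₂+k₃))² (1 − e^−(k₂+k₃)t) + (k₂k₃/(k₂+k₃)) t ]

with E the apparent active-enzyme concentration, burst rate
k_burst = k₂ + k₃ and steady-state rate k_ss = k₂k₃/(k₂+k₃) ≤ k_burst/4.
Activation by GTSF1 follows the hyperbola
k_burst = k_pot·[GTSF1]/(K_d + [GTSF1]). Duplex stability is the standard
nearest-neighbour sum, ΔG37 = init + Σ stacks + terminal-AU penalties,
over the contiguous paired span starting at guide position g2 (g1 is
anchored, unpaired).

Units throughout: minutes, nM, min⁻¹, kcal·mol⁻¹.

## Worked example

```r
library(burstfit)

# a triplicate noisy progress curve with known truth (k2, k3), 100 nM target
sc <- gen_progress_curve(assay_design(s_total = 100),
                         rate_constants(k2 = 0.6165, k3 = 0.0035),
                         noise_model(cv = 0.05, floor = 0.05, seed = 42))
fit_burst(sc$curve)
#> burst fit (16 points, converged = TRUE):
#>   E_active = 1.775 nM, k2 = 0.5942, k3 = 0.003197 min^-1
#>   k_burst = 0.5974 min^-1, k_ss = 0.00318 min^-1, SSR = 0.03609 nM^2

# a noiseless wild-type activator titration (7 points, 1-5,000 nM)
st <- gen_titration(truth = hyperbola_params(k_pot = 1.1, kd = 8))
fit_titration(st$series)
#> titration fit (7 points, converged = TRUE):
#>   k_pot = 1.1 min^-1, Kd = 8 nM, SSR = 1.318e-20

# pairing free energy of the 30-nt panel guide against its full target
seqs <- panel_sequences(30)
duplex_dg37(seqs$guides[[1]], seqs$target)
#> dG37(g2-g30) = -56.69 kcal/mol
```

The burst fit recovers the generating truth (k_burst = 0.62, k_ss = 0.0035
min⁻¹, 1.75 nM active enzyme) within the 5% assay noise; the noiseless
titration is recovered exactly. With 5 nM enzyme, 35% active, and a basal
burst rate of 0.01 min⁻¹, the default design cleaves ~15% of a 5 nM target
in 1 h — the canonical slow-slicer regime that activator addition rescues.

A command-line interface covers the same pipeline
(`inst/cli/burstfit`): `fit-progress`, `fit-titration`, `dg`, `simulate`,
`synth`, `report`. Example:

```sh
Rscript inst/cli/burstfit synth titration --kd 8 --kpot 1.1 --seed 7 --out tit.csv
Rscript inst/cli/burstfit fit-titration tit.csv --out fit.json
```

## Layout

* `R/kinetic-models.R` — closed-form models and rate identities
* `R/curve-fitting.R` — profile least-squares fits, bootstrap CIs, grid oracle
* `R/energetics.R` — paired-span detection and nearest-neighbour ΔG37
* `R/scheme-sim.R` — mass-action schemes, presets, apparent-rate extraction
* `R/synthetic-data.R` — assay designs, noise model, generators, truth maps
* `R/interface.R`, `R/cli.R` — CSV/FASTA/JSON IO and the CLI
* `vignettes/burst-kinetics.Rmd` — the methods vignette (models, numerics,
  design decisions, limitations)
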