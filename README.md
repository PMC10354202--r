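# vinkin

Mechanokinetic analysis of force-dependent talin–vinculin binding.

Vinculin binds cryptic vinculin-binding sites (VBS) in the talin rod that
only become available when mechanical force unfolds the talin domain hiding
them. In single-molecule magnetic-tweezers recordings each binding event is
visible as a ~3 nm contraction of the unfolded talin polypeptide and each
unbinding as the matching upward step. `vinkin` packages the complete
analysis of this system for experimentalists and modellers:

- **Rate laws** — Bell-Evans kinetics `k(F) = k0·exp(±F·x†/kT)`; the
  biphasic binding rate `r_B(F) = k_B(F)·P_U(F)`, where
  `P_U = r_U/(r_U + r_F)` is the talin unfolding probability that exposes
  the binding sites; force-dependent dissociation constants; crossover-force
  solving.
- **Simulator** — exact kinetic Monte Carlo of the four-state scheme
  (talin folded/unfolded, vinculin weak-bound/mature-bound) under
  piecewise-constant force protocols, rendered into noisy tweezers-like
  extension traces; hold-and-probe maturation experiments; first-passage
  traces.
- **Trace analysis** — optimal change-point step detection (PELT),
  binding/unbinding classification, dwell extraction with censoring, and
  censoring-aware mean first-passage times.
- **Fitting** — weighted log-linear Bell-Evans fits; the biphasic binding
  fit; log-binned ("square-root") dwell-time histograms in `x = ln t`,
  where each exponential timescale appears as a peak at `x0 = ln t0`;
  maximum-likelihood exponential-mixture fits with BIC model selection;
  the maturation relaxation fit `T(t) = t_w + (t_m − t_w)(1 − e^(−t/τ))`;
  50 s binding probabilities.
- **Downstream assays** — actin-bundling quantification (bundled-pixel
  ratio) with four-parameter Hill-Langmuir dose-response fits
  (`Y = b + X^h (a − b)/(X^h + EC50^h)`, saturation plateau shareable
  across datasets), and focal-adhesion geometry on segmented masks (Otsu
  cell segmentation, equivalent radius `r = sqrt(area/π)`, 0.3 µm² size
  filter, central/peripheral classification by the 0.3·r rule,
  background-subtracted adhesion intensities).

Synthetic-data generators for every stage (traces, dwell mixtures, dose
series, filament fields, cells with planted adhesions) are first-class,
seeded, and return their ground truth, so every estimator is validated by
parameter recovery.

## Worked example

Two-mode unbinding at the 40 pN probe force: draw 2,000 dwell times from
the weak/mature mixture (0.4 s and 7.4 s, weights 0.6/0.4), fit 1- and
2-component exponential mixtures by maximum likelihood, and ask below which
force maturation (τ = 37 s) outruns weak-state unbinding:

```r
library(vinkin)

d <- sample_dwell_mixture(2000, c(0.4, 7.4), c(0.6, 0.4), seed = 201)
fit_dwell_mixture(d)
#> exponential mixture fit: k = 2
#>   component 1: amplitude 0.607, timescale 0.4124 s (x0 = -0.886)
#>   component 2: amplitude 0.393, timescale 7.493 s (x0 = 2.014)
#>   logLik -3375.88; BIC k1 = 8652.37, k2 = 6774.56

th <- thermal_context(4.114 / 1.380649e-2)   # kT = 4.114 pN nm
flv <- bell_evans_params(6.6e-3, 0.72, "force_accelerated")
crossover_force(flv, 1 / 37, th)
#> [1] 8.055256
```

The BIC strongly prefers two components and recovers both timescales; the
crossover sits at ~8 pN, meaning the weak complex only survives long enough
to mature at forces below roughly 10 pN — at higher force it dissociates
before reinforcement.

## Analysis workflow

The `analysis/` directory chains the package into the three studies, each a
thin narrative driver writing tables under `results/`:

| script | what it does |
|---|---|
| `01_binding_kinetics.R` | simulate→detect→fit recovery of the unbinding law at five forces; biphasic binding curve and refit; closed-form rate separations |
| `02_maturation.R` | square-root histogram, mixture fit, hold-and-probe experiment, maturation fit, crossover force, binding probability |
| `03_bundling_dose_response.R` | synthetic filament fields, bundle-ratio measurement, shared-plateau Hill fit |
| `04_adhesion_geometry.R` | synthetic cells, Otsu segmentation, size filter, 0.3·r classification, background-subtracted intensities |

Run any of them from the repository root, e.g.
`Rscript analysis/02_maturation.R`.

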