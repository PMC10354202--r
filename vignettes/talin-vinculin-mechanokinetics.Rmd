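---
title: "Mechanokinetics of force-dependent talin-vinculin binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanokinetics of force-dependent talin-vinculin binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinkin)
```

## The system and the model

Vinculin reinforces cell-matrix adhesions by binding cryptic vinculin-binding
sites (VBS) in the talin rod, sites that are only exposed when force unfolds
the talin domain that buries them. `vinkin` models this mechanosensing cycle
at the single-molecule level, the way it is observed in magnetic-tweezers
experiments on the talin R3 domain: binding of full-length vinculin contracts
the unfolded talin polypeptide by about 3 nm (the VBS coils into a helix) and
locks talin unfolded; unbinding returns the 3 nm. Those ±3 nm steps are the
entire observable.

All transition rates follow the Bell-Evans law

$$k(F) = k_0 \exp(\pm F x^\dagger / k_\mathrm{B}T),$$

force-accelerated (+) for unfolding and unbinding, force-suppressed (−) for
folding and binding; $x^\dagger$ is the distance to the transition state. The
observed binding rate of vinculin is biphasic,

$$r_B(F) = k_B(F)\, P_U(F), \qquad
P_U(F) = \frac{r_U(F)}{r_U(F) + r_F(F)},$$

because force first exposes the binding sites (through the talin unfolding
probability $P_U$) and then disfavours the coil-to-helix contraction that
binding requires. Unbinding is biexponential: a *weak* initial complex
(sub-second lifetime under a 40 pN probe) matures irreversibly, with a
first-order timescale $\tau_\mathrm{mat}$ of tens of seconds, into a
*mature* complex roughly an order of magnitude longer-lived. The four-state
scheme is

```
talin_folded <-> talin_unfolded -> vinculin_weak -> vinculin_mature
                       ^________________|__________________|
                              (unbinding, +3 nm step)
```

with unbinding from either bound mode returning to `talin_unfolded` (the VBS
uncoils; talin stays unfolded), and maturation irreversible — no reverse
transition is modelled because none is ever observed.

## Parameters, units and defaults

Forces are pN, distances nm, rates 1/s, so $k_\mathrm{B}T$ is in pN·nm.
The temperature is configurable through `thermal_context()`; the default
298 K gives $k_\mathrm{B}T = 4.114$ pN·nm, and every fit records the value
it used. Measured anchor values used throughout the examples and tests:

| quantity | value | role |
|---|---|---|
| FLV unbinding $k_0$, $x^\dagger$ | $6.6\times10^{-3}$ 1/s, 0.72 nm | weak-state unbinding law |
| Vd1 unbinding $k_0$, $x^\dagger$ | $6.8\times10^{-6}$ 1/s, 0.81 nm | D1-domain comparison |
| weak / mature unbinding at 40 pN | 0.4 s / 7.4 s | two-mode dwell mixture |
| maturation timescale | ~37 s | weak → mature rate |
| binding contraction | 3 nm | step fingerprint |

Two classes of defaults are *not* measured values and are flagged as
placeholders: the talin R3(IVVI) folding/unfolding branches
(`default_talin_params()`: coexistence at 9 pN, 0.5 1/s, $x^\dagger$ = 10 nm
on both branches — typical of this domain's steep force dependence) and the
binding branch of the biphasic model (`bell_evans_params(0.3, 1.5,
"force_suppressed")` at 20 nM). They live in constructors and flat key-value
configs (`read_config()`/`bell_evans_from_config()`), never inside
algorithms, and should be overridden with measured values where available.
The dissociation constant converts rates at the working concentration (20 nM
in the reference experiments) into a per-molar on-rate, so
$K_d = r_{Ub} C / r_B$.

## The simulator: what it emulates, what it does not

`simulate_scheme()` is an exact kinetic Monte Carlo (Gillespie) simulation
under piecewise-constant force protocols: within a segment, waiting times
are exponential in the total exit rate; at a segment boundary the rates are
re-evaluated and the waiting time redrawn, which is valid by memorylessness
and never forces a transition. `render_extension()` turns state paths into
kHz-scale extension traces: piecewise-constant levels (unfolded gain 20 nm
by default — a typical value for this domain, not a printed one — minus the
3 nm contraction when bound) plus i.i.d. Gaussian noise, 0.8 nm and 1000 Hz
by default, both recorded in the trace provenance.

The generator reproduces the *kinetic* content of tweezers data: exponential
dwells, force-dependent rates, ±3 nm steps at the right levels, censoring at
the record end. It does not emulate bead-tracking artefacts, drift,
low-pass camera filtering, or force-calibration error. Passing tests
therefore demonstrate that the estimators are correct on data obeying the
model, not that real traces obey the model.

`simulate_maturation_experiment()` mirrors the hold-and-probe protocol:
bind at low force, hold a prescribed lifetime, probe at 40 pN. The hold
phase tracks only the maturation clock, because experimental lifetimes are
measured on complexes still bound when the pulse arrives — unbinding during
the hold is conditioned away by that selection. During the probe the scheme
runs freely (late maturation included; the record ends at first unbinding).

## Estimators and their numerical choices

**Step detection** is exact penalized least squares for a piecewise-constant
mean (optimal partitioning with PELT pruning), with penalty
$2\hat\sigma^2\ln N$ per change point and $\hat\sigma$ from the median
absolute deviation of first differences (robust to the steps themselves).
Plain binary segmentation was rejected: a short excursion inside a long
segment reduces the top-level split gain by the segment-length ratio and is
missed; the optimal partition has no such failure. Minimum segment length is
2 samples, so nothing shorter than 2 samples is detectable by construction;
the classifier's dwell tables flag inconsistent pairings (e.g. two
consecutive binding steps) rather than dropping them. Steps below 1.5 nm are
discarded by default (half the binding contraction); classification accepts
steps within ±1 nm of the contraction starting from the unfolded level.

**First-passage reading** boxcar-smooths (5 samples) and uses a 0.3 nm
hysteresis; edge windows are partial means rather than NA. The
censoring-aware mean first-passage time is the exponential MLE: total
observed time over the number of uncensored events, with
$SE = \widehat{MFPT}/\sqrt{n_\mathrm{uncensored}}$.

**Bell-Evans fitting** is weighted least squares on $\ln k$ versus $F$ with
delta-method weights $(k/SE)^2$; the biphasic binding fit holds the talin
branches fixed and refines a log-parameterized Levenberg-Marquardt from the
exact linearization of $\ln(r_B/P_U)$.

**Dwell mixtures.** The log-binned histogram uses $x = \ln t$ with 8 bins
per decade (a sensitivity test covers other widths), bins anchored on the
smallest observation so that rescaling dwells translates the histogram
exactly; for a single exponential the transformed density peaks at
$x_0 = \ln t_0$ with height $e^{-1}$, which the tests assert. The histogram
is a visualization and peak-finding device only: mixture fitting is direct
maximum likelihood on the raw dwells (EM, three quantile-based starts),
1 vs 2 components chosen by BIC, and a 2-component solution whose
timescales agree within 5% collapses to one component. Fitting raw dwells
keeps results bin-width independent.

**Maturation fit.** The default model is the mechanistic exponential
relaxation $T(t) = t_w + (t_m - t_w)(1 - e^{-t/\tau})$ implied by
first-order maturation; a phenomenological logistic-in-$\ln t$ is available
behind a flag. Weighting matters: per-point *empirical* standard errors are
correlated with the per-point means (a point that happened to draw few slow
dwells has both a low mean and a small SE), which biases the weighted curve
downward. When replicate counts are supplied, the fit therefore iterates
weights from the variance implied by the fitted two-mode mixture at each
lifetime (three reweighting passes), which is unbiased and close to
efficient. The fit is parameterized in logs for positivity and refuses
optima with $t_m \le t_w$.

**Binding probability** is the fraction of seeded replicates in a bound
state at the end of the window (occupancy definition, recorded in the
output; an "ever bound" definition is selectable since the operational
definition is a genuine choice).

**Dose-response.** Bundle quantification subtracts a smooth background by
grayscale opening (a separable running-min/running-max rolling-ball
analogue, radius 50 px default), bins gray values at 256 levels over the
16-bit range, and classifies pixels against a single-filament calibration;
the bundle threshold is 1.5× the mean single-filament intensity — a stated
surrogate for an under-specified macro step, validated only on synthetic
truth. The Hill-Langmuir fit frees EC50, HillSlope and the lower plateau
per dataset and can share the saturation plateau across datasets, the
configuration used for multi-variant bundling series; concentrations are
µM, responses percent.

**Adhesion geometry.** Cell segmentation is Otsu thresholding (256 levels)
keeping the largest component; the equivalent radius is
$r = \sqrt{\mathrm{area}/\pi}$. Adhesions at or below 0.3 µm² are removed
and centroids at a normalized edge distance strictly above 0.3 are central —
both strict inequalities, following the defining wording. The edge distance
is the exact Euclidean distance transform evaluated at the centre of mass,
intensity-weighted by default (binary optional) since the weighting is not
specified. Local background is a 5 px dilation annulus excluding other
adhesions and extracellular pixels, falling back (flagged) to the
whole-cell non-adhesion mean when empty. Because per-cell versus pooled
central fractions are both defensible summaries, the analysis scripts emit
both.

## Problem sizes

The shipped tests and scripts use desk-scale sizes chosen to keep every
estimate's sampling error well inside its assertion band: 2,000 dwells for
mixture recovery (165 — the measured event count — for model selection),
500 hold-and-probe repetitions on a 7-point lifetime grid from 2 to 150 s
with replicates allocated roughly proportional to the per-point standard
deviation, 200 events per force at five forces (10–20 pN) for the full
detect-and-fit chain at 25 Hz sampling, Gillespie validation at 5,000
dwells per state and force, and 50-seed synthetic-image batches. At 500
repetitions the maturation-timescale estimator has roughly ±25% sampling
spread — the weakest link in the chain, dominated by the variance of the
two-mode dwell mixture at intermediate lifetimes.

## Known limitations

- The weak-state Bell-Evans law extrapolated to 8.5 pN gives an unbinding
  rate of ~0.03 1/s; published discussion of the same regime quotes
  ~0.01 1/s without stating the extrapolation convention. Both numbers are
  reported by `analysis/01_binding_kinetics.R`; no agreement is forced.
- Talin folding parameters and the binding branch are placeholder defaults
  (above); quantitative binding-probability curves shift with them, though
  the biphasic shape does not.
- The detector assumes piecewise-constant levels with white noise; drift
  beyond a linear trend and correlated noise are out of scope.
- Rupture-force distributions from ramped pulling, polymer elasticity
  (WLC/FJC) corrections, and loading-rate theory are deliberately not
  implemented.
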