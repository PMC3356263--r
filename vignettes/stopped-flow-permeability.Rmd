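---
title: "Stopped-flow osmotic permeability analysis: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stopped-flow osmotic permeability analysis: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaflow)
```

## The measurement and the model

In a stopped-flow light-scattering experiment a cell suspension is rapidly
mixed with a hyperosmotic solution and the 90-degree scattered intensity is
recorded with millisecond dead time. Scattering rises as cells shrink, so the
intensity time course reports the cell-volume time course. Two classes of
challenge are analysed:

* an **impermeant osmolyte** (e.g. a 100 mM inwardly directed sucrose
  gradient): water leaves, cells shrink monotonically to a Boyle-van't Hoff
  equilibrium; the shrinkage rate constant reports the osmotic water
  permeability `Pf`;
* a **permeant solute** (glycerol or urea, 100 mM gradient after mixing):
  fast shrinkage is followed by solute entry and re-swelling back to the
  initial volume; the re-swelling rate constant reports the solute
  permeability `Pgly` / `Purea`. Aquaglyceroporins such as AQP3 carry the
  glycerol pathway, so its inhibition is read from this phase.

`simulate_volume()` integrates the standard two-compartment osmotic model
(deSolve, adaptive stiff-capable integrator, relative tolerance `1e-8`,
configurable):

$$\frac{dV_w}{dt} = -P_f\,A\,\bar V_w\,(C_{out} - C_{in}), \qquad
  \frac{dN_s}{dt} = P_s\,A\,(C_{s,out} - N_s/V_w),$$

with $V_w$ the osmotically active water volume, $N_s$ the moles of internal
permeant solute ($N_s(0)=0$), $C_{in} = (N_{imp}+N_s)/V_w$, and constant
external concentrations (effectively infinite bath at ~0.5% haematocrit).
The reported volume is $V = bV_0 + V_w$ with $b$ the osmotically inactive
fraction. Reflection coefficients are 1, there is no solvent drag, the
membrane area is constant during volume changes (shrinkage folds membrane),
and the molar volume of water $\bar V_w$ is temperature independent. All
internal computation is CGS; the mOsM to mol cm$^{-3}$ factor $10^{-6}$ is
applied at the type boundary.

Assumptions worth keeping in mind: dilute ideal osmosis (no osmotic
coefficients), no ion pumps or leaks, no regulatory volume response, and a
single well-mixed internal compartment.

## From rates to permeabilities

The package implements the classic stopped-flow estimators:

* `pf_from_rate()`: $P_f = k \cdot (V_0/A) \cdot 1/(\bar V_w\,
  (osm_{out})_\infty)$, with $k$ the single-exponential rate constant fitted
  to the shrinkage signal and $(osm_{out})_\infty$ the final total external
  osmolarity (taken from the manifest's bath composition, as measured by
  osmometer in practice, not estimated from the trace);
* `psolute_from_rate()`: $P_{gly} = k \cdot (V_0/A)$ with $k$ fitted to the
  re-swelling phase (urea uses identical machinery);
* `weighted_rate()`: for cells with biexponential shrinkage the
  amplitude-weighted rate $k_{de} = (\Delta I_1 k_1 + \Delta I_2 k_2) /
  (\Delta I_1 + \Delta I_2)$ replaces $k$; `linearized_rate()` is the exact
  algebraic inverse of `pf_from_rate()`.

### Accuracy of the single-exponential estimator

The estimator treats the whole initial cell volume as osmotically active
water. Against the full model this has two consequences, both quantified by
the test suite:

1. **Gradient nonlinearity.** The local relaxation rate of the true kinetics
   grows by a factor $osm_{out}/iso$ as the cell approaches equilibrium, so a
   single exponential is only an approximation. The default fit window runs
   from the instrument dead time to the time of **90% of the total
   amplitude**; truncating the late phase balances the early (slow-biased)
   and late (fast-biased) contributions. With this window the recovered `Pf`
   is within 0.5% of truth on a 10 mOsM gradient and within ~2.2% on the
   standard 100 mOsM gradient; windows ending at 99% amplitude would inflate
   the rate by ~11% at 100 mOsM. The window is a per-call argument.
2. **Osmotically inactive volume.** With $b > 0$ the kinetic volume scale is
   $(1-b)V_0$ while the formula uses $V_0$, so the estimator returns an
   *apparent* permeability larger by $\approx 1/(1-b)$. The re-swelling
   estimator similarly carries the quasi-steady osmotic factor
   $iso/osm_{tot}$ ($\approx 0.75$ at a 100 mM gradient on 300 mOsM).
   Every ratio quantity — percent inhibition, fold change, IC50, Hill slope,
   recovery, activation energy — is invariant to these constant factors,
   which is why the assay is read out in ratios. Absolute-permeability
   consistency checks therefore use cells with $b = 0$ (the estimator's own
   assumption); analyses that need absolute values on $b>0$ cells should
   configure the effective $V_0/A$ accordingly.

Defaults for $b$: 0.43 for erythrocytes, 0.30 for nucleated (PC12) cells —
standard literature values, explicit in every `cell_spec` and echoed in the
pipeline log. The erythrocyte membrane area is not separately measured by the
assay; the default (91.1 µm² for an 82 fL cell, i.e. $V_0/A = 9\times10^{-5}$
cm) is the configuration choice consistent with erythrocyte water
permeabilities of a few $10^{-2}$ cm s$^{-1}$ mapping onto rate constants of
a few s$^{-1}$. PC12 geometry comes from the spherical-shape assumption
(1076 fL, $A = 4\pi r^2$).

## Synthetic data

`volume_to_intensity()` renders volume kinetics through the affine optical
model $I(t) = \alpha + \beta\,(1 - V/V_0) + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$, resampled at the acquisition rate with
samples before the 2 ms dead time dropped. The mapping is the simplest
monotone choice consistent with intensity rising on shrinkage; exponential
rate constants are exactly invariant under it, so no optical calibration
enters the analysis. Defaults: $\alpha = 0.1$, $\beta = 1$,
$\sigma = 0.002$ a.u. (a signal-to-noise ratio of ~60 on the full 100 mOsM
shrinkage amplitude — typical of averaged stopped-flow records; raw
amplitudes and noise are not published quantities, so $\sigma$ is a
realism choice, not a fitted one), 1000 Hz for water traces (seconds),
100 Hz for glycerol/urea traces (tens of seconds, 120 s default horizon).

The generators build full experiment bundles with 5 replicates per condition
(typical practice is 5–7): `make_dose_response_experiment()` (Hill-law
inhibition of the solute pathway, concentrations 0.1–10 µM by default, plus
an untreated zero-concentration control), `make_time_course_experiment()`
(inhibition approaching its maximum as $1 - e^{-t/\tau}$; default
$\tau = 10$ min puts >95% of maximal inhibition at 30 min, matching the
observed time to maximal effect), and `make_arrhenius_experiment()`
($p(T) = p_{ref} e^{-E_a/R\,(1/T - 1/T_{ref})}$ over 10–37 °C). Ground-truth
defaults are the experimental anchors: control $P_{gly} = 1.8\times10^{-5}$
cm s$^{-1}$, $P_f = 4.2\times10^{-2}$ cm s$^{-1}$, IC50 0.8 µM, Hill 1,
maximal inhibition 0.9.

Determinism: every generator is a pure function of its inputs and seed.
Replicate $r$ of condition $i$ uses `derive_seed(seed, i, r)`, a documented
splitmix-style integer mixing rule, so bundles and downstream results files
are byte-identical across reruns. What the generator does *not* emulate:
mixing transients, photobleaching, heteroscedastic photon noise, cell-size
polydispersity, and temperature dependence of the water pathway within a
glycerol series. Passing recovery tests on these bundles therefore
demonstrates correctness of the estimators under the stated model, not
robustness to instrument artifacts.

## Fitting choices

* **Initialization** is deterministic and derivative-free: plateau from the
  tail mean, amplitude from the endpoints, rate from a log-linear regression
  on the first third of the relaxation; optimization by Levenberg-Marquardt
  (minpack.lm), with asymptotic standard errors from the residual variance
  and $J^\top J$. The LM backend is used directly so that exact
  (zero-residual) fits are handled cleanly.
* **Screening**: a trace whose amplitude is below 3x the noise estimate (MAD
  of the residual from a 5-sample moving average) raises a "no relaxation"
  error instead of returning a meaningless rate.
* **Biexponential acceptance** (PC12 water traces): the double-exponential
  model is kept only if it improves the residual sum of squares at an F-ratio
  significance of 0.01 (configurable) and the two rates differ by more than
  1%; otherwise the fit collapses to the single-exponential result
  (a degenerate biexponential is unidentifiable).
* **Phase splitting** for biphasic traces: coarse extremum of a moving
  average (width `max(5 samples, 1% of trace length)`), validated to be
  interior with significant amplitude on both sides, then refined by the
  analytic extremum of a biexponential fit with phase-informed starting
  values. The refinement matters: any symmetric smoother biases the argmax
  of an asymmetric fast-rise/slow-decay peak toward the slow side (~70% late
  at this window), while the model-based extremum is accurate to ~2% at the
  default noise. Noise-free traces use the raw discrete extremum. The
  re-swelling window starts 3 samples after the split.
* **Dose-response**: the printed Hill equation
  $y = y_{min} + (y_{max}-y_{min})/(1 + 10^{((\log_{10} IC_{50} - [Inh])\,H)})$
  is interpreted with $[Inh] = \log_{10}$(concentration), the standard
  log-logistic convention (any other reading leaves the exponent
  dimensional). $y_{min}$ is fixed at 0 by default (no inhibition at zero
  dose) and zero-concentration points are excluded from the fit but checked
  against $y_{min}$; fits are unweighted by default with $1/SEM^2$ weights
  optional. Reported uncertainties are asymptotic standard errors and are
  labelled as such.
* **Arrhenius**: unweighted OLS of $\ln P$ on $1/T$ (K = °C + 273.15),
  $E_a = -\mathrm{slope} \times R$, $R = 1.987\times10^{-3}$ kcal
  mol$^{-1}$ K$^{-1}$.
* **Aggregation**: replicates are summarized as mean ± SEM; a single
  replicate reports SEM 0 with a warning rather than an error, so toy
  pipelines keep running.

## Degenerate inputs and conventions

Monotone traces raise a "not biphasic" error from the splitter; flat
dose-response data raise an "unidentifiable" error; a non-increasing
inhibition time course warns but still returns the fit. Recovery fractions
outside $[0, 105]$% are clipped with a warning. `two_pathway_residual(f, i)
= 1 - f\,i` is the transparent channel+bilayer decomposition (a 90% channel
share fully blocked leaves 10% residual water permeability); percentage
bookkeeping variants found in the literature that cannot be reproduced from
this formula are not guessed at.

## Problem sizes

The test suite and acceptance script run entirely on synthetic data generated
at analysis time: water traces of 2–3 s at 1000 Hz, glycerol traces of 120 s
at 100 Hz, 5 replicates per condition, 200 seeded dose-response bundles for
the stochastic IC50 recovery (median within 15% of truth) and 60 in the
acceptance script, 100-seed Monte-Carlo checks for rate recovery. These sizes
give stable medians while keeping a full run in minutes on one core.

## Known limitations

Absolute permeabilities from $b>0$ cells are apparent values (see above); the
glycerol-series activation energy carries a small (few percent) systematic
from the temperature-dependent overlap of the water and solute phases; no
global multi-trace fitting or Bayesian uncertainty is provided; osmotic
non-ideality and UT-B-mediated urea transport are out of scope.
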