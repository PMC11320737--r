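---
title: "Quantitative developability analysis of antibody subclasses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative developability analysis of antibody subclasses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabdev)
```

## The problem

Before a therapeutic monoclonal antibody enters development, its
*developability* — the aggregate risk that the molecule will self-associate,
aggregate, unfold, or become too viscous at formulation concentrations
(> 100 mg/mL) — is assessed from a panel of biophysical assays. `mabdev`
implements the quantitative core of such a panel for comparing antibody
subclasses (e.g. an IgG1/IgG3 pair sharing identical variable domains, so
that constant-domain effects are isolated): colloidal self-interaction from
dynamic light scattering (DLS), concentration–viscosity modelling, intrinsic
viscosity and the Huggins coefficient, thermal unfolding by differential
scanning fluorimetry (DSF), plasmon red shifts from affinity-capture
self-interaction nanoparticle spectroscopy (AC-SINS), 1:1 surface plasmon
resonance (SPR) kinetics, size-exclusion purity drift, and geometric-quality
ranking of candidate homology models.

Because instrument raw data are rarely shareable, every assay modality has a
seeded synthetic generator (`make_*`) that produces data with exactly the
statistical structure the analysis assumes. All fits are therefore testable
end-to-end by round trip: generate noiselessly, fit, and require the
generating parameters back.

## Models and estimators

### Diffusion interaction parameter (colloidal module)

DLS measures the apparent diffusion coefficient across a dilute
concentration series. In the dilute regime it is linear in concentration,

$$D_\mathrm{app}(c) = D_0\,(1 + k_D\,c),$$

where $D_0$ is the self-diffusion coefficient at infinite dilution and $k_D$
(mL/g) is the diffusion interaction parameter; negative $k_D$ signals net
attractive protein–protein interactions. `fit_kd()` estimates the line by
ordinary least squares and reports $k_D = \text{slope}/\text{intercept}$,
with a delta-method standard error for the ratio. The OLS route is exact and
iteration-free. Concentrations are user-facing in mg/mL; $k_D$ is converted
to the conventional mL/g. `classify_kd()` flags molecules with
$k_D < -15$ mL/g (strict inequality; a value exactly at the threshold
passes).

The regression uses all supplied rows; replicate means are not formed first
(supply means yourself if you prefer — the OLS point estimate is invariant
to duplicating a complete dataset either way).

### Theoretical viscosity by generalized Stokes–Einstein (GSE)

Dilute-regime trends are extrapolated to formulation concentrations with two
deterministic linearized fits (`fit_trends()`): an exponential decay
$D(c) = A e^{-rc}$ fitted as OLS on $\log D$, and a power-law Z-average
diameter $\log_{10} Z = a \log_{10} c + b$. `gse_viscosity()` then evaluates

$$\eta(c) = \frac{k_B T}{3\pi\, d_H(c)\, D(c)},$$

at 298 K by default, converting the diameter from nm and reporting cP.
Using $3\pi$ with the *diameter* is algebraically identical to the textbook
$6\pi$ with the radius. A nonlinear refinement of the exponential fit is
deliberately omitted: the linearization is deterministic, testable, and
matches how such extrapolations are routinely done. Note that the
extrapolation inherits all the danger of extrapolation — the fits are made
on 1–20 mg/mL data and evaluated far outside that range, which is precisely
why measured viscosities are also analyzed.

### Concentration–viscosity models (viscometry module)

Viscometer records are first filtered (`filter_records()`): only records
with a steady plateau and a pressure-over-sensor-position linear fit
$R^2 \ge 0.998$ enter the analysis. Records at several shear rates for one
concentration are averaged only after a Newtonian-plateau check (max/min
ratio ≤ 1.05 by default; `aggregate_records()` refuses to average
shear-thinning data).

Three models are fitted to $\eta(c)$:

* **Exponential growth** $\eta = Y_0 e^{kc}$ — nonlinear least squares
  seeded from the log-linear OLS solution (`fit_expgrowth()`).
* **Tomar log-linear** $\ln(\eta/\eta_0) = \ln A + Bc$ — exact OLS
  (`fit_tomar()`), buffer viscosity $\eta_0 = 1.13$ cP by default.
* **Modified Ross–Minton**
  $\eta = \eta_0 \exp\!\big([\eta]c \,/\, (1 - (k/v)[\eta]c)\big)$ with
  intrinsic viscosity $[\eta]$, crowding factor $k$ and Simha shape
  parameter $v$ (`fit_rossminton()`). The SSE is minimized by bounded
  quasi-Newton descent from a 3×3×3 multistart grid plus one data-driven
  start obtained from the exact linearization
  $1/\ln(\eta/\eta_0) = 1/([\eta]c) - k/v$. Any local optimum that closes
  the denominator on the data span is rejected.

The Ross–Minton form enters only through $[\eta]$ and the ratio $k/v$, so
$k$ and $v$ are **not separately identifiable** from viscosity data; the
reproducible outputs are $[\eta]$, $k/v$, and the fitted curve. This is a
property of the model, not of the optimizer.

`interpolate_viscosity()` evaluates a fitted model at a target
concentration (e.g. the 180 mg/mL formulation point); anything beyond
1.25× the maximum fitted concentration warns as an extrapolation.

### Intrinsic viscosity and the Huggins coefficient

From buffer-referenced measurements in the dilute range (5–50 mg/mL),
`reduced_viscosities()` computes $\eta_{rel} = \eta/\eta_0$,
$\eta_{sp} = \eta_{rel} - 1$ and $\eta_{red} = \eta_{sp}/c$ with $c$ in
g/mL, so $\eta_{red}$ is in mL/g. `fit_huggins()` fits the Huggins relation

$$\eta_{red}(c) = [\eta] + k_H [\eta]^2 c,$$

by OLS: the intercept estimates $[\eta]$, the slope $x = k_H[\eta]^2$, and
$k_H = x/[\eta]^2$ (stored bit-exactly as that ratio). Values of
$k_H > 0.5$ (strict) are classified as "poor solvent" behaviour — solution
viscosity sensitive to protein–protein interactions
(`classify_solvent_quality()`).

The uncertainty of $k_H$ uses the full first-order delta method,
$\mathrm{Var}(k_H) = g^\top V g$ with $g = (-2x/[\eta]^3,\ 1/[\eta]^2)$ and
$V$ the OLS coefficient covariance. The intercept–slope covariance term is
kept deliberately: for an all-positive concentration design the two
estimates are strongly anticorrelated, and dropping the cross term
understates $\sigma_{k_H}$ by roughly a quarter. The implementation is
validated in the test suite against a $10^5$-draw Monte-Carlo oracle
(agreement well within 10%); at zero slope it reduces to
$\sigma_x/[\eta]^2$.

### DSF transition detection (thermal module)

The 350/330 nm intrinsic-fluorescence ratio is scanned over a 20–95 °C ramp.
`find_transitions()` computes a Savitzky–Golay *first-derivative* filter
(local quadratic, `m = 1`) — differentiating the local polynomial amplifies
far less noise than differencing a smoothed trace — and reports every local
derivative maximum whose height *and* topographic prominence exceed
`min_prominence` (default 10%) of the derivative maximum. The dual
height/prominence rule is what makes detection robust: noise bumps riding a
transition flank have height but no prominence, bumps on the flat baseline
have prominence but no height. Peaks closer than `min_separation`
(default 3 °C) collapse into the larger one; antibody domain transitions
(CH2, Fab, CH3) are typically 10–15 °C apart.

Defaults: the smoothing window spans ~3.5 °C of ramp (odd point count).
$T_{onset}$ is the first temperature at which the derivative reaches 10% of
the first peak's height — an operational convention, configurable via
`onset_fraction`, since instrument software does not document its own.
$T_{agg}$ is the argmax of the scattering-trace derivative when scattering
is supplied. At a realistic ratio noise of $10^{-4}$–$10^{-3}$, detected
midpoints sit within ~0.5 °C of the analytic derivative maxima; position
jitter grows linearly with noise, so heavily averaged replicate traces
should be supplied where available.

### AC-SINS red shift (acsins module)

Antibody-coated gold nanoparticles absorb near 530 nm; self-association
red-shifts the plasmon band. `plasmon_peak()` fits a quadratic to the points
within ±20 nm of the raw absorbance maximum and returns the vertex, giving
sub-grid resolution; a concave-up or out-of-window vertex falls back to the
raw argmax with a warning. `red_shift()` reports
$\Delta = \lambda_{sample} - \lambda_{control}$ and applies the assay QC
rule: the negative control must peak below 535 nm.

### SPR kinetics (kinetics module)

`fit_langmuir()` fits the 1:1 Langmuir model globally across analyte
concentrations, sharing $k_a$, $k_d$, $R_{max}$:
association $R(t) = R_{max} \frac{C}{C + K_D}(1 - e^{-(k_a C + k_d)t})$,
dissociation $R(t) = R_{end} e^{-k_d t}$, $K_D = k_d/k_a$. Optimization is
Levenberg–Marquardt on the stacked residuals in log-parameter space
(positivity for free). Starting values are data-driven ($k_d$ from the
top-concentration dissociation tail; $k_a$ multistarted over $K_D$ guesses
spanning 0.1–10× the median analyte concentration).
$\chi^2 = \sum r_i^2/(n-3)$ follows the per-point, DOF-corrected instrument
convention. Dissociation-only data are rejected: $k_a$ is unidentifiable
without an association phase.

### Purity drift (stability module)

`stability_flags()` applies two rules per row of an aSEC purity table:
monomer below 95% (strict), and a high-molecular-weight-species increase
from the same condition's day-0 baseline exceeding 2 percentage points
(strict). The Δ-from-baseline reading of the 2% rule is the default; an
absolute-level mode is available (`hmws_mode = "absolute"`) because
instrument thresholds are sometimes quoted that way. The earliest failing
day per condition is reported.

### Homology-model ranking (model_ranking module)

Candidate homology models (e.g. the 10 refined models of a long-hinge
construct) carry per-metric geometric quality scores, a packing score, and a
heavy-atom RMSD to the average intermediate-model position.
`normalize_scores()` min–max normalizes each metric across models onto
[0, 1] with 0 = best after orientation alignment; the packing score is
always normalized with the inverted (higher-is-better) orientation, opposite
to outlier-count-style metrics. Constant metrics are uninformative and map
to all zeros. The composite is the unweighted mean (weights configurable).
`select_model()` picks the lowest composite; ties break by lowest RMSD, then
lexical model id — fully deterministic and row-order invariant. The
normalization is kept behind one small function so an alternative scheme can
be plugged in; the exact vendor formulas are not public.

### Scorecard and correlations (report module)

`build_scorecard()` aggregates per-assay results into one record per
molecule; every flag stores the threshold and direction used, and missing
assays stay absent (never imputed). `write_scorecard()`/`read_scorecard()`
round-trip the record through JSON. `correlate()` computes pairwise Pearson
and Spearman correlations between descriptor and measurement tables using
pairwise-complete observations, reporting $n$ per pair; pairs with fewer
than 3 complete observations are undefined (NA), not an error. Permutation
p-values are deliberately not attached by default — with two or three
molecules per comparison, correlation structure is descriptive, not
inferential. All decision thresholds live in `dev_thresholds()` and can be
overridden from a YAML file (`read_config()`).

## What the generators emulate — and what they do not

Each generator draws the *reduced observable* the analysis consumes, with
additive Gaussian noise on the observable scale (a `noise_spec`; noiseless
by default, bit-reproducible under a fixed seed):

* `make_dls_series()` — linear $D_{app}(c)$ and power-law Z-average growth;
* `make_viscosity_curve()` — any of the three closed forms, with unit
  pressure-fit $R^2$ and steady plateaus;
* `make_reduced_viscosity_series()` — the Huggins line;
* `make_thermogram()` — a logistic-sigmoid sum (the logistic was chosen
  because its derivative peaks in closed form exactly at the midpoint,
  giving exact oracles); real transitions need not be logistic;
* `make_plasmon_spectrum()` — a Gaussian band (real plasmon bands are
  asymmetric; only peak position matters downstream);
* `make_sensorgram()` — the 1:1 closed forms;
* `make_purity_table()` — linear drift with the monomer fraction as the
  complement, so rows sum to 100 by construction;
* `make_score_table()` — Gaussian score draws.

Not emulated: instrument electronics (photon counts, pressure transients),
correlated or heteroscedastic noise, baseline drift, multi-species DLS,
shear thinning, mass-transport-limited SPR, non-two-state unfolding.
Passing round-trip tests therefore demonstrates correctness of the
estimators under the stated models — not robustness to every instrument
artifact.

Replicate noise magnitudes are not published for most assays; generator
sigmas are configurable arguments, and the test suite states the level it
uses wherever noise matters.

## Numerical choices

* OLS everywhere a model is linear (possibly after log transform): exact,
  deterministic, and cross-checked against closed-form normal equations in
  the tests.
* Nonlinear fits: Levenberg–Marquardt (`minpack.lm`) with analytic-free
  residuals; Ross–Minton uses box-constrained L-BFGS-B multistart because
  its feasible region (positive denominator) is parameter-dependent.
* Ross–Minton covariance is the Gauss–Newton approximation
  $\hat\sigma^2 (J^\top J)^{-1}$ with a central-difference Jacobian.
* Degenerate inputs raise typed conditions (`mabdev_invalid_input`,
  `mabdev_degenerate_fit`, `mabdev_fit_failure`, `mabdev_domain_error`,
  `mabdev_no_transition`) rather than returning NAs.
* Boundary behaviour is strict everywhere a threshold is quoted
  (−15 mL/g, 95%, 2 points, 535 nm, $k_H$ 0.5, $R^2$ 0.998): equality
  passes, except the AC-SINS control rule where the control must be
  *below* 535 nm.
* Ties in model selection break deterministically (RMSD, then lexical id).

## Problem sizes used in the tests

The suite runs in well under a minute on one CPU: DLS series of 4–6
concentrations (200 seeded replicates for the bias check), viscosity curves
of 8–15 points with 20 seeded Ross–Minton problems against a dense-grid
oracle, $10^5$-draw Monte-Carlo validation of the $k_H$ uncertainty,
thermograms of 151–751 points, 100-seed plasmon-peak recovery, 10-seed
five-concentration sensorgram studies, and 50 seeded ranking tables against
exhaustive enumeration.

## Known limitations

* The GSE extrapolation is a model statement, not a measurement; far outside
  the fitted range it can over- or under-shoot measured viscosity by large
  factors, which is expected behaviour of the assumptions rather than a bug.
* $k$ and $v$ of the Ross–Minton model are reported as fitted but only
  their ratio is identifiable (see above).
* The Huggins analysis assumes the dilute regime; it does not check for it.
* `find_transitions()` reports derivative maxima; strongly overlapping
  transitions (separation below ~5× width) merge by design.
* Correlation output is descriptive; no multiplicity control is applied.
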