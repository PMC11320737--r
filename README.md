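# mabdev

Quantitative developability analysis for therapeutic antibodies.

Developability assessment asks whether an antibody candidate will
self-associate, aggregate, unfold or turn syrupy at the high concentrations
(> 100 mg/mL) a subcutaneous formulation needs. `mabdev` implements the
analysis layer of a subclass-comparison biophysics panel (e.g. an IgG1/IgG3
pair with identical variable domains), together with seeded synthetic
generators for every assay modality, so the whole pipeline runs and is
testable without any instrument export:

| Assay | Model / estimator | Functions |
|---|---|---|
| DLS concentration series | `D_app(c) = D0 (1 + kD c)`; OLS, `kD = slope/intercept` (mL/g), delta-method SE; flag at `kD < -15 mL/g` | `fit_kd`, `classify_kd` |
| GSE theoretical viscosity | `eta = kB T / (3 pi dH(c) D(c))` with log-linear trend fits for `dH` and `D` | `fit_trends`, `gse_viscosity` |
| Viscometry | exponential growth `Y0 e^{kc}`; Tomar `ln(eta/eta0) = lnA + Bc`; modified Ross–Minton `eta0 exp([eta]c / (1 - (k/v)[eta]c))`; interpolation at a target concentration | `filter_records`, `fit_expgrowth`, `fit_tomar`, `fit_rossminton`, `interpolate_viscosity` |
| Intrinsic viscosity | Huggins relation `eta_red = [eta] + kH [eta]^2 c`; OLS + full delta-method error propagation for `kH`; poor solvent at `kH > 0.5` | `reduced_viscosities`, `fit_huggins`, `classify_solvent_quality` |
| DSF thermograms | Savitzky–Golay first derivative of the 350/330 ratio; Tm from prominent maxima, Tonset, Tagg | `find_transitions` |
| AC-SINS | quadratic-vertex plasmon peak; red shift vs control; control QC `< 535 nm` | `plasmon_peak`, `red_shift` |
| SPR kinetics | global 1:1 Langmuir fit sharing `ka`, `kd`, `Rmax`; `KD = kd/ka` | `kd_from_rates`, `fit_langmuir` |
| aSEC stability | monomer `< 95%` and HMwS increase `> 2` points from day 0 | `stability_flags` |
| Homology-model ranking | min–max normalized quality values (0 = best), inverted packing orientation; deterministic selection | `normalize_scores`, `select_model` |
| Reporting | per-molecule scorecard with thresholds, JSON round trip; pairwise Pearson/Spearman correlation | `build_scorecard`, `correlate` |

Every generator (`make_dls_series`, `make_viscosity_curve`,
`make_reduced_viscosity_series`, `make_thermogram`, `make_plasmon_spectrum`,
`make_sensorgram`, `make_purity_table`, `make_score_table`) is a pure
function of its parameters and a seed, and every fit inverts its noiseless
generator exactly — that round trip is the backbone of the test suite.
See `vignettes/developability-analysis.Rmd` for the models, assumptions,
defaults and limitations.

## Worked example

```r
library(mabdev)

## colloidal self-interaction from a DLS series (kD in mL/g)
s  <- make_dls_series(d0 = 5e-11, kd = -30, concentrations = c(1, 2, 5, 10, 20))
kd <- fit_kd(s$dapp)
kd
#> <kd_fit: D0 = 5e-11 m^2/s, kD = -30.00 (+/- 0.00) mL/g, R^2 = 1.0000, n = 5>
classify_kd(kd)
#> [1] "attractive_flag"        # -30 < -15 mL/g: net attractive interactions

## concentration-viscosity profile, modified Ross-Minton fit
curve <- make_viscosity_curve("rossminton", rossminton_params(10.4, 0.45, 0.9),
                              concentrations = seq(10, 150, 20))
eta <- aggregate_records(filter_records(curve))
#> filter_records: retained 8 of 8 records (R^2 >= 0.998, steady)
fit <- fit_rossminton(eta)
interpolate_viscosity(fit, 150)
#> [1] 1357.13                  # cP at 150 mg/mL (k and v only identified via k/v)

## intrinsic viscosity and Huggins coefficient from the dilute regime
red <- make_reduced_viscosity_series(10.42, 1.27, c(5, 10, 20, 30, 40, 50))
h <- fit_huggins(red)
h
#> <huggins_result: [eta] = 10.420 (+/- 0.000) mL/g, kH = 1.270 (+/- 0.000), n = 6>
classify_solvent_quality(h)
#> [1] "poor_solvent"           # kH > 0.5: viscosity sensitive to PPIs

## one scorecard per molecule
build_scorecard("IgG3", list(kd_fit = kd, huggins = h))
#> <scorecard: IgG3; assays: kd_fit, huggins>
#>   kd_attractive    FLAG (threshold < -15)
#>   poor_solvent     FLAG (threshold > 0.5)
```

The kD of −30 mL/g marks the molecule as self-attractive; the Huggins
coefficient of 1.27 (> 0.5) marks a "poor solvent" whose viscosity responds
strongly to protein–protein interactions; both flags carry their thresholds
into the scorecard.

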