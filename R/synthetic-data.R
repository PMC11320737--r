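#' Simulate a DLS concentration series
#'
#' Generates the two observables a concentration-gradient dynamic light
#' scattering experiment produces: the apparent diffusion coefficient
#' `Dapp(c) = D0 * (1 + kD * c)` (kD supplied in mL/g, applied internally in
#' mL/mg so that kD * c is dimensionless with c in mg/mL) and the Z-average
#' hydrodynamic diameter on a power-law (log10-linear) trend
#' `Zave(c) = 10^(a * log10(c) + b)` nm.
#'
#' @param d0 Self-diffusion coefficient at infinite dilution, m^2/s.
#' @param kd Diffusion interaction parameter, mL/g. Negative values emulate
#'   net attractive protein-protein interactions.
#' @param concentrations Strictly positive concentrations, mg/mL; at least two
#'   distinct values (a downstream regression is otherwise undefined).
#' @param zave_params Length-2 numeric `c(a, b)`: slope and intercept of the
#'   log10 Z-average fit.
#' @param noise A [noise_spec()]; additive on each observable's own scale.
#' @return A list with elements `dapp` and `zave`, each a
#'   [concentration_series()].
#' @examples
#' s <- make_dls_series(5e-11, -30, c(1, 5, 10, 20))
#' s$dapp$value   # 5e-11 * (1 - 0.030 * c)
#' @export
make_dls_series <- function(d0, kd, concentrations,
                            zave_params = c(0.46, 0.87),
                            noise = noise_spec()) {
  if (length(concentrations) < 2L || length(unique(concentrations)) < 2L)
    stop_invalid("need at least two distinct concentrations")
  if (any(concentrations <= 0))
    stop_invalid("concentrations must be strictly positive")
  kd_internal <- kd / 1000                      # mL/g -> mL/mg
  dapp <- d0 * (1 + kd_internal * concentrations)
  zave <- 10^(zave_params[1L] * log10(concentrations) + zave_params[2L])
  # independent noise streams per observable, derived from one seed
  n_d <- noise
  n_z <- noise
  if (noise$kind == "gaussian") n_z$seed <- noise$seed + 1L
  list(
    dapp = concentration_series(concentrations, apply_noise(dapp, n_d), "Dapp"),
    zave = concentration_series(concentrations, apply_noise(zave, n_z), "Zave")
  )
}

#' Simulate a viscosity-concentration curve
#'
#' Evaluates one of the three concentration-viscosity models at the requested
#' concentrations and shear rates: exponential growth
#' `eta = Y0 * exp(k * c)`, the Tomar log-linear model
#' `eta = eta0 * exp(lnA + B * c)`, or the modified Ross-Minton model
#' `eta = eta0 * exp([eta] c / (1 - (k/v) [eta] c))` (intrinsic viscosity
#' user-facing in mL/g, converted to mL/mg internally).
#'
#' @param model `"expgrowth"`, `"tomar"` or `"rossminton"`.
#' @param params Parameter record from [expgrowth_params()], [tomar_params()]
#'   or [rossminton_params()] (a plain named list with the same fields works).
#' @param concentrations Nonnegative concentrations, mg/mL.
#' @param shear_rates Shear rates, 1/s; one record is produced per
#'   (concentration, shear rate) pair.
#' @param noise A [noise_spec()], additive in cP.
#' @return A data.frame of viscosity records with columns
#'   `concentration`, `shear_rate`, `viscosity`, `pressure_fit_r2` (1.0 for
#'   synthetic records) and `steady` (TRUE).
#' @export
make_viscosity_curve <- function(model = c("expgrowth", "tomar", "rossminton"),
                                 params, concentrations, shear_rates = 1000,
                                 noise = noise_spec()) {
  model <- match.arg(model)
  if (any(concentrations < 0)) stop_invalid("concentrations must be nonnegative")
  grid <- expand.grid(concentration = concentrations, shear_rate = shear_rates,
                      KEEP.OUT.ATTRS = FALSE)
  eta <- eval_viscosity_model(model, params, grid$concentration)
  grid$viscosity <- apply_noise(eta, noise)
  grid$pressure_fit_r2 <- 1.0
  grid$steady <- TRUE
  grid
}

#' Simulate a dilute-regime reduced-viscosity series
#'
#' Generates `eta_red(c) = [eta] + kH * [eta]^2 * c` with the concentration
#' converted from the user-facing mg/mL to g/mL internally, so that eta_red
#' and the intrinsic viscosity are both in mL/g.
#'
#' @param eta_intrinsic Intrinsic viscosity, mL/g; must be positive.
#' @param k_huggins Huggins coefficient, dimensionless.
#' @param concentrations Concentrations, mg/mL (dilute regime expected but not
#'   enforced).
#' @param noise A [noise_spec()], additive in mL/g.
#' @return A [concentration_series()] with observable `eta_red`.
#' @examples
#' make_reduced_viscosity_series(10.42, 1.27, c(5, 10, 20, 30, 40, 50))
#' @export
make_reduced_viscosity_series <- function(eta_intrinsic, k_huggins,
                                          concentrations,
                                          noise = noise_spec()) {
  if (eta_intrinsic <= 0) stop_invalid("eta_intrinsic must be positive")
  c_g_ml <- concentrations / 1000
  eta_red <- eta_intrinsic + k_huggins * eta_intrinsic^2 * c_g_ml
  concentration_series(concentrations, apply_noise(eta_red, noise), "eta_red")
}

#' Simulate a DSF thermogram
#'
#' The 350/330 nm intrinsic-fluorescence ratio is modelled as a baseline plus
#' a sum of logistic sigmoids, one per unfolding transition; the analytic
#' first derivative of each sigmoid peaks exactly at its midpoint Tm, which
#' makes the generator an exact oracle for transition detection. An optional
#' aggregation event adds a logistic step to a scattering trace.
#'
#' @param transitions A list of length-3 numeric vectors `c(tm, amplitude,
#'   width)`: midpoint (deg C, inside `t_range`), ratio amplitude, and logistic
#'   scale (deg C, > 0).
#' @param t_range Ramp limits, deg C; default `c(20, 95)`.
#' @param step Temperature grid step, deg C.
#' @param baseline Pre-transition ratio level.
#' @param agg Optional `c(t_agg, amplitude, width)` logistic aggregation event
#'   added to the scattering trace.
#' @param noise A [noise_spec()] applied to the ratio trace.
#' @return A [thermogram()].
#' @export
make_thermogram <- function(transitions, t_range = c(20, 95), step = 0.1,
                            baseline = 0.5, agg = NULL,
                            noise = noise_spec()) {
  temperature <- seq(t_range[1L], t_range[2L], by = step)
  ratio <- rep(baseline, length(temperature))
  for (tr in transitions) {
    if (length(tr) != 3L || tr[3L] <= 0)
      stop_invalid("each transition must be c(tm, amplitude, width) with width > 0")
    if (tr[1L] < t_range[1L] || tr[1L] > t_range[2L])
      stop_invalid("transition midpoint ", tr[1L], " outside ramp range")
    ratio <- ratio + tr[2L] / (1 + exp(-(temperature - tr[1L]) / tr[3L]))
  }
  scattering <- NULL
  if (!is.null(agg)) {
    if (agg[1L] < t_range[1L] || agg[1L] > t_range[2L])
      stop_invalid("aggregation onset outside ramp range")
    scattering <- agg[2L] / (1 + exp(-(temperature - agg[1L]) / agg[3L]))
  }
  thermogram(temperature, apply_noise(ratio, noise), scattering)
}

#' Simulate an AC-SINS absorbance spectrum
#'
#' A Gaussian plasmon band centred at `peak_nm` on a small flat baseline, the
#' reduced observable the plate reader exports after blanking.
#'
#' @param peak_nm Plasmon peak position, nm; must lie within the grid span.
#' @param width_nm Gaussian standard deviation, nm.
#' @param wavelengths Wavelength grid, nm; default 450-650 nm in 1 nm steps.
#' @param amplitude Peak absorbance above baseline, AU.
#' @param baseline Baseline absorbance, AU.
#' @param label `"sample"`, `"control"` or `"buffer"`.
#' @param noise A [noise_spec()], additive in AU.
#' @return A [spectrum_trace()].
#' @export
make_plasmon_spectrum <- function(peak_nm, width_nm = 15,
                                  wavelengths = seq(450, 650, by = 1),
                                  amplitude = 1, baseline = 0.02,
                                  label = "sample", noise = noise_spec()) {
  if (width_nm <= 0) stop_invalid("width_nm must be positive")
  if (peak_nm < min(wavelengths) || peak_nm > max(wavelengths))
    stop_invalid("peak_nm outside the wavelength grid")
  a <- baseline + amplitude * exp(-0.5 * ((wavelengths - peak_nm) / width_nm)^2)
  spectrum_trace(wavelengths, apply_noise(a, noise), label = label)
}

#' Simulate 1:1 Langmuir SPR sensorgrams
#'
#' For each analyte concentration C the association phase follows
#' `R(t) = Rmax * C / (C + KD) * (1 - exp(-(ka*C + kd)*t))` with `KD = kd/ka`,
#' and the dissociation phase decays exponentially from the association
#' endpoint with rate `kd`.
#'
#' @param ka Association rate constant, 1/(M*s); positive.
#' @param kd Dissociation rate constant, 1/s; positive.
#' @param rmax Maximum response, RU; positive.
#' @param analyte_concs Analyte concentrations, M.
#' @param t_assoc,t_dissoc Phase durations, s.
#' @param dt Sampling interval, s.
#' @param noise A [noise_spec()], additive in RU.
#' @return A data.frame with columns `time`, `response`, `conc`, `phase`
#'   (`"association"`/`"dissociation"`) and attribute `t_assoc`.
#' @export
make_sensorgram <- function(ka, kd, rmax, analyte_concs,
                            t_assoc = 180, t_dissoc = 300, dt = 1,
                            noise = noise_spec()) {
  if (ka <= 0 || kd <= 0 || rmax <= 0)
    stop_invalid("ka, kd and rmax must be positive")
  if (any(analyte_concs <= 0)) stop_invalid("analyte concentrations must be positive")
  KD <- kd / ka
  out <- do.call(rbind, lapply(analyte_concs, function(C) {
    ta <- seq(0, t_assoc, by = dt)
    ra <- rmax * C / (C + KD) * (1 - exp(-(ka * C + kd) * ta))
    r_end <- ra[length(ra)]
    td <- seq(dt, t_dissoc, by = dt)
    rd <- r_end * exp(-kd * td)
    data.frame(time = c(ta, t_assoc + td), response = c(ra, rd), conc = C,
               phase = rep(c("association", "dissociation"),
                           c(length(ta), length(td))))
  }))
  out$response <- apply_noise(out$response, noise)
  attr(out, "t_assoc") <- t_assoc
  out
}

#' Simulate an aSEC purity time series
#'
#' Starting from a day-0 composition (monomer, high- and low-molecular-weight
#' species percentages summing to 100), HMwS and LMwS drift linearly per day
#' at condition-specific rates and the monomer fraction is the complement, so
#' every generated row sums to 100 by construction.
#'
#' @param day0 Length-3 numeric `c(pct_monomer, pct_hmws, pct_lmws)` summing
#'   to 100 within 0.01.
#' @param drift_per_day Named list, one entry per condition, each a length-2
#'   numeric `c(hmws_per_day, lmws_per_day)` in percentage points per day.
#' @param days Integer vector of sampling days (day 0 added if absent).
#' @param conditions Condition labels; default `names(drift_per_day)`.
#' @return A data.frame with columns `day`, `condition`, `pct_monomer`,
#'   `pct_hmws`, `pct_lmws`.
#' @export
make_purity_table <- function(day0, drift_per_day, days,
                              conditions = names(drift_per_day)) {
  if (abs(sum(day0) - 100) > 0.01)
    stop_invalid("day-0 fractions must sum to 100 (got ", sum(day0), ")")
  if (is.null(conditions) || !all(conditions %in% names(drift_per_day)))
    stop_invalid("drift_per_day must be a named list covering all conditions")
  days <- sort(unique(c(0L, as.integer(days))))
  rows <- lapply(conditions, function(cond) {
    dr <- drift_per_day[[cond]]
    hmws <- day0[2L] + dr[1L] * days
    lmws <- day0[3L] + dr[2L] * days
    data.frame(day = days, condition = cond,
               pct_monomer = 100 - hmws - lmws,
               pct_hmws = hmws, pct_lmws = lmws)
  })
  do.call(rbind, rows)
}

#' Simulate a homology-model geometric-score table
#'
#' Draws one row per candidate model with Gaussian scores per geometric
#' quality metric, a packing score, and a heavy-atom RMSD to the average
#' intermediate-model position.
#'
#' @param n_models Number of candidate models (>= 2).
#' @param metrics Named list of `c(mean, sd)` per geometric metric; defaults
#'   to typical protein-geometry checks.
#' @param higher_is_better Named logical per metric (packing is always scored
#'   higher-is-better and need not be listed).
#' @param packing `c(mean, sd)` for the packing score.
#' @param rmsd `c(mean, sd)` for the RMSD-to-average column, Angstrom.
#' @param seed Integer seed.
#' @return A [score_table()].
#' @export
make_score_table <- function(n_models = 10,
                             metrics = list(bond_outliers = c(5, 2),
                                            angle_outliers = c(8, 3),
                                            rotamer_strain = c(12, 4)),
                             higher_is_better = NULL,
                             packing = c(0.7, 0.1),
                             rmsd = c(1.0, 0.3),
                             seed = 1L) {
  if (n_models < 2L) stop_invalid("need at least two candidate models")
  if (is.null(higher_is_better))
    higher_is_better <- stats::setNames(rep(FALSE, length(metrics)), names(metrics))
  withr::with_seed(seed, {
    df <- data.frame(model_id = sprintf("model_%02d", seq_len(n_models)))
    for (m in names(metrics))
      df[[m]] <- stats::rnorm(n_models, metrics[[m]][1L], metrics[[m]][2L])
    df$packing <- stats::rnorm(n_models, packing[1L], packing[2L])
    df$rmsd_to_average <- abs(stats::rnorm(n_models, rmsd[1L], rmsd[2L]))
    score_table(df, higher_is_better = higher_is_better)
  })
}
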