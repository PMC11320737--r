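#' Diffusion interaction parameter from a DLS concentration series
#'
#' Fits the dilute-regime linear law `Dapp(c) = D0 (1 + kD c)` by ordinary
#' least squares of the apparent diffusion coefficient on concentration:
#' `D0` is the intercept and `kD = slope / intercept`, converted from the
#' internal mL/mg to the conventional mL/g. Standard errors come from the OLS
#' covariance; the kD standard error uses first-order (delta-method)
#' propagation for the slope/intercept ratio. Negative kD indicates net
#' attractive protein-protein interactions.
#'
#' @param series A [concentration_series()] with observable `Dapp`, at least
#'   two distinct concentrations.
#' @return A `kd_fit` list: `d0` (m^2/s), `kd` (mL/g), `stderr_d0`,
#'   `stderr_kd`, `r_squared`, `n`.
#' @examples
#' s <- make_dls_series(5e-11, -30, c(1, 5, 10, 20))$dapp
#' fit_kd(s)
#' @export
fit_kd <- function(series) {
  assert_series(series, "Dapp", min_points = 2L, what = "Dapp series")
  if (length(unique(series$concentration)) < 2L)
    stop_degenerate("all concentrations equal; kD regression is singular")
  fit <- stats::lm(value ~ concentration, data = series)
  cf <- stats::coef(fit)
  V <- quiet_vcov(fit)
  d0 <- cf[[1L]]
  slope <- cf[[2L]]
  kd_internal <- slope / d0                       # mL/mg
  # delta method for the ratio slope/intercept
  var_ratio <- V[2L, 2L] / d0^2 + slope^2 * V[1L, 1L] / d0^4 -
    2 * slope * V[1L, 2L] / d0^3
  r2 <- r_squared_lm(fit)
  structure(list(d0 = d0, kd = 1000 * kd_internal,
                 stderr_d0 = sqrt(V[1L, 1L]),
                 stderr_kd = 1000 * sqrt(max(0, var_ratio)),
                 r_squared = r2, n = nrow(series)),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit: D0 = %.4g m^2/s, kD = %.2f (+/- %.2f) mL/g, R^2 = %.4f, n = %d>\n",
              x$d0, x$kd, x$stderr_kd, x$r_squared, x$n))
  invisible(x)
}

#' Flag attractive self-interaction from kD
#'
#' kD below the threshold (default -15 mL/g, strict inequality) flags
#' predominant attractive forces; boundary equality passes.
#'
#' @param fit A `kd_fit` from [fit_kd()].
#' @param threshold Cutoff, mL/g; default -15.
#' @return `"attractive_flag"` or `"pass"`.
#' @export
classify_kd <- function(fit, threshold = -15) {
  if (!inherits(fit, "kd_fit")) stop_invalid("fit must be a kd_fit")
  if (fit$kd < threshold) "attractive_flag" else "pass"
}

#' Dilute-regime trend fits for GSE extrapolation
#'
#' Fits the two trends used to extrapolate dilute-regime DLS measurements to
#' formulation concentrations: an exponential decay of the diffusion
#' coefficient, `D(c) = A exp(-r c)`, fitted as OLS on `log D`, and a
#' power-law Z-average diameter, `log10 Zave = a log10 c + b`, fitted as OLS
#' in the log-log plane. Both linearized fits are deterministic.
#'
#' @param d_series [concentration_series()] with observable `Dapp`, >= 3
#'   points at positive concentrations.
#' @param z_series [concentration_series()] with observable `Zave`, >= 3
#'   points at positive concentrations.
#' @return A `trend_fits` list: `d_exp` (`amplitude` m^2/s, `rate` mL/mg,
#'   `r_squared`) and `zave_log` (`slope`, `intercept`, `r_squared`).
#' @export
fit_trends <- function(d_series, z_series) {
  assert_series(d_series, "Dapp", min_points = 3L, what = "Dapp series")
  assert_series(z_series, "Zave", min_points = 3L, what = "Zave series")
  if (any(d_series$concentration <= 0) || any(z_series$concentration <= 0))
    stop_invalid("concentrations must be strictly positive")
  if (any(d_series$value <= 0))
    stop_invalid("nonpositive diffusion coefficient; log fit undefined")
  if (any(z_series$value <= 0))
    stop_invalid("nonpositive Z-average; log fit undefined")
  dfit <- stats::lm(log(value) ~ concentration, data = d_series)
  zfit <- stats::lm(log10(value) ~ log10(concentration), data = z_series)
  r2 <- r_squared_lm
  structure(list(
    d_exp = list(amplitude = exp(stats::coef(dfit)[[1L]]),
                 rate = -stats::coef(dfit)[[2L]],
                 r_squared = r2(dfit)),
    zave_log = list(slope = stats::coef(zfit)[[2L]],
                    intercept = stats::coef(zfit)[[1L]],
                    r_squared = r2(zfit))),
    class = "trend_fits")
}

#' @export
print.trend_fits <- function(x, ...) {
  cat(sprintf("<trend_fits: D(c) = %.4g exp(-%.4g c) [R^2 %.4f]; log10 Z = %.3f log10 c + %.3f [R^2 %.4f]>\n",
              x$d_exp$amplitude, x$d_exp$rate, x$d_exp$r_squared,
              x$zave_log$slope, x$zave_log$intercept, x$zave_log$r_squared))
  invisible(x)
}

#' Theoretical viscosity from the generalized Stokes-Einstein relation
#'
#' Evaluates `eta(c) = kB T / (3 pi dH(c) D(c))` on a concentration grid,
#' taking the hydrodynamic diameter `dH` from the Z-average log fit
#' (nm converted to m) and the diffusion coefficient from the exponential fit,
#' then converts Pa.s to cP. Using 3 pi with the diameter is equivalent to the
#' textbook 6 pi with the radius.
#'
#' @param trends A `trend_fits` from [fit_trends()].
#' @param conc_grid Positive concentrations, mg/mL.
#' @param temperature Absolute temperature, K; default 298.
#' @return A `gse_result` data.frame with columns `concentration` and
#'   `eta_theoretical` (cP), attribute `temperature`.
#' @export
gse_viscosity <- function(trends, conc_grid, temperature = 298) {
  if (!inherits(trends, "trend_fits")) stop_invalid("trends must be trend_fits")
  if (any(conc_grid <= 0)) stop_invalid("concentration grid must be positive")
  kB <- 1.380649e-23                                        # J/K
  d_h_nm <- 10^(trends$zave_log$slope * log10(conc_grid) +
                  trends$zave_log$intercept)
  D <- trends$d_exp$amplitude * exp(-trends$d_exp$rate * conc_grid)
  if (any(!is.finite(d_h_nm)) || any(d_h_nm <= 0) || any(D <= 0))
    stop_domain("dH or D nonpositive on the requested grid")
  eta_pa_s <- kB * temperature / (3 * pi * (d_h_nm * 1e-9) * D)
  structure(data.frame(concentration = conc_grid,
                       eta_theoretical = eta_pa_s * 1000),
            temperature = temperature,
            class = c("gse_result", "data.frame"))
}
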