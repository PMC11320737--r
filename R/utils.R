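#' Noise specification for synthetic-data generators
#'
#' Describes additive observation noise applied on the observable scale.
#' Generators are pure functions of their parameters and the seed: calling a
#' generator twice with the same `noise_spec()` yields bit-identical output.
#'
#' @param kind `"none"` or `"gaussian"`.
#' @param sigma Standard deviation of the additive noise, in the units of the
#'   generated observable. Must be 0 when `kind = "none"` and positive when
#'   `kind = "gaussian"`.
#' @param seed Integer seed used for the draw.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec()                       # noiseless
#' noise_spec("gaussian", 0.5, seed = 42)
#' @export
noise_spec <- function(kind = c("none", "gaussian"), sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a single nonnegative number", call. = FALSE)
  if (kind == "none" && sigma != 0)
    stop("`sigma` must be 0 when kind = \"none\"", call. = FALSE)
  if (kind == "gaussian" && sigma == 0)
    stop("`sigma` must be positive when kind = \"gaussian\"", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

# Apply additive noise to a numeric vector under the noise_spec's seed.
apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$kind == "none") return(x)
  withr::with_seed(noise$seed,
                   x + stats::rnorm(length(x), mean = 0, sd = noise$sigma))
}

# R^2 of an lm fit without summary.lm's perfect-fit warning; 1 when the
# response is constant and perfectly reproduced.
r_squared_lm <- function(fit) {
  y <- stats::fitted(fit) + stats::residuals(fit)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / sst
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("mabdev_invalid_input", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("mabdev_degenerate_fit", "error")))
}

stop_fit_failure <- function(...) {
  stop(errorCondition(paste0(...), class = c("mabdev_fit_failure", "error")))
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("mabdev_domain_error", "error")))
}

# vcov.lm routes through summary.lm, which warns on zero-residual fits; the
# covariance itself is still what we want (zero).
quiet_vcov <- function(fit) suppressWarnings(stats::vcov(fit))

#' Concentration series container
#'
#' Paired (concentration, observable) measurements: the common currency of the
#' DLS and viscometry analyses. Concentrations are in mg/mL throughout the
#' user-facing interface.
#'
#' @param concentration Numeric vector, mg/mL, nonnegative.
#' @param value Numeric vector of the observable, same length.
#' @param observable One of `"Dapp"` (apparent diffusion coefficient, m^2/s),
#'   `"Zave"` (Z-average diameter, nm), `"eta"` (dynamic viscosity, cP) or
#'   `"eta_red"` (reduced viscosity, mL/g).
#' @param units Units tag; defaults to the conventional unit per observable.
#' @param replicate_id Optional replicate labels.
#' @return A `concentration_series` (also a data.frame with columns
#'   `concentration` and `value`).
#' @export
concentration_series <- function(concentration, value,
                                 observable = c("Dapp", "Zave", "eta", "eta_red"),
                                 units = NULL, replicate_id = NULL) {
  observable <- match.arg(observable)
  concentration <- as.numeric(concentration)
  value <- as.numeric(value)
  if (length(concentration) != length(value))
    stop_invalid("concentration and value must have equal length")
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop_invalid("concentrations must be finite and nonnegative")
  if (is.null(units))
    units <- c(Dapp = "m^2/s", Zave = "nm", eta = "cP", eta_red = "mL/g")[[observable]]
  out <- data.frame(concentration = concentration, value = value)
  if (!is.null(replicate_id)) out$replicate_id <- replicate_id
  structure(out, observable = observable, units = units,
            class = c("concentration_series", "data.frame"))
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series: %s [%s], n = %d>\n",
              attr(x, "observable"), attr(x, "units"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

assert_series <- function(x, observable, min_points = 2L, what = "series") {
  if (!inherits(x, "concentration_series"))
    stop_invalid(what, " must be a concentration_series")
  if (!identical(attr(x, "observable"), observable))
    stop_invalid(what, " must carry observable '", observable, "', got '",
                 attr(x, "observable"), "'")
  if (nrow(x) < min_points)
    stop_invalid(what, " needs at least ", min_points, " points")
  invisible(x)
}

#' Read a concentration series from CSV
#'
#' Expects two columns: concentration in mg/mL and the observable, e.g.
#' `concentration_mg_ml, dapp_m2_s` or `concentration_mg_ml, viscosity_cP`.
#' The first column is taken as concentration, the second as the value.
#'
#' @param path CSV file path.
#' @inheritParams concentration_series
#' @return A `concentration_series`.
#' @export
read_concentration_series <- function(path, observable) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop_invalid("CSV must have at least two columns")
  concentration_series(df[[1L]], df[[2L]], observable = observable)
}

#' Write a concentration series to CSV
#'
#' @param x A `concentration_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentration_series <- function(x, path) {
  stopifnot(inherits(x, "concentration_series"))
  names <- c(Dapp = "dapp_m2_s", Zave = "zave_d_nm",
             eta = "viscosity_cP", eta_red = "eta_red_ml_g")
  df <- data.frame(concentration_mg_ml = x$concentration, value = x$value)
  names(df)[2L] <- names[[attr(x, "observable")]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
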