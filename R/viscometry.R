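#' Viscosity-concentration model parameter records
#'
#' Constructors for the parameter records of the three concentration-viscosity
#' models:
#' * exponential growth: `eta(c) = Y0 * exp(k * c)`;
#' * Tomar log-linear: `eta(c) = eta0 * exp(lnA + B * c)`, i.e. `ln(eta/eta0)`
#'   is linear in concentration;
#' * modified Ross-Minton: `eta(c) = eta0 * exp([eta] c / (1 - (k/v) [eta] c))`
#'   with intrinsic viscosity `[eta]` (user-facing mL/g, applied internally in
#'   mL/mg), crowding factor `k` and Simha shape parameter `v`.
#'
#' The buffer viscosity `eta0` defaults to 1.13 cP, the formulation-buffer
#' value used for the Tomar and Ross-Minton fits.
#'
#' @param y0 Intercept viscosity at zero concentration, cP; positive.
#' @param k_rate Exponential rate constant, mL/mg.
#' @param ln_a Dimensionless Tomar intercept.
#' @param b_slope Tomar slope, mL/mg.
#' @param eta0 Buffer viscosity, cP; positive.
#' @param eta_intrinsic Intrinsic viscosity, mL/g; positive.
#' @param k_crowding Crowding factor, dimensionless.
#' @param v_shape Simha shape parameter, dimensionless; positive.
#' @return A named list of class `expgrowth_params`, `tomar_params` or
#'   `rossminton_params`.
#' @name viscosity_params
NULL

#' @rdname viscosity_params
#' @export
expgrowth_params <- function(y0, k_rate) {
  if (y0 <= 0) stop_invalid("y0 must be positive")
  structure(list(y0 = y0, k_rate = k_rate), class = "expgrowth_params")
}

#' @rdname viscosity_params
#' @export
tomar_params <- function(ln_a, b_slope, eta0 = 1.13) {
  if (eta0 <= 0) stop_invalid("eta0 must be positive")
  structure(list(ln_a = ln_a, b_slope = b_slope, eta0 = eta0),
            class = "tomar_params")
}

#' @rdname viscosity_params
#' @export
rossminton_params <- function(eta_intrinsic, k_crowding, v_shape, eta0 = 1.13) {
  if (eta_intrinsic <= 0) stop_invalid("eta_intrinsic must be positive")
  if (v_shape <= 0) stop_invalid("v_shape must be positive")
  if (eta0 <= 0) stop_invalid("eta0 must be positive")
  structure(list(eta_intrinsic = eta_intrinsic, k_crowding = k_crowding,
                 v_shape = v_shape, eta0 = eta0),
            class = "rossminton_params")
}

# Closed-form model evaluation; `params` may be a constructor record or a
# plain named list with the same fields. Concentration in mg/mL, eta in cP.
eval_viscosity_model <- function(model, params, concentration) {
  p <- params
  switch(model,
    expgrowth = {
      if (is.null(p$y0) || is.null(p$k_rate))
        stop_invalid("expgrowth params need fields y0 and k_rate")
      p$y0 * exp(p$k_rate * concentration)
    },
    tomar = {
      if (is.null(p$ln_a) || is.null(p$b_slope))
        stop_invalid("tomar params need fields ln_a and b_slope")
      eta0 <- if (is.null(p$eta0)) 1.13 else p$eta0
      eta0 * exp(p$ln_a + p$b_slope * concentration)
    },
    rossminton = {
      if (is.null(p$eta_intrinsic) || is.null(p$k_crowding) || is.null(p$v_shape))
        stop_invalid("rossminton params need eta_intrinsic, k_crowding, v_shape")
      eta0 <- if (is.null(p$eta0)) 1.13 else p$eta0
      iv <- p$eta_intrinsic / 1000              # mL/g -> mL/mg
      denom <- 1 - (p$k_crowding / p$v_shape) * iv * concentration
      if (any(denom <= 0))
        stop_domain("Ross-Minton denominator nonpositive on the requested span")
      eta0 * exp(iv * concentration / denom)
    },
    stop_invalid("unknown viscosity model '", model, "'")
  )
}

new_viscosity_fit <- function(model, params, sse, covariance, n, data) {
  structure(list(model = model, params = params, sse = sse,
                 covariance = covariance, n = n,
                 c_max = max(data$concentration)),
            class = "viscosity_model_fit")
}

#' @export
print.viscosity_model_fit <- function(x, ...) {
  cat(sprintf("<viscosity_model_fit: %s, n = %d, SSE = %.4g cP^2>\n",
              x$model, x$n, x$sse))
  print(unclass(x$params))
  invisible(x)
}

#' Filter viscometer records for analysis
#'
#' Retains records whose transient reached a steady plateau and whose
#' pressure-over-sensor-position linear fit has R^2 at or above the cutoff
#' (default 0.998). Input order is preserved.
#'
#' @param records Data.frame of viscosity records with columns `viscosity`,
#'   `shear_rate`, `pressure_fit_r2` and `steady` (as produced by
#'   [make_viscosity_curve()] or read from instrument export).
#' @param r2_min Minimum pressure-fit R^2; default 0.998.
#' @param quiet Suppress the retained/dropped message.
#' @return The retained records.
#' @export
filter_records <- function(records, r2_min = 0.998, quiet = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_invalid("records must be a nonempty data.frame")
  needed <- c("pressure_fit_r2", "steady")
  if (!all(needed %in% names(records)))
    stop_invalid("records must have columns pressure_fit_r2 and steady")
  keep <- records$steady & records$pressure_fit_r2 >= r2_min
  out <- records[keep, , drop = FALSE]
  if (!quiet)
    message(sprintf("filter_records: retained %d of %d records (R^2 >= %g, steady)",
                    nrow(out), nrow(records), r2_min))
  if (nrow(out) == 0L)
    stop_invalid("all records filtered out; no data left to fit")
  out
}

#' Collapse multi-shear-rate records to one viscosity per concentration
#'
#' Records measured at several shear rates for one concentration are averaged
#' after a Newtonian-plateau check: the max/min viscosity ratio within a
#' concentration must not exceed `plateau_tol`, otherwise the aggregation
#' aborts (shear-thinning data should not be averaged blindly).
#'
#' @param records Filtered viscosity records (see [filter_records()]).
#' @param plateau_tol Maximum allowed max/min viscosity ratio per
#'   concentration; default 1.05.
#' @return A [concentration_series()] with observable `eta`.
#' @export
aggregate_records <- function(records, plateau_tol = 1.05) {
  if (!all(c("concentration", "viscosity") %in% names(records)))
    stop_invalid("records must have columns concentration and viscosity")
  sp <- split(records$viscosity, records$concentration)
  ratios <- vapply(sp, function(v) max(v) / min(v), numeric(1))
  if (any(ratios > plateau_tol))
    stop_domain("non-Newtonian spread across shear rates (max/min ratio ",
                sprintf("%.3f", max(ratios)), " > ", plateau_tol, ")")
  conc <- as.numeric(names(sp))
  ord <- order(conc)
  concentration_series(conc[ord], vapply(sp, mean, numeric(1))[ord], "eta")
}

#' Fit the exponential-growth viscosity model
#'
#' Nonlinear least squares of `eta = Y0 * exp(k * c)`, initialized from the
#' log-linearized ordinary least-squares fit and polished with
#' Levenberg-Marquardt.
#'
#' @param data A [concentration_series()] with observable `eta`, >= 3 points.
#' @return A `viscosity_model_fit` with [expgrowth_params()], SSE (cP^2) and
#'   the parameter covariance matrix.
#' @export
fit_expgrowth <- function(data) {
  assert_series(data, "eta", min_points = 3L, what = "viscosity data")
  if (any(data$value <= 0)) stop_domain("viscosities must be positive")
  init <- stats::lm(log(value) ~ concentration, data = data)
  start <- list(y0 = exp(stats::coef(init)[[1L]]),
                k_rate = stats::coef(init)[[2L]])
  sse0 <- sum((data$value - start$y0 * exp(start$k_rate * data$concentration))^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(value ~ y0 * exp(k_rate * concentration),
                      data = data, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      # the log-linear init already interpolates the data exactly (e.g. a
      # constant series): the nls gradient is singular at the solution
      if (sse0 <= 1e-20 * max(1, sum(data$value^2))) return(NULL)
      stop_fit_failure("expgrowth fit failed: ", conditionMessage(e))
    })
  if (is.null(fit))
    return(new_viscosity_fit("expgrowth",
                             expgrowth_params(start$y0, start$k_rate),
                             sse0, matrix(0, 2L, 2L), nrow(data), data))
  cf <- stats::coef(fit)
  new_viscosity_fit("expgrowth",
                    expgrowth_params(cf[["y0"]], cf[["k_rate"]]),
                    sum(stats::residuals(fit)^2), quiet_vcov(fit),
                    nrow(data), data)
}

#' Fit the Tomar log-linear viscosity model
#'
#' Ordinary least squares of `ln(eta/eta0)` on concentration: the intercept is
#' `ln A` and the slope is `B`. Exact (no iteration) because the model is
#' linear after the log transform.
#'
#' @param data A [concentration_series()] with observable `eta`.
#' @param eta0 Buffer viscosity, cP; default 1.13.
#' @return A `viscosity_model_fit` with [tomar_params()].
#' @export
fit_tomar <- function(data, eta0 = 1.13) {
  assert_series(data, "eta", min_points = 2L, what = "viscosity data")
  if (length(unique(data$concentration)) < 2L)
    stop_degenerate("need at least two distinct concentrations")
  if (any(data$value <= 0)) stop_domain("viscosities must be positive")
  y <- log(data$value / eta0)
  fit <- stats::lm(y ~ concentration, data = data)
  cf <- stats::coef(fit)
  params <- tomar_params(cf[[1L]], cf[[2L]], eta0 = eta0)
  pred <- eval_viscosity_model("tomar", params, data$concentration)
  new_viscosity_fit("tomar", params, sum((data$value - pred)^2),
                    quiet_vcov(fit), nrow(data), data)
}

# SSE of the Ross-Minton model at theta = ([eta] mL/g, k, v); Inf when the
# denominator closes on the data span (infeasible crowding).
rm_sse <- function(theta, conc, eta, eta0) {
  iv <- theta[1L] / 1000
  denom <- 1 - (theta[2L] / theta[3L]) * iv * conc
  if (any(denom <= 1e-9)) return(Inf)
  sum((eta - eta0 * exp(iv * conc / denom))^2)
}

#' Fit the modified Ross-Minton viscosity model
#'
#' Minimizes the sum of squared viscosity errors of
#' `eta = eta0 * exp([eta] c / (1 - (k/v) [eta] c))` over intrinsic viscosity,
#' crowding factor and Simha shape parameter, within a bounds box, using
#' box-constrained quasi-Newton descent from a 3 x 3 x 3 multistart grid.
#' Starts whose optimum closes the denominator on the data span are rejected;
#' the best feasible local optimum is returned.
#'
#' Note on identifiability: the model depends on the crowding factor and the
#' Simha shape parameter only through their ratio `k/v`, so `k` and `v` are
#' not separately determined by viscosity data alone; the fitted `k/v` ratio
#' and the intrinsic viscosity are the reproducible quantities.
#'
#' @param data A [concentration_series()] with observable `eta`, >= 4 points.
#' @param eta0 Buffer viscosity, cP; default 1.13.
#' @param bounds List with `lower` and `upper` length-3 vectors for
#'   (`eta_intrinsic` mL/g, `k_crowding`, `v_shape`).
#' @return A `viscosity_model_fit` with [rossminton_params()]; the covariance
#'   is the Gauss-Newton approximation `sigma^2 (J'J)^{-1}` from a numerical
#'   Jacobian at the optimum.
#' @export
fit_rossminton <- function(data, eta0 = 1.13,
                           bounds = list(lower = c(1, 0.01, 0.05),
                                         upper = c(60, 5, 5))) {
  assert_series(data, "eta", min_points = 4L, what = "viscosity data")
  if (any(data$value <= 0)) stop_domain("viscosities must be positive")
  conc <- data$concentration
  eta <- data$value
  lo <- bounds$lower
  hi <- bounds$upper
  starts <- as.matrix(expand.grid(
    seq(lo[1L] + 0.05 * (hi[1L] - lo[1L]), hi[1L] - 0.05 * (hi[1L] - lo[1L]), length.out = 3),
    seq(lo[2L] + 0.05 * (hi[2L] - lo[2L]), hi[2L] - 0.05 * (hi[2L] - lo[2L]), length.out = 3),
    seq(lo[3L] + 0.05 * (hi[3L] - lo[3L]), hi[3L] - 0.05 * (hi[3L] - lo[3L]), length.out = 3)))
  dimnames(starts) <- NULL
  # data-driven start from the exact linearization of the model:
  # 1 / ln(eta/eta0) = 1/([eta] c) - k/v, so regressing 1/y on 1/c gives
  # [eta] = 1/slope and k/v = -intercept (v pinned at 1 for the start)
  pos <- data$value > eta0 & conc > 0
  if (sum(pos) >= 2L) {
    y <- log(data$value[pos] / eta0)
    cf <- tryCatch(stats::coef(stats::lm(I(1 / y) ~ I(1 / conc[pos]))),
                   error = function(e) NULL)
    if (!is.null(cf) && is.finite(cf[[2L]]) && cf[[2L]] > 0) {
      iv0 <- min(max(1000 / cf[[2L]], lo[1L]), hi[1L])   # mL/mg -> mL/g
      q0 <- min(max(-cf[[1L]], lo[2L] / hi[3L]), hi[2L] / lo[3L])
      v0 <- min(max(1, lo[3L]), hi[3L])
      k0 <- min(max(q0 * v0, lo[2L]), hi[2L])
      starts <- rbind(c(iv0, k0, v0), starts)
    }
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- starts[i, ]
    if (!is.finite(rm_sse(th0, conc, eta, eta0))) next
    opt <- tryCatch(
      stats::optim(th0, rm_sse, conc = conc, eta = eta, eta0 = eta0,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop_fit_failure("all Ross-Minton multistart points were infeasible")
  theta <- unname(best$par)
  # Gauss-Newton covariance from a central-difference Jacobian of predictions
  predict_rm <- function(th)
    eval_viscosity_model("rossminton",
                         list(eta_intrinsic = th[1L], k_crowding = th[2L],
                              v_shape = th[3L], eta0 = eta0), conc)
  J <- vapply(seq_along(theta), function(j) {
    h <- max(1e-6, 1e-6 * abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (predict_rm(tp) - predict_rm(tm)) / (2 * h)
  }, numeric(length(conc)))
  dof <- max(1L, length(conc) - 3L)
  sigma2 <- best$value / dof
  covariance <- tryCatch(sigma2 * solve(crossprod(J)),
                         error = function(e) matrix(NA_real_, 3, 3))
  new_viscosity_fit("rossminton",
                    rossminton_params(theta[1L], theta[2L], theta[3L], eta0 = eta0),
                    best$value, covariance, nrow(data), data)
}

#' Interpolate a fitted viscosity model at a target concentration
#'
#' Evaluates the fitted model's closed form at `c` (e.g. the 180 mg/mL
#' formulation target). Concentrations beyond 1.25 x the maximum fitted
#' concentration are extrapolations and trigger a warning.
#'
#' @param fit A `viscosity_model_fit`.
#' @param c Concentration, mg/mL.
#' @return Predicted viscosity, cP.
#' @export
interpolate_viscosity <- function(fit, c) {
  if (!inherits(fit, "viscosity_model_fit"))
    stop_invalid("fit must be a viscosity_model_fit")
  if (any(c < 0)) stop_invalid("concentration must be nonnegative")
  if (any(c > 1.25 * fit$c_max))
    warning(sprintf("extrapolating beyond 1.25 x max fitted concentration (%.3g mg/mL)",
                    fit$c_max), call. = FALSE)
  eval_viscosity_model(fit$model, fit$params, c)
}

#' @export
predict.viscosity_model_fit <- function(object, newdata, ...) {
  interpolate_viscosity(object, newdata)
}

#' Relative, specific and reduced viscosities
#'
#' Computes `eta_rel = eta/eta0`, `eta_sp = eta_rel - 1` and
#' `eta_red = eta_sp / c` with the concentration converted from mg/mL to g/mL,
#' so the reduced viscosity is in mL/g (the unit in which intrinsic viscosity
#' is reported).
#'
#' @param data A [concentration_series()] with observable `eta`, strictly
#'   positive concentrations.
#' @param eta0 Buffer viscosity, cP.
#' @return A [concentration_series()] with observable `eta_red` (mL/g).
#' @export
reduced_viscosities <- function(data, eta0 = 1.13) {
  assert_series(data, "eta", min_points = 1L, what = "viscosity data")
  if (eta0 <= 0) stop_domain("eta0 must be positive")
  if (any(data$value <= 0)) stop_domain("viscosities must be positive")
  if (any(data$concentration == 0))
    stop_domain("reduced viscosity undefined at zero concentration")
  eta_red <- (data$value / eta0 - 1) / (data$concentration / 1000)
  concentration_series(data$concentration, eta_red, "eta_red")
}

#' Intrinsic viscosity and Huggins coefficient
#'
#' Ordinary least squares of the dilute-regime Huggins relation
#' `eta_red = [eta] + kH [eta]^2 c` (c in g/mL): the intercept estimates the
#' intrinsic viscosity `[eta]` (mL/g) and the slope `x = kH [eta]^2`, from
#' which `kH = x / [eta]^2`. The uncertainty of kH is propagated to first
#' order (delta method) from the full OLS coefficient covariance:
#' `Var(kH) = g' V g` with gradient `g = (-2x/[eta]^3, 1/[eta]^2)` and `V` the
#' intercept/slope covariance matrix. The covariance cross-term matters: the
#' intercept and slope of a positive-concentration design are strongly
#' anticorrelated, and dropping it understates the uncertainty. At zero slope
#' the formula reduces to `sigma_x / [eta]^2`.
#'
#' @param red A [concentration_series()] with observable `eta_red`, >= 3
#'   points at strictly positive concentrations.
#' @return A `huggins_result` list: `eta_intrinsic`, `sigma_eta`, `slope_x`,
#'   `sigma_x`, `k_huggins`, `sigma_kh`, `r_squared`, `n`.
#' @export
fit_huggins <- function(red) {
  assert_series(red, "eta_red", min_points = 3L, what = "reduced-viscosity data")
  if (any(red$concentration <= 0))
    stop_invalid("concentrations must be strictly positive")
  c_g_ml <- red$concentration / 1000
  fit <- stats::lm(red$value ~ c_g_ml)
  cf <- stats::coef(fit)
  se <- sqrt(diag(quiet_vcov(fit)))
  eta_i <- cf[[1L]]
  x <- cf[[2L]]
  if (eta_i <= 0)
    stop_degenerate("nonpositive intrinsic-viscosity intercept; kH undefined")
  kh <- x / eta_i^2
  g <- c(-2 * x / eta_i^3, 1 / eta_i^2)
  sigma_kh <- sqrt(drop(t(g) %*% quiet_vcov(fit) %*% g))
  structure(list(eta_intrinsic = eta_i, sigma_eta = se[[1L]],
                 slope_x = x, sigma_x = se[[2L]],
                 k_huggins = kh, sigma_kh = sigma_kh,
                 r_squared = r_squared_lm(fit), n = nrow(red)),
            class = "huggins_result")
}

#' @export
print.huggins_result <- function(x, ...) {
  cat(sprintf("<huggins_result: [eta] = %.3f (+/- %.3f) mL/g, kH = %.3f (+/- %.3f), n = %d>\n",
              x$eta_intrinsic, x$sigma_eta, x$k_huggins, x$sigma_kh, x$n))
  invisible(x)
}

#' Classify solvent quality from the Huggins coefficient
#'
#' Huggins coefficients above 0.5 are read as "poorer solvents" whose solution
#' viscosity is more sensitive to protein-protein interactions.
#'
#' @param res A `huggins_result` from [fit_huggins()].
#' @param threshold Strict cutoff; default 0.5.
#' @return `"poor_solvent"` if `kH > threshold`, else `"good_solvent"`.
#' @export
classify_solvent_quality <- function(res, threshold = 0.5) {
  if (!inherits(res, "huggins_result"))
    stop_invalid("res must be a huggins_result")
  if (res$k_huggins > threshold) "poor_solvent" else "good_solvent"
}
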