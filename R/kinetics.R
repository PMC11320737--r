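#' Equilibrium dissociation constant from 1:1 rate constants
#'
#' `KD = kd / ka`, returned in nM.
#'
#' @param ka Association rate constant, 1/(M*s); positive.
#' @param kd Dissociation rate constant, 1/s; positive.
#' @return KD in nM.
#' @examples
#' kd_from_rates(3.84e5, 10.27e-4)   # ~2.67 nM
#' @export
kd_from_rates <- function(ka, kd) {
  if (any(ka <= 0) || any(kd <= 0))
    stop_invalid("rate constants must be positive")
  kd / ka * 1e9
}

# 1:1 Langmuir prediction; C is the per-row analyte concentration vector.
langmuir_response <- function(time, phase, C, ka, kd, rmax, t_assoc) {
  KD <- kd / ka
  plateau <- rmax * C / (C + KD)
  a <- phase == "association"
  r <- numeric(length(time))
  r[a] <- plateau[a] * (1 - exp(-(ka * C[a] + kd) * time[a]))
  r_end <- plateau[!a] * (1 - exp(-(ka * C[!a] + kd) * t_assoc))
  r[!a] <- r_end * exp(-kd * (time[!a] - t_assoc))
  r
}

#' Global 1:1 Langmuir fit of SPR sensorgrams
#'
#' Fits the 1:1 binding model globally across analyte concentrations, sharing
#' ka, kd and Rmax: association
#' `R(t) = Rmax C/(C + KD) (1 - exp(-(ka C + kd) t))` and exponential
#' dissociation from the association endpoint. Optimization is
#' Levenberg-Marquardt on the stacked residuals in log-parameter space
#' (which enforces positivity). The goodness of fit is
#' `chi2 = sum(resid^2) / (n_points - 3)`, the per-point DOF-corrected
#' convention of SPR evaluation software.
#'
#' @param sensorgrams Data.frame from [make_sensorgram()] or instrument
#'   export, with columns `time`, `response`, `conc`, `phase` and either an
#'   attribute `t_assoc` or a `t_assoc` argument.
#' @param t_assoc Association phase end time, s; default from the attribute.
#' @param start Optional named list of starting values `ka`, `kd`, `rmax`.
#' @return A `kinetics_fit` list: `ka`, `kd`, `KD` (= kd/ka, M), `KD_nM`,
#'   `rmax`, `chi2`, `n`.
#' @export
fit_langmuir <- function(sensorgrams, t_assoc = attr(sensorgrams, "t_assoc"),
                         start = NULL) {
  need <- c("time", "response", "conc", "phase")
  if (!is.data.frame(sensorgrams) || !all(need %in% names(sensorgrams)))
    stop_invalid("sensorgrams must have columns time, response, conc, phase")
  concs <- unique(sensorgrams$conc)
  if (length(concs) < 2L)
    stop_invalid("need at least two analyte concentrations for a global fit")
  if (!all(c("association", "dissociation") %in% sensorgrams$phase))
    stop_invalid("both association and dissociation phases are required")
  if (is.null(t_assoc))
    t_assoc <- max(sensorgrams$time[sensorgrams$phase == "association"])
  resid_fn <- function(logp) {
    ka <- exp(logp[1L]); kd <- exp(logp[2L]); rmax <- exp(logp[3L])
    pred <- langmuir_response(sensorgrams$time, sensorgrams$phase,
                              sensorgrams$conc, ka, kd, rmax, t_assoc)
    sensorgrams$response - pred
  }
  starts <- if (!is.null(start)) list(unlist(start)) else {
    # kd from a log-linear fit of the highest-concentration dissociation
    # tail; ka multistarted over KD guesses around the concentration scale
    top <- sensorgrams[sensorgrams$conc == max(concs) &
                         sensorgrams$phase == "dissociation", ]
    top <- top[top$response > 1e-6 * max(abs(top$response), 1e-12), ]
    kd0 <- if (nrow(top) >= 3L) {
      sl <- stats::coef(stats::lm(log(top$response) ~ top$time))[[2L]]
      max(1e-7, -sl)
    } else 1e-3
    rmax0 <- max(sensorgrams$response) * 1.2
    lapply(stats::median(concs) * c(0.1, 1, 10),
           function(KD0) c(ka = kd0 / KD0, kd = kd0, rmax = rmax0))
  }
  out <- NULL
  for (s0 in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(par = log(s0), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(cand) || cand$info < 1L || cand$info > 4L) next
    if (is.null(out) || sum(cand$fvec^2) < sum(out$fvec^2)) out <- cand
  }
  if (is.null(out))
    stop_fit_failure("Langmuir fit did not converge from any start")
  p <- exp(out$par)
  n <- nrow(sensorgrams)
  structure(list(ka = p[[1L]], kd = p[[2L]], KD = p[[2L]] / p[[1L]],
                 KD_nM = kd_from_rates(p[[1L]], p[[2L]]),
                 rmax = p[[3L]],
                 chi2 = sum(out$fvec^2) / (n - 3L), n = n),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit: ka = %.3g 1/(M.s), kd = %.3g 1/s, KD = %.3g nM, Rmax = %.2f RU, chi2 = %.3g>\n",
              x$ka, x$kd, x$KD_nM, x$rmax, x$chi2))
  invisible(x)
}
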