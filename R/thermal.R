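#' DSF thermogram container
#'
#' A gridded differential scanning fluorimetry trace: the 350/330 nm intrinsic
#' fluorescence intensity ratio against temperature, with an optional static
#' scattering trace for aggregation-onset detection.
#'
#' @param temperature Strictly increasing temperature grid, deg C.
#' @param ratio 350/330 nm intensity ratio, same length.
#' @param scattering Optional scattering trace, same length.
#' @return A `thermogram` object.
#' @export
thermogram <- function(temperature, ratio, scattering = NULL) {
  temperature <- as.numeric(temperature)
  ratio <- as.numeric(ratio)
  if (is.unsorted(temperature, strictly = TRUE))
    stop_invalid("temperature grid must be strictly increasing")
  if (length(ratio) != length(temperature))
    stop_invalid("ratio and temperature must have equal length")
  if (!is.null(scattering) && length(scattering) != length(temperature))
    stop_invalid("scattering and temperature must have equal length")
  structure(list(temperature = temperature, ratio = ratio,
                 scattering = scattering),
            class = "thermogram")
}

#' Read a thermogram from CSV
#'
#' Expects columns `temperature_C, ratio_350_330` and optionally `scattering`.
#'
#' @param path CSV file path.
#' @return A [thermogram()].
#' @export
read_thermogram <- function(path) {
  df <- utils::read.csv(path)
  sc <- if ("scattering" %in% names(df)) df$scattering else NULL
  thermogram(df[[1L]], df[[2L]], sc)
}

# Savitzky-Golay first derivative (per deg C). The m = 1 filter differentiates
# the local polynomial itself, which is far less noise-amplifying than
# differencing a smoothed trace. Requires a (near-)uniform grid, which DSF
# ramps provide.
smoothed_derivative <- function(x, y, window) {
  if (window %% 2L == 0L) stop_invalid("smoothing window must be odd")
  n <- length(y)
  window <- min(window, if (n %% 2L == 1L) n else n - 1L)
  step <- mean(diff(x))
  if (max(abs(diff(x) - step)) > 0.01 * step)
    stop_invalid("temperature grid must be uniform")
  p <- min(2L, window - 1L)      # local quadratic: best noise/bias trade-off
  if (window >= 5L)
    signal::sgolayfilt(y, p = p, n = window, m = 1L, ts = step)
  else c(diff(y) / diff(x), (y[n] - y[n - 1L]) / (x[n] - x[n - 1L]))
}

# Topographic prominence of an interior local maximum: height above the key
# saddle, i.e. the highest of the lowest points crossed on the way to higher
# terrain on either side (global minimum when no higher terrain exists).
peak_prominence <- function(v, i) {
  n <- length(v)
  key <- -Inf
  if (i > 1L) {
    higher <- which(v[seq_len(i - 1L)] > v[i])
    if (length(higher)) key <- max(key, min(v[max(higher):i]))
  }
  if (i < n) {
    higher <- which(v[(i + 1L):n] > v[i]) + i
    if (length(higher)) key <- max(key, min(v[i:min(higher)]))
  }
  if (!is.finite(key)) key <- min(v)
  v[i] - key
}

# Indices of interior local maxima whose height AND prominence reach `floor`
# (noise bumps riding a transition flank have height but no prominence;
# bumps on the flat baseline have prominence but no height), consolidated so
# that no two retained peaks are closer than `min_sep` grid indices (the
# larger derivative wins).
local_maxima <- function(v, floor, min_sep = 1L) {
  n <- length(v)
  idx <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
  idx <- idx[v[idx] >= floor]
  idx <- idx[vapply(idx, function(i) peak_prominence(v, i), numeric(1)) >= floor]
  if (length(idx) <= 1L || min_sep <= 1L) return(idx)
  keep <- integer(0)
  for (i in idx[order(-v[idx])]) {
    if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Detect unfolding transitions in a DSF thermogram
#'
#' Smooths the 350/330 ratio with a local-polynomial (Savitzky-Golay) filter,
#' takes a centered-difference first derivative, and reports every local
#' derivative maximum above `min_prominence` x the global derivative maximum
#' as a transition midpoint (Tm1, Tm2, ... in temperature order). The
#' unfolding onset is the first temperature at which the smoothed derivative
#' exceeds `onset_fraction` of the first peak's height. When a scattering
#' trace is present, the aggregation onset Tagg is the argmax of its smoothed
#' first derivative.
#'
#' @param tg A [thermogram()] with >= 20 grid points spanning >= 20 deg C.
#' @param smooth_window Odd Savitzky-Golay window length in points; the
#'   default (NULL) spans about 3.5 deg C of the ramp, well under the
#'   10-15 deg C spacing of antibody domain transitions but wide enough to
#'   suppress grid-scale noise in the derivative.
#' @param min_prominence Peak floor as a fraction of the maximum derivative;
#'   default 0.1.
#' @param onset_fraction Fraction of the first peak height defining Tonset;
#'   default 0.1.
#' @param min_separation Minimum temperature separation between reported
#'   transitions, deg C; closer derivative maxima are merged into the larger
#'   one. Default 3 (distinct antibody domains unfold further apart).
#' @return An `unfolding_result` list: `t_onset`, `tm` (ordered vector),
#'   `t_agg` (or NA), and the smoothed `derivative` trace for audit.
#' @export
find_transitions <- function(tg, smooth_window = NULL, min_prominence = 0.1,
                             onset_fraction = 0.1, min_separation = 3) {
  if (!inherits(tg, "thermogram")) stop_invalid("tg must be a thermogram")
  if (length(tg$temperature) < 20L)
    stop_invalid("need at least 20 grid points")
  if (diff(range(tg$temperature)) < 20)
    stop_invalid("temperature grid must span at least 20 deg C")
  step <- mean(diff(tg$temperature))
  if (is.null(smooth_window)) {
    smooth_window <- max(5L, as.integer(ceiling(3.5 / step)))
    if (smooth_window %% 2L == 0L) smooth_window <- smooth_window + 1L
  }
  dv <- smoothed_derivative(tg$temperature, tg$ratio, smooth_window)
  # a trace whose derivative never rises meaningfully above numerical jitter
  # has no transition
  jitter_floor <- 1e-8 * (max(abs(tg$ratio)) + 1) / step
  floor_v <- max(min_prominence * max(dv), jitter_floor)
  peaks <- local_maxima(dv, floor_v,
                        min_sep = max(1L, ceiling(min_separation / step)))
  if (length(peaks) == 0L || max(dv) <= jitter_floor)
    stop(errorCondition("no transition detected above the prominence threshold",
                        class = c("mabdev_no_transition", "error")))
  tm <- tg$temperature[peaks]
  onset_level <- onset_fraction * dv[peaks[1L]]
  onset_idx <- which(dv >= onset_level)[1L]
  t_agg <- NA_real_
  if (!is.null(tg$scattering)) {
    sdv <- smoothed_derivative(tg$temperature, tg$scattering, smooth_window)
    t_agg <- tg$temperature[which.max(sdv)]
  }
  structure(list(t_onset = tg$temperature[onset_idx], tm = tm, t_agg = t_agg,
                 derivative = dv),
            class = "unfolding_result")
}

#' @export
print.unfolding_result <- function(x, ...) {
  cat(sprintf("<unfolding_result: Tonset = %.1f C, Tm = %s C, Tagg = %s>\n",
              x$t_onset, paste(sprintf("%.1f", x$tm), collapse = "/"),
              if (is.na(x$t_agg)) "NA" else sprintf("%.1f C", x$t_agg)))
  invisible(x)
}
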