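#' aSEC purity stability flags
#'
#' Flags physical-stability failures in an analytical size-exclusion purity
#' time series. Per row: `monomer_fail` when the monomer percentage drops
#' below `monomer_min` (strict, default 95%), and `hmws_fail` when the
#' high-molecular-weight-species percentage exceeds its day-0 value for that
#' condition by more than `hmws_delta_max` points (strict, default 2). An
#' `absolute` mode flags on the HMwS level itself rather than the change from
#' baseline.
#'
#' @param t Purity table: data.frame with columns `day`, `condition`,
#'   `pct_monomer`, `pct_hmws`, `pct_lmws` (as from [make_purity_table()]).
#'   Every condition must include a day-0 baseline row.
#' @param monomer_min Minimum acceptable monomer percentage; default 95.
#' @param hmws_delta_max Maximum acceptable HMwS increase from day 0 (or
#'   absolute HMwS level in `"absolute"` mode), percentage points; default 2.
#' @param hmws_mode `"delta"` (change from day 0, the default) or
#'   `"absolute"`.
#' @return A `stability_flags` object: the input rows plus `hmws_delta`,
#'   `monomer_fail`, `hmws_fail`, `any_fail`, with a `first_failures`
#'   attribute giving the earliest failing day per condition (NA when a
#'   condition never fails).
#' @export
stability_flags <- function(t, monomer_min = 95, hmws_delta_max = 2,
                            hmws_mode = c("delta", "absolute")) {
  hmws_mode <- match.arg(hmws_mode)
  need <- c("day", "condition", "pct_monomer", "pct_hmws", "pct_lmws")
  if (!is.data.frame(t) || !all(need %in% names(t)))
    stop_invalid("purity table must have columns ", paste(need, collapse = ", "))
  sums <- t$pct_monomer + t$pct_hmws + t$pct_lmws
  if (any(abs(sums - 100) > 0.01))
    stop_invalid("purity fractions must sum to 100 within 0.01 in every row")
  conds <- unique(t$condition)
  baseline <- vapply(conds, function(cn) {
    i <- which(t$condition == cn & t$day == 0)
    if (length(i) == 0L)
      stop_invalid("missing day-0 baseline for condition '", cn, "'")
    t$pct_hmws[i[1L]]
  }, numeric(1))
  out <- t
  out$hmws_delta <- t$pct_hmws - baseline[match(t$condition, conds)]
  out$monomer_fail <- t$pct_monomer < monomer_min
  out$hmws_fail <- if (hmws_mode == "delta")
    out$hmws_delta > hmws_delta_max else t$pct_hmws > hmws_delta_max
  out$any_fail <- out$monomer_fail | out$hmws_fail
  first_failures <- vapply(conds, function(cn) {
    d <- out$day[out$condition == cn & out$any_fail]
    if (length(d) == 0L) NA_real_ else min(d)
  }, numeric(1))
  structure(out, first_failures = stats::setNames(first_failures, conds),
            thresholds = list(monomer_min = monomer_min,
                              hmws_delta_max = hmws_delta_max,
                              hmws_mode = hmws_mode),
            class = c("stability_flags", "data.frame"))
}
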