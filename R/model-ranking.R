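#' Homology-model geometric-score table
#'
#' One row per candidate homology model, one column per geometric quality
#' metric, plus a packing score and the heavy-atom RMSD to the average
#' position of the intermediate models. Each metric declares an orientation
#' (`higher_is_better`); the packing score is always treated as
#' higher-is-better, so its normalization is inverted relative to
#' lower-is-better geometry checks.
#'
#' @param df Data.frame with columns `model_id`, one column per metric,
#'   `packing`, `rmsd_to_average`. No missing values; >= 2 rows.
#' @param higher_is_better Named logical, one entry per metric column
#'   (excluding `packing` and `rmsd_to_average`); default all FALSE
#'   (outlier-count-style metrics where lower is better).
#' @return A `score_table` object.
#' @export
score_table <- function(df, higher_is_better = NULL) {
  need <- c("model_id", "packing", "rmsd_to_average")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop_invalid("score table needs columns model_id, packing, rmsd_to_average")
  if (nrow(df) < 2L) stop_invalid("need at least two candidate models")
  if (anyNA(df)) stop_invalid("score table must have no missing values")
  if (anyDuplicated(df$model_id)) stop_invalid("model_id values must be unique")
  metrics <- setdiff(names(df), need)
  if (is.null(higher_is_better))
    higher_is_better <- stats::setNames(rep(FALSE, length(metrics)), metrics)
  if (!all(metrics %in% names(higher_is_better)))
    stop_invalid("higher_is_better must name every metric column")
  structure(df, metrics = metrics,
            higher_is_better = higher_is_better[metrics],
            class = c("score_table", "data.frame"))
}

# Min-max normalize one metric to [0, 1] with 0 = best. A constant metric is
# uninformative and maps to all zeros.
ndv_one <- function(x, higher_is_better) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep(0, length(x)))
  if (higher_is_better) (rng[2L] - x) / (rng[2L] - rng[1L])
  else (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Normalize geometric quality scores across candidate models
#'
#' Min-max normalizes each geometric metric across the candidate models onto
#' [0, 1] with 0 = best after orientation alignment (NDV, the normalized
#' quality value). The packing score uses the inverted normalization (higher
#' packing is better, so the flip runs opposite to the lower-is-better
#' geometry checks). Constant metrics are mapped to all zeros. The composite
#' is the unweighted mean NDV; ranks are 1 = best.
#'
#' @param t A [score_table()].
#' @param weights Optional named nonnegative weights per metric (including
#'   `packing`); default equal weights.
#' @return An `ndv_table` data.frame: `model_id`, one NDV column per metric,
#'   `packing`, `composite`, `rank`.
#' @export
normalize_scores <- function(t, weights = NULL) {
  if (!inherits(t, "score_table")) stop_invalid("t must be a score_table")
  metrics <- attr(t, "metrics")
  hib <- attr(t, "higher_is_better")
  out <- data.frame(model_id = t$model_id)
  for (m in metrics) out[[m]] <- ndv_one(t[[m]], hib[[m]])
  out$packing <- ndv_one(t$packing, higher_is_better = TRUE)
  cols <- c(metrics, "packing")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(cols)), cols)
  if (!all(cols %in% names(weights)) || any(weights < 0))
    stop_invalid("weights must be nonnegative and name every metric")
  w <- weights[cols] / sum(weights[cols])
  out$composite <- as.numeric(as.matrix(out[cols]) %*% w)
  out$rank <- rank(out$composite, ties.method = "min")
  structure(out, class = c("ndv_table", "data.frame"))
}

#' Select the best candidate homology model
#'
#' Returns the model with the lowest composite NDV; composite ties are broken
#' by the lowest heavy-atom RMSD to the average intermediate-model position,
#' and any remaining ties by lexical `model_id` order, so selection is
#' deterministic and invariant to row order.
#'
#' @param ndv An `ndv_table` from [normalize_scores()].
#' @param t The matching [score_table()] (source of `rmsd_to_average`).
#' @return The selected `model_id` (character scalar).
#' @export
select_model <- function(ndv, t) {
  if (!inherits(ndv, "ndv_table")) stop_invalid("ndv must be an ndv_table")
  if (!inherits(t, "score_table")) stop_invalid("t must be a score_table")
  if (!setequal(ndv$model_id, t$model_id))
    stop_invalid("ndv and score tables cover different models")
  rmsd <- t$rmsd_to_average[match(ndv$model_id, t$model_id)]
  ord <- order(ndv$composite, rmsd, ndv$model_id)
  ndv$model_id[ord[1L]]
}
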