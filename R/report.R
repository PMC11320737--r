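#' Default developability thresholds
#'
#' The decision thresholds used across the pipeline, in one place: the kD
#' attraction cutoff (-15 mL/g), the minimum monomeric purity (95%), the
#' maximum HMwS increase from day 0 (2 points), the AC-SINS negative-control
#' QC limit (535 nm), the Huggins solvent-quality cutoff (0.5), the
#' viscometer pressure-fit R^2 cutoff (0.998), and the buffer viscosities
#' (1.13 cP for viscometry fits, 1.26 cP for the DLS dispersant).
#'
#' @return A named list of thresholds.
#' @export
dev_thresholds <- function() {
  list(
    kd_ml_g = -15,
    monomer_min_pct = 95,
    hmws_delta_max_pct = 2,
    acsins_qc_limit_nm = 535,
    huggins_kh = 0.5,
    pressure_fit_r2_min = 0.998,
    eta0_cP = 1.13,
    dls_dispersant_cP = 1.26,
    temperature_K = 298
  )
}

#' Read a thresholds/config YAML file
#'
#' Reads a YAML configuration and merges it over [dev_thresholds()]; unknown
#' keys are kept (module-specific blocks are allowed).
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_invalid("config YAML must be a mapping")
  utils::modifyList(dev_thresholds(), cfg)
}

#' Assemble a per-molecule developability scorecard
#'
#' Aggregates per-assay results into one record with the derived
#' pass/flag decisions, each flag recording the threshold and direction used.
#' Assays not supplied are marked absent, never imputed. Entries must be
#' uniquely named.
#'
#' @param molecule Molecule label.
#' @param results Named list; recognised entries are `kd_fit` (a [fit_kd()]
#'   result), `huggins` (a [fit_huggins()] result), `red_shift` (a
#'   [red_shift()] result), `kinetics` (a [fit_langmuir()] result),
#'   `unfolding` (a [find_transitions()] result), `stability` (a
#'   [stability_flags()] table), and `viscosity` (named list of
#'   `viscosity_model_fit` objects and/or interpolations). At least one entry
#'   is required.
#' @param thresholds Threshold list; default [dev_thresholds()].
#' @return A `scorecard` list with elements `molecule`, `entries`, `flags`.
#' @export
build_scorecard <- function(molecule, results, thresholds = dev_thresholds()) {
  if (!is.list(results) || length(results) == 0L)
    stop_invalid("results must be a nonempty named list")
  if (is.null(names(results)) || any(names(results) == "") ||
      anyDuplicated(names(results)))
    stop_invalid("results entries must be uniquely named")
  flags <- list()
  if (!is.null(results$kd_fit))
    flags$kd_attractive <- list(
      value = results$kd_fit$kd, threshold = thresholds$kd_ml_g,
      direction = "<",
      flagged = classify_kd(results$kd_fit, thresholds$kd_ml_g) == "attractive_flag")
  if (!is.null(results$huggins))
    flags$poor_solvent <- list(
      value = results$huggins$k_huggins, threshold = thresholds$huggins_kh,
      direction = ">",
      flagged = classify_solvent_quality(results$huggins,
                                         thresholds$huggins_kh) == "poor_solvent")
  if (!is.null(results$red_shift))
    flags$acsins_qc_fail <- list(
      value = results$red_shift$peak_control,
      threshold = thresholds$acsins_qc_limit_nm, direction = ">=",
      flagged = !results$red_shift$qc_pass)
  if (!is.null(results$stability)) {
    ff <- attr(results$stability, "first_failures")
    flags$stability_fail <- list(
      value = unname(ff), threshold = thresholds$monomer_min_pct,
      direction = "<", flagged = any(!is.na(ff)))
  }
  structure(list(molecule = molecule, entries = results, flags = flags),
            class = "scorecard")
}

#' @export
print.scorecard <- function(x, ...) {
  cat(sprintf("<scorecard: %s; assays: %s>\n", x$molecule,
              paste(names(x$entries), collapse = ", ")))
  for (fn in names(x$flags)) {
    f <- x$flags[[fn]]
    cat(sprintf("  %-16s %s (threshold %s %s)\n", fn,
                if (f$flagged) "FLAG" else "pass", f$direction,
                paste(signif(f$threshold, 4), collapse = ",")))
  }
  invisible(x)
}

# Strip non-serializable pieces (flattened for JSON) from a scorecard.
scorecard_to_list <- function(sc) {
  entries <- lapply(sc$entries, function(e) {
    if (is.data.frame(e)) {
      lapply(as.list(e), unname)
    } else if (is.list(e)) {
      lapply(e, function(v) if (is.numeric(v) || is.character(v) ||
                                is.logical(v)) unname(v) else NULL)
    } else e
  })
  list(molecule = sc$molecule, entries = entries, flags = sc$flags)
}

#' Serialize / restore a scorecard as JSON
#'
#' `write_scorecard()` writes the scorecard to a JSON file;
#' `read_scorecard()` restores it. The write -> read round trip preserves the
#' molecule label, every numeric entry, and every flag decision.
#'
#' @param sc A `scorecard`.
#' @param path JSON file path.
#' @return `write_scorecard()` returns `path` invisibly; `read_scorecard()`
#'   returns the restored list of class `scorecard`.
#' @export
write_scorecard <- function(sc, path) {
  if (!inherits(sc, "scorecard")) stop_invalid("sc must be a scorecard")
  jsonlite::write_json(scorecard_to_list(sc), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scorecard
#' @export
read_scorecard <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "scorecard")
}

#' Pairwise descriptor-measurement correlations
#'
#' Pearson and Spearman correlations between every pair of columns of the
#' combined descriptor and measurement tables, using pairwise-complete
#' observations. Pairs with fewer than three complete observations are
#' undefined and reported as NA (never an error). The matrices are symmetric
#' with unit diagonal.
#'
#' @param descriptors Data.frame of numeric columns (e.g. in-silico
#'   descriptors), one row per molecule/observation.
#' @param measurements Data.frame of numeric columns (measured parameters),
#'   same rows.
#' @return A `correlation_matrix` list: `pearson`, `spearman`, `n` (complete
#'   pairs per cell), `labels`.
#' @export
correlate <- function(descriptors, measurements) {
  x <- cbind(as.data.frame(descriptors), as.data.frame(measurements))
  if (!all(vapply(x, is.numeric, logical(1))))
    stop_invalid("all descriptor and measurement columns must be numeric")
  m <- as.matrix(x)
  p <- ncol(m)
  labels <- colnames(m)
  n_mat <- crossprod(!is.na(m))
  pearson <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                         method = "pearson"))
  spearman <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                          method = "spearman"))
  pearson[n_mat < 3L] <- NA_real_
  spearman[n_mat < 3L] <- NA_real_
  diag(pearson) <- 1
  diag(spearman) <- 1
  structure(list(pearson = pearson, spearman = spearman, n = n_mat,
                 labels = labels),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix: %d variables>\nPearson:\n", ncol(x$pearson)))
  print(round(x$pearson, 3))
  invisible(x)
}
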