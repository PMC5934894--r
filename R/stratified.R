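# Stratified ROC / cutoff / diagnostic-accuracy analysis: per stratum (stage
# group I/II vs III/IV, or TG/TL 1-3) and per PET parameter, an ROC curve
# with AUC and CI, the minimal-distance optimal cutoff, and the 2x2
# diagnostic table at that cutoff.

# Features whose published optimal cutoffs point downward ("<"): low entropy
# and low contrast predict inadequate response, so their ROC polarity is
# inverted (the biomarker is negated internally; cutoffs are reported on the
# original scale with direction "<").
.inverted_features <- c("entropy", "contrast")

#' Stratified ROC and diagnostic-accuracy report
#'
#' @param cohort Data.frame with `response` plus the feature columns (as
#'   produced by [simulate_cohort()], or assembled from [extract_all()]
#'   vectors).
#' @param strata `"stage_groups"` (I/II vs III/IV) or `"tg_tl"` (groups 1-3).
#' @param features Character vector of feature columns to analyze (default:
#'   all of [feature_names()] present in the cohort).
#' @return A `stratified_report`: list with `strata` (labels) and `results`,
#'   a data.frame with one row per stratum x feature (AUC, CI, cutoff,
#'   direction, d, tp/fn/fp/tn, sens/spec/npv/ppv percentages), plus
#'   `accuracy` (the full `diagnostic_accuracy` objects, keyed
#'   "stratum|feature") and `non_evaluable` (strata with one response class).
#' @export
run_stratified_analysis <- function(cohort,
                                    strata = c("stage_groups", "tg_tl"),
                                    features = NULL) {
  strata <- match.arg(strata)
  if (is.null(features)) {
    features <- intersect(feature_names(), names(cohort))
  }
  if (!length(features)) stop("no feature columns found", call. = FALSE)
  if (!"response" %in% names(cohort) || any(is.na(cohort$response))) {
    stop("every patient needs a response for stratified analysis",
         call. = FALSE)
  }
  lab <- if (strata == "stage_groups") {
    ifelse(stage_number(cohort$stage) %in% c("I", "II"), "I/II", "III/IV")
  } else {
    if (any(is.na(cohort$tg_tl))) stop("tg_tl must be assigned", call. = FALSE)
    paste0("TG/TL ", cohort$tg_tl)
  }
  stratum_levels <- if (strata == "stage_groups") c("I/II", "III/IV")
                    else paste0("TG/TL ", 1:3)
  rows <- list()
  accuracy <- list()
  non_evaluable <- character(0)
  for (s in stratum_levels) {
    idx <- lab == s
    resp <- cohort$response[idx]
    if (length(unique(resp)) < 2) {
      non_evaluable <- c(non_evaluable, s)
      next
    }
    for (f in features) {
      vals <- cohort[[f]][idx]
      invert <- f %in% .inverted_features
      v <- if (invert) -vals else vals
      roc <- roc_curve(v, resp)
      oc <- optimal_cutoff(roc)
      pos <- v > oc$cutoff
      is_ir <- resp == "IR"
      tab <- diagnostic_table(tp = sum(pos & is_ir), fn = sum(!pos & is_ir),
                              fp = sum(pos & !is_ir), tn = sum(!pos & !is_ir))
      acc <- diagnostic_accuracy(tab)
      accuracy[[paste(s, f, sep = "|")]] <- acc
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, feature = f, auc = roc$auc,
        auc_lo = roc$auc_ci[1], auc_hi = roc$auc_ci[2],
        cutoff = if (invert) -oc$cutoff else oc$cutoff,
        direction = if (invert) "<" else ">",
        d = oc$d, tp = tab$tp, fn = tab$fn, fp = tab$fp, tn = tab$tn,
        sens_pct = acc$sensitivity$pct, spec_pct = acc$specificity$pct,
        npv_pct = acc$npv$pct, ppv_pct = acc$ppv$pct,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(strata = stratum_levels,
                 results = do.call(rbind, rows),
                 accuracy = accuracy,
                 non_evaluable = non_evaluable),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  cat("<stratified_report>\n")
  print(x$results[, c("stratum", "feature", "auc", "cutoff", "direction",
                      "sens_pct", "spec_pct")], row.names = FALSE)
  if (length(x$non_evaluable)) {
    cat("non-evaluable strata:", paste(x$non_evaluable, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Reference 2x2 tables of the emulated 50-patient cohort

#' Published stratum margins of the emulated reference cohort
#'
#' Stratum sizes and IR counts: stage I/II (n = 27, IR 16), stage III/IV
#' (n = 23, IR 12), TG/TL 1-3 (n = 12/17/21, IR 6/10/12).
#'
#' @return Data.frame with `stratum`, `n_ir`, `n_ar`.
#' @export
reference_stratum_margins <- function() {
  data.frame(
    stratum = c("I/II", "III/IV", "TG/TL 1", "TG/TL 2", "TG/TL 3"),
    n_ir = c(16L, 12L, 6L, 10L, 12L),
    n_ar = c(11L, 11L, 6L, 7L, 9L),
    stringsAsFactors = FALSE)
}

#' Reconstruct a 2x2 table from conditional IR rates
#'
#' Finds the integer table (tp, fn, fp, tn) with `tp + fn = n_ir`,
#' `fp + tn = n_ar` whose IR rate among test-positives,
#' `tp / (tp + fp)`, and among test-negatives, `fn / (fn + tn)`, round
#' (half-up, 1 decimal) to the given percentages. Errors if the solution is
#' not unique.
#'
#' @param n_ir,n_ar Stratum response margins.
#' @param rate_high_pct IR rate among biomarker-high patients, percent.
#' @param rate_low_pct IR rate among biomarker-low patients, percent.
#' @param digits Decimals the printed rates were rounded to (default 1).
#' @return A [diagnostic_table()].
#' @export
reconstruct_table_from_rates <- function(n_ir, n_ar, rate_high_pct,
                                         rate_low_pct, digits = 1) {
  hits <- list()
  for (tp in 0:n_ir) {
    fn <- n_ir - tp
    for (fp in 0:n_ar) {
      tn <- n_ar - fp
      if (tp + fp == 0 || fn + tn == 0) next
      rh <- .round_half_up(100 * tp / (tp + fp), digits)
      rl <- .round_half_up(100 * fn / (fn + tn), digits)
      if (isTRUE(all.equal(rh, rate_high_pct)) &&
          isTRUE(all.equal(rl, rate_low_pct))) {
        hits[[length(hits) + 1L]] <- c(tp, fn, fp, tn)
      }
    }
  }
  if (length(hits) != 1L) {
    stop("2x2 reconstruction not unique: ", length(hits), " solutions",
         call. = FALSE)
  }
  h <- hits[[1]]
  diagnostic_table(tp = h[1], fn = h[2], fp = h[3], tn = h[4])
}

#' Reconstruct a 2x2 table from rounded sensitivity and specificity
#'
#' As [reconstruct_table_from_rates()], but matching whole-percent rounded
#' sensitivity `tp / n_ir` and specificity `tn / n_ar` instead of the
#' conditional IR rates.
#'
#' @param n_ir,n_ar Stratum response margins.
#' @param sens_pct,spec_pct Printed whole-percent sensitivity/specificity.
#' @return A [diagnostic_table()].
#' @export
reconstruct_table_from_sens_spec <- function(n_ir, n_ar, sens_pct, spec_pct) {
  tp <- which(.round_half_up(100 * (0:n_ir) / n_ir) == sens_pct) - 1L
  tn <- which(.round_half_up(100 * (0:n_ar) / n_ar) == spec_pct) - 1L
  if (length(tp) != 1L || length(tn) != 1L) {
    stop("2x2 reconstruction not unique from sens/spec", call. = FALSE)
  }
  diagnostic_table(tp = tp, fn = n_ir - tp, fp = n_ar - tn, tn = tn)
}

#' Reference conditional IR rates at the published MTV cutoffs
#'
#' IR rates among patients above/below the stratum's optimal MTV cutoff in
#' the emulated reference cohort: stage I/II 78.9 vs 12.5% (cutoff 80 ml),
#' stage III/IV 90.0 vs 23.1% (410 ml), TG/TL 1 85.7 vs 0% (80 ml), TG/TL 2
#' 80.0 vs 28.6% (160 ml), TG/TL 3 90.0 vs 27.3% (410 ml).
#'
#' @return Data.frame with `stratum`, `cutoff_ml`, `rate_high_pct`,
#'   `rate_low_pct`.
#' @export
reference_mtv_rates <- function() {
  data.frame(
    stratum = c("I/II", "III/IV", "TG/TL 1", "TG/TL 2", "TG/TL 3"),
    cutoff_ml = c(80, 410, 80, 160, 410),
    rate_high_pct = c(78.9, 90.0, 85.7, 80.0, 90.0),
    rate_low_pct = c(12.5, 23.1, 0.0, 28.6, 27.3),
    stringsAsFactors = FALSE)
}

#' Reference rounded sensitivity/specificity for the ASP parameter
#'
#' Whole-percent sensitivity and specificity of high asphericity toward IR
#' in the emulated reference cohort, per stratum.
#'
#' @return Data.frame with `stratum`, `sens_pct`, `spec_pct`.
#' @export
reference_asp_sens_spec <- function() {
  data.frame(
    stratum = c("I/II", "III/IV", "TG/TL 1", "TG/TL 2", "TG/TL 3"),
    sens_pct = c(81, 83, 83, 80, 58),
    spec_pct = c(55, 64, 67, 43, 78),
    stringsAsFactors = FALSE)
}
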