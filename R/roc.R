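# Empirical ROC analysis. Test-positive means biomarker value > threshold;
# the AUC equals the Mann-Whitney U statistic divided by n1*n2 (ties counted
# one half), and its 95% CI uses the DeLong variance estimator with a normal
# approximation, clipped to [0, 1].

#' Empirical ROC curve with AUC, DeLong CI and candidate cutoffs
#'
#' @param values Numeric biomarker values.
#' @param labels Condition labels: `"IR"` (positive) / `"AR"`, or a logical
#'   vector (`TRUE` = positive).
#' @param conf_level Confidence level for the AUC interval.
#' @return An object of class `roc_result`: `thresholds` (candidate cutoffs:
#'   -Inf and every distinct value), `sens`, `spec`, `auc`, `auc_ci`, `n_pos`,
#'   `n_neg`.
#' @export
roc_curve <- function(values, labels, conf_level = 0.95) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "IR"
  }
  stopifnot(length(values) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("ROC undefined: both classes must be present", call. = FALSE)
  }
  x <- values[labels]      # positives (IR)
  y <- values[!labels]     # negatives (AR)
  n1 <- length(x); n0 <- length(y)

  thresholds <- c(-Inf, sort(unique(values)))
  sens <- vapply(thresholds, function(t) mean(x > t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(y <= t), numeric(1))

  # AUC = P(X > Y) + 0.5 P(X = Y), via midranks
  r <- rank(c(x, y), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong components
  v10 <- vapply(x, function(xi) mean(xi > y) + 0.5 * mean(xi == y), numeric(1))
  v01 <- vapply(y, function(yi) mean(x > yi) + 0.5 * mean(x == yi), numeric(1))
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  if (!is.finite(var_auc)) var_auc <- 0
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * zq * sqrt(var_auc), 0), 1)

  structure(list(thresholds = thresholds, sens = sens, spec = spec,
                 auc = auc, auc_ci = ci, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Optimal cutoff by minimal distance to the (0, 1) corner
#'
#' Returns the threshold minimizing
#' `d = sqrt((1 - sens)^2 + (1 - spec)^2)`; ties are broken toward higher
#' specificity, then toward the higher threshold.
#'
#' @param roc A [roc_curve()] result.
#' @return List with `cutoff`, `d`, `sens`, `spec` at the chosen point.
#' @export
optimal_cutoff <- function(roc) {
  d <- sqrt((1 - roc$sens)^2 + (1 - roc$spec)^2)
  eps <- 1e-12
  best <- which(d <= min(d) + eps)
  if (length(best) > 1) {
    best <- best[order(-roc$spec[best], -roc$thresholds[best])][1]
  }
  list(cutoff = roc$thresholds[best], d = d[best],
       sens = roc$sens[best], spec = roc$spec[best])
}
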