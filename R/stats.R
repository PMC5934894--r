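# Diagnostic-accuracy statistics, Mann-Whitney U, and log-linear association
# for 2x2(x2) contingency tables.

#' 2x2 diagnostic table
#'
#' Orientation: test positive = biomarker above cutoff; condition positive =
#' inadequate response (IR).
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return A `diagnostic_table` list.
#' @export
diagnostic_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("table is empty", call. = FALSE)
  structure(as.list(counts), class = "diagnostic_table")
}

# round half up to `digits`
.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower, upper)
}

#' Diagnostic accuracy with exact binomial confidence intervals
#'
#' Sensitivity, specificity, NPV and PPV with Clopper-Pearson 95% CIs. Point
#' estimates and CI bounds are additionally reported rounded half-up to whole
#' percent (`*_pct` fields), matching clinical reporting; the raw fractions
#' are retained. A metric with a zero denominator is reported as `NA`.
#'
#' @param table A [diagnostic_table()].
#' @param conf_level Confidence level.
#' @return A `diagnostic_accuracy` list: per metric, `estimate` (fraction),
#'   `ci` (fractions), `pct` and `ci_pct` (whole percent).
#' @export
diagnostic_accuracy <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "diagnostic_table"))
  metric <- function(x, n) {
    if (n == 0) {
      return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                  pct = NA_real_, ci_pct = c(NA_real_, NA_real_)))
    }
    ci <- clopper_pearson(x, n, conf_level)
    list(estimate = x / n, ci = ci,
         pct = .round_half_up(100 * x / n),
         ci_pct = .round_half_up(100 * ci))
  }
  out <- list(
    sensitivity = metric(table$tp, table$tp + table$fn),
    specificity = metric(table$tn, table$tn + table$fp),
    ppv = metric(table$tp, table$tp + table$fp),
    npv = metric(table$tn, table$tn + table$fn),
    table = table
  )
  class(out) <- "diagnostic_accuracy"
  out
}

#' @export
print.diagnostic_accuracy <- function(x, ...) {
  fmt <- function(m, name) {
    if (is.na(m$pct)) return(cat(sprintf("  %-12s undefined\n", name)))
    cat(sprintf("  %-12s %3.0f%% (%.0f to %.0f%%)\n", name, m$pct,
                m$ci_pct[1], m$ci_pct[2]))
  }
  cat(sprintf("<diagnostic_accuracy> tp=%d fn=%d fp=%d tn=%d\n",
              x$table$tp, x$table$fn, x$table$fp, x$table$tn))
  fmt(x$sensitivity, "sensitivity"); fmt(x$specificity, "specificity")
  fmt(x$npv, "NPV"); fmt(x$ppv, "PPV")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U with midrank tie handling. The two-sided p-value is computed by exact
#' enumeration of all rank splits when `n1 + n2 <= 12` (p = proportion of
#' splits at least as extreme as observed, measured by `|U - n1 n2 / 2|`),
#' and otherwise by normal approximation with tie correction.
#'
#' @param x,y Numeric samples (both nonempty).
#' @return List with `U` (statistic for sample `x`), `p` (two-sided),
#'   `method`.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be nonempty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= 12) {
    splits <- utils::combn(n1 + n2, n1)
    us <- apply(splits, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = U, p = p, method = method)
}

#' Saturated log-linear association for 2x2 and 2x2x2 tables
#'
#' Fits the saturated log-linear model with effect coding (+1/-1) after
#' adding `delta` to every cell: each interaction parameter is the effect-
#' coded average of log counts, its standard error follows from the delta
#' method, and z = estimate / SE. For a 2x2 table with `delta = 0` the A:B
#' z equals the classical Wald z of the log odds ratio.
#'
#' @param counts 2x2 matrix or 2x2x2 array of non-negative counts. For three
#'   dimensions the factors are A (biomarker high/low), B (stratum), C
#'   (response IR/AR).
#' @param delta Continuity constant added to every cell (default 0.5).
#' @return Data.frame with one row per interaction term: `term`, `estimate`,
#'   `se`, `z`, `p`.
#' @export
loglinear_association <- function(counts, delta = 0.5) {
  d <- dim(counts)
  if (is.null(d) || !length(d) %in% c(2L, 3L) || any(d != 2L)) {
    stop("counts must be a 2x2 matrix or 2x2x2 array", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  n <- counts + delta
  if (any(n <= 0)) stop("counts + delta must be positive", call. = FALSE)
  logn <- log(n)
  ncell <- length(n)
  sgn <- function(k) {
    # effect codes (+1 for level 1, -1 for level 2) along dimension k
    s <- slice.index(n, k)
    ifelse(s == 1L, 1, -1)
  }
  terms <- if (length(d) == 2L) list(`A:B` = sgn(1) * sgn(2))
  else list(`A:B` = sgn(1) * sgn(2), `A:C` = sgn(1) * sgn(3),
            `B:C` = sgn(2) * sgn(3), `A:B:C` = sgn(1) * sgn(2) * sgn(3))
  rows <- lapply(names(terms), function(nm) {
    s <- terms[[nm]]
    est <- sum(s * logn) / ncell
    se <- sqrt(sum(1 / n)) / ncell
    z <- est / se
    data.frame(term = nm, estimate = est, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
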