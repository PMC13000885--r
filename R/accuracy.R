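#' Exact (Clopper–Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact binomial interval:
#' lower = qbeta(a/2; k, n−k+1), upper = qbeta(1−a/2; k+1, n−k), with the
#' conventional 0 and 1 at the k = 0 / k = n boundaries.
#'
#' @param k Number of successes (0 ≤ k ≤ n); vectorised.
#' @param n Number of trials (> 0).
#' @param level Confidence level, default 0.95.
#' @return Data frame with `numerator`, `denominator`, `proportion`,
#'   `ci_low`, `ci_high`.
#' @export
#' @examples
#' exact_binomial_ci(640, 875)   # 73.1% (70.1 to 76.1)
exact_binomial_ci <- function(k, n, level = 0.95) {
  if (any(n <= 0) || any(k < 0) || any(k > n) ||
      any(k != round(k)) || any(n != round(n)))
    stop("need integer counts with 0 <= k <= n, n > 0")
  m <- max(length(k), length(n))
  k <- rep_len(k, m); n <- rep_len(n, m)
  a <- 1 - level
  lo <- ifelse(k == 0, 0, stats::qbeta(a / 2, k, n - k + 1))
  hi <- ifelse(k == n, 1, stats::qbeta(1 - a / 2, k + 1, n - k))
  data.frame(numerator = k, denominator = n, proportion = k / n,
             ci_low = lo, ci_high = hi)
}

#' Cohort agreement with measured GFR slope
#'
#' Proportion of participants whose estimated slope is *not* a large error
#' under the chosen criterion, with an exact binomial confidence interval.
#'
#' @param errors Data frame from [classify_slope_error()] (columns
#'   `large_abs` and, for the percentage criterion, `large_pct`).
#' @param criterion `"abs3"` (within ±3 mL/min/1.73 m²/yr) or `"pct5"`
#'   (within ±5 %/yr).
#' @inheritParams exact_binomial_ci
#' @return One-row data frame as from [exact_binomial_ci()].
#' @export
agreement_summary <- function(errors, criterion = c("abs3", "pct5"),
                              level = 0.95) {
  criterion <- match.arg(criterion)
  flags <- if (criterion == "abs3") errors$large_abs else errors$large_pct
  if (is.null(flags) || length(flags) == 0) stop("no usable error flags")
  flags <- flags[!is.na(flags)]
  if (length(flags) == 0) stop("no usable error flags")
  exact_binomial_ci(sum(!flags), length(flags), level)
}

#' McNemar's test for paired binary outcomes
#'
#' Compares two paired binary flag vectors (e.g. large-error indicators for
#' two estimating equations on the same participants). Reports both the
#' exact two-sided binomial test on the discordant pairs and the asymptotic
#' chi-square statistic without continuity correction; the exact p-value is
#' taken as primary when the discordant total is 25 or fewer.
#'
#' @param flags_a,flags_b Logical vectors of equal length, paired by
#'   participant.
#' @return List with `b` (a only), `c` (b only), `p_exact`, `p_asymptotic`,
#'   `statistic` (chi-square), `p_value` (the primary p-value).
#' @export
mcnemar_paired <- function(flags_a, flags_b) {
  if (length(flags_a) != length(flags_b)) stop("paired vectors differ in length")
  keep <- !(is.na(flags_a) | is.na(flags_b))
  fa <- as.logical(flags_a[keep]); fb <- as.logical(flags_b[keep])
  b <- sum(fa & !fb)
  cc <- sum(!fa & fb)
  nd <- b + cc
  if (nd == 0) {
    p_exact <- 1; p_asym <- 1; stat <- 0
  } else {
    p_exact <- min(1, 2 * stats::pbinom(min(b, cc), nd, 0.5))
    stat <- (b - cc)^2 / nd
    p_asym <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(b = b, c = cc, discordant = nd,
       p_exact = p_exact, p_asymptotic = p_asym, statistic = stat,
       p_value = if (nd <= 25) p_exact else p_asym)
}

#' Paired difference in agreement percentage
#'
#' Difference (b − a) in the percentage of participants agreeing under two
#' equations, on the same participants, with a Wald confidence interval for
#' a paired proportion difference built from the discordant counts. Here
#' `TRUE` means the participant *agrees* (no large error) under that
#' equation.
#'
#' @param flags_a,flags_b Logical agreement indicators, paired by
#'   participant.
#' @param level Confidence level.
#' @return List with `difference` (percentage points, agreement_b −
#'   agreement_a), `ci_low`, `ci_high`, and the discordant counts.
#' @export
paired_difference <- function(flags_a, flags_b, level = 0.95) {
  if (length(flags_a) != length(flags_b)) stop("paired vectors differ in length")
  keep <- !(is.na(flags_a) | is.na(flags_b))
  fa <- as.logical(flags_a[keep]); fb <- as.logical(flags_b[keep])
  n <- length(fa)
  if (n == 0) stop("no usable pairs")
  b <- sum(!fa & fb)   # agrees under b only
  cc <- sum(fa & !fb)  # agrees under a only
  d <- (b - cc) / n    # agreement_b - agreement_a
  se <- sqrt(pmax(0, b + cc - (b - cc)^2 / n)) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(difference = 100 * d,
       ci_low = 100 * (d - z * se), ci_high = 100 * (d + z * se),
       b = b, c = cc, n = n)
}

#' Diagnostic accuracy from a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive value for a
#' binary progression call against the measured-GFR reference, each with an
#' exact binomial confidence interval. A metric whose denominator is zero is
#' returned as `NA`.
#'
#' @param tp,fn,fp,tn Confusion counts (reference positive = measured-GFR
#'   progression).
#' @inheritParams exact_binomial_ci
#' @return Data frame with one row per metric: `metric`, `numerator`,
#'   `denominator`, `proportion`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' diagnostic_metrics(75, 64, 63, 673)
diagnostic_metrics <- function(tp, fn, fp, tn, level = 0.95) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  num <- c(sensitivity = tp, specificity = tn, ppv = tp, npv = tn)
  den <- c(sensitivity = tp + fn, specificity = fp + tn,
           ppv = tp + fp, npv = fn + tn)
  out <- do.call(rbind, lapply(names(num), function(m) {
    if (den[[m]] == 0) {
      data.frame(metric = m, numerator = NA_integer_,
                 denominator = 0L, proportion = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_)
    } else {
      ci <- exact_binomial_ci(num[[m]], den[[m]], level)
      cbind(metric = m, ci)
    }
  }))
  rownames(out) <- NULL
  out
}

#' P30 accuracy of estimated against measured GFR
#'
#' Proportion of estimates within 30% of the paired measured value
#' (boundary inclusive), with an exact binomial confidence interval.
#'
#' @param estimated,measured Paired GFR values; `measured` must be positive.
#' @param threshold Relative tolerance, default 0.30.
#' @inheritParams exact_binomial_ci
#' @return One-row data frame as from [exact_binomial_ci()].
#' @export
p30 <- function(estimated, measured, threshold = 0.30, level = 0.95) {
  keep <- is.finite(estimated) & is.finite(measured)
  estimated <- estimated[keep]; measured <- measured[keep]
  if (length(measured) == 0) stop("no usable pairs")
  if (any(measured <= 0)) stop("measured GFR must be positive")
  inside <- abs(estimated - measured) / measured <= threshold
  exact_binomial_ci(sum(inside), length(inside), level)
}

#' Median bias and median change summaries
#'
#' Median of (estimated − measured) GFR at each timepoint (bias), and the
#' median with interquartile range of within-person change (follow-up −
#' baseline) for each source, optionally grouped (typically by progression
#' status).
#'
#' @param data Data frame with one row per participant and source, columns
#'   `source`, `baseline_est`, `followup_est`, `baseline_meas`,
#'   `followup_meas` (the measured columns may be `NA` when `source` is
#'   itself `"measured"`; then bias columns are zero by construction and the
#'   change summary uses the source columns).
#' @param group Optional vector (length = rows of `data`) to stratify by.
#' @return Data frame with per source (and group): `bias_baseline`,
#'   `bias_followup` (medians of est − meas), `change_median`, `change_q1`,
#'   `change_q3` for the source's own values.
#' @export
bias_summary <- function(data, group = NULL) {
  if (nrow(data) == 0) stop("empty input")
  if (is.null(group)) group <- rep("all", nrow(data))
  split_idx <- split(seq_len(nrow(data)),
                     list(source = data$source, group = group), drop = TRUE)
  rows <- lapply(names(split_idx), function(nm) {
    d <- data[split_idx[[nm]], ]
    change <- d$followup_est - d$baseline_est
    qs <- stats::quantile(change, c(0.25, 0.5, 0.75), na.rm = TRUE,
                          names = FALSE)
    data.frame(source = d$source[1],
               group = sub("^[^.]*\\.", "", nm),
               n = nrow(d),
               bias_baseline = stats::median(d$baseline_est - d$baseline_meas,
                                             na.rm = TRUE),
               bias_followup = stats::median(d$followup_est - d$followup_meas,
                                             na.rm = TRUE),
               change_q1 = qs[1], change_median = qs[2], change_q3 = qs[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
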