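#' KDIGO GFR category
#'
#' Maps GFR values to the KDIGO G-categories. Intervals are half-open with
#' the lower bound included in the less severe category, so exactly 45 maps
#' to G3a (the printed "45-59" range) and exactly 15 to G4:
#' \[90, Inf) G1, \[60, 90) G2, \[45, 60) G3a, \[30, 45) G3b, \[15, 30) G4,
#' (0, 15) G5.
#'
#' @param gfr Positive GFR values (mL/min/1.73 m²).
#' @return Ordered factor with levels `G1 < G2 < G3a < G3b < G4 < G5`
#'   (increasing severity).
#' @export
#' @examples
#' gfr_category(c(50, 45, 44.999, 14.9))
gfr_category <- function(gfr) {
  if (any(!is.finite(gfr) | gfr <= 0)) stop("GFR must be positive and finite")
  cut(gfr, breaks = c(0, 15, 30, 45, 60, 90, Inf),
      labels = c("G5", "G4", "G3b", "G3a", "G2", "G1"),
      right = FALSE) |>
    factor(levels = c("G1", "G2", "G3a", "G3b", "G4", "G5"), ordered = TRUE)
}

#' Classify kidney disease progression between two visits
#'
#' The KDIGO-aligned binary classifier used throughout the package:
#' progression is a relative reduction in GFR of at least 25% *combined with*
#' a drop to a strictly worse G-category (any number of category steps).
#' Both values must come from the same source (measured GFR, or the same
#' estimating equation).
#'
#' @param baseline,followup Positive GFR values; vectorised.
#' @return Data frame with columns `progressed`, `relative_reduction`,
#'   `baseline_category`, `followup_category`.
#' @export
#' @examples
#' classify_progression(50, 35)   # 30% drop and G3a -> G3b: progressed
#' classify_progression(44, 33)   # exactly 25% but both G3b: not progressed
classify_progression <- function(baseline, followup) {
  if (any(!is.finite(baseline) | baseline <= 0) ||
      any(!is.finite(followup) | followup <= 0))
    stop("GFR values must be positive and finite")
  n <- max(length(baseline), length(followup))
  baseline <- rep_len(baseline, n)
  followup <- rep_len(followup, n)
  rel <- (baseline - followup) / baseline
  bc <- gfr_category(baseline)
  fc <- gfr_category(followup)
  data.frame(
    progressed = rel >= 0.25 & fc > bc,
    relative_reduction = rel,
    baseline_category = bc,
    followup_category = fc
  )
}
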