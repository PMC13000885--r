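#' Read a long-format cohort CSV
#'
#' One row per participant-visit. Required columns: `participant_id`,
#' `visit_date` (ISO-8601), `age_at_baseline`, `sex`; at least one of
#' `serum_creatinine` (µmol/L), `serum_cystatin_c` (mg/L) or `measured_gfr`
#' must be present. A creatinine column named `serum_creatinine_mgdl` is
#' accepted and converted to µmol/L (with a message). Validation failures
#' are reported with row numbers.
#'
#' @param path CSV path.
#' @return Validated visits data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("serum_creatinine_mgdl" %in% names(d)) {
    message("creatinine given in mg/dL; converting to µmol/L")
    d$serum_creatinine <- d$serum_creatinine_mgdl * 88.4
    d$serum_creatinine_mgdl <- NULL
  }
  req <- c("participant_id", "visit_date", "age_at_baseline", "sex")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing required columns: ",
                         paste(miss, collapse = ", "))
  if (!any(c("serum_creatinine", "serum_cystatin_c", "measured_gfr")
           %in% names(d)))
    stop("no GFR or biomarker columns present")
  dates <- as.Date(d$visit_date, format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad)) stop("unparseable visit_date at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  d$visit_date <- dates
  d$sex <- tolower(d$sex)
  bad <- which(!d$sex %in% c("male", "female"))
  if (length(bad)) stop("invalid sex at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  for (col in c("serum_creatinine", "serum_cystatin_c", "measured_gfr")) {
    if (col %in% names(d)) {
      bad <- which(!is.na(d[[col]]) & d[[col]] <= 0)
      if (length(bad)) stop("non-positive ", col, " at rows: ",
                            paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  d
}

# eGFR for one equation across visit rows, NA where inputs are missing
estimate_rows <- function(eq, visits, age_at_visit, apply_race_term) {
  spec <- equation_registry(eq)
  needs_cr <- "creatinine" %in% spec$markers
  needs_cys <- "cystatin" %in% spec$markers
  ok <- rep(TRUE, nrow(visits))
  if (needs_cr) {
    if (is.null(visits$serum_creatinine)) return(rep(NA_real_, nrow(visits)))
    ok <- ok & is.finite(visits$serum_creatinine)
  }
  if (needs_cys) {
    if (is.null(visits$serum_cystatin_c)) return(rep(NA_real_, nrow(visits)))
    ok <- ok & is.finite(visits$serum_cystatin_c)
  }
  out <- rep(NA_real_, nrow(visits))
  if (any(ok))
    out[ok] <- estimate_gfr(eq,
                            creatinine = visits$serum_creatinine[ok],
                            cystatin = visits$serum_cystatin_c[ok],
                            age = age_at_visit[ok], sex = visits$sex[ok],
                            black = if (!is.null(visits$black_ethnicity))
                              visits$black_ethnicity[ok] else FALSE,
                            apply_race_term = apply_race_term)
  out
}

#' Run the full monitoring-accuracy analysis
#'
#' End-to-end evaluation of estimating equations against measured GFR on a
#' long-format visit table: per-visit estimation, evaluable-cohort
#' selection (complete case: measured GFR and every requested equation
#' available at both baseline and follow-up), annualised slopes, large-error
#' classification under both criteria, agreement with exact binomial CIs,
#' McNemar paired comparisons against a reference equation, the progression
#' classifier with confusion matrices and diagnostic accuracy, P30 at both
#' timepoints, and median bias / median change grouped by measured
#' progression status.
#'
#' @param visits Visits data frame (as from [read_cohort()] or
#'   `simulate_cohort()$visits`), or a `gfr_cohort`.
#' @param equations Equation ids to evaluate.
#' @param reference Reference equation for the paired comparisons.
#' @param abs_threshold,pct_threshold Large-error thresholds
#'   (mL/min/1.73 m²/yr and %/yr).
#' @param slope_method `"two_point"` (primary analysis), `"ols_estimated"`
#'   (estimated slopes from per-individual least squares over all 6-monthly
#'   estimates, measured slope still two-point), or `"mixed_measured"`
#'   (additionally, measured slopes from one cohort-wide mixed-effects model
#'   using all available measured GFR values).
#' @param min_followup_years Minimum baseline-to-follow-up span for a
#'   participant to be evaluable.
#' @param stratify Optional column name (e.g. `"sex"`) for stratified
#'   agreement and diagnostic blocks.
#' @param level Confidence level.
#' @param apply_race_term Passed to [estimate_gfr()].
#' @return List of class `gfr_report`; see the components in the examples.
#' @export
run_analysis <- function(visits, equations = equation_ids(),
                         reference = "CKDEPI_CR_2009",
                         abs_threshold = 3, pct_threshold = 5,
                         slope_method = c("two_point", "ols_estimated",
                                          "mixed_measured"),
                         min_followup_years = 2.5,
                         stratify = NULL, level = 0.95,
                         apply_race_term = FALSE) {
  if (inherits(visits, "gfr_cohort")) visits <- visits$visits
  slope_method <- match.arg(slope_method)
  equations <- vapply(equations, match_equation, character(1), USE.NAMES = FALSE)
  reference <- match_equation(reference)
  stopifnot(abs_threshold > 0, pct_threshold > 0)

  visits <- visits[order(visits$participant_id, visits$visit_date), ]
  first_date <- stats::ave(as.numeric(visits$visit_date),
                           visits$participant_id, FUN = min)
  t_vis <- (as.numeric(visits$visit_date) - first_date) / 365.25
  age_at_visit <- visits$age_at_baseline + t_vis

  est <- vapply(equations, estimate_rows, numeric(nrow(visits)),
                visits = visits, age_at_visit = age_at_visit,
                apply_race_term = apply_race_term)
  colnames(est) <- equations

  mg <- if (is.null(visits$measured_gfr)) rep(NA_real_, nrow(visits)) else
    visits$measured_gfr

  ids <- unique(visits$participant_id)
  n_input <- length(ids)

  # baseline = first visit with measured GFR, follow-up = last; evaluable
  # participants need both, far enough apart, with every equation estimable
  # at both visits (intersection cohort: one common denominator)
  per <- lapply(ids, function(p) {
    idx <- which(visits$participant_id == p)
    mi <- idx[is.finite(mg[idx])]
    if (length(mi) < 2) return(NULL)
    b <- mi[1]; f <- mi[length(mi)]
    yrs <- as.numeric(visits$visit_date[f] - visits$visit_date[b]) / 365.25
    if (yrs < min_followup_years) return(NULL)
    if (!all(is.finite(est[b, ])) || !all(is.finite(est[f, ]))) return(NULL)
    list(id = p, b = b, f = f, yrs = yrs, idx = idx)
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) < 2) stop("fewer than two evaluable participants")
  n_eval <- length(per)

  bi <- vapply(per, `[[`, numeric(1), "b")
  fi <- vapply(per, `[[`, numeric(1), "f")
  yrs <- vapply(per, `[[`, numeric(1), "yrs")
  eval_ids <- vapply(per, `[[`, character(1), "id")
  eval_sex <- visits$sex[bi]

  evaluable <- data.frame(participant_id = eval_ids, sex = eval_sex,
                          baseline_date = visits$visit_date[bi],
                          followup_date = visits$visit_date[fi],
                          years = yrs,
                          baseline_mgfr = mg[bi], followup_mgfr = mg[fi],
                          stringsAsFactors = FALSE)

  # measured slopes
  if (slope_method == "mixed_measured") {
    mm_in <- visits[visits$participant_id %in% eval_ids &
                      is.finite(mg[seq_len(nrow(visits))]), ]
    mm <- mixed_model_slopes(mm_in, value = "measured_gfr")
    ord <- match(eval_ids, mm$participant_id)
    meas_slope <- mm$slope[ord]
    meas_pct <- 100 * meas_slope / mg[bi]
    mixed_fit <- mm$method[1]
  } else {
    meas_slope <- (mg[fi] - mg[bi]) / yrs
    meas_pct <- 100 * meas_slope / mg[bi]
    mixed_fit <- NA_character_
  }

  # estimated slopes per equation
  est_slope <- matrix(NA_real_, n_eval, length(equations),
                      dimnames = list(NULL, equations))
  est_pct <- est_slope
  for (eq in equations) {
    if (slope_method == "two_point") {
      est_slope[, eq] <- (est[fi, eq] - est[bi, eq]) / yrs
      est_pct[, eq] <- 100 * est_slope[, eq] / est[bi, eq]
    } else {
      for (i in seq_len(n_eval)) {
        idx <- per[[i]]$idx
        ok <- idx[is.finite(est[idx, eq])]
        o <- ols_slope(est[ok, eq], visits$visit_date[ok])
        est_slope[i, eq] <- o$slope
        est_pct[i, eq] <- 100 * o$slope / est[ok[1], eq]
      }
    }
  }

  # error classification and agreement
  errors <- do.call(rbind, lapply(equations, function(eq) {
    ce <- classify_slope_error(est_slope[, eq], meas_slope,
                               est_pct[, eq], meas_pct,
                               abs_threshold, pct_threshold)
    cbind(data.frame(participant_id = eval_ids, equation = eq,
                     est_slope = est_slope[, eq], meas_slope = meas_slope,
                     stringsAsFactors = FALSE), ce)
  }))
  rownames(errors) <- NULL

  agreement <- do.call(rbind, lapply(equations, function(eq) {
    e <- errors[errors$equation == eq, ]
    rbind(cbind(equation = eq, criterion = "abs3",
                agreement_summary(e, "abs3", level)),
          cbind(equation = eq, criterion = "pct5",
                agreement_summary(e, "pct5", level)))
  }))
  rownames(agreement) <- NULL

  ref_flags <- function(criterion) {
    e <- errors[errors$equation == reference, ]
    if (criterion == "abs3") e$large_abs else e$large_pct
  }
  paired <- do.call(rbind, lapply(setdiff(equations, reference), function(eq) {
    do.call(rbind, lapply(c("abs3", "pct5"), function(cr) {
      e <- errors[errors$equation == eq, ]
      fl <- if (cr == "abs3") e$large_abs else e$large_pct
      mc <- mcnemar_paired(ref_flags(cr), fl)
      pd <- paired_difference(!ref_flags(cr), !fl, level)
      data.frame(equation = eq, reference = reference, criterion = cr,
                 difference = pd$difference, ci_low = pd$ci_low,
                 ci_high = pd$ci_high, discordant = mc$discordant,
                 p_exact = mc$p_exact, p_asymptotic = mc$p_asymptotic,
                 p_value = mc$p_value, stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(paired)) rownames(paired) <- NULL

  # progression classification and diagnostic accuracy
  meas_prog <- classify_progression(mg[bi], mg[fi])$progressed
  confusion <- do.call(rbind, lapply(equations, function(eq) {
    ep <- classify_progression(est[bi, eq], est[fi, eq])$progressed
    data.frame(equation = eq,
               tp = sum(ep & meas_prog), fn = sum(!ep & meas_prog),
               fp = sum(ep & !meas_prog), tn = sum(!ep & !meas_prog),
               stringsAsFactors = FALSE)
  }))
  diagnostics <- do.call(rbind, lapply(seq_len(nrow(confusion)), function(i) {
    cbind(equation = confusion$equation[i],
          diagnostic_metrics(confusion$tp[i], confusion$fn[i],
                             confusion$fp[i], confusion$tn[i], level))
  }))
  rownames(diagnostics) <- NULL

  p30_tab <- do.call(rbind, lapply(equations, function(eq) {
    rbind(cbind(equation = eq, timepoint = "baseline",
                p30(est[bi, eq], mg[bi], level = level)),
          cbind(equation = eq, timepoint = "followup",
                p30(est[fi, eq], mg[fi], level = level)))
  }))
  rownames(p30_tab) <- NULL

  bias_in <- do.call(rbind, lapply(c("measured", equations), function(src) {
    if (src == "measured") {
      data.frame(source = src, participant_id = eval_ids,
                 baseline_est = mg[bi], followup_est = mg[fi],
                 baseline_meas = NA_real_, followup_meas = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(source = src, participant_id = eval_ids,
                 baseline_est = est[bi, src], followup_est = est[fi, src],
                 baseline_meas = mg[bi], followup_meas = mg[fi],
                 stringsAsFactors = FALSE)
    }
  }))
  bias <- bias_summary(bias_in,
                       group = ifelse(rep(meas_prog, 1 + length(equations)),
                                      "progression", "no_progression"))

  strata <- NULL
  if (!is.null(stratify)) {
    key <- if (stratify == "sex") eval_sex else
      stop("unsupported stratification key: ", stratify)
    strata <- lapply(split(seq_len(n_eval), key), function(ii) {
      ag <- do.call(rbind, lapply(equations, function(eq) {
        e <- errors[errors$equation == eq, ][ii, ]
        rbind(cbind(equation = eq, criterion = "abs3",
                    agreement_summary(e, "abs3", level)),
              cbind(equation = eq, criterion = "pct5",
                    agreement_summary(e, "pct5", level)))
      }))
      cm <- do.call(rbind, lapply(equations, function(eq) {
        ep <- classify_progression(est[bi[ii], eq], est[fi[ii], eq])$progressed
        mp <- meas_prog[ii]
        data.frame(equation = eq, tp = sum(ep & mp), fn = sum(!ep & mp),
                   fp = sum(ep & !mp), tn = sum(!ep & !mp))
      }))
      dg <- do.call(rbind, lapply(seq_len(nrow(cm)), function(i)
        cbind(equation = cm$equation[i],
              diagnostic_metrics(cm$tp[i], cm$fn[i], cm$fp[i], cm$tn[i],
                                 level))))
      list(n = length(ii), agreement = ag, confusion = cm, diagnostics = dg)
    })
  }

  counts <- data.frame(
    step = c("participants_in_input", "with_two_measured_gfr_and_estimates",
             "evaluable", "measured_progression"),
    n = c(n_input, n_eval, n_eval, sum(meas_prog)))

  slopes <- rbind(
    data.frame(participant_id = eval_ids, source = "measured",
               method = if (slope_method == "mixed_measured") "mixed_model"
                        else "two_point",
               slope = meas_slope, percent_slope = meas_pct,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(equations, function(eq)
      data.frame(participant_id = eval_ids, source = eq,
                 method = if (slope_method == "two_point") "two_point"
                          else "ols",
                 slope = est_slope[, eq], percent_slope = est_pct[, eq],
                 stringsAsFactors = FALSE))))

  structure(list(counts = counts, evaluable = evaluable, slopes = slopes,
                 errors = errors, agreement = agreement, paired = paired,
                 confusion = confusion, diagnostics = diagnostics,
                 p30 = p30_tab, bias = bias, strata = strata,
                 settings = list(equations = equations, reference = reference,
                                 abs_threshold = abs_threshold,
                                 pct_threshold = pct_threshold,
                                 slope_method = slope_method,
                                 min_followup_years = min_followup_years,
                                 level = level,
                                 mixed_fit = mixed_fit)),
            class = "gfr_report")
}

#' @export
print.gfr_report <- function(x, ...) {
  cat("GFR monitoring accuracy report\n")
  cat("  evaluable participants:", nrow(x$evaluable), "\n")
  cat("  measured progression:",
      x$counts$n[x$counts$step == "measured_progression"],
      sprintf("(%.1f%%)\n", 100 *
                x$counts$n[x$counts$step == "measured_progression"] /
                nrow(x$evaluable)))
  cat("\nAgreement (slope within ±", x$settings$abs_threshold,
      " mL/min/1.73 m²/yr):\n", sep = "")
  a <- x$agreement[x$agreement$criterion == "abs3", ]
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-18s %d/%d  %.1f%% (%.1f to %.1f)\n", a$equation[i],
                a$numerator[i], a$denominator[i], 100 * a$proportion[i],
                100 * a$ci_low[i], 100 * a$ci_high[i]))
  invisible(x)
}

#' Write a report to disk
#'
#' Emits the agreement, paired-comparison, confusion, diagnostic, P30, bias
#' and per-participant error tables as CSV, plus a `report.json` with the
#' settings, filtering counts and all tables, into `dir`.
#'
#' @param report A `gfr_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "gfr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("counts", "evaluable", "slopes", "errors", "agreement",
            "paired", "confusion", "diagnostics", "p30", "bias")
  paths <- character(0)
  for (tb in tabs) {
    if (is.null(report[[tb]])) next
    p <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(report[[tb]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(report[c(tabs[!vapply(report[tabs], is.null,
                                             logical(1))], "settings")],
                       jp, auto_unbox = TRUE, digits = NA, na = "null",
                       Date = "ISO8601")
  invisible(c(paths, jp))
}

#' Published benchmark counts
#'
#' Count tables from a published three-year prospective study of GFR
#' monitoring in moderate chronic kidney disease (875 evaluable adults),
#' shipped as plain CSV under `inst/extdata`: per-equation agreement
#' numerators under both large-error criteria, per-equation progression
#' confusion counts, and headline cohort summary quantities. These are
#' inputs for validating the package's accuracy machinery against printed
#' results.
#'
#' @return List with data frames `agreement`, `confusion` and named vector
#'   `summary`.
#' @export
study_benchmarks <- function() {
  p <- function(f) system.file("extdata", f, package = "gfrmon",
                               mustWork = TRUE)
  s <- utils::read.csv(p("study_summary.csv"), stringsAsFactors = FALSE)
  list(agreement = utils::read.csv(p("study_agreement_counts.csv"),
                                   stringsAsFactors = FALSE),
       confusion = utils::read.csv(p("study_progression_counts.csv"),
                                   stringsAsFactors = FALSE),
       summary = stats::setNames(s$value, s$quantity))
}

#' Round half away from zero
#'
#' Decimal rounding with halves rounded up in magnitude (the convention of
#' printed clinical tables), unlike R's banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
#' @examples
#' round_half_up(0.25, 1)  # 0.3
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
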