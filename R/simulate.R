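#' Configuration for the synthetic longitudinal CKD cohort
#'
#' Defaults reproduce the design and marginal structure of a three-year
#' prospective GFR-monitoring cohort in moderate chronic kidney disease:
#' ~1229 adults recruited with ~29% attrition to 875 evaluable, baseline
#' measured GFR median 48.1 (IQR 40.2–57.2) mL/min/1.73 m², median age 67.1
#' (58.1–73.6), 57.7% men, measured GFR at baseline and 36 months for all
#' (plus extra measurements at 12 months for 215 and 24 months for 188
#' participants), biomarkers 6-monthly, and a progressor mixture of 15.9%.
#' Slope-mixture means/SDs and the noise CVs are modelling assumptions, not
#' study estimates (see the methods vignette).
#'
#' @param n_participants Target evaluable cohort size.
#' @param evaluable_fraction Fraction of recruited participants who complete
#'   both baseline and 36-month measured GFR; recruitment size is
#'   `round(n_participants / evaluable_fraction)`.
#' @param male_fraction Proportion of men.
#' @param age_median,age_q1,age_q3 Baseline age distribution summary; a
#'   two-piece normal matched to these quartiles, truncated to `age_range`.
#' @param age_range Admissible age interval.
#' @param gfr_median,gfr_q1,gfr_q3 Baseline true-GFR log-normal summary.
#' @param progressor_fraction Mixture weight of the progressor component.
#' @param slope_mean_prog,slope_sd_prog True-slope distribution of
#'   progressors (mL/min/1.73 m²/yr).
#' @param slope_mean_nonprog,slope_sd_nonprog Non-progressor slopes.
#' @param mgfr_cv Coefficient of variation of the multiplicative log-normal
#'   measurement error on measured GFR.
#' @param biomarker_cv Visit-level CV of each serum biomarker.
#' @param person_bias_sd SD of the person-level multiplicative (log-scale)
#'   bias of each biomarker-implied GFR.
#' @param drift Annual non-GFR drift rate of the biomarker-implied GFR
#'   (log-scale per year). Positive values make biomarkers decline more
#'   slowly than true GFR, emulating the blunting of estimated decline.
#' @param extra_mgfr_12m,extra_mgfr_24m Number of completers (at the
#'   reference cohort size of 875; scaled proportionally otherwise) with
#'   additional measured GFR at 12 and 24 months.
#' @param creatinine_equation,cystatin_equation Single-marker equations
#'   inverted to generate the serum biomarkers from the latent GFR.
#' @param recruitment_start,recruitment_years Calendar recruitment window
#'   for baseline dates.
#' @param visit_jitter_days Uniform jitter (±days) applied to nominal
#'   follow-up visit dates.
#' @return Validated list of class `gfr_sim_config`.
#' @export
cohort_config <- function(n_participants = 875,
                          evaluable_fraction = 875 / 1229,
                          male_fraction = 0.577,
                          age_median = 67.1, age_q1 = 58.1, age_q3 = 73.6,
                          age_range = c(18, 95),
                          gfr_median = 48.1, gfr_q1 = 40.2, gfr_q3 = 57.2,
                          progressor_fraction = 0.159,
                          slope_mean_prog = -5.5, slope_sd_prog = 1.5,
                          slope_mean_nonprog = -1.0, slope_sd_nonprog = 1.5,
                          mgfr_cv = 0.05, biomarker_cv = 0.05,
                          person_bias_sd = 0.10, drift = 0,
                          extra_mgfr_12m = 215, extra_mgfr_24m = 188,
                          creatinine_equation = "CKDEPI_CR_2009",
                          cystatin_equation = "CKDEPI_CYS_2012",
                          recruitment_start = "2014-04-01",
                          recruitment_years = 3.75,
                          visit_jitter_days = 14) {
  cfg <- list(n_participants = n_participants,
              evaluable_fraction = evaluable_fraction,
              male_fraction = male_fraction,
              age_median = age_median, age_q1 = age_q1, age_q3 = age_q3,
              age_range = age_range,
              gfr_median = gfr_median, gfr_q1 = gfr_q1, gfr_q3 = gfr_q3,
              progressor_fraction = progressor_fraction,
              slope_mean_prog = slope_mean_prog,
              slope_sd_prog = slope_sd_prog,
              slope_mean_nonprog = slope_mean_nonprog,
              slope_sd_nonprog = slope_sd_nonprog,
              mgfr_cv = mgfr_cv, biomarker_cv = biomarker_cv,
              person_bias_sd = person_bias_sd, drift = drift,
              extra_mgfr_12m = extra_mgfr_12m,
              extra_mgfr_24m = extra_mgfr_24m,
              creatinine_equation = match_equation(creatinine_equation),
              cystatin_equation = match_equation(cystatin_equation),
              recruitment_start = as.Date(recruitment_start),
              recruitment_years = recruitment_years,
              visit_jitter_days = visit_jitter_days)
  stopifnot(n_participants >= 2,
            evaluable_fraction > 0, evaluable_fraction <= 1,
            male_fraction >= 0, male_fraction <= 1,
            progressor_fraction >= 0, progressor_fraction <= 1,
            mgfr_cv >= 0, biomarker_cv >= 0, person_bias_sd >= 0,
            age_q1 <= age_median, age_median <= age_q3,
            gfr_q1 <= gfr_median, gfr_median <= gfr_q3)
  class(cfg) <- "gfr_sim_config"
  cfg
}

# two-piece normal matched to (q1, median, q3), truncated by resampling
rtwopiece <- function(n, med, q1, q3, range) {
  z75 <- stats::qnorm(0.75)
  sd_lo <- (med - q1) / z75
  sd_hi <- (q3 - med) / z75
  draw <- function(m) {
    side <- stats::runif(m) < 0.5
    dev <- abs(stats::rnorm(m))
    ifelse(side, med - dev * sd_lo, med + dev * sd_hi)
  }
  x <- draw(n)
  bad <- x < range[1] | x > range[2]
  while (any(bad)) {
    x[bad] <- draw(sum(bad))
    bad <- x < range[1] | x > range[2]
  }
  x
}

#' Simulate a longitudinal CKD monitoring cohort
#'
#' Draws demographics, a latent linear true-GFR trajectory per participant
#' (mixture of progressor and non-progressor slopes, floored at
#' 5 mL/min/1.73 m²), then generates the observed data: measured GFR with
#' multiplicative log-normal error, and serum creatinine / cystatin C
#' obtained by inverting the configured single-marker equations at the
#' person-biased, optionally drifting, biomarker-implied GFR, with
#' visit-level noise. Visit schedule and attrition follow the configuration.
#' Fully deterministic given `seed`.
#'
#' @param config A [cohort_config()] object.
#' @param seed Integer seed.
#' @return List of class `gfr_cohort` with elements `visits` (long-format
#'   data frame: `participant_id`, `visit_date`, `month`, `age_at_baseline`,
#'   `sex`, `serum_creatinine` (µmol/L), `serum_cystatin_c` (mg/L),
#'   `measured_gfr`), `truth` (per-participant latent values and labels),
#'   `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "gfr_sim_config"))
  set.seed(as.integer(seed))
  cfg <- config
  n_rec <- max(cfg$n_participants, round(cfg$n_participants /
                                           cfg$evaluable_fraction))

  id <- sprintf("P%04d", seq_len(n_rec))
  sex <- ifelse(stats::runif(n_rec) < cfg$male_fraction, "male", "female")
  age <- rtwopiece(n_rec, cfg$age_median, cfg$age_q1, cfg$age_q3,
                   cfg$age_range)
  sdlog <- log(cfg$gfr_q3 / cfg$gfr_q1) / (2 * stats::qnorm(0.75))
  g0 <- stats::rlnorm(n_rec, log(cfg$gfr_median), sdlog)
  g0 <- pmin(pmax(g0, 12), 140)
  prog <- stats::runif(n_rec) < cfg$progressor_fraction
  slope <- ifelse(prog,
                  stats::rnorm(n_rec, cfg$slope_mean_prog, cfg$slope_sd_prog),
                  stats::rnorm(n_rec, cfg$slope_mean_nonprog,
                               cfg$slope_sd_nonprog))
  bias_cr <- stats::rnorm(n_rec, 0, cfg$person_bias_sd)
  bias_cys <- stats::rnorm(n_rec, 0, cfg$person_bias_sd)

  evaluable <- seq_len(n_rec) %in%
    sample(n_rec, min(cfg$n_participants, n_rec))
  # dropouts leave after a uniformly chosen 6-monthly visit before 36 months
  dropout_month <- ifelse(evaluable, 36L,
                          6L * sample.int(5L, n_rec, replace = TRUE))

  scale <- cfg$n_participants / 875
  completers <- which(evaluable)
  extra12 <- completers[seq_len(min(length(completers),
                                    round(cfg$extra_mgfr_12m * scale)))]
  extra24 <- completers[length(completers) + 1 -
                          seq_len(min(length(completers),
                                      round(cfg$extra_mgfr_24m * scale)))]

  baseline_date <- cfg$recruitment_start +
    floor(stats::runif(n_rec, 0, cfg$recruitment_years * 365.25))

  months <- seq(0, 36, by = 6)
  rows <- vector("list", length(months))
  for (j in seq_along(months)) {
    m <- months[j]
    attended <- m <= dropout_month
    jit <- if (m == 0) rep(0L, n_rec) else
      as.integer(round(stats::runif(n_rec, -cfg$visit_jitter_days,
                                    cfg$visit_jitter_days)))
    vdate <- baseline_date + round(m * 30.4375) + jit
    t <- as.numeric(vdate - baseline_date) / 365.25
    true_gfr <- pmax(5, g0 + slope * t)
    has_mgfr <- m %in% c(0, 36) |
      (m == 12 & seq_len(n_rec) %in% extra12) |
      (m == 24 & seq_len(n_rec) %in% extra24)
    mgfr <- true_gfr * exp(stats::rnorm(n_rec, 0, cfg$mgfr_cv))
    mgfr[!has_mgfr] <- NA_real_

    implied_cr <- pmin(pmax(true_gfr * exp(bias_cr + cfg$drift * t), 6), 145)
    implied_cys <- pmin(pmax(true_gfr * exp(bias_cys + cfg$drift * t), 6), 145)
    age_at_visit <- age + t
    cr_mgdl <- invert_equation(cfg$creatinine_equation, implied_cr,
                               age_at_visit, sex) *
      exp(stats::rnorm(n_rec, 0, cfg$biomarker_cv))
    cys <- invert_equation(cfg$cystatin_equation, implied_cys,
                           age_at_visit, sex) *
      exp(stats::rnorm(n_rec, 0, cfg$biomarker_cv))

    rows[[j]] <- data.frame(participant_id = id, visit_date = vdate,
                            month = m, age_at_baseline = age, sex = sex,
                            serum_creatinine = cr_mgdl * 88.4,
                            serum_cystatin_c = cys,
                            measured_gfr = mgfr,
                            stringsAsFactors = FALSE)[attended, ]
  }
  visits <- do.call(rbind, rows)
  visits <- visits[order(visits$participant_id, visits$visit_date), ]
  rownames(visits) <- NULL

  truth <- data.frame(participant_id = id, sex = sex, age = age,
                      true_baseline_gfr = g0, true_slope = slope,
                      progressor = prog, evaluable = evaluable,
                      dropout_month = dropout_month,
                      creatinine_bias = bias_cr, cystatin_bias = bias_cys,
                      stringsAsFactors = FALSE)

  structure(list(visits = visits, truth = truth, config = cfg,
                 seed = as.integer(seed)),
            class = "gfr_cohort")
}

#' @export
print.gfr_cohort <- function(x, ...) {
  cat("Synthetic CKD monitoring cohort\n")
  cat("  participants recruited:", nrow(x$truth), "\n")
  cat("  evaluable (baseline + 36-month mGFR):", sum(x$truth$evaluable), "\n")
  cat("  visits:", nrow(x$visits), "\n")
  cat("  true progressor fraction:",
      round(mean(x$truth$progressor), 3), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Write a simulated cohort to CSV
#'
#' Writes the long-format visit table and a ground-truth sidecar
#' (`<stem>_truth.csv`) holding the latent trajectories and labels.
#'
#' @param cohort A `gfr_cohort` from [simulate_cohort()].
#' @param path Path of the visit CSV; the truth sidecar is written next to
#'   it.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "gfr_cohort"))
  utils::write.csv(cohort$visits, path, row.names = FALSE)
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  if (identical(truth_path, path)) truth_path <- paste0(path, "_truth.csv")
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  invisible(c(visits = path, truth = truth_path))
}
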