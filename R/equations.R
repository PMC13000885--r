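#' GFR estimating equation identifiers
#'
#' The eight creatinine and/or cystatin C based equations supported by the
#' package: the 2009 and 2021 CKD-EPI creatinine equations, the 2012 CKD-EPI
#' cystatin C equation, the 2012 and 2021 CKD-EPI combined equations, and the
#' EKFC creatinine, cystatin C and combined equations.
#'
#' @return Character vector of the eight equation ids.
#' @export
#' @examples
#' equation_ids()
equation_ids <- function() {
  c("CKDEPI_CR_2009", "CKDEPI_CYS_2012", "CKDEPI_CRCYS_2012",
    "CKDEPI_CR_2021", "CKDEPI_CRCYS_2021",
    "EKFC_CR", "EKFC_CYS", "EKFC_CRCYS")
}

# Declarative coefficient registry. All CKD-EPI equations share the form
#   A * min(m/k, 1)^alpha * max(m/k, 1)^beta * g^age * sex_f [* race_f]
# per marker; EKFC equations share 107.3 / (m/Q)^x * 0.990^(age - 40) with the
# exponent x switching at m/Q = 1. Creatinine knots/Q in mg/dL, cystatin in
# mg/L. Kept in one place so the constants can be audited against the source
# publications line by line.
.registry <- list(
  CKDEPI_CR_2009 = list(
    family = "ckdepi", markers = "creatinine", A = 141, g = 0.993,
    female_factor = 1.018, race_factor = 1.159,
    creatinine = list(knot = c(female = 0.7, male = 0.9),
                      alpha = c(female = -0.329, male = -0.411),
                      beta = -1.209)),
  CKDEPI_CYS_2012 = list(
    family = "ckdepi", markers = "cystatin", A = 133, g = 0.996,
    female_factor = 0.932, race_factor = NA_real_,
    cystatin = list(knot = c(female = 0.8, male = 0.8),
                    alpha = c(female = -0.499, male = -0.499),
                    beta = -1.328)),
  CKDEPI_CRCYS_2012 = list(
    family = "ckdepi", markers = c("creatinine", "cystatin"), A = 135,
    g = 0.995, female_factor = 0.969, race_factor = 1.08,
    creatinine = list(knot = c(female = 0.7, male = 0.9),
                      alpha = c(female = -0.248, male = -0.207),
                      beta = -0.601),
    cystatin = list(knot = c(female = 0.8, male = 0.8),
                    alpha = c(female = -0.375, male = -0.375),
                    beta = -0.711)),
  CKDEPI_CR_2021 = list(
    family = "ckdepi", markers = "creatinine", A = 142, g = 0.9938,
    female_factor = 1.012, race_factor = NA_real_,
    creatinine = list(knot = c(female = 0.7, male = 0.9),
                      alpha = c(female = -0.241, male = -0.302),
                      beta = -1.200)),
  CKDEPI_CRCYS_2021 = list(
    family = "ckdepi", markers = c("creatinine", "cystatin"), A = 135,
    g = 0.9961, female_factor = 0.963, race_factor = NA_real_,
    creatinine = list(knot = c(female = 0.7, male = 0.9),
                      alpha = c(female = -0.219, male = -0.144),
                      beta = -0.544),
    cystatin = list(knot = c(female = 0.8, male = 0.8),
                    alpha = c(female = -0.323, male = -0.323),
                    beta = -0.778)),
  EKFC_CR = list(
    family = "ekfc", markers = "creatinine",
    Q = list(type = "sex", female = 0.70, male = 0.90),
    low_exp = 0.322, high_exp = 1.132),
  EKFC_CYS = list(
    family = "ekfc", markers = "cystatin",
    Q = list(type = "age", base = 0.83, knot_age = 50, slope = 0.005),
    low_exp = 0.322, high_exp = 1.132),
  EKFC_CRCYS = list(
    family = "ekfc_mean", markers = c("creatinine", "cystatin"),
    components = c("EKFC_CR", "EKFC_CYS"))
)

#' Coefficient registry for the estimating equations
#'
#' Returns the full table of published coefficients used by
#' [estimate_gfr()], one entry per equation id. Intended for audit: the
#' values can be diffed against the original publications. Use
#' `equation_registry_json()` to serialise it.
#'
#' @param equation Optional single equation id; if given, only that entry.
#' @return Named list of coefficient sets.
#' @export
equation_registry <- function(equation = NULL) {
  if (is.null(equation)) return(.registry)
  .registry[[match_equation(equation)]]
}

#' @rdname equation_registry
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
equation_registry_json <- function(path = NULL) {
  js <- jsonlite::toJSON(.registry, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

match_equation <- function(equation) {
  eq <- match.arg(toupper(equation), equation_ids())
  eq
}

#' Convert serum creatinine from µmol/L to mg/dL
#'
#' Creatinine is reported in µmol/L in UK laboratories while the CKD-EPI and
#' EKFC coefficients are published on the mg/dL scale; the conversion factor
#' is 88.4 µmol per mg/dL.
#'
#' @param scr_umol Serum creatinine in µmol/L; must be positive.
#' @return Creatinine in mg/dL.
#' @export
#' @examples
#' creatinine_umol_to_mgdl(128)
creatinine_umol_to_mgdl <- function(scr_umol) {
  if (any(!is.finite(scr_umol) | scr_umol <= 0))
    stop("creatinine must be positive and finite")
  scr_umol / 88.4
}

check_sex <- function(sex, n) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  rep_len(sex, n)
}

# CKD-EPI power term for one marker; vectorised over marker and sex
ckdepi_marker_term <- function(marker, coefs, sex) {
  knot <- unname(coefs$knot[sex])
  alpha <- unname(coefs$alpha[sex])
  r <- marker / knot
  pmin(r, 1)^alpha * pmax(r, 1)^coefs$beta
}

ekfc_q <- function(qspec, sex, age) {
  if (qspec$type == "sex") {
    unname(c(female = qspec$female, male = qspec$male)[sex])
  } else {
    ifelse(age < qspec$knot_age, qspec$base,
           qspec$base + qspec$slope * (age - qspec$knot_age))
  }
}

ekfc_core <- function(marker, q, age) {
  r <- marker / q
  x <- ifelse(r < 1, 0.322, 1.132)
  107.3 / r^x * ifelse(age > 40, 0.990^(age - 40), 1)
}

#' Estimate GFR from serum biomarkers
#'
#' Evaluates one of the eight published CKD-EPI / EKFC estimating equations.
#' All arguments are vectorised and recycled to a common length. Results are
#' body-surface-indexed GFR in mL/min/1.73 m².
#'
#' @param equation One of [equation_ids()].
#' @param creatinine Serum creatinine (required by creatinine equations), in
#'   the unit given by `creatinine_unit`.
#' @param cystatin Serum cystatin C in mg/L (required by cystatin equations).
#' @param age Age in years; the equations are for adults, so ages below 18
#'   are rejected.
#' @param sex `"male"` or `"female"`.
#' @param black Optional logical, Black ethnicity; only consulted when
#'   `apply_race_term = TRUE` and the equation has a published race
#'   coefficient (2009/2012 CKD-EPI creatinine-containing equations).
#' @param apply_race_term Apply the historical race coefficient where one was
#'   published. Default `FALSE`, matching contemporary UK practice and the
#'   race-free 2021 revisions (which ignore the flag by construction).
#' @param creatinine_unit `"umol/L"` (default, UK reporting unit) or
#'   `"mg/dL"`.
#' @return Numeric vector of estimated GFR values.
#' @export
#' @examples
#' # CKD-EPI creatinine for a 60-year-old man, creatinine 128 umol/L
#' estimate_gfr("CKDEPI_CR_2009", creatinine = 128, age = 60, sex = "male")
#' # EKFC combined equation
#' estimate_gfr("EKFC_CRCYS", creatinine = 128, cystatin = 1.48,
#'              age = 67, sex = "female")
estimate_gfr <- function(equation, creatinine = NULL, cystatin = NULL,
                         age, sex, black = FALSE, apply_race_term = FALSE,
                         creatinine_unit = c("umol/L", "mg/dL")) {
  eq <- match_equation(equation)
  spec <- .registry[[eq]]
  creatinine_unit <- match.arg(creatinine_unit)

  n <- max(length(creatinine), length(cystatin), length(age), length(sex))
  if (any(!is.finite(age)) || any(age < 18))
    stop("age must be finite and >= 18 (adult equations only)")
  age <- rep_len(as.numeric(age), n)
  sex <- check_sex(sex, n)
  black <- rep_len(as.logical(black), n)

  needs_cr <- "creatinine" %in% spec$markers
  needs_cys <- "cystatin" %in% spec$markers
  if (needs_cr) {
    if (is.null(creatinine)) stop(eq, " requires serum creatinine")
    if (any(!is.finite(creatinine) | creatinine <= 0))
      stop("creatinine must be positive and finite")
    scr <- rep_len(as.numeric(creatinine), n)
    if (creatinine_unit == "umol/L") scr <- creatinine_umol_to_mgdl(scr)
  }
  if (needs_cys) {
    if (is.null(cystatin)) stop(eq, " requires serum cystatin C")
    if (any(!is.finite(cystatin) | cystatin <= 0))
      stop("cystatin must be positive and finite")
    scys <- rep_len(as.numeric(cystatin), n)
  }

  if (spec$family == "ckdepi") {
    g <- rep_len(spec$A, n)
    if (needs_cr) g <- g * ckdepi_marker_term(scr, spec$creatinine, sex)
    if (needs_cys) g <- g * ckdepi_marker_term(scys, spec$cystatin, sex)
    g <- g * spec$g^age
    g <- g * ifelse(sex == "female", spec$female_factor, 1)
    if (apply_race_term && !is.na(spec$race_factor))
      g <- g * ifelse(black, spec$race_factor, 1)
    g
  } else if (spec$family == "ekfc") {
    marker <- if (needs_cr) scr else scys
    q <- ekfc_q(spec$Q, sex, age)
    ekfc_core(marker, q, age)
  } else { # EKFC combined: mean of the two single-marker estimates
    0.5 * (ekfc_core(scr, ekfc_q(.registry$EKFC_CR$Q, sex, age), age) +
           ekfc_core(scys, ekfc_q(.registry$EKFC_CYS$Q, sex, age), age))
  }
}

#' Invert an estimating equation for its biomarker
#'
#' Finds the biomarker concentration at which [estimate_gfr()] returns a
#' target GFR, by bisection on the log-concentration scale (each equation is
#' strictly decreasing in its biomarker). For the combined two-marker
#' equations, cystatin C is first fixed at its own single-marker inversion
#' and creatinine is then solved for; the pair jointly reproduces the target.
#' Used by the synthetic cohort generator to manufacture biomarkers
#' consistent with a chosen true GFR.
#'
#' @inheritParams estimate_gfr
#' @param target_gfr Target GFR in mL/min/1.73 m², in (5, 150).
#' @param tol Absolute bisection tolerance on GFR.
#' @return For single-marker equations a numeric vector of concentrations
#'   (creatinine in mg/dL, cystatin in mg/L). For combined equations a list
#'   with elements `creatinine` (mg/dL) and `cystatin` (mg/L).
#' @export
invert_equation <- function(equation, target_gfr, age, sex, tol = 1e-8) {
  eq <- match_equation(equation)
  spec <- .registry[[eq]]
  if (any(!is.finite(target_gfr) | target_gfr <= 5 | target_gfr >= 150))
    stop("target_gfr must lie in (5, 150)")
  n <- max(length(target_gfr), length(age), length(sex))
  target_gfr <- rep_len(as.numeric(target_gfr), n)
  age <- rep_len(as.numeric(age), n)
  sex <- check_sex(sex, n)

  if (length(spec$markers) == 2L) {
    cys <- invert_one(sub("_CRCYS", "_CYS",
                          sub("CKDEPI_CRCYS_2021", "CKDEPI_CYS_2012",
                              sub("CKDEPI_CRCYS_2012", "CKDEPI_CYS_2012", eq))),
                      target_gfr, age, sex, tol)
    f <- function(scr) estimate_gfr(eq, creatinine = scr, cystatin = cys,
                                    age = age, sex = sex,
                                    creatinine_unit = "mg/dL")
    cr <- bisect_marker(f, target_gfr, n, tol)
    list(creatinine = cr, cystatin = cys)
  } else if ("creatinine" %in% spec$markers) {
    invert_one(eq, target_gfr, age, sex, tol)
  } else {
    invert_one(eq, target_gfr, age, sex, tol)
  }
}

invert_one <- function(eq, target, age, sex, tol) {
  is_cys <- grepl("CYS", eq)
  f <- if (is_cys) {
    function(m) estimate_gfr(eq, cystatin = m, age = age, sex = sex)
  } else {
    function(m) estimate_gfr(eq, creatinine = m, age = age, sex = sex,
                             creatinine_unit = "mg/dL")
  }
  bisect_marker(f, target, length(target), tol)
}

# vectorised bisection in log-marker space; estimate is strictly decreasing
# in the marker so the root is bracketed by wide fixed bounds
bisect_marker <- function(f, target, n, tol) {
  lo <- rep(log(0.01), n)   # very low concentration -> very high GFR
  hi <- rep(log(50), n)     # very high concentration -> very low GFR
  if (any(f(exp(lo)) < target) || any(f(exp(hi)) > target))
    stop("target GFR outside the achievable range of the equation")
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    val <- f(exp(mid))
    high <- val > target     # estimate too high -> increase marker
    lo <- ifelse(high, mid, lo)
    hi <- ifelse(high, hi, mid)
    if (max(abs(val - target)) < tol) break
  }
  exp((lo + hi) / 2)
}
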