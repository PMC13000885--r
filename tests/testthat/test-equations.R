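test_that("all eight equations match the independent conformance oracle", {
  fx <- read.csv(system.file("extdata", "equation_conformance.csv",
                             package = "gfrmon"))
  expect_equal(nrow(fx), 144)
  expect_setequal(unique(fx$equation), equation_ids())
  got <- mapply(function(eq, cr, cys, age, sex) {
    estimate_gfr(eq, creatinine = if (is.na(cr)) NULL else cr,
                 cystatin = if (is.na(cys)) NULL else cys,
                 age = age, sex = sex, creatinine_unit = "mg/dL")
  }, fx$equation, fx$creatinine_mgdl, fx$cystatin_mgl, fx$age, fx$sex)
  expect_equal(unname(got), fx$expected_gfr, tolerance = 1e-8)
})

test_that("creatinine unit conversion uses the 88.4 factor and rejects bad input", {
  expect_equal(creatinine_umol_to_mgdl(88.4), 1.0)
  expect_equal(round(creatinine_umol_to_mgdl(128), 4), 1.4480)
  expect_error(creatinine_umol_to_mgdl(0))
  expect_error(creatinine_umol_to_mgdl(-3))
  # the umol/L API path equals explicit conversion
  expect_equal(
    estimate_gfr("CKDEPI_CR_2009", creatinine = 128, age = 60, sex = "male"),
    estimate_gfr("CKDEPI_CR_2009", creatinine = 128 / 88.4, age = 60,
                 sex = "male", creatinine_unit = "mg/dL"))
})

test_that("closed forms evaluate exactly at their knots", {
  # EKFC at marker = Q and age 40: both power terms are 1
  expect_equal(estimate_gfr("EKFC_CR", creatinine = 0.9, age = 40,
                            sex = "male", creatinine_unit = "mg/dL"), 107.3)
  expect_equal(estimate_gfr("EKFC_CR", creatinine = 0.7, age = 40,
                            sex = "female", creatinine_unit = "mg/dL"), 107.3)
  # CKD-EPI 2009 male at the 0.9 mg/dL knot, age 60
  expect_equal(
    estimate_gfr("CKDEPI_CR_2009", creatinine = 0.9, age = 60, sex = "male",
                 creatinine_unit = "mg/dL"),
    141 * 0.993^60)
})

test_that("estimates are continuous at every piecewise knot", {
  eps <- 1e-9
  for (eq in equation_ids()) {
    for (sex in c("male", "female")) {
      knot_cr <- if (sex == "male") 0.9 else 0.7
      for (age in c(30, 70)) {
        lo <- est_panel(eq, data.frame(creatinine = knot_cr - eps,
                                       cystatin = 0.8 - eps,
                                       age = age, sex = sex))
        hi <- est_panel(eq, data.frame(creatinine = knot_cr + eps,
                                       cystatin = 0.8 + eps,
                                       age = age, sex = sex))
        expect_equal(lo, hi, tolerance = 1e-6)
      }
    }
  }
  # EKFC cystatin knot is age-dependent (marker = Q)
  q80 <- 0.83 + 0.005 * 30
  expect_equal(
    estimate_gfr("EKFC_CYS", cystatin = q80 - eps, age = 80, sex = "male"),
    estimate_gfr("EKFC_CYS", cystatin = q80 + eps, age = 80, sex = "male"),
    tolerance = 1e-6)
})

test_that("estimates are strictly decreasing in each biomarker", {
  p <- random_panels(300, seed = 42)
  h <- 1.001
  for (eq in equation_ids()) {
    base <- est_panel(eq, p)
    needs_cr <- "creatinine" %in% equation_registry(eq)$markers
    needs_cys <- "cystatin" %in% equation_registry(eq)$markers
    if (needs_cr) {
      p2 <- p; p2$creatinine <- p$creatinine * h
      expect_true(all(est_panel(eq, p2) < base), label = paste(eq, "creatinine"))
    }
    if (needs_cys) {
      p2 <- p; p2$cystatin <- p$cystatin * h
      expect_true(all(est_panel(eq, p2) < base), label = paste(eq, "cystatin"))
    }
  }
})

test_that("estimates are non-increasing in age and positive on the domain", {
  p <- random_panels(300, seed = 7)
  p$age <- runif(nrow(p), 18, 99)
  for (eq in equation_ids()) {
    base <- est_panel(eq, p)
    expect_true(all(is.finite(base) & base > 0), label = eq)
    p2 <- p; p2$age <- p$age + 1
    expect_true(all(est_panel(eq, p2) <= base + 1e-12), label = paste(eq, "age"))
  }
})

test_that("race coefficient is applied only where published and only when enabled", {
  args <- list(creatinine = 1.2, cystatin = 1.3, age = 60, sex = "female",
               creatinine_unit = "mg/dL")
  for (eq in equation_ids()) {
    off <- do.call(estimate_gfr, c(list(eq), args))
    on_black <- do.call(estimate_gfr,
                        c(list(eq), args,
                          list(black = TRUE, apply_race_term = TRUE)))
    fac <- equation_registry(eq)$race_factor
    if (!is.null(fac) && !is.na(fac)) {
      expect_equal(on_black / off, fac, tolerance = 1e-12, label = eq)
    } else {
      expect_equal(on_black, off, label = eq)
    }
    # flag on but not black ethnicity: unchanged
    on_nb <- do.call(estimate_gfr,
                     c(list(eq), args,
                       list(black = FALSE, apply_race_term = TRUE)))
    expect_equal(on_nb, off, label = eq)
  }
})

test_that("inputs outside the contract are rejected", {
  expect_error(estimate_gfr("CKDEPI_CR_2009", creatinine = 100, age = 17,
                            sex = "male"), "age")
  expect_error(estimate_gfr("CKDEPI_CR_2009", age = 50, sex = "male"),
               "creatinine")
  expect_error(estimate_gfr("CKDEPI_CYS_2012", age = 50, sex = "male"),
               "cystatin")
  expect_error(estimate_gfr("NOT_AN_EQUATION", creatinine = 100, age = 50,
                            sex = "male"))
  expect_error(estimate_gfr("CKDEPI_CR_2009", creatinine = -1, age = 50,
                            sex = "male"))
  expect_error(estimate_gfr("CKDEPI_CR_2009", creatinine = 100, age = 50,
                            sex = "unknown"))
})

test_that("inverting an equation then re-estimating recovers the target", {
  set.seed(11)
  targets <- runif(40, 10, 120)
  ages <- runif(40, 20, 90)
  sexes <- sample(c("male", "female"), 40, replace = TRUE)
  for (eq in equation_ids()) {
    inv <- invert_equation(eq, targets, ages, sexes)
    back <- if (is.list(inv)) {
      estimate_gfr(eq, creatinine = inv$creatinine, cystatin = inv$cystatin,
                   age = ages, sex = sexes, creatinine_unit = "mg/dL")
    } else if ("cystatin" %in% equation_registry(eq)$markers) {
      estimate_gfr(eq, cystatin = inv, age = ages, sex = sexes)
    } else {
      estimate_gfr(eq, creatinine = inv, age = ages, sex = sexes,
                   creatinine_unit = "mg/dL")
    }
    expect_equal(back, targets, tolerance = 1e-6, label = eq)
  }
})

test_that("inversion is monotone and hits the EKFC knot in closed form", {
  # target 107.3 at age 40 male: creatinine must equal the male Q
  cr <- invert_equation("EKFC_CR", 107.3, 40, "male")
  expect_equal(cr, 0.90, tolerance = 1e-6)
  lo <- invert_equation("EKFC_CR", 40, 60, "male")
  hi <- invert_equation("EKFC_CR", 80, 60, "male")
  expect_true(hi < lo)  # higher GFR target -> lower creatinine
  expect_error(invert_equation("EKFC_CR", 200, 60, "male"))
})

test_that("the coefficient registry serialises to JSON and back", {
  js <- equation_registry_json()
  parsed <- jsonlite::fromJSON(js)
  expect_setequal(names(parsed), equation_ids())
  expect_equal(parsed$CKDEPI_CR_2009$A, 141)
  expect_equal(parsed$EKFC_CR$Q$male, 0.90)
  tmp <- tempfile(fileext = ".json")
  equation_registry_json(tmp)
  expect_true(file.exists(tmp))
  unlink(tmp)
})
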