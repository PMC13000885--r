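test_that("exact binomial CI reproduces printed cohort values to 1 dp", {
  r <- exact_binomial_ci(640, 875)
  expect_equal(round_half_up(100 * c(r$proportion, r$ci_low, r$ci_high)),
               c(73.1, 70.1, 76.1))
  r <- exact_binomial_ci(702, 875)
  expect_equal(round_half_up(100 * c(r$proportion, r$ci_low, r$ci_high)),
               c(80.2, 77.4, 82.8))
  r <- exact_binomial_ci(609, 875)
  expect_equal(round_half_up(100 * c(r$proportion, r$ci_low, r$ci_high)),
               c(69.6, 66.4, 72.6))
})

test_that("exact binomial CI honours boundaries and rejects bad counts", {
  r <- exact_binomial_ci(0, 10)
  expect_equal(r$ci_low, 0)
  expect_equal(r$proportion, 0)
  r <- exact_binomial_ci(10, 10)
  expect_equal(r$ci_high, 1)
  expect_error(exact_binomial_ci(5, 0))
  expect_error(exact_binomial_ci(-1, 10))
  expect_error(exact_binomial_ci(11, 10))
  expect_error(exact_binomial_ci(2.5, 10))
})

test_that("beta-quantile CI matches the tail-inversion bisection oracle", {
  # spot grid here; the exhaustive n <= 50 sweep runs in the acceptance suite
  for (n in c(5, 17, 50, 200, 875)) {
    for (k in unique(c(0, 1, n %/% 3, n - 1, n))) {
      r <- exact_binomial_ci(k, n)
      o <- cp_oracle(k, n)
      expect_equal(c(r$ci_low, r$ci_high), o, tolerance = 1e-9,
                   label = sprintf("k=%d n=%d", k, n))
      # independent cross-check against stats::binom.test
      bt <- binom.test(k, n)$conf.int
      expect_equal(c(r$ci_low, r$ci_high), as.numeric(bt), tolerance = 1e-8)
    }
  }
})

test_that("agreement summary counts the unflagged participants", {
  e <- data.frame(large_abs = rep(FALSE, 20), large_pct = rep(FALSE, 20))
  expect_equal(agreement_summary(e, "abs3")$proportion, 1)
  e$large_abs[1:5] <- TRUE
  r <- agreement_summary(e, "abs3")
  expect_equal(r$numerator, 15)
  expect_equal(r$denominator, 20)
  # numerator + large-error count = denominator
  expect_equal(r$numerator + sum(e$large_abs), r$denominator)
  expect_equal(agreement_summary(data.frame(large_abs = TRUE),
                                 "abs3")$proportion, 0)
  expect_error(agreement_summary(data.frame(large_abs = logical(0)), "abs3"))
})

test_that("McNemar exact p matches binomial enumeration", {
  f <- rep(c(TRUE, FALSE), 10)
  same <- mcnemar_paired(f, f)
  expect_equal(same$p_value, 1)
  expect_equal(same$discordant, 0)
  # b=10, c=0: p = 2 * 0.5^10
  a <- c(rep(TRUE, 10), rep(FALSE, 10))
  b <- rep(FALSE, 20)
  r <- mcnemar_paired(a, b)
  expect_equal(r$p_exact, 2 * 0.5^10)
  expect_equal(round(r$p_exact, 5), 0.00195)
  # b=5, c=5 symmetric: p = 1
  a2 <- c(rep(TRUE, 5), rep(FALSE, 5))
  b2 <- c(rep(FALSE, 5), rep(TRUE, 5))
  expect_equal(mcnemar_paired(a2, b2)$p_exact, 1)
  expect_error(mcnemar_paired(c(TRUE, FALSE), TRUE))
})

test_that("McNemar exact p equals the enumeration oracle for all small tables", {
  for (nd in 1:20) {
    for (b in 0:nd) {
      cc <- nd - b
      fa <- c(rep(TRUE, b), rep(FALSE, cc), rep(TRUE, 3))
      fb <- c(rep(FALSE, b), rep(TRUE, cc), rep(TRUE, 3))
      r <- mcnemar_paired(fa, fb)
      expect_equal(r$p_exact, mcnemar_oracle(b, cc),
                   label = sprintf("b=%d c=%d", b, cc))
      # asymptotic statistic matches stats::mcnemar.test without correction
      if (nd > 0) {
        m <- suppressWarnings(
          mcnemar.test(matrix(c(3, b, cc, 0), 2), correct = FALSE))
        expect_equal(r$statistic, unname(m$statistic))
      }
    }
  }
})

test_that("paired agreement difference reproduces the printed 7.1% comparison", {
  # reference agrees for 640/875, comparator 702/875, nested so that the
  # discordant pairs are exactly the 62 extra agreements
  ref <- c(rep(TRUE, 640), rep(FALSE, 235))
  cmp <- c(rep(TRUE, 702), rep(FALSE, 173))
  r <- paired_difference(ref, cmp)
  expect_equal(round_half_up(r$difference), 7.1)
  expect_equal(paired_difference(ref, ref)$difference, 0)
  r2 <- paired_difference(rep(FALSE, 4), rep(TRUE, 4))
  expect_equal(r2$difference, 100)
  expect_error(paired_difference(TRUE, c(TRUE, FALSE)))
})

test_that("diagnostic metrics reproduce printed confusion-table rows", {
  d <- diagnostic_metrics(75, 64, 63, 673)
  got <- round_half_up(100 * d$proportion)
  expect_equal(got, c(54.0, 91.4, 54.3, 91.3))
  expect_equal(round_half_up(100 * d$ci_low), c(45.3, 89.2, 45.7, 89.0))
  expect_equal(round_half_up(100 * d$ci_high), c(62.4, 93.4, 62.8, 93.2))
  d2 <- diagnostic_metrics(69, 70, 44, 692)
  expect_equal(round_half_up(100 * d2$proportion[d2$metric == "specificity"]),
               94.0)
  d3 <- diagnostic_metrics(1, 0, 0, 1)
  expect_equal(d3$proportion, rep(1, 4))
})

test_that("diagnostic metric identities hold", {
  set.seed(17)
  for (i in 1:25) {
    cm <- sample(0:40, 4, replace = TRUE)
    if (cm[1] + cm[2] == 0 || cm[3] + cm[4] == 0) next
    d <- diagnostic_metrics(cm[1], cm[2], cm[3], cm[4])
    # swapping the reference labels swaps sensitivity and specificity
    d_rev <- diagnostic_metrics(cm[4], cm[3], cm[2], cm[1])
    expect_equal(d$proportion[d$metric == "sensitivity"],
                 d_rev$proportion[d_rev$metric == "specificity"])
    # when fp = fn the row and column denominators coincide: ppv = sens
    d_eq <- diagnostic_metrics(cm[1], 7, 7, cm[4])
    expect_equal(d_eq$proportion[d_eq$metric == "ppv"],
                 d_eq$proportion[d_eq$metric == "sensitivity"])
  }
  # zero denominator reported as missing
  d0 <- diagnostic_metrics(0, 0, 5, 5)
  expect_true(is.na(d0$proportion[d0$metric == "sensitivity"]))
  expect_error(diagnostic_metrics(-1, 0, 0, 0))
})

test_that("P30 uses an inclusive 30% boundary and is scale invariant", {
  expect_equal(p30(c(50, 60), c(50, 60))$proportion, 1)
  expect_equal(p30(70, 100)$proportion, 1)    # exactly 30% inside
  expect_equal(p30(c(129, 131), c(100, 100))$proportion, 0.5)
  set.seed(23)
  est <- runif(100, 20, 90)
  meas <- runif(100, 20, 90)
  s <- runif(100, 0.5, 2)
  expect_equal(p30(est, meas)$proportion, p30(est * s, meas * s)$proportion)
  expect_error(p30(numeric(0), numeric(0)))
  expect_error(p30(50, -1))
})

test_that("bias summary reports medians by group", {
  d <- data.frame(source = "EQ",
                  baseline_est = c(40, 60), followup_est = c(38, 55),
                  baseline_meas = c(50, 50), followup_meas = c(40, 50))
  r <- bias_summary(d)
  expect_equal(r$bias_baseline, 0)  # median of (40-50, 60-50)
  expect_equal(r$change_median, median(c(-2, -5)))
  # est == meas everywhere: zero bias
  d2 <- data.frame(source = "EQ", baseline_est = c(45, 55),
                   followup_est = c(40, 50), baseline_meas = c(45, 55),
                   followup_meas = c(40, 50))
  expect_equal(bias_summary(d2)$bias_baseline, 0)
  expect_equal(bias_summary(d2)$bias_followup, 0)
  # grouping splits rows
  g <- bias_summary(rbind(d, d2), group = c("p", "p", "n", "n"))
  expect_equal(nrow(g), 2)
  expect_error(bias_summary(d[0, ]))
})
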