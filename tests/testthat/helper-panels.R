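# random adult biomarker panels on the equations' stated domain
random_panels <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    creatinine = exp(runif(n, log(0.11), log(20))),  # mg/dL
    cystatin = exp(runif(n, log(0.11), log(10))),    # mg/L
    age = runif(n, 18, 100),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

est_panel <- function(eq, p, ...) {
  estimate_gfr(eq, creatinine = p$creatinine, cystatin = p$cystatin,
               age = p$age, sex = p$sex, creatinine_unit = "mg/dL", ...)
}
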