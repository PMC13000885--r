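# independent Clopper-Pearson oracle: invert the binomial tail probabilities
# by bisection (uniroot), no beta quantiles involved
cp_oracle <- function(k, n, level = 0.95) {
  a <- 1 - level
  lo <- if (k == 0) 0 else
    uniroot(function(p) 1 - pbinom(k - 1, n, p) - a / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (k == n) 1 else
    uniroot(function(p) pbinom(k, n, p) - a / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

# exact two-sided McNemar p by enumeration of the discordant binomial
mcnemar_oracle <- function(b, cc) {
  nd <- b + cc
  if (nd == 0) return(1)
  min(1, 2 * sum(dbinom(0:min(b, cc), nd, 0.5)))
}
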