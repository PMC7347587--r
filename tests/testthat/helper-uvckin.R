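# shared fixtures: every test builds inputs from these reference objects
refConstants <- defaultConstants()
refGenome <- defaultEcoliGenome()

expect_rel <- function(actual, expected, tol) {
  expect_true(
    abs(actual - expected) <= tol * abs(expected),
    label = sprintf(
      "%.8g vs expected %.8g (rel err %.3g, tol %.3g)",
      actual, expected, abs(actual - expected) / abs(expected), tol
    )
  )
}

# deterministic parameter draws for property-style loops; N0/k is kept
# within 10^[-2, 2.5] so the landmark times exp(N0/k), exp(N0/2k) stay
# resolvable in double precision (t - 1 not lost to rounding)
randomParams <- function(n, seed = 20260927) {
  set.seed(seed)
  k <- 10^stats::runif(n, -2, 8)
  data.frame(k = k, n0 = k * 10^stats::runif(n, -2, 2.5))
}

randomGenomes <- function(n, seed = 20260927) {
  set.seed(seed)
  data.frame(
    nj = 10^stats::runif(n, 5, 7.5),
    vg = 10^stats::runif(n, -14, -12),
    dx = 10^stats::runif(n, -6, -4),
    sigma = 10^stats::runif(n, -17, -15)
  )
}
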