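test_that("mortality is k ln(t): zero at t = 1, k at t = e, matches integral oracle", {
  p <- kineticParams(k = 6.8065e7, n0 = 1e9)
  expect_identical(mortalityAt(1, p), 0)
  expect_equal(mortalityAt(exp(1), p), 6.8065e7, tolerance = 1e-12)

  # independent oracle: Riemann integration of dN/dt = k/t from 1 to 10
  k <- 2
  tt <- seq(1, 10, length.out = 2e5)
  mid <- (tt[-1] + tt[-length(tt)]) / 2
  riemann <- sum(k / mid * diff(tt))
  p2 <- kineticParams(k = k, n0 = 100)
  expect_rel(mortalityAt(10, p2), riemann, 1e-6)
})

test_that("dead plus surviving cells conserve the initial population", {
  rp <- randomParams(50)
  for (i in seq_len(nrow(rp))) {
    p <- kineticParams(k = rp$k[i], n0 = rp$n0[i])
    tmax <- min(rp$n0[i] / rp$k[i], 600) # stay inside representable exp()
    ts <- exp(stats::runif(5, 0, tmax))
    expect_equal(
      mortalityAt(ts, p, clamp = FALSE) + survivalAt(ts, p, clamp = FALSE),
      rep(rp$n0[i], 5),
      tolerance = 1e-12
    )
  }
})

test_that("survival equals N0 at t = 1 and hits zero at the absolute death time", {
  p <- kineticParams(k = 1, n0 = 2)
  expect_identical(survivalAt(1, p), 2)
  expect_equal(survivalAt(exp(2 / 1), p, clamp = FALSE), 0, tolerance = 1e-9)
  expect_error(survivalAt(0, p), "logarithm")
  expect_error(mortalityAt(-3, p), "logarithm")
})

test_that("yield/speed conversions use Ea and round-trip exactly", {
  # printed theoretical yield maps to the printed mortality speed
  expect_rel(ssmFromCqmy(1.4435e-5, refConstants), 6.8065e7, 1e-3)
  set.seed(1)
  for (x in 10^stats::runif(20, -8, 0)) {
    expect_equal(cqmyFromSsm(ssmFromCqmy(x)), x, tolerance = 1e-12)
  }
  # phi_mu = k lambda / (n0 h c): doubling lambda doubles the yield at fixed k
  doubled <- suppressWarnings(physicalConstants(
    6.0225e23, 6.6256e-27, 2.9979e10, 2 * 2.537e-5
  ))
  expect_equal(cqmyFromSsm(1, doubled), 2 * cqmyFromSsm(1, refConstants),
    tolerance = 1e-12
  )
  expect_error(ssmFromCqmy(-1), "positive")
})

test_that("LDR50 halves the population and depends only on N0/k", {
  expect_equal(ldr50(kineticParams(k = 1, n0 = 2)), exp(1), tolerance = 1e-12)
  rp <- randomParams(30, seed = 4)
  for (i in seq_len(nrow(rp))) {
    p <- kineticParams(k = rp$k[i], n0 = rp$n0[i])
    t50 <- suppressWarnings(ldr50(p))
    if (is.finite(t50)) {
      expect_equal(survivalAt(t50, p, clamp = FALSE) / (rp$n0[i] / 2), 1,
        tolerance = 1e-12
      )
    }
  }
  # ratio invariance: (N0, k) and (2 N0, 2 k) share the same LDR50
  expect_equal(ldr50(kineticParams(k = 2, n0 = 4)),
    ldr50(kineticParams(k = 1, n0 = 2)),
    tolerance = 1e-12
  )
  # overflow is reported, not silently wrong
  expect_warning(
    t50 <- ldr50(kineticParams(k = 1, n0 = 1e7)),
    "beyond representable"
  )
  expect_identical(as.numeric(t50), Inf)
  expect_equal(attr(t50, "log_time"), 5e6)
})

test_that("minimum mortality time is 1/k and matches the wavelength form", {
  expect_rel(minimumMortalityTime(kineticParams(k = 6.8065e7, n0 = 1)),
    1.4691e-8, 1e-3
  )
  expect_identical(minimumMortalityTime(kineticParams(k = 1, n0 = 1)), 1)
  set.seed(2)
  ea <- activationEnergy(refConstants)
  for (phi in 10^stats::runif(100, -7, -3)) {
    p <- kineticParams(phiMu = phi, n0 = 1)
    # tu = 1/k and tu = lambda / (phi_mu n0 h c) agree
    expect_equal(minimumMortalityTime(p), 1 / (phi * ea), tolerance = 1e-12)
  }
})

test_that("absolute death time is the square of LDR50", {
  p <- kineticParams(k = 1, n0 = 2)
  expect_equal(absoluteDeathTime(p), exp(2), tolerance = 1e-12)
  expect_equal(survivalAt(absoluteDeathTime(p), p, clamp = FALSE), 0,
    tolerance = 1e-6 * 2
  )
  rp <- randomParams(30, seed = 9)
  for (i in seq_len(nrow(rp))) {
    p <- kineticParams(k = rp$k[i], n0 = rp$n0[i])
    t100 <- suppressWarnings(absoluteDeathTime(p))
    t50 <- suppressWarnings(ldr50(p))
    if (is.finite(t100)) {
      expect_equal(t100, t50^2, tolerance = 1e-9 * t100)
    }
  }
})

test_that("predictCurve vectorises, clamps, conserves and reports landmarks", {
  p <- kineticParams(k = 5e7, n0 = 3e8)
  cv <- predictCurve(c(1, seq(30, 300, 30)), p)
  df <- as.data.frame(cv)
  expect_identical(df$N_dead[1], 0)
  expect_identical(df$N1_surviving[1], 3e8)
  expect_true(all(diff(df$N_dead) >= 0))
  expect_true(all(diff(df$N1_surviving) <= 0))
  expect_true(all(df$N_dead >= 0 & df$N1_surviving >= 0))

  # landmark consistency: at the LDR50 the curves cross at N0/2
  t50 <- cv@landmarks[["ldr50"]]
  expect_equal(survivalAt(t50, p), mortalityAt(t50, p), tolerance = 1e-9)

  # t < 1 is the pre-unitary regime: raw mortality negative, flagged+clamped
  cv2 <- predictCurve(0.5, p)
  expect_true(cv2@clamped[1])
  expect_identical(cv2@dead[1], 0)
  cvRaw <- predictCurve(0.5, p, clamp = FALSE)
  expect_true(cvRaw@dead[1] < 0)
  expect_true(cvRaw@clamped[1])

  expect_error(predictCurve(c(10, 0, 30), p), "index 2")
})
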