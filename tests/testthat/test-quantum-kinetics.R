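test_that("mean free path is the reciprocal of the macroscopic section", {
  g <- refGenome
  # derived oracle: reciprocal of the printed Z = 1.1806e4 cm^-1
  expect_rel(meanFreePath(g), 1 / 1.1806e4, 1e-3)
  expect_equal(meanFreePath(g) * macroscopicSection(g), 1, tolerance = 1e-12)
  # doubling sigma halves the free path
  g2 <- genomeSpec(5.2e6, 4.3716e-13, 5.5111e-5, 2 * 4.9627e-16)
  expect_equal(meanFreePath(g2), meanFreePath(g) / 2, tolerance = 1e-12)
})

test_that("excitation time and impact frequency are mutual reciprocals", {
  expect_rel(excitationTime(refGenome, refConstants), 2.8252e-15, 1e-3)
  expect_rel(impactFrequency(refGenome, refConstants), 1 / 2.8252e-15, 1e-3)
  expect_equal(
    excitationTime(refGenome, refConstants),
    meanFreePath(refGenome) / lightSpeed(refConstants),
    tolerance = 1e-12
  )
  rg <- randomGenomes(30, seed = 5)
  for (i in seq_len(nrow(rg))) {
    g <- genomeSpec(rg$nj[i], rg$vg[i], rg$dx[i], rg$sigma[i])
    expect_equal(
      impactFrequency(g, refConstants) * excitationTime(g, refConstants), 1,
      tolerance = 1e-12
    )
  }
  # doubling the base density doubles the impact frequency
  gHalfV <- genomeSpec(5.2e6, 4.3716e-13 / 2, 5.5111e-5, 4.9627e-16)
  expect_equal(impactFrequency(gHalfV, refConstants),
    2 * impactFrequency(refGenome, refConstants),
    tolerance = 1e-12
  )
})

test_that("the three absorbed-fraction forms agree and hit the printed values", {
  g <- refGenome
  expect_rel(absorbedFraction(g), 0.6506, 1e-3)
  expect_rel(macroscopicSection(g), 1.1806e4, 1e-3)
  rg <- randomGenomes(50, seed = 11)
  for (i in seq_len(nrow(rg))) {
    gi <- genomeSpec(rg$nj[i], rg$vg[i], rg$dx[i], rg$sigma[i])
    a <- absorbedFraction(gi, "density")
    expect_equal(absorbedFraction(gi, "area"), a, tolerance = 1e-12)
    expect_equal(absorbedFraction(gi, "path"), a, tolerance = 1e-12)
  }
  # Beer-Lambert variant is a probability, strictly below the linear count
  expect_true(absorbedProbabilityBeerLambert(g) < absorbedFraction(g))
  expect_true(absorbedProbabilityBeerLambert(g) < 1)
})

test_that("lethal impact number couples k to impact statistics and round-trips", {
  g <- refGenome
  kBar <- theoreticalSSM(g, refConstants)
  fTu <- lethalImpactNumber(kBar, g, refConstants)
  # proportionality hypothesis: f(tu) ~ Nj at the theoretical speed
  expect_rel(fTu, 5.2e6, 1e-3)
  expect_equal(ssmFromLin(fTu, g, refConstants), kBar, tolerance = 1e-12)
  # unitary identity: exactly one death over the minimum mortality time
  expect_equal(unitaryMortality(kBar, fTu, g, refConstants), 1,
    tolerance = 1e-12
  )
  # tu = f(tu) * excitation time
  expect_equal(fTu * excitationTime(g, refConstants), 1 / kBar,
    tolerance = 1e-12
  )
  expect_error(lethalImpactNumber(0, g), "positive")
  expect_error(ssmFromLin(-2, g), "positive")
})

test_that("impact-based curves equal the physical-model curves pointwise", {
  g <- refGenome
  set.seed(3)
  ts <- exp(stats::runif(20, 0, 6))
  for (fTu in 10^stats::runif(5, 5, 7)) {
    k <- ssmFromLin(fTu, g, refConstants)
    p <- kineticParams(k = k, n0 = 1e9)
    expect_equal(
      mortalityFromImpacts(ts, fTu, g, refConstants, clamp = FALSE),
      mortalityAt(ts, p, clamp = FALSE),
      tolerance = 1e-12
    )
    expect_equal(
      survivalFromImpacts(ts, fTu, 1e9, g, refConstants, clamp = FALSE),
      survivalAt(ts, p, clamp = FALSE),
      tolerance = 1e-12
    )
  }
  # at f(tu) = Nj the speed reduces to 2 sigma c / VG
  expect_rel(
    ssmFromLin(basePairs(g), g, refConstants),
    2 * impactSection(g) * lightSpeed(refConstants) / genomeVolume(g),
    1e-4
  )
})

test_that("theoretical predictions reproduce the closed-form reference values", {
  g <- refGenome
  expect_rel(theoreticalSSM(g, refConstants), 6.8065e7, 1e-3)
  expect_rel(theoreticalMMT(g, refConstants), 1.4691e-8, 1e-3)
  expect_rel(theoreticalCQMY(g, refConstants), 1.4435e-5, 1e-3)
  expect_equal(
    theoreticalSSM(g, refConstants) * theoreticalMMT(g, refConstants), 1,
    tolerance = 1e-12
  )
  # excited-state lifetime scale: tu within the 1e-9 - 1e-7 s band
  expect_true(theoreticalMMT(g, refConstants) > 1e-9)
  expect_true(theoreticalMMT(g, refConstants) < 1e-7)
  # yield within the published 1e-6 - 1e-5 order band
  expect_true(theoreticalCQMY(g, refConstants) >= 1e-6)
  expect_true(theoreticalCQMY(g, refConstants) < 1e-4)
  # halving the genome volume doubles the speed
  gHalfV <- genomeSpec(5.2e6, 4.3716e-13 / 2, 5.5111e-5, 4.9627e-16)
  expect_equal(theoreticalSSM(gHalfV), 2 * theoreticalSSM(g), tolerance = 1e-12)
  # doubling lambda doubles the yield
  doubled <- suppressWarnings(physicalConstants(
    6.0225e23, 6.6256e-27, 2.9979e10, 2 * 2.537e-5
  ))
  expect_equal(theoreticalCQMY(g, doubled), 2 * theoreticalCQMY(g, refConstants),
    tolerance = 1e-12
  )
  # the nine-quantity report carries everything above
  rep9 <- theoryReport(g, refConstants)
  expect_length(rep9, 9)
  expect_equal(rep9$ssm_k_per_s, theoreticalSSM(g, refConstants))
})

test_that("Monte Carlo impact oracle converges to the analytic statistics", {
  g <- refGenome
  mc <- mcImpactOracle(g, refConstants, nPhotons = 1e5, seed = 123)
  # exponential free paths: mean within 3 SE of 1/Z
  expect_true(abs(mc$meanPath - meanFreePath(g)) <= 3 * mc$sePath)
  # Poisson traversal impacts: mean within 3 SE of delta
  expect_true(abs(mc$meanImpacts - absorbedFraction(g)) <= 3 * mc$seImpacts)
  expect_true(
    abs(mc$meanExcitationTime - excitationTime(g, refConstants)) <=
      3 * mc$seExcitationTime
  )
  # determinism: same seed, bit-identical results
  mc2 <- mcImpactOracle(g, refConstants, nPhotons = 1e5, seed = 123)
  expect_identical(mc, mc2)
  # 1/sqrt(n) convergence: 100x photons shrinks the SE ~10x
  mcSmall <- mcImpactOracle(g, refConstants, nPhotons = 1e3, seed = 123)
  expect_rel(mcSmall$sePath / mc$sePath, 10, 0.35)
  expect_error(mcImpactOracle(g, refConstants, nPhotons = 10), "seed")
})
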