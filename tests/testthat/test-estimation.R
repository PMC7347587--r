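makeDataset <- function(k = 5e7, n0 = 3e8, times = seq(30, 300, 30),
                        reps = 1, dilution = 1e5, strain = "test") {
  rows <- do.call(rbind, lapply(seq_len(reps), function(r) {
    n1 <- n0 - k * log(times)
    rbind(
      data.frame(
        time_s = 0, replicate = r, dilution_factor = dilution,
        cfu_per_ml = n0 / dilution
      ),
      data.frame(
        time_s = times, replicate = r, dilution_factor = dilution,
        cfu_per_ml = n1 / dilution
      )
    )
  }))
  survivalData(strain, rows)
}

test_that("plate counts back-calculate to survivors and controls set N0", {
  d <- survivalData("s1", data.frame(
    time_s = c(0, 30), replicate = 1, dilution_factor = c(1e5, 1e5),
    cfu_per_ml = c(2000, 100)
  ))
  conv <- countsToSurvivors(d, "absolute")
  expect_identical(conv$data$n1, 100 * 1e5)
  expect_identical(conv$n0, 2e8)

  # normalized mode: exposed at half the control is 50%
  d2 <- survivalData("s2", data.frame(
    time_s = c(0, 30), replicate = 1, dilution_factor = 1e5,
    cfu_per_ml = c(2000, 1000)
  ))
  convN <- countsToSurvivors(d2, "normalized")
  expect_identical(convN$data$n1, 50)
  expect_identical(convN$n0, 100)

  # round-trip: normalized * N0/100 recovers the absolute counts
  convA <- countsToSurvivors(d2, "absolute")
  expect_equal(convN$data$n1 * convA$n0 / 100, convA$data$n1,
    tolerance = 1e-12
  )

  # missing or zero controls are errors that name the strain
  noCtrl <- survivalData("orphan", data.frame(
    time_s = 30, replicate = 1, dilution_factor = 1e5, cfu_per_ml = 10
  ))
  expect_error(countsToSurvivors(noCtrl), "orphan")
  zeroCtrl <- survivalData("blank", data.frame(
    time_s = c(0, 30), replicate = 1, dilution_factor = 1e5,
    cfu_per_ml = c(0, 10)
  ))
  expect_error(countsToSurvivors(zeroCtrl), "blank")
})

test_that("noiseless model data are recovered exactly by the regression", {
  d <- makeDataset(k = 5e7, n0 = 3e8)
  fit <- suppressWarnings(fitSurvival(d))
  expect_rel(ssmHat(fit), 5e7, 1e-9)
  expect_rel(n0Hat(fit), 3e8, 1e-9)
  expect_equal(detR2(fit), 1, tolerance = 1e-9)
  expect_true(fit@slope < 0)
  # R^2 = R^2 identity and the yield via the slope relation
  expect_equal(detR2(fit), corR(fit)^2, tolerance = 1e-12)
  expect_equal(cqmyHat(fit), ssmHat(fit) / activationEnergy(refConstants),
    tolerance = 1e-12
  )
})

test_that("degenerate designs are rejected", {
  d <- makeDataset(times = c(30, 60)) # only two distinct times
  expect_error(fitSurvival(d), "3 distinct")
  dEq <- makeDataset(times = rep(30, 5))
  expect_error(fitSurvival(dEq), "3 distinct")
})

test_that("R^2 is invariant under count rescaling while k scales linearly", {
  d <- makeDataset(k = 3e7, n0 = 3e8)
  # add deterministic perturbation so R^2 < 1 meaningfully
  rec <- records(d)
  idx <- rec$time_s > 0
  set.seed(77)
  rec$cfu_per_ml[idx] <- rec$cfu_per_ml[idx] * (1 + 0.05 * stats::rnorm(sum(idx)))
  d <- survivalData("pert", rec)
  fit1 <- suppressWarnings(fitSurvival(d, mode = "absolute"))
  fit2 <- suppressWarnings(fitSurvival(d, mode = "normalized"))
  expect_equal(detR2(fit1), detR2(fit2), tolerance = 1e-9)
  # normalized counts are absolute counts x 100/N0
  n0Abs <- countsToSurvivors(d, "absolute")$n0
  expect_equal(ssmHat(fit2), ssmHat(fit1) * 100 / n0Abs, tolerance = 1e-9)
})

test_that("confidence and prediction bands bracket the fitted line correctly", {
  d <- simulateDataset(simulationDesign(trueK = 5e7, seed = 31))
  fit <- fitSurvival(d, confidence = 0.97)
  b <- fit@band
  expect_true(all(b$conf_lo <= b$fitted & b$fitted <= b$conf_hi))
  # fiducial (prediction) band contains the mean-response band
  expect_true(all(b$pred_lo <= b$conf_lo))
  expect_true(all(b$pred_hi >= b$conf_hi))
  # wider confidence -> wider band
  fitWide <- fitSurvival(d, confidence = 0.995)
  expect_true(all(
    fitWide@band$conf_hi - fitWide@band$conf_lo >= b$conf_hi - b$conf_lo
  ))
})

test_that("mortality view mirrors the survival fit", {
  d <- makeDataset(k = 5e7, n0 = 3e8)
  fit <- suppressWarnings(fitSurvival(d))
  mv <- mortalityView(fit, d)
  expect_equal(mv$mortalitySlope, -fit@slope, tolerance = 1e-15)
  # fitted LDR50 satisfies N1(ldr50) = N0/2 under the fitted parameters
  p <- kineticParams(k = ssmHat(fit), n0 = n0Hat(fit))
  expect_equal(survivalAt(mv$ldr50Hat, p), n0Hat(fit) / 2,
    tolerance = 1e-6 * n0Hat(fit)
  )
  expect_rel(mv$ldr50Hat, exp(3e8 / (2 * 5e7)), 1e-6)
  # dead + surviving = fitted N0 at every observation
  expect_equal(mv$data$n_dead + mv$data$n1, rep(n0Hat(fit), nrow(mv$data)),
    tolerance = 1e-9 * n0Hat(fit)
  )
})

test_that("one-mean t-test against theory behaves at both extremes", {
  kRef <- theoreticalSSM(refGenome, refConstants)
  # exact agreement: t = 0, p = 1
  res <- tTestVsTheory(rep(kRef, 3), kRef)
  expect_identical(res$statistic, 0)
  expect_identical(res$p_value, 1)
  expect_false(res$reject)
  # gross shift: rejected
  res2 <- tTestVsTheory(c(1.1, 1.2, 1.05) * 10 * kRef, kRef)
  expect_true(res2$p_value < 0.03)
  expect_true(res2$reject)
  expect_error(tTestVsTheory(kRef, kRef), "at least 2")
})

test_that("t-test type-I error rate matches the nominal significance level", {
  kRef <- 5e7
  alpha <- 0.03
  set.seed(42)
  nSims <- 200
  rejected <- vapply(seq_len(nSims), function(i) {
    kHats <- stats::rnorm(6, mean = kRef, sd = 0.02 * kRef)
    tTestVsTheory(kHats, kRef, alpha = alpha)$reject
  }, logical(1))
  rate <- mean(rejected)
  mcSe <- sqrt(alpha * (1 - alpha) / nSims)
  expect_true(abs(rate - alpha) <= 3 * mcSe)
})

test_that("per-replicate fits feed the theory comparison", {
  d <- simulateDataset(simulationDesign(trueK = 5e7, replicates = 3, seed = 8))
  fits <- fitSurvivalByReplicate(d)
  expect_length(fits, 3)
  kHats <- vapply(fits, ssmHat, numeric(1))
  res <- tTestVsTheory(kHats, 5e7)
  expect_true(res$p_value > 0.03) # simulated at the reference value itself
})
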