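## Simulator of the plating experiment: stationary-phase culture (~1e8
## CFU/ml, 3 ml per dish -> N0 ~ 3e8), 30 s exposure steps to 300 s, five
## decimal serial dilutions, triplicate series, Poisson plate counts.

#' Construct a simulation design
#'
#' Defaults reproduce the experimental design the models were tested
#' against: N0 = 3e8 (a ~1e8 CFU/ml stationary culture, 3 ml per dish),
#' exposures every 30 s up to 300 s, three replicates, five decimal
#' dilutions, Poisson plate-count noise, and a lamp fluence rate of
#' 2.75 mJ/(s cm^2) recorded as metadata.
#'
#' @param trueK true specific speed of mortality (default 5e7, mid-range of
#'   the fitted strain values 2e7-7e7).
#' @param trueN0 true initial population, CFU/ml scale (default 3e8).
#' @param times exposure times, s (default \code{seq(30, 300, by = 30)}).
#' @param replicates replicate series (default 3).
#' @param dilutionSteps decimal dilution steps available (default 5).
#' @param platedVolumeMl plated volume, ml (default 1).
#' @param noiseModel "poisson" (default), "poisson_lognormal" or "none"
#'   (deterministic expected counts).
#' @param overdispersionSigma lognormal sigma for "poisson_lognormal"
#'   (default 0.1 when that model is selected).
#' @param fluenceRate mJ/(s cm^2), metadata only (default 2.75).
#' @param seed mandatory integer seed.
#' @return a [SimulationDesign-class].
#' @export
simulationDesign <- function(trueK = 5e7, trueN0 = 3e8,
                             times = seq(30, 300, by = 30),
                             replicates = 3, dilutionSteps = 5,
                             platedVolumeMl = 1,
                             noiseModel = c("poisson", "poisson_lognormal", "none"),
                             overdispersionSigma = 0.1,
                             fluenceRate = 2.75, seed) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  noiseModel <- match.arg(noiseModel)
  new("SimulationDesign",
    trueK = as.numeric(trueK), trueN0 = as.numeric(trueN0),
    times = as.numeric(times), replicates = as.integer(replicates),
    dilutionSteps = as.integer(dilutionSteps),
    platedVolumeMl = as.numeric(platedVolumeMl),
    noiseModel = noiseModel,
    overdispersionSigma = as.numeric(overdispersionSigma),
    fluenceRate = as.numeric(fluenceRate),
    seed = as.integer(seed)
  )
}

setMethod("show", "SimulationDesign", function(object) {
  cat("SimulationDesign\n")
  cat(sprintf("  true k = %.3e, true N0 = %.3e\n", object@trueK, object@trueN0))
  cat(sprintf(
    "  %d times (%g-%g s), %d replicate(s), %d dilution steps\n",
    length(object@times), min(object@times), max(object@times),
    object@replicates, object@dilutionSteps
  ))
  cat(sprintf("  noise: %s, seed = %d\n", object@noiseModel, object@seed))
  invisible(NULL)
})

# Pick the decimal dilution whose expected plate count falls in the standard
# countable range (30-300 colonies); otherwise the closest achievable.
.pickDilution <- function(expectedPerMl, platedVolumeMl, dilutionSteps,
                          lo = 30, hi = 300) {
  factors <- 10^(0:dilutionSteps)
  expectedCounts <- expectedPerMl * platedVolumeMl / factors
  inRange <- which(expectedCounts >= lo & expectedCounts <= hi)
  idx <- if (length(inRange) > 0) {
    inRange[1]
  } else {
    which.min(abs(log(pmax(expectedCounts, .Machine$double.xmin) / sqrt(lo * hi))))
  }
  list(factor = factors[idx], expectedCount = expectedCounts[idx])
}

.sampleCount <- function(mu, noiseModel, overdispersionSigma) {
  if (noiseModel == "none") {
    return(mu)
  }
  if (noiseModel == "poisson_lognormal" && overdispersionSigma > 0) {
    # mean-preserving lognormal multiplier on the Poisson intensity
    mu <- mu * stats::rlnorm(length(mu),
      meanlog = -overdispersionSigma^2 / 2, sdlog = overdispersionSigma
    )
  }
  stats::rpois(length(mu), lambda = mu)
}

#' Simulate a CFU survival dataset
#'
#' Generates one strain's plating experiment under the log-time survival
#' model: expected survivors N1(t) = max(0, N0 - k ln t) per time and
#' replicate, a dilution chosen so the expected plate count sits in the
#' countable 30-300 colony range, a plate count drawn under the design's
#' noise model, and CFU/ml back-calculated through the dilution factor.
#' Control rows (t = 0) carry the undiminished N0. Fully reproducible per
#' seed; with \code{noiseModel = "none"} the stored counts are the exact
#' model expectations, so [countsToSurvivors()] inverts the generator
#' exactly.
#'
#' @param design a [SimulationDesign-class].
#' @return a [SurvivalData-class]; the records carry an extra
#'   \code{fluence_mJ_cm2} metadata column (fluence rate x time).
#' @examples
#' d <- simulateDataset(simulationDesign(seed = 42))
#' head(records(d))
#' @export
simulateDataset <- function(design) {
  stopifnot(is(design, "SimulationDesign"))
  set.seed(design@seed)
  expected <- pmax(design@trueN0 - design@trueK * log(design@times), 0)
  if (all(expected == 0)) {
    warning("all exposure times are beyond absolute death; counts will be 0")
  }
  rows <- list()
  for (r in seq_len(design@replicates)) {
    # control: unexposed culture at N0
    ctrlDil <- .pickDilution(
      design@trueN0, design@platedVolumeMl, design@dilutionSteps
    )
    ctrlCount <- .sampleCount(
      ctrlDil$expectedCount, design@noiseModel, design@overdispersionSigma
    )
    rows[[length(rows) + 1]] <- data.frame(
      time_s = 0, replicate = r, dilution_factor = ctrlDil$factor,
      cfu_per_ml = ctrlCount / design@platedVolumeMl,
      fluence_mJ_cm2 = 0
    )
    for (i in seq_along(design@times)) {
      dil <- .pickDilution(
        expected[i], design@platedVolumeMl, design@dilutionSteps
      )
      count <- .sampleCount(
        dil$expectedCount, design@noiseModel, design@overdispersionSigma
      )
      rows[[length(rows) + 1]] <- data.frame(
        time_s = design@times[i], replicate = r,
        dilution_factor = dil$factor,
        cfu_per_ml = count / design@platedVolumeMl,
        fluence_mJ_cm2 = design@fluenceRate * design@times[i]
      )
    }
  }
  survivalData(
    strain = sprintf("sim_k%.3g_n%.3g", design@trueK, design@trueN0),
    records = do.call(rbind, rows),
    platedVolumeMl = design@platedVolumeMl
  )
}

#' Parameter-recovery study
#'
#' Runs simulate-fit loops over one or more designs and summarises how well
#' the regression recovers the true parameters: median relative error and
#' RMSE for k-hat, N0-hat and phi_mu-hat, and the empirical coverage of the
#' slope confidence interval, with Monte Carlo standard errors.
#'
#' @param designs a [SimulationDesign-class] or list of them; each design's
#'   own seed is ignored in favour of per-simulation seeds derived from
#'   \code{seed}.
#' @param nSims simulations per design (>= 50 for stable summaries; smaller
#'   values allowed for smoke tests).
#' @param seed master seed for the per-simulation seed stream.
#' @param confidence CI level for the coverage column (default 0.97).
#' @return data.frame, one row per design: true_k, true_n0, n_sims,
#'   n_failed, k_median_rel_err, k_rmse, n0_median_rel_err,
#'   phi_mu_median_rel_err, coverage, coverage_mc_se. The per-simulation
#'   draws (true_k, k_hat, n0_hat, phi_mu_hat, covered) are attached as the
#'   \code{"sims"} attribute for pooled summaries.
#' @examples
#' \donttest{
#' recoveryStudy(simulationDesign(seed = 1), nSims = 50, seed = 1)
#' }
#' @export
recoveryStudy <- function(designs, nSims = 200, seed, confidence = 0.97) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (is(designs, "SimulationDesign")) designs <- list(designs)
  set.seed(as.integer(seed))
  # pre-drawn seed stream keeps designs independent of evaluation order
  simSeeds <- sample.int(.Machine$integer.max - 1L,
    size = length(designs) * nSims
  )
  out <- vector("list", length(designs))
  simsOut <- vector("list", length(designs))
  for (d in seq_along(designs)) {
    des <- designs[[d]]
    kHat <- n0HatV <- phiHat <- covered <- rep(NA_real_, nSims)
    for (i in seq_len(nSims)) {
      s <- simSeeds[(d - 1) * nSims + i]
      desI <- des
      desI@seed <- as.integer(s)
      fit <- tryCatch(
        suppressWarnings(fitSurvival(simulateDataset(desI),
          confidence = confidence
        )),
        error = function(e) NULL
      )
      if (is.null(fit)) next # e.g. too few positive times after clamping
      kHat[i] <- ssmHat(fit)
      n0HatV[i] <- n0Hat(fit)
      phiHat[i] <- cqmyHat(fit)
      ci <- sort(abs(slopeCI(fit)))
      covered[i] <- des@trueK >= ci[1] && des@trueK <= ci[2]
    }
    truePhi <- cqmyFromSsm(des@trueK)
    ok <- !is.na(kHat)
    cov <- mean(covered[ok])
    out[[d]] <- data.frame(
      true_k = des@trueK, true_n0 = des@trueN0, n_sims = nSims,
      n_failed = sum(!ok),
      k_median_rel_err = stats::median(abs(kHat[ok] - des@trueK) / des@trueK),
      k_rmse = sqrt(mean((kHat[ok] - des@trueK)^2)),
      n0_median_rel_err = stats::median(abs(n0HatV[ok] - des@trueN0) / des@trueN0),
      phi_mu_median_rel_err = stats::median(abs(phiHat[ok] - truePhi) / truePhi),
      coverage = cov,
      coverage_mc_se = sqrt(cov * (1 - cov) / sum(ok))
    )
    simsOut[[d]] <- data.frame(
      true_k = des@trueK, k_hat = kHat, n0_hat = n0HatV,
      phi_mu_hat = phiHat, covered = covered
    )
  }
  structure(do.call(rbind, out), sims = do.call(rbind, simsOut))
}
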