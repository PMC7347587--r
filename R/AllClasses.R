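#' @import methods
NULL

#' Physical constants for quantum bookkeeping
#'
#' Immutable value object holding the four physical constants that drive both
#' kinetic models: Avogadro's number, Planck's constant, the speed of light
#' and the lamp wavelength. All quantities are in CGS units (erg, cm, s);
#' inputs must be supplied on that scale. Constants are frozen at
#' construction — overrides happen by constructing a new object (for example
#' through a configuration file), never by slot mutation.
#'
#' @slot avogadro Avogadro's constant, 1/mol.
#' @slot planck Planck's constant, erg s.
#' @slot lightSpeed speed of light, cm/s.
#' @slot wavelength lamp wavelength, cm. Values outside the UV-C band
#'   (2.0e-5 to 2.8e-5 cm) are accepted with a warning.
#'
#' @seealso [defaultConstants()]
#' @export
setClass("PhysicalConstants",
  representation(
    avogadro = "numeric",
    planck = "numeric",
    lightSpeed = "numeric",
    wavelength = "numeric"
  )
)

setValidity("PhysicalConstants", function(object) {
  vals <- c(
    avogadro = object@avogadro, planck = object@planck,
    lightSpeed = object@lightSpeed, wavelength = object@wavelength
  )
  if (length(vals) != 4L || any(!is.finite(vals))) {
    return("all four constants must be finite scalars")
  }
  if (any(vals <= 0)) {
    return(paste0(
      "constants must be strictly positive; offending: ",
      paste(names(vals)[vals <= 0], collapse = ", ")
    ))
  }
  TRUE
})

#' Genome geometry of the photon target
#'
#' Describes the genome as the matrix that UV-C photons traverse: number of
#' base pairs, the volume the nucleoid occupies, its mean thickness along the
#' photon path, and the effective impact cross-section of one nitrogenous
#' base. The derived quantities used throughout the corpuscular model —
#' the base density N* = 2 Nj / VG (both strands), the genome area
#' A_G = VG / dx, and the effective macroscopic section Z = N* sigma — are
#' exposed through [baseDensity()], [genomeArea()] and
#' [macroscopicSection()].
#'
#' @slot basePairs number of base pairs Nj (bp).
#' @slot genomeVolume genome volume VG, cm^3.
#' @slot genomeThickness mean genome thickness along the beam dx, cm.
#' @slot impactSection effective impact cross-section sigma, cm^2.
#' @slot label free-text strain/species label.
#'
#' @seealso [defaultEcoliGenome()]
#' @export
setClass("GenomeSpec",
  representation(
    basePairs = "numeric",
    genomeVolume = "numeric",
    genomeThickness = "numeric",
    impactSection = "numeric",
    label = "character"
  )
)

setValidity("GenomeSpec", function(object) {
  vals <- c(
    basePairs = object@basePairs, genomeVolume = object@genomeVolume,
    genomeThickness = object@genomeThickness,
    impactSection = object@impactSection
  )
  if (length(vals) != 4L || any(!is.finite(vals))) {
    return("all genome parameters must be finite scalars")
  }
  if (any(vals <= 0)) {
    return(paste0(
      "genome parameters must be strictly positive; offending: ",
      paste(names(vals)[vals <= 0], collapse = ", ")
    ))
  }
  TRUE
})

#' Kinetic parameters of the log-time mortality model
#'
#' Couples the specific speed of mortality k (the slope magnitude of dead
#' cells against ln time), the activation energy Ea per mole of photons, and
#' the initial population size N0. The cell quantum mortality yield
#' phi_mu = k / Ea is always derived, never stored, so k = phi_mu * Ea holds
#' by construction.
#'
#' @slot ssm specific speed of mortality k, 1/s (count per ln-second).
#' @slot activationEnergy activation energy Ea = n0 h c / lambda, erg/mol.
#' @slot initialCells initial population N0 (count; CFU-scale).
#'
#' @seealso [kineticParams()], [cqmy()]
#' @export
setClass("KineticParams",
  representation(
    ssm = "numeric",
    activationEnergy = "numeric",
    initialCells = "numeric"
  )
)

setValidity("KineticParams", function(object) {
  if (!is.finite(object@ssm) || object@ssm <= 0) {
    return("ssm (k) must be a positive finite scalar")
  }
  if (!is.finite(object@activationEnergy) || object@activationEnergy <= 0) {
    return("activationEnergy (Ea) must be a positive finite scalar")
  }
  if (!is.finite(object@initialCells) || object@initialCells < 0) {
    return("initialCells (N0) must be a non-negative finite scalar")
  }
  TRUE
})

#' Evaluated mortality/survival curves
#'
#' Result of [predictCurve()]: element-wise dead and surviving counts at a
#' grid of exposure times, with per-point clamping flags and the derived
#' landmark times (LDR50, minimum mortality time, absolute death time).
#'
#' @slot times exposure times, s.
#' @slot dead predicted dead-cell counts N(t).
#' @slot surviving predicted surviving counts N1(t).
#' @slot clamped logical; TRUE where the raw model left [0, N0] and the
#'   returned value was clamped.
#' @slot params the [KineticParams-class] used.
#' @slot landmarks named numeric: ldr50, mmt, absoluteDeath (s).
#'
#' @export
setClass("KineticsCurve",
  representation(
    times = "numeric",
    dead = "numeric",
    surviving = "numeric",
    clamped = "logical",
    params = "KineticParams",
    landmarks = "numeric"
  )
)

setValidity("KineticsCurve", function(object) {
  n <- length(object@times)
  if (length(object@dead) != n || length(object@surviving) != n ||
    length(object@clamped) != n) {
    return("times, dead, surviving and clamped must have equal length")
  }
  if (any(object@times <= 0)) {
    return("all times must be strictly positive")
  }
  TRUE
})

#' A CFU survival dataset
#'
#' One strain's plate-count survival experiment: exposure times, replicate
#' ids, the decimal dilution factor each count was read at, and the colony
#' count per ml of plated dilution. Rows with \code{time_s == 0} are the
#' unexposed controls that define N0 (100\% viability).
#'
#' @slot strain strain label.
#' @slot records data.frame with columns \code{time_s}, \code{replicate},
#'   \code{dilution_factor}, \code{cfu_per_ml} (colonies per ml of the plated
#'   dilution; multiply by \code{dilution_factor} to recover CFU/ml of the
#'   undiluted culture).
#' @slot platedVolumeMl volume plated per dish, ml.
#'
#' @seealso [survivalData()], [readSurvivalCSV()], [simulateDataset()]
#' @export
setClass("SurvivalData",
  representation(
    strain = "character",
    records = "data.frame",
    platedVolumeMl = "numeric"
  )
)

setValidity("SurvivalData", function(object) {
  req <- c("time_s", "replicate", "dilution_factor", "cfu_per_ml")
  miss <- setdiff(req, names(object@records))
  if (length(miss) > 0) {
    return(paste0("records is missing column(s): ", paste(miss, collapse = ", ")))
  }
  rec <- object@records
  if (nrow(rec) > 0) {
    if (any(!is.finite(rec$time_s)) || any(rec$time_s < 0)) {
      return("time_s must be finite and >= 0")
    }
    if (any(!is.finite(rec$cfu_per_ml)) || any(rec$cfu_per_ml < 0)) {
      return("cfu_per_ml must be finite and >= 0")
    }
    if (any(!is.finite(rec$dilution_factor)) || any(rec$dilution_factor <= 0)) {
      return("dilution_factor must be finite and > 0")
    }
  }
  if (!is.finite(object@platedVolumeMl) || object@platedVolumeMl <= 0) {
    return("platedVolumeMl must be positive")
  }
  TRUE
})

#' Least-squares fit of the log-time survival model
#'
#' Output of [fitSurvival()]: the straight-line fit of surviving counts
#' against ln(exposure time), the derived kinetic parameters, correlation
#' and determination coefficients, and mean-response ("confidence") plus
#' individual-observation ("fiducial"/prediction) bands.
#'
#' @slot strain strain label carried from the dataset.
#' @slot slope fitted slope of N1 on ln(t) (negative for survival data).
#' @slot intercept fitted intercept, the estimate of N0.
#' @slot ssmHat estimated specific speed of mortality, |slope|.
#' @slot cqmyHat estimated quantum mortality yield, ssmHat / Ea.
#' @slot corR Pearson correlation between ln(t) and N1 (signed).
#' @slot detR2 coefficient of determination R^2.
#' @slot confidence band confidence level (fraction).
#' @slot band data.frame per fitted point: time_s, ln_t, observed, fitted,
#'   conf_lo, conf_hi (mean response), pred_lo, pred_hi (fiducial).
#' @slot ciSlope confidence interval for the slope at \code{confidence}.
#' @slot mode count mode used: "absolute" (CFU/ml) or "normalized" (percent
#'   of control).
#' @slot flags character vector of diagnostic flags (e.g. negative fitted
#'   intercept).
#' @slot lmFit the underlying [stats::lm] object.
#'
#' @export
setClass("FitResult",
  representation(
    strain = "character",
    slope = "numeric",
    intercept = "numeric",
    ssmHat = "numeric",
    cqmyHat = "numeric",
    corR = "numeric",
    detR2 = "numeric",
    confidence = "numeric",
    band = "data.frame",
    ciSlope = "numeric",
    mode = "character",
    flags = "character",
    lmFit = "ANY"
  )
)

#' Design of a simulated plating experiment
#'
#' Fixes the full statistical design of one simulated UV-C exposure series:
#' the true kinetic parameters, the exposure-time grid, replication, the
#' serial-dilution scheme, the plate-count noise model and the seed.
#'
#' @slot trueK true specific speed of mortality (count per ln-second).
#' @slot trueN0 true initial population (CFU/ml scale).
#' @slot times exposure times, s.
#' @slot replicates independent replicate series.
#' @slot dilutionSteps number of decimal dilution steps available (the
#'   simulator may also plate undiluted).
#' @slot platedVolumeMl plated volume, ml.
#' @slot noiseModel one of "poisson", "poisson_lognormal", "none".
#' @slot overdispersionSigma lognormal sigma for "poisson_lognormal".
#' @slot fluenceRate lamp fluence rate, mJ/(s cm^2); metadata only.
#' @slot seed integer RNG seed (mandatory).
#'
#' @seealso [simulationDesign()], [simulateDataset()]
#' @export
setClass("SimulationDesign",
  representation(
    trueK = "numeric",
    trueN0 = "numeric",
    times = "numeric",
    replicates = "integer",
    dilutionSteps = "integer",
    platedVolumeMl = "numeric",
    noiseModel = "character",
    overdispersionSigma = "numeric",
    fluenceRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationDesign", function(object) {
  if (any(object@times <= 0)) {
    return("all exposure times must be strictly positive")
  }
  if (object@trueK <= 0 || object@trueN0 <= 0) {
    return("trueK and trueN0 must be positive")
  }
  if (object@replicates < 1L) {
    return("replicates must be >= 1")
  }
  if (object@dilutionSteps < 0L) {
    return("dilutionSteps must be >= 0")
  }
  if (!object@noiseModel %in% c("poisson", "poisson_lognormal", "none")) {
    return('noiseModel must be "poisson", "poisson_lognormal" or "none"')
  }
  if (length(object@seed) != 1L || is.na(object@seed)) {
    return("an explicit integer seed is mandatory")
  }
  TRUE
})
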