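## Corpuscular model: the photon is a particle crossing the genome matrix;
## the base density N*, cross-section sigma and slab thickness dx set the
## collision statistics, and the lethal impact number f(tu) couples them to
## the population-level mortality speed k.

#' Mean free path of a photon in the genome matrix
#'
#' Average distance a photon travels between base impacts,
#' l = 1 / (N* sigma) = 1 / Z.
#'
#' @param genome a [GenomeSpec-class].
#' @return cm.
#' @examples
#' meanFreePath(defaultEcoliGenome()) # ~8.47e-5 cm
#' @export
meanFreePath <- function(genome) {
  1 / macroscopicSection(genome)
}

#' Molecular excitation time
#'
#' Mean time between photon-base absorption events,
#' dt_i = l / c = 1 / (N* sigma c); a far briefer lapse than the minimum
#' mortality time.
#'
#' @param genome a [GenomeSpec-class].
#' @param constants a [PhysicalConstants-class].
#' @return s.
#' @examples
#' excitationTime(defaultEcoliGenome(), defaultConstants()) # ~2.825e-15 s
#' @export
excitationTime <- function(genome, constants = defaultConstants()) {
  1 / impactFrequency(genome, constants)
}

#' Impact frequency
#'
#' Number of photon-base impacts per unit time, f = N* sigma c, the
#' reciprocal of the excitation time.
#'
#' @inheritParams excitationTime
#' @return 1/s.
#' @export
impactFrequency <- function(genome, constants = defaultConstants()) {
  baseDensity(genome) * impactSection(genome) * lightSpeed(constants)
}

#' Absorbed fraction of a photon traversal
#'
#' Expected number of impacts per photon traversal of the genome slab.
#' Three algebraically equivalent forms are available:
#' \describe{
#'   \item{"density"}{delta = N* sigma dx (the canonical form)}
#'   \item{"area"}{delta = 2 Nj sigma / A_G}
#'   \item{"path"}{delta = dx / l (thickness over mean free path)}
#' }
#' This is the linear (expected-impact-count) form, which can exceed 1 for
#' thick or dense targets; the Beer-Lambert absorption probability
#' 1 - exp(-Z dx) is available separately as
#' [absorbedProbabilityBeerLambert()] for comparison only.
#'
#' @param genome a [GenomeSpec-class].
#' @param form which equivalent expression to evaluate.
#' @return dimensionless expected impact count per traversal.
#' @examples
#' absorbedFraction(defaultEcoliGenome()) # ~0.6506
#' @export
absorbedFraction <- function(genome, form = c("density", "area", "path")) {
  form <- match.arg(form)
  switch(form,
    density = baseDensity(genome) * impactSection(genome) *
      genomeThickness(genome),
    area = 2 * basePairs(genome) * impactSection(genome) / genomeArea(genome),
    path = genomeThickness(genome) / meanFreePath(genome)
  )
}

#' Beer-Lambert absorption probability (comparison variant)
#'
#' Probability that a photon traversing the slab is absorbed at least once,
#' 1 - exp(-Z dx), under exponential attenuation. Not used by the kinetic
#' models, which work with the linear expected impact count
#' [absorbedFraction()].
#'
#' @param genome a [GenomeSpec-class].
#' @return probability in [0, 1).
#' @export
absorbedProbabilityBeerLambert <- function(genome) {
  1 - exp(-macroscopicSection(genome) * genomeThickness(genome))
}

#' Lethal impact number
#'
#' Number of photon impacts accumulated over the minimum mortality time,
#' f(tu) = N* sigma c / k. Under the proportionality hypothesis f(tu) is
#' approximately the number of genome base pairs Nj. \code{ssmFromLin} is
#' the exact inverse, recovering k = N* sigma c / f(tu).
#'
#' @param k specific speed of mortality, 1/s.
#' @param fTu lethal impact number (dimensionless count).
#' @param genome a [GenomeSpec-class].
#' @param constants a [PhysicalConstants-class].
#' @return \code{lethalImpactNumber}: f(tu); \code{ssmFromLin}: k (1/s).
#' @examples
#' g <- defaultEcoliGenome()
#' lethalImpactNumber(6.8065e7, g) # ~5.2e6, i.e. ~Nj
#' @export
lethalImpactNumber <- function(k, genome, constants = defaultConstants()) {
  if (any(k <= 0)) stop("k must be positive")
  impactFrequency(genome, constants) / k
}

#' @rdname lethalImpactNumber
#' @export
ssmFromLin <- function(fTu, genome, constants = defaultConstants()) {
  if (any(fTu <= 0)) stop("fTu must be positive")
  impactFrequency(genome, constants) / fTu
}

#' Unitary mortality identity
#'
#' N = N* sigma c / (f(tu) k): equals exactly 1 when k and f(tu) are coupled
#' through the lethal-impact relation, expressing that exactly one cell dies
#' over the minimum mortality time.
#'
#' @inheritParams lethalImpactNumber
#' @return dimensionless; 1 under consistent coupling.
#' @export
unitaryMortality <- function(k, fTu, genome, constants = defaultConstants()) {
  impactFrequency(genome, constants) / (fTu * k)
}

#' Mortality and survival curves from impact bookkeeping
#'
#' The corpuscular form of the kinetic curves:
#' N(t) = [N* sigma c / f(tu)] ln(t) and N1(t) = N0 - N(t). Pointwise
#' identical to [mortalityAt()]/[survivalAt()] with k = N* sigma c / f(tu).
#'
#' @param t exposure time(s), s.
#' @param fTu lethal impact number.
#' @param n0 initial population.
#' @param genome a [GenomeSpec-class].
#' @param constants a [PhysicalConstants-class].
#' @param clamp clamp into [0, N0]? Default TRUE.
#' @return count(s).
#' @export
mortalityFromImpacts <- function(t, fTu, genome,
                                 constants = defaultConstants(),
                                 n0 = Inf, clamp = TRUE) {
  k <- ssmFromLin(fTu, genome, constants)
  .checkTimes(t)
  n <- k * log(t)
  if (clamp) n <- pmin(pmax(n, 0), n0)
  n
}

#' @rdname mortalityFromImpacts
#' @export
survivalFromImpacts <- function(t, fTu, n0, genome,
                                constants = defaultConstants(),
                                clamp = TRUE) {
  k <- ssmFromLin(fTu, genome, constants)
  .checkTimes(t)
  n1 <- n0 - k * log(t)
  if (clamp) n1 <- pmin(pmax(n1, 0), n0)
  n1
}

#' Theoretical specific speed of mortality
#'
#' Under the proportionality hypothesis (f(tu) ~ Nj) the lethal impact number
#' cancels the base count and the mortality speed reduces to a pure
#' geometry/speed ratio: k = 2 sigma c / VG.
#'
#' @param genome a [GenomeSpec-class].
#' @param constants a [PhysicalConstants-class].
#' @return 1/s.
#' @examples
#' theoreticalSSM(defaultEcoliGenome()) # ~6.8065e7
#' @export
theoreticalSSM <- function(genome, constants = defaultConstants()) {
  2 * impactSection(genome) * lightSpeed(constants) / genomeVolume(genome)
}

#' Theoretical minimum mortality time
#'
#' Reciprocal of [theoreticalSSM()]; of the order of the 1e-8 s half-life of
#' an excited base.
#'
#' @inheritParams theoreticalSSM
#' @return s.
#' @export
theoreticalMMT <- function(genome, constants = defaultConstants()) {
  1 / theoreticalSSM(genome, constants)
}

#' Theoretical cell quantum mortality yield
#'
#' phi_mu = 2 sigma lambda / (VG n0 h): the yield implied by the
#' proportionality hypothesis, consistent with k = phi_mu Ea.
#'
#' @inheritParams theoreticalSSM
#' @return mol/(erg s).
#' @examples
#' theoreticalCQMY(defaultEcoliGenome()) # ~1.4435e-5
#' @export
theoreticalCQMY <- function(genome, constants = defaultConstants()) {
  2 * impactSection(genome) * wavelength(constants) /
    (genomeVolume(genome) * avogadro(constants) * planck(constants))
}

#' Theory table of the corpuscular model
#'
#' All closed-form predictions in one named list: base density N*, mean free
#' path, excitation time, impact frequency, absorbed fraction delta,
#' macroscopic section Z, and the theoretical k, tu and phi_mu.
#'
#' @inheritParams theoreticalSSM
#' @return named list of nine numeric quantities.
#' @examples
#' unlist(theoryReport(defaultEcoliGenome()))
#' @export
theoryReport <- function(genome = defaultEcoliGenome(),
                         constants = defaultConstants()) {
  list(
    base_density_n_star = baseDensity(genome),
    mean_free_path_cm = meanFreePath(genome),
    excitation_time_s = excitationTime(genome, constants),
    impact_frequency_per_s = impactFrequency(genome, constants),
    absorbed_fraction_delta = absorbedFraction(genome),
    macroscopic_section_z_per_cm = macroscopicSection(genome),
    ssm_k_per_s = theoreticalSSM(genome, constants),
    mmt_tu_s = theoreticalMMT(genome, constants),
    cqmy_phi_mu_mol_per_erg_s = theoreticalCQMY(genome, constants)
  )
}

#' Monte Carlo oracle for photon free-path statistics
#'
#' Samples the collision process the analytic formulas summarise: free-path
#' lengths are exponential with rate Z = N* sigma, and the impact count per
#' traversal of the slab of thickness dx is Poisson with mean Z dx = delta.
#' Intended as an independent stochastic check of [meanFreePath()],
#' [excitationTime()] and [absorbedFraction()]; it assumes homogeneous,
#' independent, immovable targets and is not a transport engine.
#'
#' @param genome a [GenomeSpec-class].
#' @param constants a [PhysicalConstants-class].
#' @param nPhotons number of simulated photons (>= 1).
#' @param seed mandatory integer seed; results are bit-identical per seed.
#' @return list with \code{meanPath}/\code{sePath} (cm),
#'   \code{meanExcitationTime}/\code{seExcitationTime} (s),
#'   \code{meanImpacts}/\code{seImpacts} (per traversal), and
#'   \code{nPhotons}.
#' @examples
#' mc <- mcImpactOracle(defaultEcoliGenome(), nPhotons = 1e4, seed = 1)
#' mc$meanImpacts # ~0.65
#' @export
mcImpactOracle <- function(genome, constants = defaultConstants(),
                           nPhotons, seed) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  nPhotons <- as.integer(nPhotons)
  if (nPhotons < 1L) stop("nPhotons must be >= 1")
  z <- macroscopicSection(genome)
  set.seed(as.integer(seed))
  paths <- stats::rexp(nPhotons, rate = z)
  impacts <- stats::rpois(nPhotons, lambda = z * genomeThickness(genome))
  c0 <- lightSpeed(constants)
  list(
    meanPath = mean(paths),
    sePath = stats::sd(paths) / sqrt(nPhotons),
    meanExcitationTime = mean(paths) / c0,
    seExcitationTime = stats::sd(paths) / c0 / sqrt(nPhotons),
    meanImpacts = mean(impacts),
    seImpacts = stats::sd(impacts) / sqrt(nPhotons),
    nPhotons = nPhotons
  )
}
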