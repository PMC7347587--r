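## Proportionality hypothesis: the number of genome base pairs is
## proportional to the lethal impact number, Nj / f(tu) =
## phi_mu n0 h VG / (2 sigma lambda), with a coefficient near one. Its
## reciprocal bookkeeping gives Dp, the photons needed per pyrimidine dimer.

#' Genome/wavelength dimer constant
#'
#' n0 h VG / (2 sigma lambda): the constant that every
#' (coefficient, photons-per-dimer) pair multiplies to. Equals the
#' reciprocal of the theoretical quantum mortality yield
#' (about 6.9275e4 for the reference E. coli genome at 253.7 nm).
#'
#' @param genome a [GenomeSpec-class].
#' @param constants a [PhysicalConstants-class].
#' @return dimensionless constant.
#' @export
dimerConstant <- function(genome = defaultEcoliGenome(),
                          constants = defaultConstants()) {
  avogadro(constants) * planck(constants) * genomeVolume(genome) /
    (2 * impactSection(genome) * wavelength(constants))
}

#' Proportionality coefficient Nj / f(tu)
#'
#' The ratio of base pairs to the lethal impact number implied by a quantum
#' mortality yield: coefficient = phi_mu n0 h VG / (2 sigma lambda), i.e.
#' phi_mu divided by the theoretical yield. A value near one supports the
#' proportionality hypothesis.
#'
#' @param phiMu cell quantum mortality yield, mol/(erg s).
#' @param genome a [GenomeSpec-class].
#' @param constants a [PhysicalConstants-class].
#' @return dimensionless coefficient.
#' @examples
#' proportionalityCoefficient(theoreticalCQMY(defaultEcoliGenome())) # 1
#' @export
proportionalityCoefficient <- function(phiMu, genome = defaultEcoliGenome(),
                                       constants = defaultConstants()) {
  if (any(phiMu <= 0)) stop("phiMu must be positive")
  phiMu * dimerConstant(genome, constants)
}

#' Photons per pyrimidine dimer
#'
#' Dp = 1 / phi_mu in the model's numerical convention: the number of photon
#' absorptions needed to form one dimer. Dp >> 1 signals multi-impact
#' kinetics.
#'
#' @param phiMu cell quantum mortality yield.
#' @return photons per dimer (dimensionless count).
#' @examples
#' photonsPerDimer(1.4435e-5) # ~69276
#' @export
photonsPerDimer <- function(phiMu) {
  if (any(phiMu <= 0)) stop("phiMu must be positive")
  1 / phiMu
}

#' Quantum mortality yield from a dimer/photon budget
#'
#' phi_mu = D-hat_p / gamma_abs: formed dimers over absorbed photons per
#' cell. The photon budget gamma_abs is never measured here; both arguments
#' are caller-supplied.
#'
#' @param dimersFormed number of dimers formed, D-hat_p.
#' @param photonsAbsorbed number of photons absorbed per cell, gamma_abs.
#' @return phi_mu.
#' @export
cqmyFromBudget <- function(dimersFormed, photonsAbsorbed) {
  if (any(photonsAbsorbed == 0)) stop("photonsAbsorbed must be non-zero")
  dimersFormed / photonsAbsorbed
}

#' Complete proportionality-table rows
#'
#' From each entry's proportionality coefficient \emph{or} photons-per-dimer
#' count (exactly one of the two), completes the full row: coefficient,
#' phi_mu, Dp, and a multi-impact flag (Dp > 1). All rows are completed at
#' the constants' wavelength (253.7 nm by default); any per-row wavelength
#' annotation in \code{entries$wavelength_nm} is carried through as
#' annotation only.
#'
#' @param entries data.frame with columns \code{label} and exactly one
#'   non-NA of \code{coefficient} / \code{dp} per row; an optional
#'   \code{wavelength_nm} column is kept as annotation.
#' @param genome a [GenomeSpec-class].
#' @param constants a [PhysicalConstants-class].
#' @return data.frame: label, wavelength_nm (annotation),
#'   wavelength_used_nm, coefficient, phi_mu, dp, dp_rounded, multi_impact.
#' @examples
#' proportionalityReport(data.frame(label = "polA-", coefficient = 1.0613))
#' @export
proportionalityReport <- function(entries, genome = defaultEcoliGenome(),
                                  constants = defaultConstants()) {
  entries <- as.data.frame(entries)
  if (!"label" %in% names(entries)) stop("entries must have a 'label' column")
  if (!"coefficient" %in% names(entries)) entries$coefficient <- NA_real_
  if (!"dp" %in% names(entries)) entries$dp <- NA_real_
  hasCoef <- !is.na(entries$coefficient)
  hasDp <- !is.na(entries$dp)
  bad <- which(hasCoef == hasDp)
  if (length(bad) > 0) {
    stop(sprintf(
      "each entry needs exactly one of coefficient/dp; offending row(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  konst <- dimerConstant(genome, constants)
  coefficient <- ifelse(hasCoef, entries$coefficient, konst / entries$dp)
  dp <- ifelse(hasDp, entries$dp, konst / entries$coefficient)
  phiMu <- coefficient / konst
  data.frame(
    label = entries$label,
    wavelength_nm = if ("wavelength_nm" %in% names(entries)) {
      entries$wavelength_nm
    } else {
      NA_real_
    },
    wavelength_used_nm = wavelength(constants) * 1e7,
    coefficient = coefficient,
    phi_mu = phiMu,
    dp = dp,
    dp_rounded = round(dp),
    multi_impact = dp > 1
  )
}

#' Published E. coli proportionality coefficients
#'
#' The ten proportionality-coefficient / photons-per-dimer rows reported for
#' E. coli strains (six measured with a 253.7 nm lamp plus four taken from
#' the UV-inactivation literature). \code{wavelength_nm} is the wavelength
#' annotation attached to each source; the internal consistency
#' coefficient x Dp = n0 h VG / (2 sigma lambda) holds for every row at
#' 253.7 nm, which is therefore the wavelength used in recomputations.
#'
#' @return data.frame: label, source, wavelength_nm, coefficient,
#'   dp_printed.
#' @export
ecoliProportionalityTable <- function() {
  data.frame(
    label = c(
      "polA-", "ATCC25922", "DH5alpha thy-", "HfrH180", "W3110", "polA+",
      "K12 (1981)", "unnamed (Harm)", "IFO 3301", "K12 (wild type)"
    ),
    source = c(rep("experimental", 6), rep("literature", 4)),
    wavelength_nm = c(rep(253.7, 6), 260, 254, 254, 254),
    coefficient = c(
      1.0613, 0.8862, 0.6260, 0.8346, 0.3538, 0.3810,
      1.0578, 1.4076, 2.7709, 4.4335
    ),
    dp_printed = c(
      65274, 78168, 110664, 82994, 195771, 181798,
      65488, 49213, 25000, 15625
    )
  )
}
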