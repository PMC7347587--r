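## Unit system is CGS throughout (erg, cm, s), matching the reference
## parameterisation of the models; no conversion layer is provided.

.UVC_BAND_CM <- c(2.0e-5, 2.8e-5)

#' Construct a PhysicalConstants object
#'
#' @param avogadro Avogadro's constant, 1/mol.
#' @param planck Planck's constant, erg s.
#' @param lightSpeed speed of light, cm/s.
#' @param wavelength lamp wavelength, cm. A value outside the UV-C band
#'   (200-280 nm, i.e. 2.0e-5-2.8e-5 cm) triggers a warning, not an error.
#' @return a [PhysicalConstants-class] object.
#' @examples
#' physicalConstants(6.0225e23, 6.6256e-27, 2.9979e10, 2.537e-5)
#' @export
physicalConstants <- function(avogadro, planck, lightSpeed, wavelength) {
  obj <- new("PhysicalConstants",
    avogadro = as.numeric(avogadro), planck = as.numeric(planck),
    lightSpeed = as.numeric(lightSpeed), wavelength = as.numeric(wavelength)
  )
  if (wavelength < .UVC_BAND_CM[1] || wavelength > .UVC_BAND_CM[2]) {
    warning(sprintf(
      "wavelength %.4g cm is outside the UV-C band (%.1e-%.1e cm)",
      wavelength, .UVC_BAND_CM[1], .UVC_BAND_CM[2]
    ))
  }
  obj
}

#' Reference physical constants
#'
#' The canonical constants of the models: Avogadro's number, Planck's
#' constant, the speed of light, and the emission wavelength of a
#' low-pressure mercury germicidal lamp (253.7 nm). These 4-5
#' significant-figure CGS values are the package's fixed reference set; no
#' CODATA-updated values are substituted.
#'
#' @return a [PhysicalConstants-class] with n0 = 6.0225e23 /mol,
#'   h = 6.6256e-27 erg s, c = 2.9979e10 cm/s, lambda = 2.537e-5 cm.
#' @examples
#' cc <- defaultConstants()
#' wavelength(cc)
#' @export
defaultConstants <- function() {
  physicalConstants(
    avogadro = 6.0225e23,
    planck = 6.6256e-27,
    lightSpeed = 2.9979e10,
    wavelength = 2.537e-5
  )
}

#' Construct a GenomeSpec
#'
#' @param basePairs number of base pairs Nj (bp).
#' @param genomeVolume genome volume VG, cm^3.
#' @param genomeThickness mean genome thickness dx, cm.
#' @param impactSection effective impact cross-section sigma, cm^2.
#' @param label strain/species label.
#' @return a [GenomeSpec-class].
#' @export
genomeSpec <- function(basePairs, genomeVolume, genomeThickness,
                       impactSection, label = "genome") {
  new("GenomeSpec",
    basePairs = as.numeric(basePairs),
    genomeVolume = as.numeric(genomeVolume),
    genomeThickness = as.numeric(genomeThickness),
    impactSection = as.numeric(impactSection),
    label = as.character(label)
  )
}

#' Reference E. coli genome geometry
#'
#' Mean genome of \emph{Escherichia coli} as a photon target: 5.2 Mbp,
#' nucleoid volume 4.3716e-13 cm^3, mean thickness 5.5111e-5 cm, and an
#' effective impact cross-section per base of 4.9627e-16 cm^2.
#'
#' @return a [GenomeSpec-class].
#' @examples
#' g <- defaultEcoliGenome()
#' baseDensity(g) # 2 * 5.2e6 / 4.3716e-13
#' @export
defaultEcoliGenome <- function() {
  genomeSpec(
    basePairs = 5.2e6,
    genomeVolume = 4.3716e-13,
    genomeThickness = 5.5111e-5,
    impactSection = 4.9627e-16,
    label = "E. coli (mean)"
  )
}

#' Activation energy per mole of photons
#'
#' One einstein (a mole of photons) at the lamp wavelength carries energy
#' Ea = n0 h c / lambda (erg/mol). This is the energy scale that links the
#' quantum mortality yield to the specific speed of mortality, k = phi_mu Ea.
#'
#' @param constants a [PhysicalConstants-class].
#' @return Ea in erg/mol.
#' @examples
#' activationEnergy(defaultConstants()) # ~4.715e12 erg/mol
#' @export
activationEnergy <- function(constants) {
  stopifnot(is(constants, "PhysicalConstants"))
  constants@avogadro * constants@planck * constants@lightSpeed /
    constants@wavelength
}

#' Energy of a single photon
#'
#' h c / lambda in erg; the per-photon counterpart of [activationEnergy()],
#' which is per mole of photons.
#'
#' @param constants a [PhysicalConstants-class].
#' @return erg per photon.
#' @export
photonEnergy <- function(constants) {
  stopifnot(is(constants, "PhysicalConstants"))
  constants@planck * constants@lightSpeed / constants@wavelength
}

## ---- accessors ----

#' @rdname PhysicalConstants-class
#' @export
setMethod("wavelength", "PhysicalConstants", function(object) object@wavelength)

#' @rdname PhysicalConstants-class
#' @param x a \code{PhysicalConstants}.
#' @export
avogadro <- function(x) {
  stopifnot(is(x, "PhysicalConstants"))
  x@avogadro
}

#' @rdname PhysicalConstants-class
#' @export
planck <- function(x) {
  stopifnot(is(x, "PhysicalConstants"))
  x@planck
}

#' @rdname PhysicalConstants-class
#' @export
lightSpeed <- function(x) {
  stopifnot(is(x, "PhysicalConstants"))
  x@lightSpeed
}

#' @rdname GenomeSpec-class
#' @export
setMethod("basePairs", "GenomeSpec", function(object) object@basePairs)

#' @rdname GenomeSpec-class
#' @export
setMethod("genomeVolume", "GenomeSpec", function(object) object@genomeVolume)

#' @rdname GenomeSpec-class
#' @param x a \code{GenomeSpec}.
#' @export
genomeThickness <- function(x) {
  stopifnot(is(x, "GenomeSpec"))
  x@genomeThickness
}

#' @rdname GenomeSpec-class
#' @export
impactSection <- function(x) {
  stopifnot(is(x, "GenomeSpec"))
  x@impactSection
}

#' @rdname baseDensity
#' @export
setMethod("baseDensity", "GenomeSpec", function(object) {
  2 * object@basePairs / object@genomeVolume
})

#' @rdname genomeArea
#' @export
setMethod("genomeArea", "GenomeSpec", function(object) {
  object@genomeVolume / object@genomeThickness
})

#' @rdname macroscopicSection
#' @export
setMethod("macroscopicSection", "GenomeSpec", function(object) {
  baseDensity(object) * object@impactSection
})

setMethod("show", "PhysicalConstants", function(object) {
  cat("PhysicalConstants (CGS)\n")
  cat(sprintf("  n0 (Avogadro):  %.4e 1/mol\n", object@avogadro))
  cat(sprintf("  h  (Planck):    %.4e erg s\n", object@planck))
  cat(sprintf("  c  (light):     %.4e cm/s\n", object@lightSpeed))
  cat(sprintf(
    "  lambda:         %.4e cm (%.1f nm)\n",
    object@wavelength, object@wavelength * 1e7
  ))
  cat(sprintf("  Ea = n0 h c / lambda = %.4e erg/mol\n", activationEnergy(object)))
  invisible(NULL)
})

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec:", object@label, "\n")
  cat(sprintf("  Nj (base pairs):      %.4e bp\n", object@basePairs))
  cat(sprintf("  VG (volume):          %.4e cm^3\n", object@genomeVolume))
  cat(sprintf("  dx (thickness):       %.4e cm\n", object@genomeThickness))
  cat(sprintf("  sigma (impact sect.): %.4e cm^2\n", object@impactSection))
  cat(sprintf("  N* = 2Nj/VG:          %.4e bases/cm^3\n", baseDensity(object)))
  cat(sprintf("  Z  = N* sigma:        %.4e 1/cm\n", macroscopicSection(object)))
  invisible(NULL)
})
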