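#' @rdname PhysicalConstants-class
#' @param object a \code{PhysicalConstants}, \code{GenomeSpec} or other
#'   uvckin object.
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @rdname GenomeSpec-class
#' @param object a \code{GenomeSpec}.
#' @export
setGeneric("basePairs", function(object) standardGeneric("basePairs"))

#' @rdname GenomeSpec-class
#' @export
setGeneric("genomeVolume", function(object) standardGeneric("genomeVolume"))

#' Base density N* of a genome
#'
#' Number of nitrogenous bases per unit genome volume, N* = 2 Nj / VG
#' (the factor 2 counts both strands).
#'
#' @param object a [GenomeSpec-class].
#' @return bases per cm^3.
#' @examples
#' baseDensity(defaultEcoliGenome()) # ~2.379e19 bases/cm^3
#' @export
setGeneric("baseDensity", function(object) standardGeneric("baseDensity"))

#' Genome area A_G
#'
#' Cross-sectional area of the genome slab, A_G = VG / dx, so that
#' A_G dx / VG = 1.
#'
#' @param object a [GenomeSpec-class].
#' @return cm^2.
#' @export
setGeneric("genomeArea", function(object) standardGeneric("genomeArea"))

#' Effective macroscopic section Z
#'
#' Z = N* sigma, the inverse of the mean free path (cm^-1).
#'
#' @param object a [GenomeSpec-class].
#' @return cm^-1.
#' @export
setGeneric("macroscopicSection",
  function(object) standardGeneric("macroscopicSection")
)

#' @rdname KineticParams-class
#' @param object a \code{KineticParams}.
#' @export
setGeneric("ssm", function(object) standardGeneric("ssm"))

#' Cell quantum mortality yield
#'
#' The efficiency with which absorbed light converts into cell mortality:
#' dead cells per absorbed einstein per unit time, phi_mu = k / Ea
#' (mol/(erg s)).
#'
#' @param object a [KineticParams-class].
#' @export
setGeneric("cqmy", function(object) standardGeneric("cqmy"))

#' @rdname KineticParams-class
#' @export
setGeneric("initialCells", function(object) standardGeneric("initialCells"))

#' @rdname SurvivalData-class
#' @param object a \code{SurvivalData}.
#' @export
setGeneric("strainLabel", function(object) standardGeneric("strainLabel"))

#' @rdname SurvivalData-class
#' @export
setGeneric("records", function(object) standardGeneric("records"))
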