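## Physical model: mortality grows as k * ln(t). Time enters the logarithm
## as the dimensionless numeric value of time-in-seconds (t = 1 s gives
## N = 0), the operational convention under which the survival fits are done.

#' Construct kinetic parameters
#'
#' Exactly one of \code{k} (specific speed of mortality) or \code{phiMu}
#' (cell quantum mortality yield) must be given; the other is derived through
#' k = phi_mu * Ea, so the pair can never be stored inconsistently.
#'
#' @param k specific speed of mortality, 1/s (count per ln-second).
#' @param phiMu cell quantum mortality yield, mol/(erg s).
#' @param n0 initial population N0 (count).
#' @param constants a [PhysicalConstants-class]; sets Ea.
#' @return a [KineticParams-class].
#' @examples
#' p <- kineticParams(k = 6.8065e7, n0 = 3e8)
#' cqmy(p)
#' @export
kineticParams <- function(k = NULL, phiMu = NULL, n0,
                          constants = defaultConstants()) {
  ea <- activationEnergy(constants)
  if (is.null(k) == is.null(phiMu)) {
    stop("supply exactly one of 'k' or 'phiMu'")
  }
  if (is.null(k)) {
    if (phiMu <= 0) stop("phiMu must be positive")
    k <- phiMu * ea
  }
  if (k <= 0) stop("k must be positive")
  new("KineticParams",
    ssm = as.numeric(k), activationEnergy = ea,
    initialCells = as.numeric(n0)
  )
}

#' @rdname KineticParams-class
#' @export
setMethod("ssm", "KineticParams", function(object) object@ssm)

#' @rdname cqmy
#' @export
setMethod("cqmy", "KineticParams", function(object) {
  object@ssm / object@activationEnergy
})

#' @rdname KineticParams-class
#' @export
setMethod("initialCells", "KineticParams", function(object) object@initialCells)

setMethod("show", "KineticParams", function(object) {
  cat("KineticParams\n")
  cat(sprintf("  k (SSM):       %.4e 1/s\n", object@ssm))
  cat(sprintf("  Ea:            %.4e erg/mol\n", object@activationEnergy))
  cat(sprintf("  phi_mu (cQMY): %.4e mol/(erg s)\n", cqmy(object)))
  cat(sprintf("  N0:            %.4e\n", object@initialCells))
  if (object@initialCells > 0) {
    cat(sprintf("  LDR50:         %.4g s\n", ldr50(object)))
    cat(sprintf("  MMT (tu):      %.4e s\n", minimumMortalityTime(object)))
  }
  invisible(NULL)
})

.checkTimes <- function(t) {
  if (any(!is.finite(t))) stop("exposure times must be finite")
  bad <- which(t <= 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "logarithm undefined: exposure time must be > 0 (offending index %s)",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Dead cells after exposure time t
#'
#' N(t) = k ln(t): the mortality curve of the log-time model. For t < 1 s
#' the raw model is negative (the pre-unitary regime); with \code{clamp}
#' (the default) values are clamped into [0, N0].
#'
#' @param t exposure time(s), s; must be > 0.
#' @param params a [KineticParams-class].
#' @param clamp clamp the result into [0, N0]? Default TRUE.
#' @return dead-cell count(s) N.
#' @examples
#' p <- kineticParams(k = 2, n0 = 10)
#' mortalityAt(exp(1), p) # = k
#' @export
mortalityAt <- function(t, params, clamp = TRUE) {
  .checkTimes(t)
  n <- params@ssm * log(t)
  if (clamp) n <- pmin(pmax(n, 0), params@initialCells)
  n
}

#' Surviving cells after exposure time t
#'
#' N1(t) = N0 - k ln(t). With \code{clamp} (default) survivors never go
#' below zero; the raw (possibly negative) line is what regression operates
#' on, so fitting code passes \code{clamp = FALSE}.
#'
#' @inheritParams mortalityAt
#' @return surviving count(s) N1.
#' @export
survivalAt <- function(t, params, clamp = TRUE) {
  .checkTimes(t)
  n1 <- params@initialCells - params@ssm * log(t)
  if (clamp) n1 <- pmin(pmax(n1, 0), params@initialCells)
  n1
}

#' Convert between the mortality yield and the mortality speed
#'
#' k = phi_mu * Ea = phi_mu * n0 h c / lambda, and inversely
#' phi_mu = k lambda / (n0 h c). The two functions are exact algebraic
#' inverses of each other.
#'
#' @param phiMu cell quantum mortality yield, mol/(erg s).
#' @param k specific speed of mortality, 1/s.
#' @param constants a [PhysicalConstants-class].
#' @return \code{ssmFromCqmy}: k (1/s); \code{cqmyFromSsm}: phi_mu
#'   (mol/(erg s)).
#' @examples
#' ssmFromCqmy(1.4435e-5) # ~6.8065e7 1/s
#' @export
ssmFromCqmy <- function(phiMu, constants = defaultConstants()) {
  if (any(phiMu <= 0)) stop("phiMu must be positive")
  phiMu * activationEnergy(constants)
}

#' @rdname ssmFromCqmy
#' @export
cqmyFromSsm <- function(k, constants = defaultConstants()) {
  if (any(k <= 0)) stop("k must be positive")
  k / activationEnergy(constants)
}

.expGuard <- function(lnT, what) {
  if (lnT > log(.Machine$double.xmax)) {
    warning(sprintf(
      "%s is beyond representable time (ln t = %.4g); returning Inf",
      what, lnT
    ))
    return(structure(Inf, log_time = lnT))
  }
  exp(lnT)
}

#' Half-lethal exposure time (LDR50)
#'
#' The exposure time at which dead and surviving cells are equal (half the
#' initial population): t = exp(N0 / (2k)). Computed in log space; if the
#' exponent exceeds the representable range, Inf is returned with the
#' \code{log_time} attribute carrying ln(t).
#'
#' @param params a [KineticParams-class] with N0 > 0.
#' @return time in s.
#' @examples
#' ldr50(kineticParams(k = 1, n0 = 2)) # e
#' @export
ldr50 <- function(params) {
  if (params@initialCells <= 0) stop("N0 must be positive for LDR50")
  .expGuard(params@initialCells / (2 * params@ssm), "LDR50")
}

#' Minimum mortality time (MMT)
#'
#' The minimal exposure producing one dead cell, tu = 1/k; equivalently
#' lambda / (phi_mu n0 h c).
#'
#' @param params a [KineticParams-class].
#' @return tu in s.
#' @export
minimumMortalityTime <- function(params) {
  1 / params@ssm
}

#' Absolute death time
#'
#' The time T = exp(N0 / k) at which predicted survivors reach zero.
#' T equals LDR50 squared. Overflow handled as in [ldr50()].
#'
#' @param params a [KineticParams-class] with N0 > 0.
#' @return T in s.
#' @export
absoluteDeathTime <- function(params) {
  if (params@initialCells <= 0) stop("N0 must be positive for absolute death time")
  .expGuard(params@initialCells / params@ssm, "absolute death time")
}

#' Evaluate the mortality and survival curves on a time grid
#'
#' Vectorised evaluation of N(t) and N1(t) with conservation
#' (N + N1 = N0 before clamping) and per-point clamping flags, plus the
#' landmark times LDR50, MMT and the absolute death time.
#'
#' @param times exposure times, s; all > 0.
#' @param params a [KineticParams-class].
#' @param clamp clamp curves into [0, N0] (default TRUE); flagged points are
#'   recorded either way.
#' @return a [KineticsCurve-class].
#' @examples
#' p <- kineticParams(k = 5e7, n0 = 3e8)
#' cv <- predictCurve(seq(30, 300, 30), p)
#' as.data.frame(cv)
#' @export
predictCurve <- function(times, params, clamp = TRUE) {
  .checkTimes(times)
  rawDead <- params@ssm * log(times)
  n0 <- params@initialCells
  clamped <- rawDead < 0 | rawDead > n0
  dead <- if (clamp) pmin(pmax(rawDead, 0), n0) else rawDead
  surv <- if (clamp) pmin(pmax(n0 - rawDead, 0), n0) else n0 - rawDead
  landmarks <- c(
    ldr50 = if (n0 > 0) suppressWarnings(ldr50(params)) else NA_real_,
    mmt = minimumMortalityTime(params),
    absoluteDeath = if (n0 > 0) {
      suppressWarnings(absoluteDeathTime(params))
    } else {
      NA_real_
    }
  )
  new("KineticsCurve",
    times = as.numeric(times), dead = as.numeric(dead),
    surviving = as.numeric(surv), clamped = clamped,
    params = params, landmarks = landmarks
  )
}

#' @describeIn KineticsCurve-class tabular view: t_s, ln_t, N_dead,
#'   N1_surviving, clamped.
#' @param x a \code{KineticsCurve}.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "KineticsCurve", function(x, ...) {
  data.frame(
    t_s = x@times, ln_t = log(x@times), N_dead = x@dead,
    N1_surviving = x@surviving, clamped = x@clamped
  )
})

setMethod("show", "KineticsCurve", function(object) {
  cat(sprintf("KineticsCurve over %d times\n", length(object@times)))
  cat(sprintf(
    "  landmarks: LDR50 = %.4g s, MMT = %.4g s, absolute death = %.4g s\n",
    object@landmarks["ldr50"], object@landmarks["mmt"],
    object@landmarks["absoluteDeath"]
  ))
  print(utils::head(as.data.frame(object), 6))
  if (length(object@times) > 6) cat("  ...\n")
  invisible(NULL)
})
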