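#' Construct a SurvivalData object
#'
#' @param strain strain label.
#' @param records data.frame with columns \code{time_s}, \code{replicate},
#'   \code{dilution_factor}, \code{cfu_per_ml}. Rows with \code{time_s == 0}
#'   are unexposed controls.
#' @param platedVolumeMl plated volume per dish, ml (default 1).
#' @return a [SurvivalData-class].
#' @export
survivalData <- function(strain, records, platedVolumeMl = 1) {
  new("SurvivalData",
    strain = as.character(strain),
    records = as.data.frame(records),
    platedVolumeMl = as.numeric(platedVolumeMl)
  )
}

#' @rdname SurvivalData-class
#' @export
setMethod("strainLabel", "SurvivalData", function(object) object@strain)

#' @rdname SurvivalData-class
#' @export
setMethod("records", "SurvivalData", function(object) object@records)

setMethod("show", "SurvivalData", function(object) {
  rec <- object@records
  nCtrl <- sum(rec$time_s == 0)
  cat(sprintf(
    "SurvivalData: %s (%d records, %d controls, %d exposure times)\n",
    object@strain, nrow(rec), nCtrl, length(unique(rec$time_s[rec$time_s > 0]))
  ))
  invisible(NULL)
})

#' Convert plate counts to surviving-cell numbers
#'
#' Back-calculates survivors from dilution plating. In \code{"absolute"}
#' mode each record's survivors are
#' N1 = cfu_per_ml * dilution_factor (CFU/ml of the undiluted culture), and
#' N0 is the mean over the \code{time_s == 0} controls. In
#' \code{"normalized"} mode N1 is expressed as percent of the control
#' (N0 = 100), the convention under which unexposed cultures are 100\%
#' viability.
#'
#' @param dataset a [SurvivalData-class].
#' @param mode "absolute" (CFU/ml) or "normalized" (percent of control).
#' @return list with \code{data} (data.frame time_s, replicate, n1),
#'   \code{n0}, \code{mode}, \code{strain}.
#' @examples
#' d <- simulateDataset(simulationDesign(seed = 1))
#' head(countsToSurvivors(d)$data)
#' @export
countsToSurvivors <- function(dataset, mode = c("absolute", "normalized")) {
  mode <- match.arg(mode)
  rec <- records(dataset)
  ctrl <- rec[rec$time_s == 0, , drop = FALSE]
  if (nrow(ctrl) == 0) {
    stop(sprintf(
      "no control (time_s = 0) records for strain '%s'", strainLabel(dataset)
    ))
  }
  n0Abs <- mean(ctrl$cfu_per_ml * ctrl$dilution_factor)
  if (n0Abs <= 0) {
    stop(sprintf(
      "control count is zero for strain '%s'; cannot set N0", strainLabel(dataset)
    ))
  }
  exposed <- rec[rec$time_s > 0, , drop = FALSE]
  n1Abs <- exposed$cfu_per_ml * exposed$dilution_factor
  if (mode == "absolute") {
    out <- data.frame(
      time_s = exposed$time_s, replicate = exposed$replicate, n1 = n1Abs
    )
    n0 <- n0Abs
  } else {
    out <- data.frame(
      time_s = exposed$time_s, replicate = exposed$replicate,
      n1 = 100 * n1Abs / n0Abs
    )
    n0 <- 100
  }
  list(data = out, n0 = n0, mode = mode, strain = strainLabel(dataset))
}

#' Fit the log-time survival model by least squares
#'
#' Ordinary least squares of surviving counts on ln(exposure time):
#' N1 = N0 - k ln(t). Control rows (t = 0) set N0/100\% and are excluded
#' from the regression. Returns the slope (k-hat is its magnitude), the
#' intercept (N0-hat), the derived quantum mortality yield
#' phi_mu-hat = k-hat lambda / (n0 h c), the correlation and determination
#' coefficients, and two bands at the requested confidence level: the
#' mean-response (confidence) band and the individual-observation
#' (fiducial/prediction) band.
#'
#' @param dataset a [SurvivalData-class].
#' @param confidence confidence level for bands and slope CI (default 0.97).
#' @param mode count mode passed to [countsToSurvivors()].
#' @param constants a [PhysicalConstants-class] (sets Ea for phi_mu-hat).
#' @param dropZeros exclude zero-count records before fitting (default
#'   TRUE)? A plate with no colonies is below the detection limit of the
#'   dilution series, while the line N0 - k ln(t) is already negative there;
#'   keeping such points would bend the fitted line. Excluded records are
#'   counted in the result's flags.
#' @return a [FitResult-class].
#' @examples
#' d <- simulateDataset(simulationDesign(seed = 7))
#' fit <- fitSurvival(d)
#' ssmHat(fit)
#' @export
fitSurvival <- function(dataset, confidence = 0.97,
                        mode = c("absolute", "normalized"),
                        constants = defaultConstants(),
                        dropZeros = TRUE) {
  mode <- match.arg(mode)
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  conv <- countsToSurvivors(dataset, mode)
  df <- conv$data
  flags0 <- character(0)
  if (dropZeros && any(df$n1 == 0)) {
    nZero <- sum(df$n1 == 0)
    df <- df[df$n1 > 0, , drop = FALSE]
    flags0 <- sprintf("%d zero-count record(s) excluded (below detection)", nZero)
  }
  if (length(unique(df$time_s)) < 3) {
    stop("need at least 3 distinct positive exposure times to fit")
  }
  df$ln_t <- log(df$time_s)
  fit <- stats::lm(n1 ~ ln_t, data = df)
  coefs <- stats::coef(fit)
  slope <- unname(coefs["ln_t"])
  intercept <- unname(coefs["(Intercept)"])
  flags <- flags0
  if (intercept < 0) {
    flags <- c(flags, "negative fitted N0")
    warning("fitted intercept (N0 estimate) is negative")
  }
  r <- stats::cor(df$ln_t, df$n1)
  r2 <- summary(fit)$r.squared
  grid <- data.frame(ln_t = sort(unique(df$ln_t)))
  confBand <- stats::predict(fit,
    newdata = grid, interval = "confidence",
    level = confidence
  )
  predBand <- stats::predict(fit,
    newdata = grid, interval = "prediction",
    level = confidence
  )
  band <- data.frame(
    time_s = exp(grid$ln_t), ln_t = grid$ln_t,
    fitted = confBand[, "fit"],
    conf_lo = confBand[, "lwr"], conf_hi = confBand[, "upr"],
    pred_lo = predBand[, "lwr"], pred_hi = predBand[, "upr"]
  )
  ci <- stats::confint(fit, "ln_t", level = confidence)
  kHat <- abs(slope)
  new("FitResult",
    strain = conv$strain, slope = slope, intercept = intercept,
    ssmHat = kHat, cqmyHat = cqmyFromSsm(kHat, constants),
    corR = r, detR2 = r2, confidence = confidence, band = band,
    ciSlope = as.numeric(ci), mode = mode, flags = flags, lmFit = fit
  )
}

#' Fit each replicate separately
#'
#' Runs [fitSurvival()] on each replicate series of the dataset; the
#' per-replicate k-hats feed [tTestVsTheory()].
#'
#' @inheritParams fitSurvival
#' @return list of [FitResult-class], one per replicate.
#' @export
fitSurvivalByReplicate <- function(dataset, confidence = 0.97,
                                   mode = c("absolute", "normalized"),
                                   constants = defaultConstants()) {
  mode <- match.arg(mode)
  rec <- records(dataset)
  reps <- sort(unique(rec$replicate))
  lapply(reps, function(r) {
    sub <- survivalData(
      strainLabel(dataset), rec[rec$replicate == r, , drop = FALSE],
      dataset@platedVolumeMl
    )
    fitSurvival(sub, confidence = confidence, mode = mode, constants = constants)
  })
}

## ---- FitResult accessors ----

#' @rdname FitResult-class
#' @param x a \code{FitResult}.
#' @export
ssmHat <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@ssmHat
}

#' @rdname FitResult-class
#' @export
cqmyHat <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@cqmyHat
}

#' @rdname FitResult-class
#' @export
n0Hat <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@intercept
}

#' @rdname FitResult-class
#' @export
corR <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@corR
}

#' @rdname FitResult-class
#' @export
detR2 <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@detR2
}

#' @rdname FitResult-class
#' @export
slopeCI <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@ciSlope
}

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %s (%s counts)\n", object@strain, object@mode))
  cat(sprintf(
    "  slope = %.4e, N0-hat = %.4e\n", object@slope, object@intercept
  ))
  cat(sprintf(
    "  k-hat (SSM) = %.4e, phi_mu-hat (cQMY) = %.4e\n",
    object@ssmHat, object@cqmyHat
  ))
  cat(sprintf("  R = %.4f, R^2 = %.4f\n", object@corR, object@detR2))
  cat(sprintf(
    "  %.0f%% CI for slope: [%.4e, %.4e]\n",
    100 * object@confidence, object@ciSlope[1], object@ciSlope[2]
  ))
  if (length(object@flags) > 0) {
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  }
  invisible(NULL)
})

#' Mortality view of a survival fit
#'
#' Complements the survival regression: dead cells N = N0-hat - N1 at each
#' observation, the mortality regression (slope is exactly the negated
#' survival slope), and the fitted LDR50 = exp(N0-hat / (2 k-hat)).
#'
#' @param fit a [FitResult-class].
#' @param dataset the [SurvivalData-class] the fit came from.
#' @return list with \code{data} (time_s, replicate, n1, n_dead),
#'   \code{mortalitySlope}, \code{mortalityIntercept}, \code{ldr50Hat},
#'   \code{mmtHat}.
#' @export
mortalityView <- function(fit, dataset) {
  conv <- countsToSurvivors(dataset, fit@mode)
  df <- conv$data
  df$n_dead <- fit@intercept - df$n1
  params <- kineticParams(k = fit@ssmHat, n0 = max(fit@intercept, 0))
  ldr <- if (fit@intercept > 0) suppressWarnings(ldr50(params)) else NA_real_
  list(
    data = df,
    mortalitySlope = -fit@slope,
    mortalityIntercept = 0,
    ldr50Hat = ldr,
    mmtHat = minimumMortalityTime(params)
  )
}

#' One-mean t-test of fitted mortality speeds against theory
#'
#' Tests whether the mean of independently estimated specific speeds of
#' mortality differs from a theoretical reference value, using a one-sample
#' Student t-test (default significance level 0.03, i.e. 97\% confidence).
#'
#' @param kHats numeric vector of fitted k values (>= 2).
#' @param kReference theoretical k to test against, e.g.
#'   [theoreticalSSM()].
#' @param alpha significance level (default 0.03).
#' @return list: statistic, df, p_value, reference_k, mean_k_hat, alpha,
#'   reject (logical), conf_int at 1 - alpha.
#' @examples
#' tTestVsTheory(c(6.5e7, 7.0e7, 6.9e7), theoreticalSSM(defaultEcoliGenome()))
#' @export
tTestVsTheory <- function(kHats, kReference, alpha = 0.03) {
  if (length(kHats) < 2) stop("need at least 2 estimates for a t-test")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (stats::sd(kHats) == 0) {
    # degenerate sample: t.test() refuses constant data
    exact <- isTRUE(all.equal(mean(kHats), kReference))
    return(list(
      statistic = if (exact) 0 else sign(mean(kHats) - kReference) * Inf,
      df = length(kHats) - 1,
      p_value = if (exact) 1 else 0,
      reference_k = kReference,
      mean_k_hat = mean(kHats),
      alpha = alpha,
      reject = !exact,
      conf_int = rep(mean(kHats), 2)
    ))
  }
  tt <- stats::t.test(kHats, mu = kReference, conf.level = 1 - alpha)
  list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    reference_k = kReference,
    mean_k_hat = mean(kHats),
    alpha = alpha,
    reject = tt$p.value < alpha,
    conf_int = as.numeric(tt$conf.int)
  )
}
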