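## CSV dialect: comma-separated, UTF-8, '.' decimal, header mandatory.

.REQUIRED_COLUMNS <- c(
  "strain", "time_s", "replicate", "dilution_factor", "cfu_per_ml"
)

#' Read survival datasets from CSV
#'
#' Expects a header with columns \code{strain,time_s,replicate,
#' dilution_factor,cfu_per_ml}; rows with \code{time_s = 0} are unexposed
#' controls. Extra columns (e.g. fluence metadata) are carried through.
#' Malformed rows are reported with their file line numbers.
#'
#' @param path CSV file path.
#' @param platedVolumeMl plated volume to attach to each dataset, ml.
#' @return named list of [SurvivalData-class], one per strain.
#' @export
readSurvivalCSV <- function(path, platedVolumeMl = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.REQUIRED_COLUMNS, names(df))
  if (length(miss) > 0) {
    stop(sprintf(
      "missing required column(s): %s", paste(miss, collapse = ", ")
    ))
  }
  # +1 for the header line
  lineNo <- seq_len(nrow(df)) + 1L
  problems <- character(0)
  for (col in c("time_s", "dilution_factor", "cfu_per_ml")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "non-numeric %s on line(s) %s", col,
        paste(lineNo[bad], collapse = ", ")
      ))
    }
    df[[col]] <- v
  }
  if (length(problems) == 0) {
    bad <- which(df$time_s < 0)
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "negative time_s on line(s) %s", paste(lineNo[bad], collapse = ", ")
      ))
    }
    bad <- which(df$dilution_factor <= 0)
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "non-positive dilution_factor on line(s) %s",
        paste(lineNo[bad], collapse = ", ")
      ))
    }
    bad <- which(df$cfu_per_ml < 0)
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "negative cfu_per_ml on line(s) %s", paste(lineNo[bad], collapse = ", ")
      ))
    }
  }
  if (length(problems) > 0) {
    stop(paste0("parse errors in ", path, ":\n  ", paste(problems, collapse = "\n  ")))
  }
  if (all(df$time_s == 0)) {
    stop("no positive exposure times in file")
  }
  strains <- unique(df$strain)
  out <- lapply(strains, function(s) {
    rec <- df[df$strain == s, setdiff(names(df), "strain"), drop = FALSE]
    rownames(rec) <- NULL
    survivalData(s, rec, platedVolumeMl)
  })
  names(out) <- strains
  out
}

#' Write survival datasets to CSV
#'
#' Inverse of [readSurvivalCSV()]: serialises one or more datasets into the
#' canonical column layout. Writing the same datasets twice produces
#' byte-identical files.
#'
#' @param datasets a [SurvivalData-class] or list of them.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSurvivalCSV <- function(datasets, path) {
  if (is(datasets, "SurvivalData")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    rec <- records(d)
    cbind(strain = strainLabel(d), rec)
  })
  df <- do.call(rbind, rows)
  front <- intersect(.REQUIRED_COLUMNS, names(df))
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fitResultAsList <- function(fit) {
  params <- kineticParams(k = fit@ssmHat, n0 = max(fit@intercept, 0))
  list(
    strain = fit@strain,
    mode = fit@mode,
    slope = fit@slope,
    n0_hat = fit@intercept,
    k_hat = fit@ssmHat,
    phi_mu_hat = fit@cqmyHat,
    R = fit@corR,
    R2 = fit@detR2,
    confidence = fit@confidence,
    ci_slope = fit@ciSlope,
    ldr50_s = if (fit@intercept > 0) {
      suppressWarnings(ldr50(params))
    } else {
      NA_real_
    },
    mmt_s = minimumMortalityTime(params),
    flags = fit@flags
  )
}

#' Serialise results to JSON or CSV
#'
#' Writes fit results, theory tables or proportionality tables with
#' deterministic field order, plus provenance (package version and any
#' supplied seed/config digest). Identical inputs produce byte-identical
#' JSON.
#'
#' @param results a [FitResult-class], a list of them, or any list/data.frame
#'   (e.g. [theoryReport()] output or [proportionalityReport()] rows).
#' @param path output file path.
#' @param format "json" or "csv". CSV is only available for tabular results.
#' @param seed optional seed to record in the provenance block.
#' @return the path, invisibly.
#' @export
writeReport <- function(results, path, format = c("json", "csv"), seed = NULL) {
  format <- match.arg(format)
  if (is(results, "FitResult")) {
    results <- .fitResultAsList(results)
  } else if (is.list(results) && !is.data.frame(results)) {
    results <- lapply(results, function(x) {
      if (is(x, "FitResult")) .fitResultAsList(x) else x
    })
  }
  if (format == "json") {
    payload <- list(
      provenance = list(
        package = "uvckin",
        version = as.character(utils::packageVersion("uvckin")),
        seed = seed
      ),
      results = results
    )
    jsonlite::write_json(payload, path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    )
  } else {
    if (!is.data.frame(results)) {
      results <- tryCatch(
        as.data.frame(lapply(results, function(x) x[[1]])),
        error = function(e) stop("CSV format needs tabular results")
      )
    }
    utils::write.csv(results, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a run configuration file
#'
#' Flat YAML (or key: value) configuration overriding the reference
#' constants and genome, e.g. \code{constants.wavelength: 2.6e-5} or nested
#' \code{constants: {wavelength: 2.6e-5}}. Unknown keys are an error.
#' Returns fully-built objects; constants and genome values are frozen at
#' construction.
#'
#' @param path YAML file path.
#' @return list with \code{constants} ([PhysicalConstants-class]),
#'   \code{genome} ([GenomeSpec-class]), \code{confidence}, \code{alpha}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  # accept flat dotted keys as well as nested maps
  flat <- list()
  for (k in names(raw)) {
    if (is.list(raw[[k]])) {
      for (k2 in names(raw[[k]])) flat[[paste(k, k2, sep = ".")]] <- raw[[k]][[k2]]
    } else {
      flat[[k]] <- raw[[k]]
    }
  }
  constDefaults <- list(
    avogadro = 6.0225e23, planck = 6.6256e-27,
    lightSpeed = 2.9979e10, wavelength = 2.537e-5
  )
  genomeDefaults <- list(
    basePairs = 5.2e6, genomeVolume = 4.3716e-13,
    genomeThickness = 5.5111e-5, impactSection = 4.9627e-16,
    label = "E. coli (mean)"
  )
  other <- list(confidence = 0.97, alpha = 0.03)
  for (k in names(flat)) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2 && parts[1] == "constants" &&
      parts[2] %in% names(constDefaults)) {
      constDefaults[[parts[2]]] <- flat[[k]]
    } else if (length(parts) == 2 && parts[1] == "genome" &&
      parts[2] %in% names(genomeDefaults)) {
      genomeDefaults[[parts[2]]] <- flat[[k]]
    } else if (length(parts) == 1 && parts[1] %in% names(other)) {
      other[[parts[1]]] <- flat[[k]]
    } else {
      stop(sprintf("unknown configuration key: %s", k))
    }
  }
  list(
    constants = do.call(physicalConstants, constDefaults[1:4]),
    genome = do.call(genomeSpec, genomeDefaults),
    confidence = other$confidence,
    alpha = other$alpha
  )
}
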