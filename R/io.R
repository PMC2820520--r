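## Run configuration, survey-table serialization, and provenance records.

.CONFIG_KEYS <- c("params", "topology", "protocol", "metrics", "output_dir",
                  "seed", "n_sets", "tolerances", "k_dil",
                  "molecules_per_conc_unit", "intervals", "k_ph_rest",
                  "k_ph_act", "ga")

#' Read a run configuration
#'
#' Declarative YAML configuration resolving everything a run needs before
#' any computation starts: the parameter source (\code{params: fixture:
#' <name>} or \code{params: file: <path>}, or sampling \code{intervals:}),
#' the circuit \code{topology}, a \code{protocol} (list of
#' \code{[time, k_ph]} or \code{[time, k_ph, k_ap]} segments), the metric
#' selection, the output directory, \code{seed}, and the unit constants.
#' Unknown top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return named list (class \code{tcs_config}) with resolved entries:
#'   \code{params} is a \code{tcs_params} (when given), \code{topology} a
#'   \code{tcs_topology}, \code{protocol} a \code{tcs_protocol},
#'   \code{intervals} a \code{tcs_intervals}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  k_dil <- cfg$k_dil %||% 2e-4
  conv <- cfg$molecules_per_conc_unit %||% 1000
  out <- cfg
  out$k_dil <- k_dil
  out$molecules_per_conc_unit <- conv
  if (!is.null(cfg$params)) {
    if (!is.null(cfg$params$fixture))
      out$params <- loadFixture(cfg$params$fixture, k_dil = k_dil,
                                molecules_per_conc_unit = conv)
    else if (!is.null(cfg$params$file))
      out$params <- readParams(cfg$params$file, k_dil = k_dil,
                               molecules_per_conc_unit = conv)
    else stop("config 'params' must carry 'fixture' or 'file'")
  }
  if (!is.null(cfg$intervals)) {
    lows <- vapply(cfg$intervals, function(x) as.numeric(x[[1]]), 0)
    highs <- vapply(cfg$intervals, function(x) as.numeric(x[[2]]), 0)
    out$intervals <- samplingIntervals(low = lows, high = highs)
  }
  if (!is.null(cfg$topology)) {
    tv <- cfg$topology
    if (is.character(tv)) tv <- list(variant = tv)
    out$topology <- makeTopology(tv$variant, params = out$params,
                                 calibration_signal = tv$calibration_signal %||% 0.1,
                                 R0 = tv$R0,
                                 const_tcs_txn = tv$const_tcs_txn,
                                 const_shk_txn = tv$const_shk_txn,
                                 const_rr_txn = tv$const_rr_txn)
  }
  if (!is.null(cfg$protocol)) {
    seg <- cfg$protocol
    times <- vapply(seg, function(s) as.numeric(s[[1]]), 0)
    kph <- vapply(seg, function(s) as.numeric(s[[2]]), 0)
    kap <- vapply(seg, function(s)
      if (length(s) >= 3) as.numeric(s[[3]]) else NA_real_, 0)
    out$protocol <- signalProtocol(times, kph, kap)
  }
  structure(out, class = "tcs_config")
}

#' Write / read survey tables
#'
#' Comma-delimited serialization of \code{\link{runSurvey}} outputs with a
#' lossless round-trip of every field, including undefined metrics, which are
#' written as the explicit sentinel strings \code{"undefined"} (NA) and
#' \code{"unbounded"} (Inf) rather than empty cells so tables stay
#' machine-checkable. \code{writeSurvey} also writes a
#' \code{<path>.provenance.yml} record (seed, intervals, package version)
#' sufficient to re-run the survey bit-identically.
#'
#' @param survey a survey data.frame.
#' @param path CSV path.
#' @param provenance write the companion provenance file (default TRUE).
#' @export
writeSurvey <- function(survey, path, provenance = TRUE) {
  df <- as.data.frame(survey)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      x <- format(df[[j]], digits = 17, trim = TRUE, scientific = TRUE)
      x[is.na(df[[j]])] <- "undefined"
      x[is.infinite(df[[j]]) & df[[j]] > 0] <- "unbounded"
      x[is.infinite(df[[j]]) & df[[j]] < 0] <- "-unbounded"
      df[[j]] <- x
    } else if (is.logical(df[[j]])) {
      x <- ifelse(df[[j]], "TRUE", "FALSE")
      x[is.na(df[[j]])] <- "undefined"
      df[[j]] <- x
    } else {
      df[[j]][is.na(df[[j]])] <- "undefined"
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  if (provenance) {
    iv <- attr(survey, "intervals")
    prov <- list(
      package = "tcsfeedback",
      version = as.character(utils::packageVersion("tcsfeedback")),
      seed = as.integer(attr(survey, "seed")),
      attempts = attr(survey, "attempts"),
      n_records = nrow(survey),
      intervals = if (!is.null(iv))
        stats::setNames(lapply(seq_len(nrow(iv)), function(i)
          c(iv$low[i], iv$high[i])), iv$parameter))
    yaml::write_yaml(prov, paste0(path, ".provenance.yml"))
  }
  invisible(path)
}

#' @rdname writeSurvey
#' @return \code{readSurvey}: the survey data.frame with numeric/logical
#'   types and sentinels restored.
#' @export
readSurvey <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || first %in% c("", "\"\""))
    return(data.frame())
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  flag_cols <- c("overshoot", "mrna_overshoot", "converged", "feasible")
  bad <- NULL
  for (j in seq_along(df)) {
    x <- df[[j]]
    x[x == "undefined"] <- NA
    if (all(is.na(x))) {
      ## type not recoverable from an all-undefined column: flags stay
      ## logical, metrics numeric
      df[[j]] <- if (names(df)[j] %in% flag_cols) as.logical(x)
                 else as.numeric(x)
      next
    }
    if (all(x %in% c("TRUE", "FALSE", NA))) {
      df[[j]] <- as.logical(x)
      next
    }
    x[x == "unbounded"] <- "Inf"
    x[x == "-unbounded"] <- "-Inf"
    num <- suppressWarnings(as.numeric(x))
    if (any(is.na(num) & !is.na(x))) {
      if (names(df)[j] %in% c("gain_sign")) { df[[j]] <- x; next }
      bad <- c(bad, which(is.na(num) & !is.na(x))[1])
      next
    }
    df[[j]] <- num
  }
  if (length(bad))
    stop("malformed survey file: unparseable value in row ", bad[1])
  df
}
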