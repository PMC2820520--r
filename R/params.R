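## Kinetic parameter container, validation, fixtures, and flat-file I/O.

## The 21 kinetic constants of the reaction network, in canonical order.
.TCS_KINETIC_PARAMS <- c(
  "k_ap", "k_ad", "k_pt", "k_tp", "k_b", "k_d", "k_b1", "k_d1",
  "k_RRPdm", "k_RRPmd", "k_txn", "k_SKtsn", "tsn_mult", "k_txnbasal",
  "K_mDS", "K_m", "k_mRNAdeg", "k_exp", "K_mexp", "k_exd", "K_mexd"
)

## Full field list: kinetic constants + signal + cell-physiology constants.
.TCS_PARAM_NAMES <- c(.TCS_KINETIC_PARAMS, "k_ph", "k_dil",
                      "molecules_per_conc_unit")

#' Kinetic parameters of the two-component system model
#'
#' Builds and validates the full parameter set of the reaction network:
#' the 21 kinetic constants of the binding/phosphotransfer/expression
#' reactions, the signal parameter \code{k_ph} (phosphatase catalytic rate on
#' the SHK.RRP complex, the primary input of the model), the growth-dilution
#' rate \code{k_dil} applied to all proteins, complexes and the phospho-dimer,
#' and the unit conversion \code{molecules_per_conc_unit} used only by the
#' molecule-per-cell feasibility thresholds.
#'
#' Units: concentrations in \eqn{\mu}M, time in seconds. First-order rates are
#' s\eqn{^{-1}}; bimolecular rates \eqn{\mu}M\eqn{^{-1}}s\eqn{^{-1}};
#' transcription rates and the exogenous (de)phosphorylation Vmax constants
#' \eqn{\mu}M s\eqn{^{-1}}; Michaelis constants \eqn{\mu}M.
#'
#' @param ... named parameter values; every kinetic constant listed in
#'   \code{tcsParamNames()} except \code{k_ph}, \code{k_dil} and
#'   \code{molecules_per_conc_unit} must be supplied.
#' @param k_ph phosphatase rate (s^-1); high values (default 10) correspond to
#'   the resting signal, low values (0.1) to the activating signal.
#' @param k_dil growth dilution rate (s^-1); default 2e-4 (~58 min doubling).
#' @param molecules_per_conc_unit molecules per cell per \eqn{\mu}M; default
#'   1000 (~1.66 fL cell volume).
#' @return an object of class \code{tcs_params}: a named list of numeric
#'   scalars.
#' @examples
#' p <- loadFixture("negative_example")
#' p$k_ap
#' @export
tcsParams <- function(..., k_ph = 10, k_dil = 2e-4,
                      molecules_per_conc_unit = 1000) {
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) && is.list(vals[[1]]))
    vals <- vals[[1]]
  vals$k_ph <- k_ph
  vals$k_dil <- k_dil
  vals$molecules_per_conc_unit <- molecules_per_conc_unit
  unknown <- setdiff(names(vals), .TCS_PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.TCS_PARAM_NAMES, names(vals))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  vals <- lapply(vals[.TCS_PARAM_NAMES], as.numeric)
  validateParams(vals)
  structure(vals, class = "tcs_params")
}

#' @rdname tcsParams
#' @export
tcsParamNames <- function() .TCS_PARAM_NAMES

#' Validate a parameter set
#'
#' Checks the structural invariants every parameter set must satisfy: all
#' rates and Michaelis constants finite and nonnegative, and \code{k_dil > 0}
#' so proteins have a well-defined steady state. (The survey feasibility
#' criteria, e.g. \code{k_txnbasal < k_txn}, are stricter and live in
#' \code{\link{feasibilityFilter}}.)
#'
#' @param params a \code{tcs_params} object or named list.
#' @return invisibly \code{TRUE}; errors otherwise.
#' @export
validateParams <- function(params) {
  v <- unlist(params[.TCS_PARAM_NAMES])
  if (anyNA(v) || any(!is.finite(v)))
    stop("parameters must be finite and non-missing")
  if (any(v < 0))
    stop("negative parameter(s): ",
         paste(names(v)[v < 0], collapse = ", "))
  ## k_dil = 0 is tolerated for conservation analyses; steady-state solving
  ## requires k_dil > 0 and checks it itself
  if (params$k_dil < 0) stop("k_dil must be >= 0")
  if (params$molecules_per_conc_unit <= 0)
    stop("molecules_per_conc_unit must be > 0")
  invisible(TRUE)
}

#' Modify a parameter set
#'
#' Returns a copy of \code{params} with the named values replaced, re-running
#' validation. Convenient for signal changes and knockouts
#' (e.g. \code{setParams(p, k_txn = 0)}).
#'
#' @param params a \code{tcs_params} object.
#' @param ... named replacements.
#' @return a \code{tcs_params} object.
#' @export
setParams <- function(params, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), .TCS_PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params[names(repl)] <- lapply(repl, as.numeric)
  validateParams(params)
  structure(params, class = "tcs_params")
}

#' @export
print.tcs_params <- function(x, ...) {
  cat("Two-component system kinetic parameters (uM, s)\n")
  print(unlist(x), ...)
  invisible(x)
}

#' Load a published example parameter set
#'
#' Two complete parameter sets ship with the package:
#' \code{"negative_example"}, which operates in the effectively negative
#' feedback regime at the activating signal (substantial exogenous
#' phosphorylation flux), and \code{"positive_example"}, which operates in the
#' positive regime. Values are stored to full precision in
#' \code{inst/extdata/}.
#'
#' @param name one of \code{"negative_example"}, \code{"positive_example"}.
#' @param k_ph,k_dil,molecules_per_conc_unit see \code{\link{tcsParams}}.
#' @return a \code{tcs_params} object.
#' @export
loadFixture <- function(name, k_ph = 10, k_dil = 2e-4,
                        molecules_per_conc_unit = 1000) {
  available <- c("negative_example", "positive_example")
  if (!is.character(name) || length(name) != 1L || !(name %in% available))
    stop("unknown fixture; available fixtures: ",
         paste(available, collapse = ", "))
  path <- system.file("extdata", paste0(name, ".txt"),
                      package = "tcsfeedback", mustWork = TRUE)
  readParams(path, k_ph = k_ph, k_dil = k_dil,
             molecules_per_conc_unit = molecules_per_conc_unit)
}

#' Read / write parameter sets as flat key-value text
#'
#' One \code{key value} pair per line, \code{#} comments allowed. Keys are the
#' canonical parameter names (\code{tcsParamNames()}). \code{k_ph},
#' \code{k_dil} and \code{molecules_per_conc_unit} may be present in the file;
#' when absent the function arguments supply them.
#'
#' @param path file path.
#' @param k_ph,k_dil,molecules_per_conc_unit defaults used when the file does
#'   not carry these keys.
#' @return \code{readParams}: a \code{tcs_params} object.
#' @export
readParams <- function(path, k_ph = 10, k_dil = 2e-4,
                       molecules_per_conc_unit = 1000) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]:=]+")
  keys <- vapply(parts, `[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(vals))
    stop("malformed parameter file line(s): ",
         paste(lines[is.na(vals)], collapse = "; "))
  p <- as.list(vals)
  names(p) <- keys
  if (is.null(p$k_ph)) p$k_ph <- k_ph
  if (is.null(p$k_dil)) p$k_dil <- k_dil
  if (is.null(p$molecules_per_conc_unit))
    p$molecules_per_conc_unit <- molecules_per_conc_unit
  tcsParams(p[setdiff(names(p), c("k_ph", "k_dil", "molecules_per_conc_unit"))],
            k_ph = p$k_ph, k_dil = p$k_dil,
            molecules_per_conc_unit = p$molecules_per_conc_unit)
}

#' @rdname readParams
#' @param params a \code{tcs_params} object to serialize.
#' @export
writeParams <- function(params, path) {
  stopifnot(inherits(params, "tcs_params"))
  lines <- sprintf("%s %.17g", .TCS_PARAM_NAMES,
                   unlist(params[.TCS_PARAM_NAMES]))
  writeLines(lines, path)
  invisible(path)
}
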