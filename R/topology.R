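## Circuit wiring variants and their calibration against the wild type.

.TCS_VARIANTS <- c("wild_type", "open_loop", "no_feedback",
                   "circuit_I", "circuit_II")

.checkTopology <- function(topology) {
  if (!inherits(topology, "tcs_topology"))
    stop("topology must be created with makeTopology()")
  v <- topology$variant
  need <- switch(v,
    open_loop = "R0",
    no_feedback = "const_tcs_txn",
    circuit_I = "const_shk_txn",
    circuit_II = "const_rr_txn",
    NULL)
  if (!is.null(need) && (is.null(topology[[need]]) || is.na(topology[[need]])))
    stop("variant '", v, "' requires constant '", need, "'")
  invisible(TRUE)
}

#' Circuit wiring variants
#'
#' Builds one of the five wirings of the model:
#' \describe{
#'   \item{wild_type}{both TCS genes autoregulated from one operon.}
#'   \item{open_loop}{the TCS operon is driven by a fixed exogenous regulator
#'     concentration \code{R0} instead of the phospho-dimer; the downstream
#'     operon stays under RRP2 control so downstream readouts remain
#'     signal-responsive.}
#'   \item{no_feedback}{TCS transcription is a fixed flux
#'     \code{const_tcs_txn}, calibrated to the total wild-type transcription
#'     flux (regulated + basal) at the activated steady state.}
#'   \item{circuit_I}{feedback to the RR gene only; SHK production is the
#'     fixed flux \code{const_shk_txn}.}
#'   \item{circuit_II}{feedback to the SHK gene only; RR production is the
#'     fixed flux \code{const_rr_txn}.}
#' }
#' For the calibrated variants the constitutive flux equals the corresponding
#' wild-type production flux at the wild-type steady state under
#' \code{calibration_signal} (default \code{k_ph = 0.1}/s, an expression level
#' away from both saturation extremes), supplied either directly through the
#' \code{...} constants or computed from \code{params}.
#'
#' @param variant one of \code{"wild_type"}, \code{"open_loop"},
#'   \code{"no_feedback"}, \code{"circuit_I"}, \code{"circuit_II"}.
#' @param params a \code{tcs_params} object; required for calibrated variants
#'   unless the constant is given explicitly.
#' @param calibration_signal \code{k_ph} (s^-1) of the wild-type steady state
#'   used for calibration.
#' @param R0 exogenous regulator concentration (open_loop).
#' @param const_tcs_txn,const_shk_txn,const_rr_txn explicit constitutive
#'   fluxes overriding calibration.
#' @return a \code{tcs_topology} object.
#' @export
makeTopology <- function(variant = "wild_type", params = NULL,
                         calibration_signal = 0.1, R0 = NULL,
                         const_tcs_txn = NULL, const_shk_txn = NULL,
                         const_rr_txn = NULL) {
  variant <- match.arg(variant, .TCS_VARIANTS)
  topo <- structure(list(variant = variant, R0 = R0,
                         const_tcs_txn = const_tcs_txn,
                         const_shk_txn = const_shk_txn,
                         const_rr_txn = const_rr_txn),
                    class = "tcs_topology")
  needCalib <- switch(variant,
    no_feedback = is.null(const_tcs_txn),
    circuit_I = is.null(const_shk_txn),
    circuit_II = is.null(const_rr_txn),
    FALSE)
  if (needCalib) {
    if (is.null(params))
      stop("variant '", variant,
           "' needs params for calibration (or an explicit constant)")
    wt <- solveSteadyState(params, makeTopology("wild_type"),
                           k_ph = calibration_signal)
    if (!wt$converged)
      stop("wild-type calibration steady state did not converge")
    fl <- reactionFluxes(wt$state, params, makeTopology("wild_type"),
                         k_ph = calibration_signal)
    topo[[switch(variant,
                 no_feedback = "const_tcs_txn",
                 circuit_I = "const_shk_txn",
                 circuit_II = "const_rr_txn")]] <-
      switch(variant,
             no_feedback = unname(fl["r1_txn_tcs_regulated"] +
                                  fl["r3_txn_tcs_basal"]),
             circuit_I = unname(fl["r6_tsn_shk"]),
             circuit_II = unname(fl["r7_tsn_rr"]))
  }
  .checkTopology(topo)
  topo
}

#' @export
print.tcs_topology <- function(x, ...) {
  cat("TCS circuit topology:", x$variant, "\n")
  for (f in c("R0", "const_tcs_txn", "const_shk_txn", "const_rr_txn"))
    if (!is.null(x[[f]])) cat(" ", f, "=", format(x[[f]]), "\n")
  invisible(x)
}
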