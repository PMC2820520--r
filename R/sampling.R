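## Monte Carlo parameter sampling (log-uniform), the seven-criterion
## feasibility filter, and the batch survey harness.

#' Log-uniform sampling intervals
#'
#' Per-parameter \code{(low, high)} bounds for log-uniform Monte Carlo
#' sampling of the 21 kinetic constants. The default intervals span from
#' one tenth of the smaller to ten times the larger of the two shipped
#' example values of each parameter, so both published regimes are interior
#' points of the sampled space.
#'
#' @param low,high named numeric vectors over (a subset of) the kinetic
#'   parameter names; defaults as above.
#' @return a \code{tcs_intervals} object: data.frame with \code{parameter},
#'   \code{low}, \code{high}.
#' @export
samplingIntervals <- function(low = NULL, high = NULL) {
  neg <- loadFixture("negative_example")
  pos <- loadFixture("positive_example")
  base_lo <- pmin(unlist(neg[.TCS_KINETIC_PARAMS]),
                  unlist(pos[.TCS_KINETIC_PARAMS])) / 10
  base_hi <- pmax(unlist(neg[.TCS_KINETIC_PARAMS]),
                  unlist(pos[.TCS_KINETIC_PARAMS])) * 10
  if (!is.null(low)) base_lo[names(low)] <- low
  if (!is.null(high)) base_hi[names(high)] <- high
  if (any(base_lo <= 0) || any(base_hi < base_lo))
    stop("intervals must satisfy 0 < low <= high")
  structure(data.frame(parameter = .TCS_KINETIC_PARAMS,
                       low = unname(base_lo), high = unname(base_hi),
                       stringsAsFactors = FALSE),
            class = c("tcs_intervals", "data.frame"))
}

#' Draw one parameter set
#'
#' Each kinetic constant is drawn independently log-uniformly from its
#' interval (a degenerate interval fixes the parameter); \code{k_ph},
#' \code{k_dil} and the unit conversion are not sampled. Uses the current
#' RNG stream, so draws are reproducible under \code{set.seed()}.
#'
#' @param intervals a \code{tcs_intervals} object.
#' @param k_ph,k_dil,molecules_per_conc_unit fixed (non-sampled) constants.
#' @return a \code{tcs_params} object.
#' @export
sampleParameterSet <- function(intervals = samplingIntervals(), k_ph = 10,
                               k_dil = 2e-4, molecules_per_conc_unit = 1000) {
  u <- stats::runif(nrow(intervals))
  vals <- exp(log(intervals$low) + u * (log(intervals$high) -
                                        log(intervals$low)))
  names(vals) <- intervals$parameter
  tcsParams(as.list(vals), k_ph = k_ph, k_dil = k_dil,
            molecules_per_conc_unit = molecules_per_conc_unit)
}

#' Feasibility filter
#'
#' Tests a parameter set for physical realizability and consistency with
#' known characteristics of two-component systems, using seven criteria:
#' \enumerate{
#'   \item mRNA below 100 copies/cell at every tested steady state;
#'   \item mRNA degradation faster than protein dilution
#'     (\code{k_mRNAdeg > k_dil});
#'   \item basal transcription below the regulated rate
#'     (\code{k_txnbasal < k_txn});
#'   \item sufficient induction of active regulator:
#'     \eqn{[RRP_2](k_{ph}=10^{-3}) - [RRP_2](k_{ph}=10) >} 1 molecule/cell;
#'   \item low basal activity: \eqn{[RRP_2](k_{ph}=10) \le} 1 molecule/cell
#'     both with and without regulated transcription (\code{k_txn = 0});
#'   \item downstream expression at rest insensitive to the feedback:
#'     \eqn{[DS](k_{ph}=10)} with vs without regulated transcription differs
#'     by less than 10\%;
#'   \item sufficient overall induction: \eqn{[DS]}, \eqn{[RRP_2]} and
#'     \eqn{RR_{tot}} each change more than 2-fold between
#'     \eqn{k_{ph} = 10} and \eqn{k_{ph} = 0.1}.
#' }
#' Steady-state failures yield the verdict \code{"unsolvable"}, distinct
#' from \code{"infeasible"}; such sets are discarded from surveys but never
#' silently zeroed.
#'
#' @param params a \code{tcs_params} object.
#' @param detail return per-criterion booleans and the steady states used.
#' @return list with \code{verdict} (\code{"feasible"}, \code{"infeasible"},
#'   \code{"unsolvable"}), \code{criteria} (named logical vector c1..c7),
#'   \code{reasons} (failed criteria as a string), and (when
#'   \code{detail = TRUE}) the steady states \code{rest}, \code{act},
#'   \code{saturated}, \code{rest_noreg}.
#' @export
feasibilityFilter <- function(params, detail = FALSE) {
  crit <- stats::setNames(rep(NA, 7), paste0("c", 1:7))
  crit["c2"] <- params$k_mRNAdeg > params$k_dil
  crit["c3"] <- params$k_txnbasal < params$k_txn
  if (!crit["c2"] || !crit["c3"]) {
    return(list(verdict = "infeasible", criteria = crit,
                reasons = paste(names(crit)[!crit %in% TRUE &
                                            !is.na(crit)], collapse = ";")))
  }
  conv <- params$molecules_per_conc_unit
  wt <- makeTopology("wild_type")
  rest <- solveSteadyState(params, wt, k_ph = 10)
  act <- if (rest$converged)
    solveSteadyState(params, wt, k_ph = 0.1, guess = rest$state) else
      list(converged = FALSE)
  sat <- if (act$converged)
    solveSteadyState(params, wt, k_ph = 1e-3, guess = act$state) else
      list(converged = FALSE)
  p0 <- setParams(params, k_txn = 0)
  rest0 <- solveSteadyState(p0, wt, k_ph = 10)
  if (!rest$converged || !act$converged || !sat$converged ||
      !rest0$converged)
    return(list(verdict = "unsolvable", criteria = crit,
                reasons = "steady_state_failure"))
  mol <- function(x) unname(x) * conv
  mrna <- c(rest$state[c("mRNA_tcs", "mRNA_ds")],
            act$state[c("mRNA_tcs", "mRNA_ds")],
            sat$state[c("mRNA_tcs", "mRNA_ds")])
  crit["c1"] <- all(mol(mrna) < 100)
  crit["c4"] <- mol(sat$state["RRP2"] - rest$state["RRP2"]) > 1
  crit["c5"] <- mol(rest$state["RRP2"]) <= 1 && mol(rest0$state["RRP2"]) <= 1
  ds_rest <- unname(rest$state["DS"]); ds_rest0 <- unname(rest0$state["DS"])
  crit["c6"] <- is.finite(ds_rest) && ds_rest > 0 &&
    abs(ds_rest - ds_rest0) / ds_rest < 0.10
  fold <- function(sp) {
    lo <- .observableTarget(rest$state, sp)
    hi <- .observableTarget(act$state, sp)
    if (lo <= 0) Inf else hi / lo
  }
  crit["c7"] <- fold("DS") > 2 && fold("RRP2") > 2 && fold("RR_tot") > 2
  verdict <- if (all(crit)) "feasible" else "infeasible"
  out <- list(verdict = verdict, criteria = crit,
              reasons = paste(names(crit)[!crit], collapse = ";"))
  if (detail)
    out <- c(out, list(rest = rest$state, act = act$state,
                       saturated = sat$state, rest_noreg = rest0$state))
  out
}

## metric blocks a survey can compute per feasible set
.SURVEY_METRICS <- c("gain", "flux", "overshoot", "response", "learning",
                     "induction", "circuits")

## analysis of one feasible set, sharing steady states/trajectories between
## metric blocks
.analyzeParams <- function(params, metrics, feas, k_ph_rest = 10,
                           k_ph_act = 0.1) {
  rec <- list()
  rest <- feas$rest; act <- feas$act
  need_traj <- any(c("overshoot", "learning", "response") %in% metrics)
  traj <- NULL
  if (need_traj)
    traj <- .activationTrajectory(params, makeTopology("wild_type"),
                                  k_ph_rest, k_ph_act, act, state0 = rest)
  if ("gain" %in% metrics) {
    g <- openLoopGain(params, k_ph = k_ph_act, closed_ss = act)
    rec$gain <- g$gain; rec$gain_sign <- g$sign
  }
  if ("flux" %in% metrics) {
    f <- fluxFraction(params, k_ph = k_ph_act, closed_ss = act)
    rec$J_E <- f$J_E; rec$J_S <- f$J_S; rec$flux_fraction <- f$fraction
  }
  if ("overshoot" %in% metrics) {
    ov <- overshoot(traj, act)
    rec$overshoot <- ov$flag; rec$overshoot_magnitude <- ov$magnitude
    rec$overshoot_peak_time <- ov$peak_time
    rec$mrna_overshoot <- ov$mrna_overshoot
  }
  if ("response" %in% metrics) {
    ok <- isTRUE(attr(traj, "converged"))
    rec$tau50_ds <- if (ok) responseTime(traj, "DS", 0.5,
                                         unname(act["DS"])) else NA_real_
    rec$tau95_ds <- if (ok) responseTime(traj, "DS", 0.95,
                                         unname(act["DS"])) else NA_real_
    rr <- responseTimeRatio(params, k_ph_rest = k_ph_rest,
                            k_ph_act = k_ph_act)
    rec$tau95_ds_nofb <- rr$tau_nofb
    rec$tau_ratio_95 <- rr$ratio
  }
  if ("learning" %in% metrics) {
    le <- learningExperiment(params, k_ph_rest = k_ph_rest,
                             k_ph_act = k_ph_act)
    rec$tau_first <- le$tau_first; rec$tau_second <- le$tau_second
    rec$learning_ratio <- le$ratio
    rec$delta_SHK_tot_pct <- unname(le$delta_SHK_tot_pct)
    rec$delta_RR_tot_pct <- unname(le$delta_RR_tot_pct)
  }
  if (any(c("induction", "circuits") %in% metrics)) {
    nofb <- try(makeTopology("no_feedback", params,
                             calibration_signal = k_ph_act), silent = TRUE)
    nofb_ok <- !inherits(nofb, "try-error")
    if ("induction" %in% metrics) {
      ir <- if (nofb_ok)
        inductionRange(params, nofb_topology = nofb,
                       calibration_signal = k_ph_act)
      else list(range = NA_real_)
      rec$induction_range <- ir$range
    }
    if ("circuits" %in% metrics) {
      cI <- try(makeTopology("circuit_I", params,
                             calibration_signal = k_ph_act), silent = TRUE)
      cII <- try(makeTopology("circuit_II", params,
                              calibration_signal = k_ph_act), silent = TRUE)
      if (nofb_ok && !inherits(cI, "try-error")) {
        r_wt <- responseTimeRatio(params, nofb_topology = nofb,
                                  k_ph_rest = k_ph_rest, k_ph_act = k_ph_act)
        r_cI <- responseTimeRatio(params, topology = cI, nofb_topology = nofb,
                                  k_ph_rest = k_ph_rest, k_ph_act = k_ph_act)
        rec$tau95_ratio_wt <- r_wt$ratio
        rec$tau95_ratio_circuit_I <- r_cI$ratio
      } else {
        rec$tau95_ratio_wt <- NA_real_
        rec$tau95_ratio_circuit_I <- NA_real_
      }
      if (nofb_ok && !inherits(cII, "try-error")) {
        ir_wt <- inductionRange(params, nofb_topology = nofb,
                                calibration_signal = k_ph_act)
        ir_cII <- inductionRange(params, topology = cII, nofb_topology = nofb,
                                 calibration_signal = k_ph_act)
        rec$induction_range_wt <- ir_wt$range
        rec$induction_range_circuit_II <- ir_cII$range
      } else {
        rec$induction_range_wt <- NA_real_
        rec$induction_range_circuit_II <- NA_real_
      }
    }
  }
  rec
}

#' Monte Carlo parameter survey
#'
#' Samples parameter sets log-uniformly until \code{n_sets} feasible sets are
#' obtained (or the attempt cap is reached), and computes the requested
#' metric blocks for each feasible set. Fully reproducible from \code{seed}.
#' Infeasible and unsolvable draws are recorded in the attempt log attribute,
#' never dropped silently.
#'
#' @param n_sets number of feasible parameter sets to collect.
#' @param intervals a \code{tcs_intervals} object.
#' @param seed integer seed for the sampler.
#' @param metrics subset of \code{c("gain", "flux", "overshoot", "response",
#'   "learning", "induction", "circuits")}.
#' @param k_ph_rest,k_ph_act resting/activating signal for all metrics.
#' @param max_attempts cap on total draws (default \code{100 * n_sets}).
#' @param k_dil,molecules_per_conc_unit fixed constants of every draw.
#' @param verbose print per-set progress.
#' @return data.frame (one row per feasible set) with the draw index, the 21
#'   sampled parameters and the metric columns; attributes:
#'   \code{"attempts"} (total draws), \code{"verdicts"} (table of verdicts),
#'   \code{"seed"}, \code{"intervals"}. If the attempt cap is reached a
#'   warning is issued and the partial table returned.
#' @export
runSurvey <- function(n_sets, intervals = samplingIntervals(), seed = 1,
                      metrics = c("gain", "flux", "overshoot"),
                      k_ph_rest = 10, k_ph_act = 0.1,
                      max_attempts = 100 * n_sets, k_dil = 2e-4,
                      molecules_per_conc_unit = 1000, verbose = FALSE) {
  metrics <- match.arg(metrics, .SURVEY_METRICS, several.ok = TRUE)
  set.seed(seed)
  rows <- list()
  verdicts <- c(feasible = 0L, infeasible = 0L, unsolvable = 0L)
  attempts <- 0L
  while (length(rows) < n_sets && attempts < max_attempts) {
    attempts <- attempts + 1L
    params <- sampleParameterSet(intervals, k_ph = k_ph_rest, k_dil = k_dil,
                                 molecules_per_conc_unit =
                                   molecules_per_conc_unit)
    feas <- feasibilityFilter(params, detail = TRUE)
    verdicts[feas$verdict] <- verdicts[feas$verdict] + 1L
    if (feas$verdict != "feasible") next
    rec <- .analyzeParams(params, metrics, feas, k_ph_rest = k_ph_rest,
                          k_ph_act = k_ph_act)
    rows[[length(rows) + 1L]] <-
      c(list(id = length(rows) + 1L, draw = attempts),
        params[.TCS_KINETIC_PARAMS], rec)
    if (verbose)
      message(sprintf("feasible set %d/%d (draw %d)", length(rows), n_sets,
                      attempts))
  }
  if (length(rows) < n_sets)
    warning(sprintf("attempt cap reached: %d/%d feasible sets found",
                    length(rows), n_sets))
  out <- if (length(rows))
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  else
    data.frame()
  attr(out, "attempts") <- attempts
  attr(out, "verdicts") <- verdicts
  attr(out, "seed") <- seed
  attr(out, "intervals") <- intervals
  out
}
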