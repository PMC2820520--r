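## Feedback-sign and response statistics: open-loop gain, exogenous flux
## decomposition, overshoot, response times, signal-interruption "learning",
## induction range, and signal-space gain maps.

#' Open-loop gain (effective feedback sign)
#'
#' The effective sign of the transcriptional feedback loop is measured on the
#' open-loop circuit, in which a fixed exogenous regulator concentration
#' \eqn{R_0} replaces the phospho-dimer in the TCS operon's transcription law.
#' The gain is the log-log sensitivity
#' \eqn{g = d\,\ln [RRP_2]_{open} / d\,\ln R_0}
#' evaluated at \eqn{R_0^* =} the closed-loop steady-state \eqn{[RRP_2]} at
#' the given signal, by central difference with a multiplicative perturbation
#' (\code{rel_step}, default 1\%). \eqn{g < 0} means the feedback effectively
#' attenuates activated regulator (negative feedback); \eqn{g > 0} amplifies
#' it (positive feedback).
#'
#' @inheritParams solveSteadyState
#' @param rel_step relative perturbation of \eqn{R_0} (default 0.01).
#' @param sign_tol gains with \eqn{|g| <} \code{sign_tol} are labeled
#'   \code{"zero"} (default 1e-4).
#' @param closed_ss optional precomputed closed-loop steady state at the
#'   signal (a state vector), to avoid recomputation.
#' @return list with \code{gain}, \code{sign} (\code{"negative"},
#'   \code{"positive"}, \code{"zero"}), \code{k_ph}, \code{k_ap}, \code{R0},
#'   \code{rel_step}, \code{converged}.
#' @examples
#' p <- loadFixture("negative_example")
#' openLoopGain(p, k_ph = 1)$sign
#' @export
openLoopGain <- function(params, k_ph = 0.1, k_ap = params$k_ap,
                         rel_step = 0.01, sign_tol = 1e-4,
                         closed_ss = NULL) {
  fail <- function() list(gain = NA_real_, sign = NA_character_, k_ph = k_ph,
                          k_ap = k_ap, R0 = NA_real_, rel_step = rel_step,
                          converged = FALSE)
  if (is.null(closed_ss)) {
    cl <- solveSteadyState(params, makeTopology("wild_type"),
                           k_ph = k_ph, k_ap = k_ap)
    if (!cl$converged) return(fail())
    closed_ss <- cl$state
  }
  R0 <- unname(closed_ss["RRP2"])
  if (!is.finite(R0) || R0 <= 0) return(fail())
  solveOpen <- function(R0v) {
    ## small gains demand residuals far below the R0-induced flux change,
    ## hence the tight polishing tolerance here
    s <- solveSteadyState(params, makeTopology("open_loop", R0 = R0v),
                          k_ph = k_ph, k_ap = k_ap, guess = closed_ss,
                          tol = 1e-13)
    if (!s$converged) return(NA_real_)
    unname(s$state["RRP2"])
  }
  up <- solveOpen(R0 * (1 + rel_step))
  dn <- solveOpen(R0 / (1 + rel_step))
  if (!is.finite(up) || !is.finite(dn) || up <= 0 || dn <= 0) return(fail())
  gain <- (log(up) - log(dn)) / (2 * log(1 + rel_step))
  sign <- if (abs(gain) < sign_tol) "zero" else
    if (gain < 0) "negative" else "positive"
  list(gain = gain, sign = sign, k_ph = k_ph, k_ap = k_ap, R0 = R0,
       rel_step = rel_step, converged = TRUE)
}

#' Exogenous phosphorylation flux fraction
#'
#' Decomposes response-regulator phosphorylation at the closed-loop steady
#' state into the exogenous flux \eqn{J_E} (Michaelis-Menten phosphorylation
#' of free RR by non-cognate sources) and the SHK-mediated flux \eqn{J_S}
#' (release of RRP from the SHK.RRP complex), and reports
#' \eqn{J_E/(J_E+J_S)}. An exogenous fraction above ~1e-3 accompanies every
#' effectively negative feedback loop in this model.
#'
#' @inheritParams openLoopGain
#' @return list with \code{J_E}, \code{J_S}, \code{fraction}, \code{k_ph},
#'   \code{converged}.
#' @export
fluxFraction <- function(params, k_ph = 0.1, k_ap = params$k_ap,
                         closed_ss = NULL) {
  if (is.null(closed_ss)) {
    cl <- solveSteadyState(params, makeTopology("wild_type"),
                           k_ph = k_ph, k_ap = k_ap)
    if (!cl$converged)
      return(list(J_E = NA_real_, J_S = NA_real_, fraction = NA_real_,
                  k_ph = k_ph, converged = FALSE))
    closed_ss <- cl$state
  }
  fl <- reactionFluxes(closed_ss, params, makeTopology("wild_type"),
                       k_ph = k_ph, k_ap = k_ap)
  JE <- unname(fl["r19_exogenous_phosphorylation"])
  JS <- unname(fl["r16_dissoc_shk_rrp"])
  fraction <- if (JE == 0) 0 else JE / (JE + JS)
  list(J_E = JE, J_S = JS, fraction = fraction, k_ph = k_ph, converged = TRUE)
}

#' Overshoot detection
#'
#' Flags feedback-induced overshoot on an activation trajectory: the peak
#' \eqn{[RRP_2]} must exceed the activated steady state by more than
#' \code{threshold} (default 50\%), and — unless
#' \code{require_mrna_overshoot = FALSE} — the downstream mRNA must also peak
#' above its steady state, which excludes purely post-translational RRP2
#' spikes that do not involve the transcriptional loop. The flag is only
#' valid when the trajectory has settled to within \code{settle_rtol} of the
#' activated steady state by its end.
#'
#' @param trajectory a \code{tcs_trajectory} from an activation protocol.
#' @param activated_ss the activated steady-state vector the trajectory
#'   approaches.
#' @param threshold relative exceedance defining overshoot (default 0.5).
#' @param require_mrna_overshoot require a concomitant downstream-mRNA peak.
#' @param mrna_margin relative margin by which the mRNA peak must exceed its
#'   steady state to count (default 1\%).
#' @param settle_rtol settling tolerance for validity (default 1\%).
#' @return list with \code{flag}, \code{magnitude} ((peak - ss)/ss),
#'   \code{peak_time}, \code{mrna_overshoot}, \code{valid}.
#' @export
overshoot <- function(trajectory, activated_ss, threshold = 0.5,
                      require_mrna_overshoot = TRUE, mrna_margin = 0.01,
                      settle_rtol = 0.01) {
  if (!isTRUE(attr(trajectory, "converged") %||% TRUE) ||
      nrow(trajectory) < 2L)
    return(list(flag = NA, magnitude = NA_real_, peak_time = NA_real_,
                mrna_overshoot = NA, valid = FALSE))
  final <- trajectory[nrow(trajectory), .TCS_SPECIES]
  sc <- pmax(abs(activated_ss), 1e-12 * max(abs(activated_ss), 1))
  valid <- max(abs(final - activated_ss) / sc) < settle_rtol
  ss <- unname(activated_ss["RRP2"])
  peak_i <- which.max(trajectory[, "RRP2"])
  peak <- unname(trajectory[peak_i, "RRP2"])
  magnitude <- if (ss > 0) (peak - ss) / ss else NA_real_
  mrna_ss <- unname(activated_ss["mRNA_ds"])
  mrna_over <- mrna_ss > 0 &&
    max(trajectory[, "mRNA_ds"]) > (1 + mrna_margin) * mrna_ss
  flag <- isTRUE(magnitude > threshold) &&
    (!require_mrna_overshoot || mrna_over)
  list(flag = if (valid) flag else NA, magnitude = magnitude,
       peak_time = unname(trajectory[peak_i, "time"]),
       mrna_overshoot = mrna_over, valid = valid)
}

.observable <- function(trajectory, observable) {
  if (observable %in% .TCS_SPECIES) return(trajectory[, observable])
  tot <- speciesTotals(trajectory[, .TCS_SPECIES, drop = FALSE])
  if (!observable %in% colnames(tot))
    stop("unknown observable: ", observable)
  tot[, observable]
}

.observableTarget <- function(state, observable) {
  if (observable %in% .TCS_SPECIES) return(unname(state[observable]))
  unname(speciesTotals(state)[observable])
}

#' Response time of an activation trajectory
#'
#' Time of the first upward crossing of \code{level} times the activated
#' steady-state value of an observable (a species name or one of
#' \code{"SHK_tot"}, \code{"RR_tot"}, \code{"RRP_tot"}), linearly
#' interpolated between output points. \code{level = 0.50} gives
#' \eqn{\tau_{50}}, \code{0.95} gives \eqn{\tau_{95}}. A trajectory that
#' starts at or above the target level has response time 0; a level never
#' reached is reported as \code{NA}.
#'
#' @param trajectory a \code{tcs_trajectory}.
#' @param observable species or total name.
#' @param level fraction of the steady-state value (0.50 or 0.95 in typical
#'   use).
#' @param target steady-state value of the observable; defaults to the
#'   trajectory's final value.
#' @return time in seconds, or \code{NA} if never reached.
#' @export
responseTime <- function(trajectory, observable = "DS", level = 0.95,
                         target = NULL) {
  y <- .observable(trajectory, observable)
  t <- trajectory[, "time"]
  if (is.null(target)) target <- y[length(y)]
  thr <- level * target
  if (y[1] >= thr) return(0)
  above <- which(y >= thr)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  t[i - 1] + (thr - y[i - 1]) * (t[i] - t[i - 1]) / (y[i] - y[i - 1])
}

## activation trajectory that extends its horizon until settled near act_ss
.activationTrajectory <- function(params, topology, k_ph_rest, k_ph_act,
                                  act_ss, state0 = NULL, n_out = 240L) {
  duration <- 60 / params$k_dil
  for (trial in 1:3) {
    proto <- if (is.null(state0))
      signalProtocol(0, k_ph_act, rest_k_ph = k_ph_rest)
    else
      signalProtocol(0, k_ph_act, init = "given_state",
                     rest_k_ph = k_ph_rest)
    traj <- integrateProtocol(params, topology, proto, duration = duration,
                              state0 = state0, n_out = n_out)
    if (!isTRUE(attr(traj, "converged"))) return(traj)
    final <- traj[nrow(traj), .TCS_SPECIES]
    sc <- pmax(abs(act_ss), 1e-12 * max(abs(act_ss), 1))
    if (max(abs(final - act_ss) / sc) < 0.01) return(traj)
    duration <- duration * 10
  }
  traj
}

#' Signal-interruption ("learning") experiment
#'
#' Simulates the canonical two-stimulus protocol: activate from the resting
#' steady state until the activated steady state is reached, interrupt the
#' signal (return to the resting level) for \code{interregnum} seconds, then
#' re-activate. Response times are \eqn{\tau_{50}} of total phosphorylated
#' response regulator (\code{RRP_tot}), measured against the activated steady
#' state: \code{tau_first} from rest, \code{tau_second} from the
#' end-of-interregnum state. A ratio \code{tau_first/tau_second > 1} means
#' the second response is faster — the system has "learned" by accumulating
#' SHK and RR protein during the first stimulus, quantified by
#' \code{delta_SHK_tot_pct} (percent change of total SHK over the episode
#' relative to rest). \eqn{\tau_{50}} of the downstream protein is reported
#' alongside.
#'
#' @inheritParams solveSteadyState
#' @param interregnum signal interruption length in seconds (default 2700 s,
#'   i.e. 45 min). With \code{interregnum = 0} the second stimulus starts at
#'   the activated state itself, so \code{tau_second = 0} and the ratio is
#'   unbounded (\code{Inf}).
#' @param k_ph_rest,k_ph_act resting and activating signal levels (s^-1).
#' @return list with \code{tau_first}, \code{tau_second}, \code{ratio},
#'   \code{delta_SHK_tot_pct}, \code{delta_RR_tot_pct}, \code{tau_first_ds},
#'   \code{tau_second_ds}, \code{converged}.
#' @export
learningExperiment <- function(params, topology = makeTopology("wild_type"),
                               interregnum = 2700, k_ph_rest = 10,
                               k_ph_act = 0.1) {
  fail <- list(tau_first = NA_real_, tau_second = NA_real_, ratio = NA_real_,
               delta_SHK_tot_pct = NA_real_, delta_RR_tot_pct = NA_real_,
               tau_first_ds = NA_real_, tau_second_ds = NA_real_,
               converged = FALSE)
  rest <- solveSteadyState(params, topology, k_ph = k_ph_rest)
  if (!rest$converged) return(fail)
  act <- solveSteadyState(params, topology, k_ph = k_ph_act,
                          guess = rest$state)
  if (!act$converged) return(fail)
  traj1 <- .activationTrajectory(params, topology, k_ph_rest, k_ph_act,
                                 act$state, state0 = rest$state)
  if (!isTRUE(attr(traj1, "converged"))) return(fail)
  tau1 <- responseTime(traj1, "RRP_tot", 0.5,
                       target = .observableTarget(act$state, "RRP_tot"))
  tau1_ds <- responseTime(traj1, "DS", 0.5, target = unname(act$state["DS"]))
  if (interregnum > 0) {
    off <- integrateProtocol(params, topology,
                             signalProtocol(0, k_ph_rest,
                                            init = "given_state"),
                             duration = interregnum, state0 = act$state)
    if (!isTRUE(attr(off, "converged"))) return(fail)
    s2 <- off[nrow(off), .TCS_SPECIES]
  } else {
    s2 <- act$state
  }
  tgt <- .observableTarget(act$state, "RRP_tot")
  if (.observableTarget(s2, "RRP_tot") >= 0.5 * tgt) {
    tau2 <- 0; tau2_ds <- 0
  } else {
    traj2 <- .activationTrajectory(params, topology, k_ph_rest, k_ph_act,
                                   act$state, state0 = s2)
    if (!isTRUE(attr(traj2, "converged"))) return(fail)
    tau2 <- responseTime(traj2, "RRP_tot", 0.5, target = tgt)
    tau2_ds <- responseTime(traj2, "DS", 0.5,
                            target = unname(act$state["DS"]))
  }
  totRest <- speciesTotals(rest$state)
  tot2 <- speciesTotals(s2)
  ratio <- if (is.na(tau1) || is.na(tau2)) NA_real_
           else if (tau2 == 0) Inf else tau1 / tau2
  list(tau_first = tau1, tau_second = tau2, ratio = ratio,
       delta_SHK_tot_pct = unname(100 * (tot2["SHK_tot"] -
         totRest["SHK_tot"]) / totRest["SHK_tot"]),
       delta_RR_tot_pct = unname(100 * (tot2["RR_tot"] -
         totRest["RR_tot"]) / totRest["RR_tot"]),
       tau_first_ds = tau1_ds, tau_second_ds = tau2_ds,
       converged = TRUE)
}

#' Induction range
#'
#' Steady-state difference of \eqn{[RRP_2]} between the high-signal limit
#' (\code{k_ph = 0}: phosphatase off, saturated response) and the basal
#' state (\code{k_ph = 10}), normalized to the same difference in the
#' calibrated no-feedback control. Values below 1 mean the feedback wiring
#' narrows the accessible output range.
#'
#' @inheritParams solveSteadyState
#' @param topology circuit variant to evaluate (wild type or a circuit
#'   variant); the no-feedback control is calibrated automatically at
#'   \code{calibration_signal} unless supplied.
#' @param k_ph_high,k_ph_low signal levels of the saturated (default 0) and
#'   basal (default 10) limits.
#' @param calibration_signal \code{k_ph} at which constitutive controls are
#'   calibrated (default 0.1).
#' @param nofb_topology optional precalibrated no-feedback control topology.
#' @return list with \code{range} (normalized), \code{raw_range},
#'   \code{control_range}, \code{converged}; a zero control range gives
#'   \code{range = NA} with \code{converged = FALSE}.
#' @export
inductionRange <- function(params, topology = makeTopology("wild_type"),
                           k_ph_high = 0, k_ph_low = 10,
                           calibration_signal = 0.1, nofb_topology = NULL) {
  fail <- list(range = NA_real_, raw_range = NA_real_,
               control_range = NA_real_, converged = FALSE)
  span <- function(topo) {
    lo <- solveSteadyState(params, topo, k_ph = k_ph_low)
    if (!lo$converged) return(NA_real_)
    hi <- solveSteadyState(params, topo, k_ph = k_ph_high,
                           guess = lo$state)
    if (!hi$converged) return(NA_real_)
    unname(hi$state["RRP2"] - lo$state["RRP2"])
  }
  if (is.null(nofb_topology)) {
    nofb_topology <- try(makeTopology("no_feedback", params,
                                      calibration_signal = calibration_signal),
                         silent = TRUE)
    if (inherits(nofb_topology, "try-error")) return(fail)
  }
  raw <- span(topology)
  ctrl <- span(nofb_topology)
  if (!is.finite(raw) || !is.finite(ctrl) || ctrl == 0) return(fail)
  list(range = raw / ctrl, raw_range = raw, control_range = ctrl,
       converged = TRUE)
}

#' Response-time ratio with and without feedback
#'
#' \eqn{\tau} of downstream-protein accumulation for a feedback wiring,
#' normalized to the calibrated no-feedback control going to the same
#' activated expression level. Ratios below 1 mean the feedback speeds the
#' response (the negative-feedback signature); above 1, slows it.
#'
#' @inheritParams inductionRange
#' @param level response-time level (default 0.95 for \eqn{\tau_{95}}).
#' @param observable observable for the response time (default "DS").
#' @param k_ph_rest,k_ph_act resting/activating signal.
#' @return list with \code{ratio}, \code{tau}, \code{tau_nofb},
#'   \code{converged}.
#' @export
responseTimeRatio <- function(params, topology = makeTopology("wild_type"),
                              level = 0.95, observable = "DS",
                              k_ph_rest = 10, k_ph_act = 0.1,
                              nofb_topology = NULL) {
  fail <- list(ratio = NA_real_, tau = NA_real_, tau_nofb = NA_real_,
               converged = FALSE)
  tauOf <- function(topo) {
    act <- solveSteadyState(params, topo, k_ph = k_ph_act)
    if (!act$converged) return(NA_real_)
    traj <- .activationTrajectory(params, topo, k_ph_rest, k_ph_act,
                                  act$state)
    if (!isTRUE(attr(traj, "converged"))) return(NA_real_)
    responseTime(traj, observable, level,
                 target = .observableTarget(act$state, observable))
  }
  if (is.null(nofb_topology)) {
    nofb_topology <- try(makeTopology("no_feedback", params,
                                      calibration_signal = k_ph_act),
                         silent = TRUE)
    if (inherits(nofb_topology, "try-error")) return(fail)
  }
  tau <- tauOf(topology)
  tau0 <- tauOf(nofb_topology)
  if (!is.finite(tau) || !is.finite(tau0) || tau0 == 0) return(fail)
  list(ratio = tau / tau0, tau = tau, tau_nofb = tau0, converged = TRUE)
}

#' Gain map over signal space
#'
#' Open-loop gain on a grid of signal values: a \code{k_ph} scan at fixed
#' kinase activity, or a full \code{k_ap x k_ph} map. Steady states are
#' continued along the \code{k_ph} axis for speed. The number of feedback
#' sign switches along each \code{k_ph} scan is reported (systems can
#' reverse sign more than once).
#'
#' @inheritParams openLoopGain
#' @param k_ph_grid positive signal grid (log-spaced recommended).
#' @param k_ap_grid optional kinase-activity grid; default: the parameter
#'   set's own \code{k_ap}.
#' @return data.frame in long format with columns \code{k_ap}, \code{k_ph},
#'   \code{gain}, \code{sign}, \code{converged}; attribute
#'   \code{"sign_switches"} (named per \code{k_ap}) counts sign reversals
#'   along \code{k_ph} (zero-labeled cells are transparent).
#' @export
gainScan <- function(params, k_ph_grid, k_ap_grid = params$k_ap,
                     rel_step = 0.01, sign_tol = 1e-4) {
  stopifnot(all(k_ph_grid > 0), all(k_ap_grid > 0))
  k_ph_grid <- sort(k_ph_grid, decreasing = TRUE)  # continue from rest down
  rows <- vector("list", length(k_ap_grid) * length(k_ph_grid))
  switches <- stats::setNames(integer(length(k_ap_grid)),
                              format(k_ap_grid))
  k <- 0L
  for (ia in seq_along(k_ap_grid)) {
    kap <- k_ap_grid[ia]
    guess <- NULL
    signs <- character(0)
    for (kph in k_ph_grid) {
      cl <- solveSteadyState(params, makeTopology("wild_type"),
                             k_ph = kph, k_ap = kap, guess = guess)
      g <- if (cl$converged)
        openLoopGain(params, k_ph = kph, k_ap = kap, rel_step = rel_step,
                     sign_tol = sign_tol, closed_ss = cl$state)
      else
        list(gain = NA_real_, sign = NA_character_, converged = FALSE)
      if (cl$converged) guess <- cl$state
      k <- k + 1L
      rows[[k]] <- data.frame(k_ap = kap, k_ph = kph, gain = g$gain,
                              sign = g$sign, converged = g$converged,
                              stringsAsFactors = FALSE)
      if (isTRUE(g$converged) && g$sign != "zero") signs <- c(signs, g$sign)
    }
    switches[ia] <- if (length(signs) > 1L) sum(signs[-1] != signs[-length(signs)]) else 0L
  }
  out <- do.call(rbind, rows)
  attr(out, "sign_switches") <- switches
  out
}

#' Dose-response curve
#'
#' Steady-state \eqn{[RRP_2]} across a \code{k_ph} grid (continued from the
#' resting end). The system's response increases with the signal, i.e.
#' \eqn{[RRP_2]} is non-increasing in \code{k_ph}.
#'
#' @inheritParams solveSteadyState
#' @param k_ph_grid positive signal grid.
#' @return data.frame with \code{k_ph}, \code{RRP2}, \code{converged}.
#' @export
doseResponse <- function(params, topology = makeTopology("wild_type"),
                         k_ph_grid = 10^seq(1, -3, length.out = 20)) {
  k_ph_grid <- sort(k_ph_grid, decreasing = TRUE)
  guess <- NULL
  rows <- lapply(k_ph_grid, function(kph) {
    ss <- solveSteadyState(params, topology, k_ph = kph, guess = guess)
    if (ss$converged) guess <<- ss$state
    data.frame(k_ph = kph,
               RRP2 = if (ss$converged) unname(ss$state["RRP2"]) else NA_real_,
               converged = ss$converged)
  })
  do.call(rbind, rows)
}
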