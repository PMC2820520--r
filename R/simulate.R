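## Steady-state solving and stiff time integration under piecewise-constant
## signal protocols. Integration runs on the compiled right-hand side
## (src/tcs_deriv.c) through deSolve; steady states are obtained by
## integrating toward the attractor and polishing with a damped Newton
## iteration on the pure-R derivative.

.DEFAULT_RTOL <- 1e-8
.DEFAULT_ATOL <- 1e-12

.integrateRaw <- function(y0, pv, times, rtol = .DEFAULT_RTOL,
                          atol = .DEFAULT_ATOL) {
  out <- try(deSolve::lsoda(
    y = stats::setNames(as.numeric(y0), .TCS_SPECIES),
    times = times, func = "tcs_derivs", parms = unname(pv),
    dllname = "tcsfeedback", initfunc = "tcs_init",
    rtol = rtol, atol = atol, maxsteps = 50000), silent = TRUE)
  if (inherits(out, "try-error")) return(NULL)
  if (nrow(out) < length(times)) return(NULL)  # integrator bailed out early
  out
}

## numerical Jacobian of the RHS (central differences)
.rhsJacobian <- function(y, pv) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * abs(y[j]) + 1e-12
    yp <- y; yp[j] <- y[j] + h
    ym <- y; ym[j] <- y[j] - h
    J[, j] <- (.rhs(yp, pv) - .rhs(ym, pv)) / (2 * h)
  }
  J
}

.residNorm <- function(f) max(abs(f))

## damped Newton polish; returns list(state, residual, converged)
.newtonPolish <- function(y, pv, tol, max_iter = 60L) {
  y <- pmax(y, 0)
  f <- .rhs(y, pv)
  best <- list(state = y, residual = .residNorm(f))
  for (i in seq_len(max_iter)) {
    tolAbs <- tol * max(1, max(abs(y)))
    if (.residNorm(f) < tolAbs)
      return(list(state = y, residual = .residNorm(f), converged = TRUE))
    J <- .rhsJacobian(y, pv)
    step <- try(solve(J, -f), silent = TRUE)
    if (inherits(step, "try-error")) {
      step <- try(qr.solve(J, -f), silent = TRUE)
      if (inherits(step, "try-error")) break
    }
    lambda <- 1
    improved <- FALSE
    for (k in 1:12) {
      yn <- y + lambda * step
      if (all(yn > -1e-12 * max(1, max(abs(y))))) {
        fn <- .rhs(pmax(yn, 0), pv)
        if (.residNorm(fn) < .residNorm(f)) {
          y <- pmax(yn, 0); f <- fn; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    if (.residNorm(f) < best$residual)
      best <- list(state = y, residual = .residNorm(f))
  }
  tolAbs <- tol * max(1, max(abs(best$state)))
  list(state = best$state, residual = best$residual,
       converged = best$residual < tolAbs)
}

#' Solve a steady state
#'
#' Finds the stable steady state of a circuit variant at fixed signal values.
#' From the initial condition (all-zero by default, or \code{guess}) the
#' system is integrated toward its attractor, then the endpoint is polished by
#' a damped Newton iteration until the residual derivative norm falls below
#' \code{tol * max(1, max(abs(state)))}. If Newton polishing fails, the
#' integration horizon is extended (up to 4000 dilution times) before the
#' solve is declared non-converged; failures are reported through the
#' \code{converged} flag, never as a silently zeroed state.
#'
#' @inheritParams reactionFluxes
#' @param guess optional initial state (e.g. a nearby steady state); when
#'   supplied, Newton runs first and integration is only a fallback.
#' @param tol relative residual tolerance (default 1e-10).
#' @return list with \code{state} (named vector), \code{residual},
#'   \code{converged} (logical).
#' @examples
#' p <- loadFixture("negative_example")
#' ss <- solveSteadyState(p, k_ph = 0.1)
#' ss$state["RRP2"]
#' @export
solveSteadyState <- function(params, topology = makeTopology("wild_type"),
                             k_ph = params$k_ph, k_ap = params$k_ap,
                             guess = NULL, tol = 1e-10) {
  .checkTopology(topology)
  if (params$k_dil <= 0)
    stop("steady-state solving requires k_dil > 0")
  pv <- .parmVector(params, topology, k_ph = k_ph, k_ap = k_ap)
  if (!is.null(guess)) {
    res <- .newtonPolish(as.numeric(guess), pv, tol)
    if (res$converged)
      return(list(state = stats::setNames(res$state, .TCS_SPECIES),
                  residual = res$residual, converged = TRUE))
    y0 <- pmax(as.numeric(guess), 0)
  } else {
    y0 <- numeric(length(.TCS_SPECIES))
  }
  horizon <- 40 / params$k_dil
  for (trial in 1:3) {
    out <- .integrateRaw(y0, pv, c(0, horizon / 4, horizon))
    if (!is.null(out)) {
      y <- pmax(as.numeric(out[nrow(out), -1]), 0)
      res <- .newtonPolish(y, pv, tol)
      if (res$converged)
        return(list(state = stats::setNames(res$state, .TCS_SPECIES),
                    residual = res$residual, converged = TRUE))
      y0 <- y
    }
    horizon <- horizon * 10
  }
  res <- .newtonPolish(y0, pv, tol)
  list(state = stats::setNames(res$state, .TCS_SPECIES),
       residual = res$residual, converged = res$converged)
}

#' Piecewise-constant signal protocols
#'
#' A protocol is an ordered set of segments, each holding the signal
#' parameters (\code{k_ph}, optionally \code{k_ap}) constant from its start
#' time to the next segment's start. The first segment must start at 0.
#'
#' @param times numeric vector of segment start times (s), strictly
#'   increasing, starting at 0.
#' @param k_ph phosphatase rate per segment (s^-1).
#' @param k_ap optional kinase rate per segment (NA = use the parameter set's
#'   value).
#' @param init \code{"resting_steady_state"} (the default: initialize at the
#'   steady state under \code{rest_k_ph}) or \code{"given_state"}.
#' @param rest_k_ph signal defining the resting steady state (default 10/s).
#' @return a \code{tcs_protocol} object.
#' @export
signalProtocol <- function(times, k_ph, k_ap = rep(NA_real_, length(times)),
                           init = c("resting_steady_state", "given_state"),
                           rest_k_ph = 10) {
  init <- match.arg(init)
  times <- as.numeric(times); k_ph <- as.numeric(k_ph)
  k_ap <- as.numeric(k_ap)
  if (length(times) != length(k_ph) || length(times) != length(k_ap))
    stop("times, k_ph, k_ap must have equal length")
  if (length(times) < 1L || times[1] != 0)
    stop("first protocol segment must start at time 0")
  if (any(diff(times) <= 0))
    stop("segment start times must be strictly increasing")
  if (any(k_ph < 0) || any(k_ap < 0, na.rm = TRUE))
    stop("signal values must be nonnegative")
  structure(list(times = times, k_ph = k_ph, k_ap = k_ap, init = init,
                 rest_k_ph = rest_k_ph),
            class = "tcs_protocol")
}

#' @export
print.tcs_protocol <- function(x, ...) {
  cat("Signal protocol (", x$init, ")\n", sep = "")
  print(data.frame(start_s = x$times, k_ph = x$k_ph, k_ap = x$k_ap))
  invisible(x)
}

#' Activation protocol
#'
#' The canonical stimulus of the model: the phosphatase signal drops from the
#' resting level (\code{k_ph} = 10/s) to the activating level (0.1/s) at
#' t = 0, starting from the resting steady state.
#'
#' @param k_ph_rest,k_ph_act resting and activating phosphatase rates (s^-1).
#' @return a \code{tcs_protocol}.
#' @export
activationProtocol <- function(k_ph_rest = 10, k_ph_act = 0.1)
  signalProtocol(0, k_ph_act, rest_k_ph = k_ph_rest)

## per-segment output grid: log-spaced early points capture the fast
## phospho-relaxation, denser linear tail resolves protein accumulation
.segmentGrid <- function(t0, t1, n = 240L) {
  span <- t1 - t0
  lo <- min(max(span * 1e-7, 1e-3), span / 10)
  early <- 10^seq(log10(lo), log10(span), length.out = (n * 3L) %/% 4L)
  grid <- unique(sort(c(0, early, seq(0, span, length.out = max(n %/% 4L, 2L)))))
  t0 + grid
}

#' Integrate a signal protocol
#'
#' Stiff integration (deSolve's \code{lsoda} on the compiled model) of any
#' circuit variant under a piecewise-constant protocol. Segment boundaries
#' are integration restart points. Output uses a mixed log/linear grid per
#' segment, dense enough for interpolation-based response-time readouts.
#'
#' @inheritParams solveSteadyState
#' @param protocol a \code{tcs_protocol}.
#' @param duration total duration (s), measured from time 0.
#' @param state0 initial state, required when the protocol's \code{init} is
#'   \code{"given_state"}.
#' @param n_out approximate number of output points per segment.
#' @param rtol,atol integrator tolerances.
#' @return a \code{tcs_trajectory}: matrix with a \code{time} column and one
#'   column per species, plus attributes \code{protocol} and
#'   \code{converged}; failure is reported via \code{attr(x, "converged")}
#'   and a diagnostic message attribute.
#' @export
integrateProtocol <- function(params, topology = makeTopology("wild_type"),
                              protocol = activationProtocol(),
                              duration, state0 = NULL, n_out = 240L,
                              rtol = .DEFAULT_RTOL, atol = .DEFAULT_ATOL) {
  .checkTopology(topology)
  if (!inherits(protocol, "tcs_protocol")) stop("protocol must be a tcs_protocol")
  if (duration <= max(protocol$times))
    stop("duration must exceed the last segment start")
  if (protocol$init == "given_state") {
    if (is.null(state0)) stop("protocol requires state0")
    y <- as.numeric(state0)
  } else {
    rest <- solveSteadyState(params, topology, k_ph = protocol$rest_k_ph)
    if (!rest$converged)
      return(structure(matrix(numeric(0), 0, 11), converged = FALSE,
                       message = "resting steady state did not converge",
                       class = "tcs_trajectory"))
    y <- as.numeric(rest$state)
  }
  bounds <- c(protocol$times, duration)
  pieces <- vector("list", length(protocol$times))
  for (i in seq_along(protocol$times)) {
    kap <- if (is.na(protocol$k_ap[i])) params$k_ap else protocol$k_ap[i]
    pv <- .parmVector(params, topology, k_ph = protocol$k_ph[i], k_ap = kap)
    times <- .segmentGrid(bounds[i], bounds[i + 1], n_out)
    out <- .integrateRaw(y, pv, times, rtol = rtol, atol = atol)
    if (is.null(out))
      return(structure(matrix(numeric(0), 0, 11), converged = FALSE,
                       message = sprintf("integration failed in segment %d", i),
                       class = "tcs_trajectory"))
    y <- as.numeric(out[nrow(out), -1])
    pieces[[i]] <- if (i > 1L) out[-1, , drop = FALSE] else out
  }
  traj <- do.call(rbind, pieces)
  colnames(traj) <- c("time", .TCS_SPECIES)
  structure(traj, protocol = protocol, converged = TRUE,
            class = "tcs_trajectory")
}

#' @export
print.tcs_trajectory <- function(x, ...) {
  if (!isTRUE(attr(x, "converged"))) {
    cat("TCS trajectory: FAILED (", attr(x, "message"), ")\n", sep = "")
    return(invisible(x))
  }
  cat("TCS trajectory:", nrow(x), "time points over",
      format(x[nrow(x), "time"]), "s\n")
  invisible(x)
}

#' Export a trajectory as a delimited table
#'
#' @param trajectory a \code{tcs_trajectory}.
#' @param path output CSV path.
#' @export
writeTrajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(unclass(trajectory)), path,
                   row.names = FALSE)
  invisible(path)
}

## time of (near-)settling of a trajectory onto target state: first time
## from which all species stay within rtol of target
.settlingTime <- function(traj, target, rtol = 0.01) {
  sc <- pmax(abs(target), 1e-12 * max(abs(target), 1))
  dev <- sweep(abs(sweep(traj[, .TCS_SPECIES, drop = FALSE], 2, target)),
               2, sc, "/")
  ok <- apply(dev, 1, max) < rtol
  settled <- rev(cumprod(rev(ok))) > 0  # settled from this row onward
  if (!any(settled)) return(NA_real_)
  traj[which(settled)[1], "time"]
}

#' Signal-interruption protocol
#'
#' Builds the "learning" stimulus schedule: activate from rest, hold until the
#' activated steady state is attained (settling detected on the simulated
#' activation time course), return the signal to the resting level for
#' \code{interregnum} seconds, then re-activate.
#'
#' @inheritParams solveSteadyState
#' @param interregnum duration (s) of the signal interruption; default 2700 s
#'   (45 min) — longer than phospho-relaxation (seconds-minutes), shorter than
#'   protein dilution (hours).
#' @param k_ph_rest,k_ph_act resting and activating signal levels.
#' @return a \code{tcs_protocol} with three segments (activate, interrupt,
#'   re-activate); for \code{interregnum = 0} a degenerate two-segment
#'   protocol with an immediate re-activation is returned.
#' @export
interruptionProtocol <- function(params, topology = makeTopology("wild_type"),
                                 interregnum = 2700, k_ph_rest = 10,
                                 k_ph_act = 0.1) {
  act <- solveSteadyState(params, topology, k_ph = k_ph_act)
  if (!act$converged) stop("activated steady state did not converge")
  traj <- integrateProtocol(params, topology,
                            activationProtocol(k_ph_rest, k_ph_act),
                            duration = 60 / params$k_dil)
  if (!isTRUE(attr(traj, "converged"))) stop("activation integration failed")
  t_act <- .settlingTime(traj, act$state, rtol = 0.005)
  if (is.na(t_act)) t_act <- traj[nrow(traj), "time"]
  if (interregnum <= 0)
    return(signalProtocol(c(0, t_act), c(k_ph_act, k_ph_act),
                          rest_k_ph = k_ph_rest))
  signalProtocol(c(0, t_act, t_act + interregnum),
                 c(k_ph_act, k_ph_rest, k_ph_act),
                 rest_k_ph = k_ph_rest)
}
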