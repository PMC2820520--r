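## Test-side oracles, written independently of the package internals.

## A second, straight-line transcription of the reaction rate laws: one
## named scalar per reaction row (pooled rows expanded per species).
oracleFluxes <- function(state, p, variant = "wild_type", R0 = NA,
                         const_tcs = NA, const_shk = NA, const_rr = NA,
                         k_ph = p$k_ph, k_ap = p$k_ap) {
  s <- as.list(state)
  hill <- function(a, K) if (a <= 0) 0 else a / (K + a)
  act_tcs <- if (variant == "open_loop") R0 else s$RRP2
  v <- c(
    r1  = if (variant == "no_feedback") const_tcs
          else p$k_txn * hill(act_tcs, p$K_m),
    r2  = p$k_txn * hill(s$RRP2, p$K_mDS),
    r3  = if (variant == "no_feedback") 0 else p$k_txnbasal,
    r4  = p$k_txnbasal,
    r5_mT = p$k_mRNAdeg * s$mRNA_tcs,
    r5_mD = p$k_mRNAdeg * s$mRNA_ds,
    r6  = if (variant == "circuit_I") const_shk else p$k_SKtsn * s$mRNA_tcs,
    r7  = if (variant == "circuit_II") const_rr
          else p$tsn_mult * p$k_SKtsn * s$mRNA_tcs,
    r8  = p$k_SKtsn * s$mRNA_ds,
    r9_SHK = p$k_dil * s$SHK, r9_SHKP = p$k_dil * s$SHKP,
    r9_RR = p$k_dil * s$RR, r9_RRP = p$k_dil * s$RRP,
    r9_Ct = p$k_dil * s$C_t, r9_Cp = p$k_dil * s$C_p,
    r9_RRP2 = p$k_dil * s$RRP2, r9_DS = p$k_dil * s$DS,
    r10 = k_ap * s$SHK,
    r11 = p$k_ad * s$SHKP,
    r12 = p$k_b * s$SHK * s$RRP,
    r13 = p$k_b1 * s$SHKP * s$RR,
    r14 = p$k_pt * s$C_p,
    r15 = p$k_tp * s$C_t,
    r16 = p$k_d * s$C_t,
    r17 = p$k_d1 * s$C_p,
    r18 = k_ph * s$C_t,
    r19 = p$k_exp * hill(s$RR, p$K_mexp),
    r20 = p$k_exd * hill(s$RRP, p$K_mexd),
    r21 = p$k_RRPdm * s$RRP^2,
    r22 = p$k_RRPmd * s$RRP2
  )
  v
}

## Open-loop gain by implicit differentiation of the steady-state system:
## at f(x, R0) = 0, dx/dR0 = -J^-1 df/dR0; gain = (R0/RRP2) dRRP2/dR0.
oracleGainSensitivity <- function(params, k_ph) {
  cl <- solveSteadyState(params, k_ph = k_ph)
  stopifnot(cl$converged)
  R0 <- unname(cl$state["RRP2"])
  topo <- makeTopology("open_loop", R0 = R0)
  op <- solveSteadyState(params, topo, k_ph = k_ph, guess = cl$state,
                         tol = 1e-13)
  stopifnot(op$converged)
  x <- op$state
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * abs(x[j]) + 1e-12
    xp <- x; xp[j] <- x[j] + h
    xm <- pmax(x, 0); xm[j] <- max(x[j] - h, 0)
    J[, j] <- (timeDerivative(xp, params, topo, k_ph = k_ph) -
               timeDerivative(xm, params, topo, k_ph = k_ph)) /
      (xp[j] - xm[j])
  }
  hR <- 1e-6 * R0
  fp <- timeDerivative(x, params, makeTopology("open_loop", R0 = R0 + hR),
                       k_ph = k_ph)
  fm <- timeDerivative(x, params, makeTopology("open_loop", R0 = R0 - hR),
                       k_ph = k_ph)
  dfdR0 <- (fp - fm) / (2 * hR)
  dxdR0 <- stats::setNames(solve(J, -dfdR0), tcsSpecies())
  (R0 / unname(x["RRP2"])) * unname(dxdR0["RRP2"])
}

## random nonnegative state on biologically plausible scales
randomState <- function(rng_scale = 1) {
  s <- stats::setNames(rng_scale * stats::runif(10) *
                         c(0.02, 0.02, 5, 5, 5, 1, 0.5, 0.5, 2, 5),
                       tcsSpecies())
  s
}

## parameters with all synthesis, degradation and dilution off (closed
## phospho-cycle; totals conserved)
conservativeParams <- function() {
  p <- loadFixture("negative_example")
  setParams(p, k_txn = 0, k_txnbasal = 0, k_SKtsn = 0, k_mRNAdeg = 0,
            k_dil = 0)
}

## rebuild a tcs_params from one survey row
paramsFromSurveyRow <- function(row, k_dil = 2e-4,
                                molecules_per_conc_unit = 1000) {
  vals <- as.list(row[tcsfeedback::tcsParamNames()[1:21]])
  tcsParams(lapply(vals, as.numeric), k_ph = 10, k_dil = k_dil,
            molecules_per_conc_unit = molecules_per_conc_unit)
}
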