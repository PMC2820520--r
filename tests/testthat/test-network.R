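test_that("an all-zero state produces only basal transcription flux", {
  for (fx in c("negative_example", "positive_example")) {
    p <- loadFixture(fx)
    fl <- reactionFluxes(tcsState(), p)
    expect_equal(unname(fl["r1_txn_tcs_regulated"]), 0)
    expect_equal(unname(fl["r2_txn_ds_regulated"]), 0)
    expect_equal(unname(fl["r3_txn_tcs_basal"]), p$k_txnbasal)
    expect_equal(unname(fl["r4_txn_ds_basal"]), p$k_txnbasal)
    other <- setdiff(names(fl), c("r3_txn_tcs_basal", "r4_txn_ds_basal"))
    expect_true(all(fl[other] == 0))
  }
})

test_that("exogenous phosphorylation vanishes at zero substrate", {
  p <- setParams(loadFixture("negative_example"), k_exp = 50)
  set.seed(11)
  s <- randomState()
  s["RR"] <- 0
  fl <- reactionFluxes(s, p)
  expect_identical(unname(fl["r19_exogenous_phosphorylation"]), 0)
})

test_that("negative concentrations and missing variant constants are rejected", {
  p <- loadFixture("negative_example")
  s <- tcsState(RR = -1)
  expect_error(reactionFluxes(s, p), "negative")
  expect_error(makeTopology("open_loop"), "R0")
  expect_error(makeTopology("circuit_I"), "calibration|const")
})

test_that("fluxes agree with an independently coded evaluator", {
  set.seed(21)
  for (fx in c("negative_example", "positive_example")) {
    p <- loadFixture(fx)
    for (i in 1:20) {
      s <- randomState()
      got <- reactionFluxes(s, p, expanded = TRUE)
      want <- oracleFluxes(s, p)
      expect_equal(unname(got), unname(want), tolerance = 1e-12)
      ## lumped Table-1 view pools decay and dilution rows
      lump <- reactionFluxes(s, p)
      expect_equal(unname(lump["r5_mrna_decay"]),
                   unname(want["r5_mT"] + want["r5_mD"]), tolerance = 1e-12)
      expect_equal(unname(lump["r9_protein_dilution"]),
                   sum(want[grep("^r9", names(want))]), tolerance = 1e-12)
    }
    ## circuit variants reroute the production fluxes
    sv <- randomState()
    topo <- makeTopology("open_loop", R0 = 0.7)
    expect_equal(unname(reactionFluxes(sv, p, topo, expanded = TRUE)),
                 unname(oracleFluxes(sv, p, "open_loop", R0 = 0.7)),
                 tolerance = 1e-12)
    topo <- makeTopology("circuit_II", const_rr_txn = 1e-3)
    expect_equal(unname(reactionFluxes(sv, p, topo, expanded = TRUE)),
                 unname(oracleFluxes(sv, p, "circuit_II", const_rr = 1e-3)),
                 tolerance = 1e-12)
  }
})

test_that("time derivative equals stoichiometry times elementary fluxes", {
  S <- stoichiometryMatrix(expanded = TRUE)
  expect_identical(dim(S), c(10L, 30L))
  p <- loadFixture("negative_example")
  topo <- makeTopology("wild_type")
  set.seed(31)
  for (i in 1:1000) {
    s <- randomState(rng_scale = stats::runif(1, 0.1, 10))
    v <- reactionFluxes(s, p, topo, expanded = TRUE)
    d <- timeDerivative(s, p, topo)
    expect_equal(unname(d), as.numeric(S %*% v), tolerance = 1e-12)
  }
})

test_that("totals are conserved when synthesis and loss are off", {
  p <- conservativeParams()
  set.seed(41)
  for (i in 1:50) {
    s <- randomState()
    d <- timeDerivative(s, p)
    dRR <- d[["RR"]] + d[["RRP"]] + d[["C_t"]] + d[["C_p"]] + 2 * d[["RRP2"]]
    dSHK <- d[["SHK"]] + d[["SHKP"]] + d[["C_t"]] + d[["C_p"]]
    scale <- max(abs(reactionFluxes(s, p)), 1e-12)
    expect_lt(abs(dRR) / scale, 1e-12)
    expect_lt(abs(dSHK) / scale, 1e-12)
  }
})

test_that("compiled and R derivative evaluators agree along a short step", {
  ## integrate a very short interval with the compiled RHS; the secant must
  ## match the pure-R derivative
  p <- loadFixture("positive_example")
  set.seed(51)
  for (i in 1:5) {
    s <- randomState()
    h <- 1e-6
    traj <- integrateProtocol(p, protocol = signalProtocol(0, p$k_ph,
                                                           init = "given_state"),
                              duration = h, state0 = s, n_out = 4,
                              rtol = 1e-10, atol = 1e-14)
    slope <- (traj[nrow(traj), tcsSpecies()] - s) / h
    d <- timeDerivative(s, p)
    denom <- max(abs(d))
    expect_lt(max(abs(slope - d)) / denom, 1e-3)
  }
})

test_that("derivative is zero at a solved steady state", {
  p <- loadFixture("negative_example")
  ss <- solveSteadyState(p, k_ph = 0.1)
  expect_true(ss$converged)
  d <- timeDerivative(ss$state, p, k_ph = 0.1)
  expect_lt(max(abs(d)), 1e-9 * max(1, max(abs(ss$state))))
})
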