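test_that("steady state is empty without production and phospho-free without kinase", {
  p <- loadFixture("negative_example")
  ss <- solveSteadyState(setParams(p, k_txn = 0, k_txnbasal = 0))
  expect_true(ss$converged)
  expect_equal(unname(ss$state), rep(0, 10))
  ## no phosphorylation source at all
  ss2 <- solveSteadyState(setParams(p, k_ap = 0, k_exp = 0))
  expect_true(ss2$converged)
  phospho <- c("SHKP", "RRP", "C_t", "C_p", "RRP2")
  expect_true(all(abs(ss2$state[phospho]) < 1e-10))
  expect_gt(ss2$state["SHK"], 0)
})

test_that("root-finder steady state matches long-time integration", {
  p <- loadFixture("negative_example")
  ss <- solveSteadyState(p, k_ph = 0.1)
  expect_lt(ss$residual, 1e-10 * max(1, max(abs(ss$state))))
  traj <- integrateProtocol(p, protocol = activationProtocol(),
                            duration = 50 / p$k_dil)
  final <- traj[nrow(traj), tcsSpecies()]
  sc <- pmax(abs(ss$state), 1e-9)
  expect_lt(max(abs(final - ss$state) / sc), 1e-6)
})

test_that("the resting equilibrium is invariant under a holding protocol", {
  p <- loadFixture("positive_example")
  proto <- signalProtocol(0, 10)
  traj <- integrateProtocol(p, protocol = proto, duration = 5e4)
  ref <- traj[1, tcsSpecies()]
  sc <- pmax(abs(ref), 1e-9)
  dev <- sweep(abs(sweep(traj[, tcsSpecies()], 2, ref)), 2, sc, "/")
  expect_lt(max(dev), 1e-6)
})

test_that("totals are conserved along trajectories without synthesis or loss", {
  p <- conservativeParams()
  set.seed(61)
  s0 <- randomState()
  traj <- integrateProtocol(p, protocol = signalProtocol(0, 2,
                                                         init = "given_state"),
                            duration = 1e4, state0 = s0)
  tot <- speciesTotals(traj[, tcsSpecies()])
  for (col in c("SHK_tot", "RR_tot")) {
    expect_lt(diff(range(tot[, col])) / tot[1, col], 1e-6)
  }
})

test_that("trajectories are insensitive to a tenfold tolerance refinement", {
  p <- loadFixture("negative_example")
  run <- function(rtol, atol)
    integrateProtocol(p, protocol = activationProtocol(), duration = 2e4,
                      rtol = rtol, atol = atol)
  a <- run(1e-8, 1e-12)
  b <- run(1e-9, 1e-13)
  for (tcheck in c(1e2, 1e3, 1e4)) {
    i <- which.min(abs(a[, "time"] - tcheck))
    sc <- pmax(abs(b[i, tcsSpecies()]), 1e-10)
    expect_lt(max(abs(a[i, tcsSpecies()] - b[i, tcsSpecies()]) / sc), 1e-5)
  }
})

test_that("trajectories stay nonnegative for random feasible-scale systems", {
  set.seed(71)
  iv <- samplingIntervals()
  n_ok <- 0
  for (i in 1:20) {
    p <- sampleParameterSet(iv)
    if (p$k_txnbasal >= p$k_txn || p$k_mRNAdeg <= p$k_dil) next
    traj <- integrateProtocol(p, protocol = activationProtocol(),
                              duration = 1e5)
    if (!isTRUE(attr(traj, "converged"))) next
    n_ok <- n_ok + 1
    expect_gt(min(traj[, tcsSpecies()]), -1e-8 * max(traj[, tcsSpecies()]))
  }
  expect_gt(n_ok, 5)
})

test_that("interruption protocols have the documented segment structure", {
  p <- loadFixture("positive_example")
  proto <- interruptionProtocol(p, interregnum = 2700)
  expect_length(proto$times, 3L)
  expect_identical(proto$k_ph, c(0.1, 10, 0.1))
  expect_equal(proto$times[3] - proto$times[2], 2700)
  p0 <- interruptionProtocol(p, interregnum = 0)
  expect_length(p0$times, 2L)
  expect_true(all(p0$k_ph == 0.1))
})

test_that("protocol validation rejects malformed schedules", {
  expect_error(signalProtocol(c(1, 2), c(10, 0.1)), "start at time 0")
  expect_error(signalProtocol(c(0, 5, 5), c(10, 0.1, 10)),
               "strictly increasing")
  expect_error(signalProtocol(0, -1), "nonnegative")
})

test_that("deactivation relaxes phospho-dimer faster than total kinase", {
  ## signal-off kinetics show two time scales: fast phospho-relaxation, slow
  ## protein decay
  for (fx in c("negative_example", "positive_example")) {
    p <- loadFixture(fx)
    act <- solveSteadyState(p, k_ph = 0.1)
    rest <- solveSteadyState(p, k_ph = 10)
    off <- integrateProtocol(p, protocol = signalProtocol(0, 10,
                                                          init = "given_state"),
                             duration = 60 / p$k_dil, state0 = act$state)
    halfTime <- function(obs) {
      y <- if (obs %in% tcsSpecies()) off[, obs]
           else speciesTotals(off[, tcsSpecies()])[, obs]
      a <- y[1]
      b <- if (obs %in% tcsSpecies()) unname(rest$state[obs])
           else unname(speciesTotals(rest$state)[obs])
      mid <- (a + b) / 2
      i <- which(y <= mid)[1]
      off[i - 1, "time"] + (mid - y[i - 1]) * (off[i, "time"] -
        off[i - 1, "time"]) / (y[i] - y[i - 1])
    }
    expect_lt(halfTime("RRP2"), halfTime("SHK_tot"))
  }
})
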