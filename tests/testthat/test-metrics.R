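test_that("open-loop gain is zero without regulated TCS transcription", {
  p <- setParams(loadFixture("negative_example"), k_txn = 0,
                 k_txnbasal = 1e-5)
  g <- openLoopGain(p, k_ph = 1)
  expect_true(g$converged)
  expect_identical(g$sign, "zero")
  expect_lt(abs(g$gain), 1e-4)
})

test_that("printed example sets separate by feedback sign at the sign-determination signal", {
  ## sign determination compares the system activated from k_ph = 10/s to the
  ## low phosphatase level of 1/s
  neg <- openLoopGain(loadFixture("negative_example"), k_ph = 1)
  pos <- openLoopGain(loadFixture("positive_example"), k_ph = 1)
  expect_true(neg$converged && pos$converged)
  expect_lt(neg$gain, 0)
  expect_gt(pos$gain, 0)
  expect_identical(neg$sign, "negative")
  expect_identical(pos$sign, "positive")
})

test_that("central-difference gain matches the implicit-sensitivity oracle", {
  for (fx in c("negative_example", "positive_example")) {
    p <- loadFixture(fx)
    for (kph in c(10, 1)) {
      gd <- openLoopGain(p, k_ph = kph)
      gs <- oracleGainSensitivity(p, k_ph = kph)
      expect_true(gd$converged)
      expect_lt(abs(gd$gain - gs) / max(abs(gs), 1e-3), 1e-3)
    }
  }
})

test_that("flux fraction is zero without exogenous phosphorylation and matches a duplicate evaluator", {
  p <- loadFixture("negative_example")
  f0 <- fluxFraction(setParams(p, k_exp = 0), k_ph = 0.1)
  expect_identical(f0$fraction, 0)
  f <- fluxFraction(p, k_ph = 0.1)
  ss <- solveSteadyState(p, k_ph = 0.1)
  o <- oracleFluxes(ss$state, p, k_ph = 0.1)
  expect_equal(f$J_E, unname(o["r19"]), tolerance = 1e-12)
  expect_equal(f$J_S, unname(o["r16"]), tolerance = 1e-12)
  expect_equal(f$fraction, unname(o["r19"] / (o["r19"] + o["r16"])),
               tolerance = 1e-12)
  expect_gte(f$fraction, 0)
  expect_lte(f$fraction, 1)
})

## build a synthetic settled activation trajectory with a controllable peak
syntheticTrajectory <- function(ss, peak_rrp2 = NA, peak_mrna = NA) {
  t <- seq(0, 2000, by = 5)
  shape <- 1 - exp(-t / 80)
  m <- sapply(tcsSpecies(), function(sp) unname(ss[sp]) * shape)
  bump <- exp(-((t - 1200) / 60)^2)
  if (!is.na(peak_rrp2))
    m[, "RRP2"] <- m[, "RRP2"] + (peak_rrp2 - 1) * unname(ss["RRP2"]) * bump
  if (!is.na(peak_mrna))
    m[, "mRNA_ds"] <- m[, "mRNA_ds"] +
      (peak_mrna - 1) * unname(ss["mRNA_ds"]) * bump
  structure(cbind(time = t, m), converged = TRUE, class = "tcs_trajectory")
}

test_that("overshoot detection obeys the 50% and mRNA-confirmation rules", {
  ss <- stats::setNames(c(0.01, 0.01, 2, 1, 2, 0.5, 0.2, 0.2, 1, 3),
                        tcsSpecies())
  mono <- syntheticTrajectory(ss)
  ov <- overshoot(mono, ss)
  expect_true(ov$valid)
  expect_false(ov$flag)
  expect_lte(ov$magnitude, 0)
  ## 1.6x peak in both RRP2 and downstream mRNA: flagged, magnitude 0.60
  both <- overshoot(syntheticTrajectory(ss, peak_rrp2 = 1.6, peak_mrna = 1.6),
                    ss)
  expect_true(both$flag)
  expect_equal(both$magnitude, 0.6, tolerance = 1e-6)
  ## RRP2 peak without an mRNA peak is excluded as non-transcriptional
  rrp_only <- overshoot(syntheticTrajectory(ss, peak_rrp2 = 1.6), ss)
  expect_false(rrp_only$flag)
  expect_true(overshoot(syntheticTrajectory(ss, peak_rrp2 = 1.6), ss,
                        require_mrna_overshoot = FALSE)$flag)
  ## unsettled trajectory invalidates the flag
  short <- syntheticTrajectory(ss, peak_rrp2 = 1.6, peak_mrna = 1.6)
  short <- structure(short[short[, "time"] <= 150, ], converged = TRUE,
                     class = "tcs_trajectory")
  expect_false(overshoot(short, ss)$valid)
})

test_that("response time interpolates crossings and handles edge cases", {
  ## pure birth-death accumulation x' = a - k x from 0: tau50 = ln(2)/k
  k <- 1 / 500; a <- 2e-3
  t <- seq(0, 6000, by = 10)
  x <- (a / k) * (1 - exp(-k * t))
  m <- matrix(0, length(t), 10, dimnames = list(NULL, tcsSpecies()))
  m[, "DS"] <- x
  traj <- structure(cbind(time = t, m), converged = TRUE,
                    class = "tcs_trajectory")
  tau <- responseTime(traj, "DS", 0.5, target = a / k)
  expect_equal(tau, log(2) / k, tolerance = 1e-3)
  ## starting at the target level gives tau = 0
  m2 <- m; m2[, "DS"] <- a / k
  traj2 <- structure(cbind(time = t, m2), converged = TRUE,
                     class = "tcs_trajectory")
  expect_identical(responseTime(traj2, "DS", 0.95, target = a / k), 0)
  ## a level never reached is undefined
  expect_true(is.na(responseTime(traj, "DS", 0.95,
                                 target = 10 * a / k)))
})

test_that("the negative-feedback example responds faster than the positive one", {
  taus <- sapply(c("negative_example", "positive_example"), function(fx) {
    p <- loadFixture(fx)
    act <- solveSteadyState(p, k_ph = 0.1)
    traj <- integrateProtocol(p, protocol = activationProtocol(),
                              duration = 60 / p$k_dil)
    responseTime(traj, "DS", 0.95, target = unname(act$state["DS"]))
  })
  expect_lt(taus[1], taus[2])
})

test_that("learning vanishes after a full relaxation and is unbounded without one", {
  p <- loadFixture("positive_example")
  full <- learningExperiment(p, interregnum = 100 / p$k_dil)
  expect_true(full$converged)
  expect_equal(full$ratio, 1, tolerance = 0.01)
  expect_lt(abs(full$delta_SHK_tot_pct), 1)
  none <- learningExperiment(p, interregnum = 0)
  expect_identical(none$ratio, Inf)
})

test_that("a 45-minute interruption leaves accumulated protein and speeds the second response", {
  p <- loadFixture("positive_example")
  le <- learningExperiment(p, interregnum = 2700)
  expect_true(le$converged)
  expect_gt(le$delta_SHK_tot_pct, 0)
  expect_gt(le$delta_RR_tot_pct, 0)
  expect_gt(le$ratio, 1)
})

test_that("induction range is exactly 1 for the no-feedback control and cross-checks directly", {
  p <- loadFixture("negative_example")
  nofb <- makeTopology("no_feedback", p, calibration_signal = 0.1)
  self <- inductionRange(p, topology = nofb, nofb_topology = nofb)
  expect_identical(self$range, 1)
  ir <- inductionRange(p, nofb_topology = nofb)
  expect_true(ir$converged)
  ## direct two-steady-state recomputation
  span <- function(topo) {
    lo <- solveSteadyState(p, topo, k_ph = 10)
    hi <- solveSteadyState(p, topo, k_ph = 0)
    unname(hi$state["RRP2"] - lo$state["RRP2"])
  }
  expect_equal(ir$range, span(makeTopology("wild_type")) / span(nofb),
               tolerance = 1e-6)
})

test_that("gain maps are consistent with pointwise gains and find sign switches", {
  p <- loadFixture("negative_example")
  grid <- 10^seq(-3, 1, length.out = 8)
  sc <- gainScan(p, k_ph_grid = grid)
  expect_identical(nrow(sc), 8L)
  i <- 3
  direct <- openLoopGain(p, k_ph = sc$k_ph[i])
  expect_equal(sc$gain[i], direct$gain, tolerance = 1e-6)
  expect_gte(attr(sc, "sign_switches")[[1]], 1L)
  ## without exogenous phosphorylation no negative-feedback cells appear
  p0 <- setParams(p, k_exp = 0)
  sc0 <- gainScan(p0, k_ph_grid = 10^seq(-2, 1, length.out = 6))
  expect_false(any(sc0$sign == "negative", na.rm = TRUE))
})

test_that("the dose response is monotone in the signal for both example sets", {
  for (fx in c("negative_example", "positive_example")) {
    dr <- doseResponse(loadFixture(fx))
    expect_true(all(dr$converged))
    ## grid is stored from high k_ph (rest) to low (activated): RRP2 rises
    expect_true(all(diff(dr$RRP2) >= -1e-9 * max(dr$RRP2)))
  }
})
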