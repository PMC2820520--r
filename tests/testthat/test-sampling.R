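test_that("log-uniform sampling is reproducible, respects bounds, and honors degenerate intervals", {
  iv <- samplingIntervals()
  expect_true(all(iv$low > 0))
  expect_true(all(iv$high > iv$low))
  set.seed(5); a <- sampleParameterSet(iv)
  set.seed(5); b <- sampleParameterSet(iv)
  expect_identical(unlist(a), unlist(b))
  for (nm in tcsParamNames()[1:21]) {
    lo <- iv$low[iv$parameter == nm]; hi <- iv$high[iv$parameter == nm]
    expect_gte(a[[nm]], lo); expect_lte(a[[nm]], hi)
  }
  ivd <- samplingIntervals(low = c(k_ap = 0.5), high = c(k_ap = 0.5))
  set.seed(6)
  expect_identical(sampleParameterSet(ivd)$k_ap, 0.5)
})

test_that("draws are log-uniform (Kolmogorov-Smirnov at n = 1e5)", {
  iv <- samplingIntervals(low = c(k_ap = 1e-3), high = c(k_ap = 10))
  set.seed(7)
  draws <- replicate(1e5, {
    u <- stats::runif(nrow(iv))
    exp(log(iv$low) + u * (log(iv$high) - log(iv$low)))[iv$parameter == "k_ap"]
  })
  ## the replicate above inlines the sampler's draw rule; check the actual
  ## sampler on a smaller run for agreement of the marginal too
  ks <- suppressWarnings(stats::ks.test(log10(draws), "punif", -3, 1))
  expect_gt(ks$p.value, 0.01)
  set.seed(8)
  small <- replicate(2000, sampleParameterSet(iv)$k_ap)
  ks2 <- suppressWarnings(stats::ks.test(log10(small), "punif", -3, 1))
  expect_gt(ks2$p.value, 0.01)
})

test_that("feasibility filter rejects parameter-level violations with reasons", {
  p <- loadFixture("positive_example")
  bad3 <- setParams(p, k_txnbasal = p$k_txn * 2)
  f3 <- feasibilityFilter(bad3)
  expect_identical(f3$verdict, "infeasible")
  expect_false(f3$criteria[["c3"]])
  expect_match(f3$reasons, "c3")
  bad2 <- setParams(p, k_mRNAdeg = p$k_dil / 2)
  expect_false(feasibilityFilter(bad2)$criteria[["c2"]])
  ## no phosphorylation source: induction impossible (criterion 4)
  dead <- setParams(p, k_ap = 0, k_exp = 0)
  fd <- feasibilityFilter(dead)
  expect_identical(fd$verdict, "infeasible")
  expect_false(fd$criteria[["c4"]])
})

test_that("the positive example set passes the full feasibility filter", {
  f <- feasibilityFilter(loadFixture("positive_example"), detail = TRUE)
  expect_identical(f$verdict, "feasible")
  expect_true(all(f$criteria))
  ## detail carries the steady states the criteria were evaluated on
  expect_true(all(c("rest", "act", "saturated", "rest_noreg") %in% names(f)))
  ## the negative example illustrates response kinetics but sits above the
  ## molecule-count thresholds at this growth rate: parameter-level criteria
  ## hold, steady-state-level ones do not
  fn <- feasibilityFilter(loadFixture("negative_example"))
  expect_true(all(fn$criteria[c("c1", "c2", "c3", "c4")]))
  expect_false(all(fn$criteria))
})

test_that("surveys are reproducible, byte-identical on disk, and match direct calls", {
  sv1 <- runSurvey(2, seed = 99, metrics = c("gain", "flux"))
  sv2 <- runSurvey(2, seed = 99, metrics = c("gain", "flux"))
  expect_identical(sv1, sv2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeSurvey(sv1, f1, provenance = FALSE)
  writeSurvey(sv2, f2, provenance = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  ## harness bypass: metrics recomputed directly from the stored parameters
  p <- paramsFromSurveyRow(sv1[1, ])
  g <- openLoopGain(p, k_ph = 0.1)
  expect_equal(sv1$gain[1], g$gain, tolerance = 1e-9)
  fl <- fluxFraction(p, k_ph = 0.1)
  expect_equal(sv1$flux_fraction[1], fl$fraction, tolerance = 1e-9)
  ## every record marked feasible re-passes the filter
  for (i in seq_len(nrow(sv1)))
    expect_identical(feasibilityFilter(paramsFromSurveyRow(sv1[i, ]))$verdict,
                     "feasible")
})

test_that("an empty survey returns an empty table and caps are reported", {
  sv <- runSurvey(0)
  expect_identical(nrow(sv), 0L)
  expect_warning(runSurvey(5, seed = 3, max_attempts = 2,
                           metrics = "gain"),
                 "attempt cap")
})
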