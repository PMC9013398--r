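test_that("RMS and MAD follow their definitions and units", {
  expect_equal(rmsError(c(0, 0, 0)), 0)
  expect_equal(madMonths(c(0, 0, 0)), 0)
  expect_equal(rmsError(c(0.5, -0.5)), 0.5)
  expect_equal(madMonths(c(0.5, -0.5)), 6.0)
  expect_equal(rmsError(c(1, 0, 0, 0)), 0.5)
  expect_equal(madMonths(c(1, 0, 0, 0)), 3.0)
  expect_error(rmsError(numeric()), "empty")
  expect_error(madMonths(numeric()), "empty")
})

test_that("MAD in years never exceeds the RMS error (Jensen)", {
  set.seed(31)
  for (i in 1:50) {
    e <- rnorm(sample(2:100, 1), 0, runif(1, 0.1, 2))
    expect_lte(madMonths(e) / 12, rmsError(e) + 1e-12)
  }
  # equality iff all absolute errors are equal
  expect_equal(madMonths(c(0.5, -0.5)) / 12, rmsError(c(0.5, -0.5)))
})

test_that("panel reference and its residual error follow the mean formulas", {
  expect_equal(panelReference(c(10, 10, 10)), 10)
  expect_equal(panelReference(rbind(c(9, 11), c(5, 7))), c(10, 6))
  expect_equal(referenceErrorSD(0.52, 3), 0.52 / sqrt(3))
  expect_equal(round(referenceErrorSD(0.52, 3), 3), 0.300)
  # the 6-rater formula gives 0.278, not a rounded-up 0.31
  expect_equal(round(referenceErrorSD(0.68, 6), 3), 0.278)
  expect_error(referenceErrorSD(0.5, 0), ">= 1")
})

test_that("quadrature decomposition reproduces the printed chain", {
  expect_equal(round(trueAccuracy(0.45, 0.31), 2), 0.33)
  expect_equal(round(raterVariability(0.62, 0.33), 2), 0.52)
  expect_equal(trueAccuracy(0.7, 0), 0.7)
  expect_equal(trueAccuracy(0.5, 0.5), 0)
  expect_error(trueAccuracy(0.3, 0.31), "infeasible")
  expect_error(raterVariability(0.3, 0.31), "infeasible")
})

test_that("decomposition round-trip is an exact algebraic identity", {
  set.seed(13)
  for (i in 1:50) {
    a <- runif(1, 0, 2); b <- runif(1, 0, 2)
    expect_equal(trueAccuracy(sqrt(a^2 + b^2), b), a, tolerance = 1e-12)
    expect_equal(raterVariability(sqrt(a^2 + b^2), a), b, tolerance = 1e-12)
  }
})

test_that("variance fractions are percentages of the natural variance", {
  expect_equal(round(varianceFraction(0.58)), 34)
  expect_equal(round(varianceFraction(0.33)), 11)
  expect_equal(varianceFraction(1.0), 100)
  expect_equal(varianceFraction(0.5, 2), 100 * 0.25 / 4)
})

test_that("single-case sensitivity separates RMS from MAD", {
  r <- singleCaseSensitivity(200, 0.45, 4.1, 4, 24)
  expect_equal(round(r$delta_mad_pct, 1), 2.4)
  expect_equal(round(r$delta_rms_pct, 1), 4.7)
  r0 <- singleCaseSensitivity(200, 0.45, 4.1, 4, 4)
  expect_equal(r0$delta_rms_pct, 0)
  expect_equal(r0$delta_mad_pct, 0)
  expect_error(singleCaseSensitivity(10, 0, 1, 1, 2), "undefined")
})

test_that("Bland-Altman uses the two-method mean, bias and 1.96 SD limits", {
  r <- blandAltman(c(10, 8), c(9, 9))
  expect_equal(r$table$mean, c(9.5, 8.5))
  expect_equal(r$table$diff, c(1, -1))
  expect_equal(r$bias, 0)
  expect_equal(r$loa, c(-1.96 * sd(c(1, -1)), 1.96 * sd(c(1, -1))))

  same <- blandAltman(c(3, 4, 5), c(3, 4, 5))
  expect_true(all(same$table$diff == 0))
  expect_equal(same$bias, 0)
  expect_error(blandAltman(1, 1), "at least 2")

  coh <- simulateCohort(SimulationSpec(nCases = 10000, sigmaAuto = 0.33,
                                       sigmaRater = 0.52, grossErrorRate = 0,
                                       truthRangeMale = c(3, 17),
                                       truthRangeFemale = c(3, 15),
                                       seed = 21))
  r <- blandAltman(coh$auto_ba, coh$rating_1)
  target <- sqrt(0.33^2 + 0.52^2)
  expect_lt(abs(sd(r$table$diff) - target), 3 * target / sqrt(2 * 10000))
})

test_that("agreement reports decompose a panel-rated cohort", {
  spec <- SimulationSpec(nCases = 4000, sigmaAuto = 0.33, sigmaRater = 0.52,
                         nRaters = 3, grossErrorRate = 0,
                         truthRangeMale = c(3, 17),
                         truthRangeFemale = c(3, 15), seed = 8)
  coh <- simulateCohort(spec)
  rep <- agreementReport(coh$auto_ba,
                         as.matrix(coh[paste0("rating_", 1:3)]))
  expect_s4_class(rep, "AgreementReport")
  expect_equal(rep@n, 4000L)
  expect_lt(abs(rep@raterSD - 0.52), 0.03)
  expect_lt(abs(rep@trueAccuracy - 0.33), 0.03)
  expect_lte(rep@madMonths / 12, rep@rms)
})

test_that("bootstrap decomposition recovers sigma_auto within 3 SE", {
  spec <- SimulationSpec(nCases = 2000, sigmaAuto = 0.33, sigmaRater = 0.52,
                         nRaters = 3, grossErrorRate = 0, seed = 19)
  coh <- simulateCohort(spec)
  d <- decomposeAccuracy(coh$auto_ba, as.matrix(coh[paste0("rating_", 1:3)]),
                         B = 200, seed = 1)
  expect_lt(abs(d$true_accuracy - 0.33), 3 * d$se)
})

test_that("report rounding reproduces the printed rates and ratios", {
  expect_equal(percentRate(59, 14036), 0.4)
  expect_equal(percentRate(330, 14036), 2.4)
  expect_equal(percentRate(121, 8250), 1.5)
  expect_equal(foldRatio(72, 6), 12)
})

test_that("disputed-case analysis counts disputes, proximity and grave errors", {
  # constructed 3-case table evaluated by hand
  auto <- c(10, 12.5, 10)
  manual <- c(12.5, 10, 10.5)
  panel <- rbind(c(10.1, 9.9, 10.0), c(10.1, 9.9, 10.0), c(10, 10, 10))
  d <- disputedCaseAnalysis(auto, manual, panel)
  expect_equal(d@nDisputed, 2L)      # case C differs by only 0.5
  expect_equal(d@nAutoCloser, 1L)    # case A
  expect_equal(d@nManualGrave, 1L)   # case A: manual 12.5 vs ref 10
  expect_equal(d@nAutoGrave, 1L)     # case B: auto 12.5 vs ref 10

  # no disputes when the methods agree
  d0 <- disputedCaseAnalysis(manual, manual, panel)
  expect_equal(d0@nDisputed, 0L)

  # row-order invariance
  ord <- c(3, 1, 2)
  d2 <- disputedCaseAnalysis(auto[ord], manual[ord], panel[ord, ])
  expect_equal(d2@nDisputed, d@nDisputed)
  expect_equal(d2@nAutoCloser, d@nAutoCloser)

  # label symmetry: swapping methods swaps the counts
  d3 <- disputedCaseAnalysis(manual, auto, panel)
  expect_equal(d3@nDisputed, d@nDisputed)
  expect_equal(d3@nManualGrave, d@nAutoGrave)
  expect_equal(d3@nAutoGrave, d@nManualGrave)
  expect_equal(d3@nAutoCloser, 1L)   # case B's original manual rating wins

  # a disputed case without a rerating panel is an error
  panelNA <- panel; panelNA[1, ] <- NA
  expect_error(disputedCaseAnalysis(auto, manual, panelNA), "missing")
})

test_that("the lower-sigma method makes fewer grave errors in simulation", {
  ok <- vapply(1:20, function(s) {
    d <- simulateDisputedWorkflow(
      SimulationSpec(nCases = 8250, sigmaAuto = 0.33, sigmaRater = 0.52,
                     seed = s))
    d@nManualGrave > d@nAutoGrave
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
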