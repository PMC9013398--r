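test_that("deviation threshold ramps linearly from birth to the plateau", {
  cfg <- ValidationConfig()
  expect_equal(deviationThreshold(0, cfg), 1.2)
  expect_equal(deviationThreshold(7, cfg), 2.4)
  expect_equal(deviationThreshold(12, cfg), 2.4)
  expect_equal(deviationThreshold(3.5, cfg), 1.2 + 1.2 * 3.5 / 7)
  # continuous, piecewise linear, non-decreasing over a fine grid
  ba <- seq(0, 20, by = 0.05)
  thr <- deviationThreshold(ba, cfg)
  expect_true(all(diff(thr) >= -1e-12))
  interior <- ba < 7
  expect_equal(thr[interior], 1.2 + (2.4 - 1.2) * ba[interior] / 7)
  expect_error(deviationThreshold(-1, cfg), "finite and >= 0")
  expect_error(deviationThreshold(NaN, cfg), "finite and >= 0")
})

test_that("appearance rejection uses a strict threshold and spares the rest", {
  cfg <- ValidationConfig()
  b <- boneTable(boneRoster(), rep(10, 21), rep(0, 21))
  expect_true(all(rejectByAppearance(b, cfg)$accepted))

  b$appearance_score <- c(0.9, rep(0.1, 20))
  r <- rejectByAppearance(b, cfg)
  expect_identical(r$accepted, c(FALSE, rep(TRUE, 20)))
  expect_identical(r$rejection_reason[1], "appearance")

  # values exactly at the threshold are kept
  b$appearance_score <- rep(0.5, 21)
  expect_true(all(rejectByAppearance(b, cfg)$accepted))

  b$appearance_score[1] <- 1.2
  expect_error(rejectByAppearance(b, cfg), "\\[0, 1\\]")
})

test_that("deviation rejection removes outliers worst-first against the LOO mean", {
  cfg <- ValidationConfig()
  r <- rejectByDeviation(cleanBones(10))
  expect_true(all(r$bones$accepted))
  expect_equal(r$consensus_ba, 10)

  # 3.0 y above the leave-one-out mean of 10 exceeds the 2.4 plateau
  b <- boneTable(boneRoster(), c(rep(10, 20), 13))
  r <- rejectByDeviation(b, cfg)
  expect_equal(sum(!r$bones$accepted), 1)
  expect_identical(r$bones$rejection_reason[!r$bones$accepted], "deviation")
  expect_equal(r$consensus_ba, 10)

  # 2.0 y is below the plateau: everything kept, contaminated mean
  b <- boneTable(boneRoster(), c(rep(10, 20), 12))
  r <- rejectByDeviation(b, cfg)
  expect_true(all(r$bones$accepted))
  expect_equal(r$consensus_ba, (20 * 10 + 12) / 21, tolerance = 1e-12)

  # low bone age: the ramp tightens the threshold below the deviation
  b <- boneTable(boneRoster()[1:11], c(rep(1, 10), 2.5))
  r <- rejectByDeviation(b, cfg)
  expect_equal(sum(!r$bones$accepted), 1)
  expect_equal(r$consensus_ba, 1)

  expect_error(rejectByDeviation(boneTable("radius", 5,
                                           1)[c(), , drop = FALSE]),
               "no accepted bones")
})

test_that("grand-mean single-pass mode is available for comparison", {
  cfg <- ValidationConfig(deviationMode = "grand_single")
  b <- boneTable(boneRoster(), c(rep(10, 20), 13))
  r <- rejectByDeviation(b, cfg)
  # grand mean 10.14; outlier deviation 2.86 > 2.4 -> rejected in one pass
  expect_equal(sum(!r$bones$accepted), 1)
  expect_equal(r$consensus_ba, 10)
})

test_that("image gates fire in order with the printed thresholds", {
  cfg <- ValidationConfig()

  # gate 1: fewer than 8 surviving bones, never bypassable
  b7 <- cleanBones(10, 7)
  a <- runCascade(b7, sharpness = 6, sex = "male")
  expect_identical(imageStatus(a), "hand_not_found")
  expect_true(is.na(finalBoneAge(a)))
  aBy <- runCascade(b7, sharpness = 6, sex = "male",
                    config = ValidationConfig(bypassQualityGates = TRUE))
  expect_identical(imageStatus(aBy), "hand_not_found")

  # gates 2 and 3: sharpness window (4, 13], strict comparisons
  expect_identical(imageStatus(runCascade(cleanBones(10), 14, "male")),
                   "too_sharp")
  expect_identical(imageStatus(runCascade(cleanBones(10), 13, "male")),
                   "accepted")
  expect_identical(imageStatus(runCascade(cleanBones(10), 3, "male")),
                   "too_blurred")
  expect_identical(imageStatus(runCascade(cleanBones(10), 4, "male")),
                   "accepted")
  expect_identical(
    imageStatus(runCascade(cleanBones(10), 14, "male",
                           ValidationConfig(bypassQualityGates = TRUE))),
    "accepted_with_warning")

  # gate 4: near-mature short bones with a rejected radius
  b <- boneTable(boneRoster(), c(14, rep(17.5, 20)))  # radius lags
  b$appearance_score[b$bone_id == "radius"] <- 0.9
  expect_identical(imageStatus(runCascade(b, 6, "male")), "no_radius_mature")
  expect_identical(imageStatus(runCascade(b, 6, "male",
                     ValidationConfig(bypassQualityGates = TRUE))),
                   "accepted_with_warning")
  # radius accepted: the rule does not fire even above the female limit
  b2 <- boneTable(boneRoster(), rep(15.5, 21))
  expect_identical(imageStatus(runCascade(b2, 6, "female")), "accepted")

  # missing sharpness is an input error while gates 2-3 can reject
  expect_error(runCascade(cleanBones(10), NA, "male"), "sharpness is missing")
})

test_that("the full cascade composes the steps and reports the final bone age", {
  a <- runCascade(cleanBones(8), 5.5, "female")
  expect_identical(imageStatus(a), "accepted")
  expect_equal(finalBoneAge(a), 8)
  expect_equal(acceptedBoneCount(a), 21)

  # 9 clean bones survive among 12 anomalous ones: accepted (>= 8)
  b <- boneTable(boneRoster(), rep(9, 21),
                 c(rep(0, 9), rep(1, 12)))
  a <- runCascade(b, 5.5, "female")
  expect_identical(imageStatus(a), "accepted")
  expect_equal(acceptedBoneCount(a), 9)
  expect_equal(finalBoneAge(a), 9)

  # 7 clean among 14 anomalous: hand not found
  b <- boneTable(boneRoster(), rep(9, 21), c(rep(0, 7), rep(1, 14)))
  expect_identical(imageStatus(runCascade(b, 5.5, "female")),
                   "hand_not_found")

  expect_error(runCascade(cleanBones(10, 1)[c(), , drop = FALSE], 5, "male"),
               "at least one bone")
})

test_that("the cascade is idempotent and permutation-invariant", {
  set.seed(42)
  cfg <- ValidationConfig()
  for (i in 1:20) {
    ba <- pmax(0, rnorm(21, runif(1, 1, 15), 0.8))
    ba[sample(21, 3)] <- ba[sample(21, 3)] + runif(3, 0, 5)
    sc <- runif(21, 0, 0.8)
    b <- boneTable(boneRoster(), ba, sc)
    a1 <- runCascade(b, 6, "male", cfg)

    # permutation invariance
    perm <- b[sample(nrow(b)), ]
    a2 <- runCascade(perm, 6, "male", cfg)
    expect_identical(bones(a1), bones(a2))
    expect_identical(imageStatus(a1), imageStatus(a2))

    # idempotence: surviving bones pass through unchanged
    surv <- bones(a1)[bones(a1)$accepted, , drop = FALSE]
    if (nrow(surv) > 0) {
      a3 <- runCascade(surv, 6, "male", cfg)
      expect_true(all(bones(a3)$accepted))
      if (imageStatus(a1) %in% c("accepted", "accepted_with_warning"))
        expect_equal(finalBoneAge(a3), finalBoneAge(a1))
    }
  }
})

test_that("bone tables enforce roster membership and basic invariants", {
  expect_error(boneTable("femur", 10), "unknown bone_id")
  expect_error(boneTable(c("radius", "radius"), c(1, 2)), "duplicate")
  expect_error(boneTable("radius", -1), ">= 0")
  expect_error(boneTable("radius", NaN), ">= 0")
  expect_length(boneRoster(), 21)
  expect_false(anyDuplicated(boneRoster()) > 0)
})
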