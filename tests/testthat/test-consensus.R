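# Consensus comparator parameters: TVD, PVD, PPV, MFI (quadrant), MHI.

test_that("flowScore maps the ordinal scale 0-3", {
  expect_identical(flowScore("absent"), 0L)
  expect_identical(flowScore("intermittent"), 1L)
  expect_identical(flowScore("sluggish"), 2L)
  expect_identical(flowScore("continuous"), 3L)
  expect_identical(flowScore(c("Continuous", " absent ")), c(3L, 0L))
  expect_error(flowScore("fast"), "unknown")
})

test_that("TVD is small-vessel length over field area in mm/mm^2", {
  # 20 segments of 1 mm each in a 2 mm x 2 mm field -> 20 mm / 4 mm^2 = 5
  clip <- makeClip(rep("continuous", 20), length_um = 1000,
                   fieldWidth = 2000, fieldHeight = 2000)
  expect_equal(totalVesselDensity(clip), 5.0)
  # segments above the diameter cutoff are excluded
  big <- makeClip(rep("continuous", 4), diameter = 25, length_um = 1000,
                  fieldWidth = 2000, fieldHeight = 2000)
  expect_equal(totalVesselDensity(big), 0)
  expect_equal(totalVesselDensity(big, smallVesselMaxDiameter = 30), 1.0)
  # doubling every centerline length doubles TVD
  half <- makeClip(rep("continuous", 10), length_um = 200)
  full <- makeClip(rep("continuous", 10), length_um = 400)
  expect_equal(totalVesselDensity(full), 2 * totalVesselDensity(half))
})

test_that("PPV is the perfused share of small-vessel segments", {
  clip <- makeClip(rep(c("continuous", "sluggish", "absent", "intermittent"),
                       c(5, 3, 1, 1)))
  expect_equal(proportionPerfused(clip), 0.8)
  expect_equal(proportionPerfused(makeClip(rep("absent", 7))), 0)
  expect_equal(proportionPerfused(makeClip(rep("continuous", 7))), 1)
  expect_error(proportionPerfused(makeClip(rep("absent", 3), diameter = 30)),
               "undefined")
})

test_that("PVD sums only perfused lengths and never exceeds TVD", {
  # 12 mm perfused length in a 2 x 2 mm field -> 3.0
  clip <- makeClip(rep(c("continuous", "absent"), c(12, 6)), length_um = 1000,
                   fieldWidth = 2000, fieldHeight = 2000)
  expect_equal(perfusedVesselDensity(clip), 3.0)
  allPerf <- makeClip(rep(c("continuous", "sluggish"), 5))
  expect_equal(perfusedVesselDensity(allPerf), totalVesselDensity(allPerf))
  expect_equal(perfusedVesselDensity(makeClip(rep("absent", 5))), 0)
  # property on random simulated clips
  set.seed(9)
  for (i in 1:15) {
    cl <- simulateClip(sample(10:40, 1), runif(1), runif(1, 0, 0.5))
    expect_lte(perfusedVesselDensity(cl), totalVesselDensity(cl) + 1e-12)
  }
})

test_that("quadrant MFI averages predominant flow scores over non-empty quadrants", {
  # one segment per quadrant: scores 3,2,2,3 -> 2.5
  clip <- makeClip(c("continuous", "sluggish", "sluggish", "continuous"),
                   quadrant = 1:4)
  expect_equal(mfiQuadrant(clip), 2.5)
  # all quadrants continuous -> 3
  expect_equal(mfiQuadrant(makeClip(rep("continuous", 8), quadrant = rep(1:4, 2))), 3.0)
  # empty quadrant excluded from the mean
  expect_equal(mfiQuadrant(makeClip(rep("continuous", 3), quadrant = 1:3)), 3.0)
  # predominance by count within quadrant
  clip2 <- makeClip(c(rep("continuous", 3), "absent"), quadrant = rep(1L, 4))
  expect_equal(mfiQuadrant(clip2), 3.0)
  # ties break towards the lower flow score
  tie <- makeClip(c("continuous", "absent"), quadrant = c(2L, 2L))
  expect_equal(mfiQuadrant(tie), 0)
  # MFI = 3 iff every non-empty quadrant is predominantly continuous
  expect_lt(mfiQuadrant(makeClip(c("sluggish", "continuous"), quadrant = c(1L, 2L))), 3)
})

test_that("MFI stays within [0, 3] on random fields", {
  set.seed(10)
  for (i in 1:20) {
    m <- mfiQuadrant(simulateClip(sample(6:40, 1), runif(1), runif(1, 0, 0.5)))
    expect_gte(m, 0)
    expect_lte(m, 3)
  }
})

test_that("MHI is the range of clip MFIs over their mean", {
  expect_equal(mhi(c(3, 3, 3, 3)), 0)
  expect_equal(mhi(c(3, 2, 2.75, 2.25)), 0.4)
  x <- c(2, 1, 1.5, 2.5)
  expect_equal(mhi(3 * x), mhi(x))  # scale invariance
  expect_equal(mhi(x) == 0, FALSE)
  expect_equal(mhi(rep(1.7, 4)), 0)
  expect_error(mhi(c(2)), "at least two")
  expect_error(mhi(c(0, 0, 0, 0)), "mean MFI is zero")
})

test_that("consensusParams returns one tidy row per clip", {
  clips <- list(makeClip(rep("continuous", 10), clipId = "a"),
                makeClip(rep(c("continuous", "absent"), 5), clipId = "b"))
  tab <- consensusParams(clips)
  expect_equal(tab$clip_id, c("a", "b"))
  expect_true(all(tab$pvd <= tab$tvd + 1e-12))
  expect_true(all(tab$ppv >= 0 & tab$ppv <= 1))
  expect_true(all(tab$mfi >= 0 & tab$mfi <= 3))
})

test_that("stopped fraction and MFI are strongly negatively rank-correlated", {
  set.seed(12)
  sev <- runif(60)
  frac <- numeric(60)
  mfi <- numeric(60)
  for (i in seq_along(sev)) {
    cl <- simulateClip(30, sev[i], 0)
    frac[i] <- stoppedFraction(cl)
    mfi[i] <- mfiQuadrant(cl)
  }
  expect_lt(cor(frac, mfi, method = "spearman"), -0.8)
})
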