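# Per-clip flow grading, heterogeneity detection, and four-clip aggregation.

test_that("stoppedFraction counts segments in the stopped set", {
  clip <- makeClip(rep(c("sluggish", "continuous"), c(5, 15)))
  expect_equal(stoppedFraction(clip), 0.25)
  expect_equal(stoppedFraction(makeClip(rep("continuous", 12))), 0)
  mixed <- makeClip(c(rep("continuous", 3), "sluggish", "absent", "intermittent"))
  expect_equal(stoppedFraction(mixed), 0.5)
  # configurable stopped set
  cfg <- ScoringConfig(stoppedCategories = c("absent", "sluggish"))
  expect_equal(stoppedFraction(mixed, cfg), 2 / 6)
})

test_that("empty clips are rejected by name", {
  seg <- data.frame(segment_id = character(), diameter_um = numeric(),
                    flow_category = character())
  seg$polyline <- list()
  empty <- ClipAnnotation("void", seg)
  expect_error(stoppedFraction(empty), "empty clip.*void")
  expect_error(detectHeterogeneity(empty), "empty clip")
  expect_error(assessClip(empty), "empty clip")
})

test_that("flow bands: < 25% normal, 25-50% impaired (closed), > 50% critical", {
  expect_equal(classifyClipFlow(0.24), "normal")
  expect_equal(classifyClipFlow(0.25), "impaired")
  expect_equal(classifyClipFlow(0.50), "impaired")
  expect_equal(classifyClipFlow(0.51), "critically_impaired")
  expect_equal(classifyClipFlow(c(0, 1)), c("normal", "critically_impaired"))
  expect_error(classifyClipFlow(1.2), "\\[0, 1\\]")
  expect_error(classifyClipFlow(-0.1), "\\[0, 1\\]")
  # custom bands move the boundaries with them
  cfg <- ScoringConfig(normalUpper = 0.1, criticalLower = 0.3)
  expect_equal(classifyClipFlow(c(0.09, 0.1, 0.3, 0.31), cfg),
               c("normal", "impaired", "impaired", "critically_impaired"))
})

test_that("heterogeneity needs strictly more than 5 deviant segments", {
  expect_equal(detectHeterogeneity(makeClip(rep(c("continuous", "sluggish"), c(14, 6)))),
               "present")
  expect_equal(detectHeterogeneity(makeClip(rep(c("continuous", "sluggish"), c(15, 5)))),
               "absent")
  expect_equal(detectHeterogeneity(makeClip(rep("sluggish", 30))), "absent")
})

test_that("heterogeneity is invariant to segment order and category relabeling", {
  set.seed(41)
  for (i in 1:25) {
    sizes <- as.vector(stats::rmultinom(1, size = sample(8:35, 1), prob = rep(1, 4)))
    cats <- rep(flowCategories(), sizes)
    base <- detectHeterogeneity(makeClip(cats))
    expect_equal(detectHeterogeneity(makeClip(sample(cats))), base)
    relabeled <- rep(sample(flowCategories()), sizes)
    expect_equal(detectHeterogeneity(makeClip(relabeled)), base)
  }
})

test_that("assessClip asks the heterogeneity question only for normal clips", {
  # 10% stopped, 2 deviants -> normal, absent
  a <- assessClip(makeClip(rep(c("continuous", "sluggish"), c(18, 2))))
  expect_equal(flowGrade(a), "normal")
  expect_equal(heterogeneity(a), "absent")
  # 30% stopped -> impaired, heterogeneity forced present even with few deviants
  b <- assessClip(makeClip(rep(c("continuous", "sluggish"), c(14, 6))))
  expect_equal(flowGrade(b), "impaired")
  expect_equal(heterogeneity(b), "present")
  # 60% stopped -> critically impaired, present
  c3 <- assessClip(makeClip(rep(c("continuous", "absent"), c(8, 12))))
  expect_equal(flowGrade(c3), "critically_impaired")
  expect_equal(heterogeneity(c3), "present")
  expect_equal(stoppedFraction(c3), 0.6)
})

test_that("ClipAssessment enforces the non-normal-implies-heterogeneity invariant", {
  expect_equal(heterogeneity(ClipAssessment("x", "impaired", "absent")), "present")
  expect_error(new("ClipAssessment", clipId = "x", stoppedFraction = 0.4,
                   flowGrade = "impaired", heterogeneity = "absent"),
               "always present")
})

test_that("computePoem reproduces the published mapping", {
  expect_equal(poemScore(computePoem(c("critical", "critical", "normal_no_het", "normal_no_het"))), 1L)
  expect_equal(poemScore(computePoem(c("impaired", "impaired", "normal_no_het", "normal_no_het"))), 2L)
  expect_equal(poemScore(computePoem(rep("normal_het", 4))), 3L)
  expect_equal(poemScore(computePoem(c("normal_het", "normal_het", "normal_no_het", "normal_no_het"))), 4L)
  expect_equal(poemScore(computePoem(rep("normal_no_het", 4))), 5L)
  # one critical + one impaired counts the critical clip toward the impaired tally
  expect_equal(poemScore(computePoem(c("critical", "impaired", "normal_no_het", "normal_no_het"))), 2L)
  # labels track the score
  expect_equal(poemLabel(computePoem(rep("normal_het", 4))),
               "normal with marked heterogeneity")
  expect_equal(poemLabel(computePoem(c("impaired", "impaired", "normal_het", "normal_no_het"))),
               "impaired")
})

test_that("computePoem rejects anything but exactly four clips", {
  expect_error(computePoem(c("impaired", "impaired", "normal_no_het")), "exactly 4")
  expect_error(computePoem(rep("normal_no_het", 5)), "exactly 4")
  expect_error(computePoem(list()), "exactly 4")
})

test_that("computePoem is total, permutation invariant, and monotone", {
  combos <- allStateCombos()
  scoreOf <- function(states) poemScore(computePoem(states))
  scores <- apply(combos, 1, scoreOf)
  expect_true(all(scores %in% 1:5))

  set.seed(7)
  for (i in sample(nrow(combos), 40)) {
    states <- unlist(combos[i, ])
    for (r in 1:3) {
      expect_equal(scoreOf(sample(states)), scores[i])
    }
  }

  # degrading any single clip one step never raises the overall score
  states <- c("critical", "impaired", "normal_het", "normal_no_het")
  for (i in seq_len(nrow(combos))) {
    s0 <- unlist(combos[i, ])
    for (j in 1:4) {
      idx <- match(s0[j], states)
      if (idx == 1L) next
      s1 <- s0
      s1[j] <- states[idx - 1L]
      expect_lte(scoreOf(s1), scores[i])
    }
  }
})

test_that("sequence assessments carry their clips and serialize to JSON", {
  sa <- computePoem(c("impaired", "impaired", "normal_no_het", "normal_no_het"),
                    sequenceId = "pt1_t0")
  expect_length(clipAssessments(sa), 4L)
  j <- jsonlite::fromJSON(assessmentToJSON(sa))
  expect_equal(j$poem_score, 2L)
  expect_equal(j$label, "impaired")
  expect_equal(j$sequence_id, "pt1_t0")
  expect_equal(nrow(j$clips), 4L)
})
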