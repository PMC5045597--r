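# ICC, error-score regression, linear R^2, Kruskal-Wallis + Dunn.

test_that("identical rater columns give ICC 1 in both flavors", {
  m <- cbind(c(5, 3, 1, 4), c(5, 3, 1, 4), c(5, 3, 1, 4))
  expect_equal(icc(m, "consistency")$estimate, 1)
  expect_equal(icc(m, "agreement")$estimate, 1)
})

test_that("a constant rater offset spares consistency but lowers agreement", {
  m <- cbind(c(4, 3, 1, 2), c(4, 2, 1, 3), c(3, 3, 1, 2))
  base_c <- icc(m, "consistency")$estimate
  base_a <- icc(m, "agreement")$estimate
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 1
  expect_equal(icc(shifted, "consistency")$estimate, base_c)
  expect_lt(icc(shifted, "agreement")$estimate, base_a)
  expect_lte(icc(shifted, "agreement")$estimate,
             icc(shifted, "consistency")$estimate)
})

test_that("fixed 4x3 matrix matches the two-way ANOVA oracle", {
  m <- rbind(c(5, 4, 5), c(2, 2, 1), c(3, 4, 3), c(1, 2, 2))
  for (flavor in c("consistency", "agreement")) {
    for (measure in c("single", "average")) {
      expect_equal(icc(m, flavor, measure)$estimate,
                   iccOracle(m, flavor, measure), tolerance = 1e-12)
    }
  }
})

test_that("ICC confidence interval brackets the estimate", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(sample(1:5, 8 * 5, TRUE), 8, 5)
    if (var(rowMeans(m)) == 0) next
    for (flavor in c("consistency", "agreement")) {
      r <- icc(m, flavor)
      expect_lte(r$ci_low, r$estimate + 1e-12)
      expect_gte(r$ci_high, r$estimate - 1e-12)
    }
  }
})

test_that("constant ratings are a degenerate-variance error", {
  m <- matrix(3, 4, 3, dimnames = list(paste0("i", 1:4), paste0("r", 1:3)))
  expect_error(icc(m, "consistency"), "degenerate")
  expect_error(icc(cbind(1:4, 1:4), "consistency"), NA)
})

test_that("RatingMatrix validates completeness and score range", {
  expect_error(RatingMatrix(cbind(c(1, 2), c(3, NA))), "complete")
  expect_error(RatingMatrix(cbind(c(1, 6), c(3, 2))), "1..5")
  expect_error(RatingMatrix(matrix(3, 1, 3)), "at least 2")
  rm <- RatingMatrix(cbind(c(1, 2), c(3, 2)))
  expect_equal(dim(scores(rm)), c(2L, 2L))
})

test_that("error-score regression flags the all-zero case and finds a biased rater", {
  m <- cbind(c(5, 3, 2, 1, 4), c(5, 3, 2, 1, 4), c(5, 3, 2, 1, 4))
  expert <- c(5, 3, 2, 1, 4)
  r <- errorScoreRegression(m, expert)
  expect_true(r$degenerate)
  expect_true(is.na(r$p_rater))

  biased <- m
  biased[, 2] <- pmin(biased[, 2] + 1, 5)
  biased[1, 2] <- 5  # score 5 stays 5: bias +1 where possible
  r2 <- errorScoreRegression(biased, expert)
  expect_false(r2$degenerate)
  expect_lt(r2$p_rater, 0.01)

  # oracle: balanced two-way F for the rater factor from explicit sums of squares
  err <- biased - matrix(expert, nrow(biased), ncol(biased))
  n <- nrow(err); k <- ncol(err)
  grand <- mean(err)
  ssr <- k * sum((rowMeans(err) - grand)^2)
  ssc <- n * sum((colMeans(err) - grand)^2)
  sse <- sum((err - grand)^2) - ssr - ssc
  fRater <- (ssc / (k - 1)) / (sse / ((n - 1) * (k - 1)))
  pRater <- pf(fRater, k - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  expect_equal(r2$p_rater, pRater, tolerance = 1e-10)
  fItem <- (ssr / (n - 1)) / (sse / ((n - 1) * (k - 1)))
  expect_equal(r2$p_item, pf(fItem, n - 1, (n - 1) * (k - 1), lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("linearR2 matches the squared-correlation identity", {
  x <- c(1, 2, 3, 4, 5)
  exact <- linearR2(x, 2 * x + 1)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(linearR2(x, rep(4, 5))$r_squared, 0)
  # fixed 6-point fixture against the Pearson identity
  xf <- c(1, 1, 2, 3, 4, 5)
  yf <- c(2.3, 1.9, 2.8, 2.6, 4.0, 4.4)
  expect_equal(linearR2(xf, yf)$r_squared, cor(xf, yf)^2, tolerance = 1e-12)
  # random fixtures
  set.seed(31)
  for (i in 1:10) {
    xr <- rnorm(12)
    yr <- rnorm(12)
    expect_equal(linearR2(xr, yr)$r_squared, cor(xr, yr)^2, tolerance = 1e-10)
  }
  expect_error(linearR2(rep(2, 5), rnorm(5)), "constant")
  expect_error(linearR2(1:2, 1:2), "at least 3")
})

test_that("identical groups give H = 0 and two-group z^2 equals H", {
  r <- kruskalDunn(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r$kw_h, 0)
  set.seed(32)
  for (i in 1:10) {
    v <- c(rnorm(6), rnorm(5, 1))
    g <- rep(c("a", "b"), c(6, 5))
    r <- kruskalDunn(v, g)
    expect_equal(r$pairwise$z^2, r$kw_h, tolerance = 1e-10)
  }
})

test_that("Dunn adjusted p-values are valid and monotone in comparisons", {
  set.seed(33)
  v <- rnorm(24)
  g <- rep(letters[1:4], each = 6)
  r <- kruskalDunn(v, g)
  expect_equal(nrow(r$pairwise), 6L)
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p_raw))
  expect_true(all(r$pairwise$p_adj <= 1))
  r2 <- kruskalDunn(v, g, adjust = "none")
  expect_equal(r2$pairwise$p_adj, r2$pairwise$p_raw)
  expect_error(kruskalDunn(v, rep("a", 24)), "two groups")
})
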