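# Fixture builders shared across test files. All fixtures are constructed
# in code; nothing is read from disk.

# A clip whose segments carry the given flow categories. Polylines are laid
# out on a grid inside the field so geometry is always valid; `quadrant`
# (optional, values 1-4: TL, TR, BL, BR) pins each segment's midpoint into a
# chosen quadrant of the field for MFI tests. `length_um` fixes every
# centerline length for density tests.
makeClip <- function(categories, clipId = "clip", quadrant = NULL,
                     diameter = 8, length_um = 100,
                     fieldWidth = 1000, fieldHeight = 750) {
  n <- length(categories)
  if (is.null(quadrant)) quadrant <- rep(1:4, length.out = n)
  qx <- c(0, fieldWidth / 2, 0, fieldWidth / 2)[quadrant]
  qy <- c(0, 0, fieldHeight / 2, fieldHeight / 2)[quadrant]
  # stack short horizontal segments inside each quadrant
  offset <- stats::ave(seq_len(n), quadrant, FUN = seq_along)
  y <- qy + 10 + (offset * 17) %% (fieldHeight / 2 - 20)
  x0 <- qx + 20
  seg <- data.frame(
    segment_id = sprintf("%s_s%03d", clipId, seq_len(n)),
    diameter_um = rep(diameter, length.out = n),
    flow_category = categories,
    stringsAsFactors = FALSE
  )
  seg$polyline <- lapply(seq_len(n), function(i) {
    x1 <- min(x0[i] + length_um, fieldWidth - 5)
    rem <- length_um - (x1 - x0[i])
    if (rem > 0) {
      # fold the remaining arc length downward at the field edge
      cbind(c(x0[i], x1, x1), c(y[i], y[i], y[i] + rem))
    } else {
      cbind(c(x0[i], x1), c(y[i], y[i]))
    }
  })
  ClipAnnotation(clipId, seg, fieldWidth, fieldHeight)
}

# all 256 four-clip state combinations
allStateCombos <- function() {
  states <- c("critical", "impaired", "normal_het", "normal_no_het")
  expand.grid(c1 = states, c2 = states, c3 = states, c4 = states,
              stringsAsFactors = FALSE)
}

# textbook two-way ICC oracle: mean squares extracted via aov(), estimates
# assembled from the published variance-component formulas (independent of
# the package's direct sums-of-squares route)
iccOracle <- function(m, flavor, measure = "single") {
  d <- data.frame(
    score = as.vector(m),
    item = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  ms <- summary(aov(score ~ item + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(m); k <- ncol(m)
  if (flavor == "consistency") {
    if (measure == "single") (msr - mse) / (msr + (k - 1) * mse) else (msr - mse) / msr
  } else {
    if (measure == "single") {
      (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    } else {
      (msr - mse) / (msr + (msc - mse) / n)
    }
  }
}
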