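## Synthetic vessel-field and rater-study simulator. Everything here is
## synthetic plumbing: it emulates segment-level annotations of sublingual
## video-microscopy clips so the scoring, consensus-parameter and agreement
## modules can be exercised end to end without clinical video data.

## Severity tilt: severity s in [0,1] maps the four ordinal flow categories
## onto a binomial(3, 1 - s) distribution of the 0-3 flow score. s = 0 puts
## all mass on continuous, s = 1 all mass on absent, and intermediate s
## moves smoothly through mixed compositions along the ordinal scale.
.severityProbs <- function(severity) {
  stats::dbinom(0:3, size = 3, prob = 1 - severity)
}

## the deviant flow regime sits one severity band (a third of the scale,
## i.e. one flow-category step in expectation) away from the base regime,
## towards worse flow unless the base is already in the worst third.
.deviantSeverity <- function(severity) {
  if (severity <= 2 / 3) severity + 1 / 3 else severity - 1 / 3
}

## expected fraction of non-continuous ("stopped") segments in a clip
## simulated at (severity, heterogeneityLevel)
.expectedStoppedFraction <- function(severity, het) {
  pContBase <- (1 - severity)^3
  pContDev <- (1 - .deviantSeverity(severity))^3
  1 - ((1 - het) * pContBase + het * pContDev)
}

## severity whose expected stopped fraction equals `target` at the given
## mixing weight; clamped to the attainable range (the mixing alone puts a
## floor on the stopped fraction, and the expectation peaks at severity 2/3
## where the deviant regime is all-absent)
.severityForStoppedFraction <- function(target, het) {
  if (.expectedStoppedFraction(0, het) >= target) return(0)
  if (.expectedStoppedFraction(2 / 3, het) <= target) return(2 / 3)
  stats::uniroot(function(s) .expectedStoppedFraction(s, het) - target,
                 c(0, 2 / 3), tol = 1e-9)$root
}

.checkProb <- function(x, name, upper = 1) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > upper) {
    stop(sprintf("%s must be a single value in [0, %g]", name, upper), call. = FALSE)
  }
}

#' Simulate one annotated video clip
#'
#' Draws a synthetic vessel field: random centerline polylines inside the
#' field of view, lognormal diameters, and per-segment flow categories from
#' a severity-tilted distribution. Severity 0 yields all-continuous flow,
#' severity 1 all-absent, with mixed compositions in between (binomial tilt
#' of the 0-3 flow score). A fraction \code{heterogeneityLevel} of segments
#' is drawn instead from a second regime one severity band away, creating
#' within-clip flow heterogeneity.
#'
#' @param nSegments Number of vessel segments (>= 6 so the >5-deviant
#'   heterogeneity rule is reachable).
#' @param severity Value in \code{[0, 1]} tilting flow from continuous
#'   towards absent.
#' @param heterogeneityLevel Value in \code{[0, 1]}: expected fraction of
#'   segments drawn from the deviant regime.
#' @param fieldWidth,fieldHeight Field of view in micrometres.
#' @param clipId Identifier for the simulated clip.
#' @param seed Optional integer seed; given the same seed and arguments the
#'   clip is reproduced exactly. When \code{NULL} the current RNG stream is
#'   used (callers seed once per study).
#' @return A \code{\link{ClipAnnotation}}.
#' @export
#' @examples
#' clip <- simulateClip(20, severity = 0.1, heterogeneityLevel = 0.3, seed = 1)
#' assessClip(clip)
simulateClip <- function(nSegments = 25, severity = 0, heterogeneityLevel = 0,
                         fieldWidth = 1000, fieldHeight = 750,
                         clipId = "simclip", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(nSegments) != 1L || nSegments < 6L) {
    stop("nSegments must be a single integer >= 6", call. = FALSE)
  }
  .checkProb(severity, "severity")
  .checkProb(heterogeneityLevel, "heterogeneityLevel")
  n <- as.integer(nSegments)

  deviant <- runif(n) < heterogeneityLevel
  pBase <- .severityProbs(severity)
  pDev <- .severityProbs(.deviantSeverity(severity))
  score <- integer(n)
  score[!deviant] <- sample(0:3, sum(!deviant), replace = TRUE, prob = pBase)
  score[deviant] <- sample(0:3, sum(deviant), replace = TRUE, prob = pDev)
  category <- .FLOW_CATEGORIES[score + 1L]

  diam <- pmin(pmax(rlnorm(n, meanlog = log(9), sdlog = 0.35), 3), 35)

  ## polylines: start inside an inner box, head in a random direction for a
  ## random arc length, with a perpendicular kink at the midpoint
  margin <- 0.05
  x0 <- runif(n, margin * fieldWidth, (1 - margin) * fieldWidth)
  y0 <- runif(n, margin * fieldHeight, (1 - margin) * fieldHeight)
  ang <- runif(n, 0, 2 * pi)
  len <- runif(n, 60, 350)
  polyline <- vector("list", n)
  for (i in seq_len(n)) {
    dx <- cos(ang[i]); dy <- sin(ang[i])
    ## largest step keeping the endpoint inside the field
    tmax <- min(
      if (dx > 0) (fieldWidth - x0[i]) / dx else if (dx < 0) -x0[i] / dx else Inf,
      if (dy > 0) (fieldHeight - y0[i]) / dy else if (dy < 0) -y0[i] / dy else Inf
    )
    L <- min(len[i], 0.95 * tmax)
    L <- max(L, 20)
    x1 <- x0[i] + L * dx; y1 <- y0[i] + L * dy
    jit <- runif(1, -15, 15)
    mx <- (x0[i] + x1) / 2 - jit * dy
    my <- (y0[i] + y1) / 2 + jit * dx
    mx <- min(max(mx, 0), fieldWidth)
    my <- min(max(my, 0), fieldHeight)
    x1 <- min(max(x1, 0), fieldWidth)
    y1 <- min(max(y1, 0), fieldHeight)
    polyline[[i]] <- cbind(c(x0[i], mx, x1), c(y0[i], my, y1))
  }

  seg <- data.frame(
    segment_id = sprintf("%s_s%02d", clipId, seq_len(n)),
    diameter_um = diam,
    flow_category = category,
    stringsAsFactors = FALSE
  )
  seg$polyline <- polyline
  ClipAnnotation(clipId, seg, fieldWidth, fieldHeight)
}

## map a ClipAssessment to its ordinal clip state (worst -> best)
.clipState <- function(a) {
  switch(a@flowGrade,
    critically_impaired = "critical",
    impaired = "impaired",
    normal = if (a@heterogeneity == "present") "normal_het" else "normal_no_het"
  )
}

## perturb a clip state one ordinal step with probability p (rater noise);
## at the ends of the scale the step goes inward
.perturbState <- function(state, p) {
  idx <- match(state, .CLIP_STATES)
  flip <- runif(length(state)) < p
  dir <- sample(c(-1L, 1L), length(state), replace = TRUE)
  idx2 <- idx + ifelse(flip, dir, 0L)
  idx2[idx2 < 1L] <- 2L
  idx2[idx2 > length(.CLIP_STATES)] <- length(.CLIP_STATES) - 1L
  .CLIP_STATES[idx2]
}

#' Simulate a complete rater study
#'
#' Emulates the design used to validate the POEM score: a panel of raters
#' each grades the same set of video sequences (four clips per sequence).
#' Ground-truth POEM scores come from noiseless assessment of the simulated
#' clips; each simulated rater independently misclassifies each clip's
#' state one ordinal step (on the scale critical < impaired < normal with
#' heterogeneity < normal without heterogeneity) with probability
#' \code{raterNoise} before the four clips are aggregated, mirroring how
#' human raters confuse adjacent grades. The expert is noiseless.
#'
#' Default sequence severities and heterogeneity levels emulate a
#' validation panel spanning the clinical spectrum, from a healthy
#' homogeneous field through normal-flow fields with increasing
#' heterogeneity to impaired and critically impaired fields, so the test
#' sequences cover the range of the score as the real test sequences were
#' designed to do. (The exact ground-truth scores still vary with the seed:
#' clips near a band boundary can fall either side of it, as in real
#' material.)
#'
#' @param nSequences Number of rated sequences (items). Default 5.
#' @param nRaters Number of raters (>= 2). Default 32.
#' @param raterNoise Per-clip misclassification probability in
#'   \code{[0, 0.5]}.
#' @param severities,hetLevels Optional numeric vectors (length
#'   \code{nSequences}) of per-sequence severity and heterogeneity-mixing
#'   levels; the defaults cycle through five (severity, heterogeneity)
#'   design points running from healthy-homogeneous to critically
#'   impaired.
#' @param nSegmentsRange Integer range of segments per clip; default 10-40.
#' @param fieldWidth,fieldHeight Field of view in micrometres.
#' @param config \code{\link{ScoringConfig}} used for ground-truth
#'   assessment.
#' @param seed Optional integer seed for full reproducibility.
#' @return A list of class \code{PoemStudy} with elements
#'   \code{sequences} (list: per sequence a list of four
#'   \code{\link{ClipAnnotation}}s and the truth
#'   \code{SequenceAssessment}), \code{truth} (named integer vector of
#'   ground-truth POEM scores), \code{expert} (same, the expert's scores),
#'   \code{ratings} (a \code{\link{RatingMatrix}} of noisy rater scores)
#'   and the simulation parameters.
#' @export
#' @examples
#' st <- simulateStudy(nSequences = 5, nRaters = 8, raterNoise = 0, seed = 1)
#' st$truth
#' icc(st$ratings, "agreement")$estimate  # 1 at zero noise
simulateStudy <- function(nSequences = 5, nRaters = 32, raterNoise = 0.1,
                          severities = NULL, hetLevels = NULL,
                          nSegmentsRange = c(10L, 40L),
                          fieldWidth = 1000, fieldHeight = 750,
                          config = ScoringConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nRaters < 2L) stop("need at least 2 raters for agreement analysis", call. = FALSE)
  if (nSequences < 2L) stop("need at least 2 sequences", call. = FALSE)
  .checkProb(raterNoise, "raterNoise", upper = 0.5)
  ## five design points: healthy/homogeneous, normal with borderline
  ## heterogeneity, normal with marked heterogeneity, impaired, critical
  if (is.null(severities)) {
    severities <- rep(c(0.005, 0.01, 0.0, 0.13, 0.30), length.out = nSequences)
  }
  if (is.null(hetLevels)) {
    hetLevels <- rep(c(0.02, 0.20, 0.30, 0.05, 0.10), length.out = nSequences)
  }
  stopifnot(length(severities) == nSequences, length(hetLevels) == nSequences)
  if (nSegmentsRange[1] < 6L) stop("nSegmentsRange minimum must be >= 6", call. = FALSE)

  seqIds <- sprintf("seq%02d", seq_len(nSequences))
  sequences <- vector("list", nSequences)
  truth <- integer(nSequences)
  trueStates <- matrix("", nSequences, 4L)
  for (s in seq_len(nSequences)) {
    clips <- lapply(1:4, function(j) {
      n <- sample(seq(nSegmentsRange[1], nSegmentsRange[2]), 1L)
      simulateClip(n, severities[s], hetLevels[s], fieldWidth, fieldHeight,
                   clipId = sprintf("%s_clip%d", seqIds[s], j))
    })
    assess <- lapply(clips, assessClip, config = config)
    sa <- computePoem(assess, sequenceId = seqIds[s])
    sequences[[s]] <- list(clips = clips, assessment = sa)
    truth[s] <- sa@poemScore
    trueStates[s, ] <- vapply(assess, .clipState, character(1))
  }
  names(truth) <- seqIds

  ratings <- matrix(NA_integer_, nSequences, nRaters,
                    dimnames = list(seqIds, sprintf("rater%02d", seq_len(nRaters))))
  for (r in seq_len(nRaters)) {
    for (s in seq_len(nSequences)) {
      states <- .perturbState(trueStates[s, ], raterNoise)
      ratings[s, r] <- computePoem(states)@poemScore
    }
  }

  structure(list(
    sequences = sequences,
    truth = truth,
    expert = truth,
    ratings = RatingMatrix(ratings),
    params = list(nSequences = nSequences, nRaters = nRaters,
                  raterNoise = raterNoise, severities = severities,
                  hetLevels = hetLevels, nSegmentsRange = nSegmentsRange,
                  fieldWidth = fieldWidth, fieldHeight = fieldHeight,
                  seed = seed)
  ), class = "PoemStudy")
}

#' @export
print.PoemStudy <- function(x, ...) {
  cat(sprintf("Simulated POEM rater study: %d sequences x %d raters, rater noise %.2f\n",
              x$params$nSequences, x$params$nRaters, x$params$raterNoise))
  cat("  ground-truth POEM:", paste(x$truth, collapse = " "), "\n")
  invisible(x)
}

#' Severity/heterogeneity sweep linking POEM to consensus parameters
#'
#' Generates sequences whose expected stopped-segment fraction is spread
#' evenly over \code{[0, 1]} -- the per-sequence severity is solved so that
#' the expected fraction, accounting for the heterogeneity mixing, hits a
#' stratified grid of targets -- with uniformly varying heterogeneity
#' mixing weight in \code{[0, 0.5)} (the deviant regime is by definition a
#' minority of the field). For each sequence the ground-truth POEM score is
#' returned alongside the clip-mean MFI and the MHI. This is the synthetic
#' analogue of comparing expert scores with offline computer-analysis
#' parameters across the clinical spectrum.
#'
#' @param nSequences Number of simulated sequences.
#' @param nSegmentsRange Integer range of segments per clip.
#' @param config \code{\link{ScoringConfig}}.
#' @param seed Optional integer seed.
#' @return A \code{data.frame} with one row per sequence: \code{severity},
#'   \code{het_level}, \code{poem}, \code{mean_mfi}, \code{mhi},
#'   \code{mean_stopped}.
#' @export
poemParameterSweep <- function(nSequences = 200, nSegmentsRange = c(10L, 40L),
                               config = ScoringConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fStop <- (seq_len(nSequences) - 0.5) / nSequences
  het <- runif(nSequences, 0, 0.5)
  sev <- mapply(.severityForStoppedFraction, fStop, het)
  out <- data.frame(severity = sev, het_level = het, poem = NA_integer_,
                    mean_mfi = NA_real_, mhi = NA_real_, mean_stopped = NA_real_)
  for (s in seq_len(nSequences)) {
    clips <- lapply(1:4, function(j) {
      n <- sample(seq(nSegmentsRange[1], nSegmentsRange[2]), 1L)
      simulateClip(n, sev[s], het[s], clipId = sprintf("sweep%03d_c%d", s, j))
    })
    assess <- lapply(clips, assessClip, config = config)
    out$poem[s] <- computePoem(assess)@poemScore
    mfis <- vapply(clips, mfiQuadrant, numeric(1))
    out$mean_mfi[s] <- mean(mfis)
    out$mhi[s] <- if (mean(mfis) > 0) mhi(mfis) else NA_real_
    out$mean_stopped[s] <- mean(vapply(assess, function(a) a@stoppedFraction, numeric(1)))
  }
  out
}
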