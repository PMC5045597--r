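## POEM clip grading and four-clip aggregation.

.checkNonEmptyClip <- function(clip) {
  if (nrow(clip@segments) == 0L) {
    stop(sprintf("empty clip: '%s' has no annotated vessel segments", clip@clipId),
         call. = FALSE)
  }
}

#' Fraction of sluggish/stopped vessel segments
#'
#' The driving quantity of the POEM flow grade: the proportion of annotated
#' vessel segments in a clip whose flow category belongs to the configured
#' sluggish/stopped set. Each segment counts once, regardless of its length
#' (the grade definitions count "vessel segments in view").
#'
#' @param x A \code{\link{ClipAnnotation}} (the fraction is computed), or a
#'   \code{\link{ClipAssessment}} (the stored fraction is returned).
#' @param config A \code{\link{ScoringConfig}}; only \code{stoppedCategories}
#'   is used here.
#' @return A single number in \code{[0, 1]}.
#' @export
#' @examples
#' seg <- data.frame(segment_id = as.character(1:4), diameter_um = 8,
#'                   flow_category = c("continuous", "continuous",
#'                                     "sluggish", "absent"))
#' seg$polyline <- replicate(4, cbind(c(10, 90), c(10, 90)), simplify = FALSE)
#' stoppedFraction(ClipAnnotation("c", seg))  # 0.5
#' @name stoppedFraction
NULL

#' @rdname stoppedFraction
setMethod("stoppedFraction", "ClipAnnotation", function(x, config = ScoringConfig()) {
  .checkNonEmptyClip(x)
  mean(x@segments$flow_category %in% config@stoppedCategories)
})

#' @rdname stoppedFraction
setMethod("stoppedFraction", "ClipAssessment", function(x, config = ScoringConfig()) {
  x@stoppedFraction
})

#' Classify clip flow from the stopped-segment fraction
#'
#' Maps a stopped-segment fraction onto the three POEM flow grades using
#' the published bands: normal when strictly less than 25\% of segments are
#' sluggish/stopped, impaired for 25-50\% (both endpoints included),
#' critically impaired when strictly more than 50\%.
#'
#' @param fraction Numeric vector of fractions in \code{[0, 1]}.
#' @param config A \code{\link{ScoringConfig}} supplying the band bounds.
#' @return Character vector of \code{"normal"}, \code{"impaired"},
#'   \code{"critically_impaired"}.
#' @export
#' @examples
#' classifyClipFlow(c(0.24, 0.25, 0.50, 0.51))
classifyClipFlow <- function(fraction, config = ScoringConfig()) {
  if (!is.numeric(fraction) || anyNA(fraction) ||
      any(fraction < 0) || any(fraction > 1)) {
    stop("fraction must be numeric in [0, 1]", call. = FALSE)
  }
  ifelse(fraction < config@normalUpper, "normal",
         ifelse(fraction > config@criticalLower, "critically_impaired", "impaired"))
}

#' Detect flow heterogeneity within a clip
#'
#' Heterogeneity is present when strictly more than
#' \code{hetDeviantThreshold} (default 5) vessel segments show flow
#' different from the remainder. "The remainder" is operationalized as the
#' modal flow category of the clip; the deviant count is the number of
#' segments outside the modal category, which is the same whichever way a
#' plurality tie is broken, so no tie rule is needed.
#'
#' @param clip A \code{\link{ClipAnnotation}} with at least one segment.
#' @param config A \code{\link{ScoringConfig}}.
#' @return \code{"present"} or \code{"absent"}.
#' @export
#' @examples
#' seg <- data.frame(segment_id = as.character(1:20), diameter_um = 8,
#'                   flow_category = rep(c("continuous", "sluggish"), c(14, 6)))
#' seg$polyline <- replicate(20, cbind(c(10, 90), c(10, 90)), simplify = FALSE)
#' detectHeterogeneity(ClipAnnotation("c", seg))  # 6 deviants -> "present"
detectHeterogeneity <- function(clip, config = ScoringConfig()) {
  .checkNonEmptyClip(clip)
  counts <- table(clip@segments$flow_category)
  deviants <- nrow(clip@segments) - max(counts)
  if (deviants > config@hetDeviantThreshold) "present" else "absent"
}

#' Assess a single clip
#'
#' Runs the full per-clip POEM assessment: computes the stopped-segment
#' fraction, classifies flow, and determines heterogeneity. The segment
#' count rule is only consulted for clips with normal flow; impaired and
#' critically impaired clips are always heterogeneous (heterogeneity was
#' found to be universal in such clips during the score's development).
#'
#' @param clip A \code{\link{ClipAnnotation}}.
#' @param config A \code{\link{ScoringConfig}}.
#' @return A \code{\link{ClipAssessment}}.
#' @export
#' @examples
#' seg <- data.frame(segment_id = as.character(1:10), diameter_um = 8,
#'                   flow_category = rep(c("continuous", "sluggish"), c(9, 1)))
#' seg$polyline <- replicate(10, cbind(c(10, 90), c(10, 90)), simplify = FALSE)
#' assessClip(ClipAnnotation("c", seg))
assessClip <- function(clip, config = ScoringConfig()) {
  frac <- stoppedFraction(clip, config)
  grade <- classifyClipFlow(frac, config)
  het <- if (grade == "normal") detectHeterogeneity(clip, config) else "present"
  ClipAssessment(clip@clipId, grade, heterogeneity = het, stoppedFraction = frac)
}

#' Build a ClipAssessment from a clip-state label
#'
#' Convenience constructor mapping the four per-clip outcomes of the POEM
#' system (\code{"critical"}, \code{"impaired"}, \code{"normal_het"},
#' \code{"normal_no_het"}) to \code{\link{ClipAssessment}} objects. This is
#' the tool-parity entry point: a human rater (or the online calculator)
#' records only these four states per clip.
#'
#' @param state Character vector of clip states.
#' @param clipId Optional identifiers (recycled/defaulted).
#' @return A list of \code{\link{ClipAssessment}} objects (a single object
#'   when \code{length(state) == 1}).
#' @export
#' @examples
#' clipStateAssessment(c("impaired", "impaired", "normal_no_het", "normal_no_het"))
clipStateAssessment <- function(state, clipId = NULL) {
  state <- tolower(trimws(state))
  bad <- !(state %in% .CLIP_STATES)
  if (any(bad)) {
    stop(sprintf("unknown clip state(s): %s (must be one of %s)",
                 paste(unique(state[bad]), collapse = ", "),
                 paste(.CLIP_STATES, collapse = ", ")), call. = FALSE)
  }
  if (is.null(clipId)) clipId <- paste0("clip", seq_along(state))
  out <- mapply(function(s, id) {
    switch(s,
      critical = ClipAssessment(id, "critically_impaired"),
      impaired = ClipAssessment(id, "impaired"),
      normal_het = ClipAssessment(id, "normal", "present"),
      normal_no_het = ClipAssessment(id, "normal", "absent")
    )
  }, state, clipId, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  if (length(out) == 1L) out[[1L]] else out
}

#' Compute the overall POEM score from four clip assessments
#'
#' Aggregates exactly four per-clip assessments into the 1-5 ordinal POEM
#' score. With C, I, N the counts of critically impaired, impaired and
#' normal clips and H the count of clips with heterogeneity present, the
#' rules are applied in order:
#' \enumerate{
#'   \item C >= 2: score 1 (critically impaired);
#'   \item C + I >= 2: score 2 (impaired) -- a critically impaired clip
#'     counts towards the impaired tally, so a mixed
#'     one-critical/one-impaired pair still scores 2, the most conservative
#'     reading of the published algorithm's severity ordering;
#'   \item otherwise N >= 3: score 3 if all four clips show heterogeneity,
#'     4 if two or three do, 5 if one or none does.
#' }
#' Impaired and critically impaired clips always count as heterogeneous in
#' H. The result is invariant under permutation of the four clips.
#'
#' @param assessments List of exactly four \code{\link{ClipAssessment}}
#'   objects (or character clip states accepted by
#'   \code{\link{clipStateAssessment}}).
#' @param sequenceId Identifier stored on the result.
#' @return A \code{SequenceAssessment} holding the four assessments, the
#'   integer POEM score and its microcirculatory function label.
#' @export
#' @examples
#' computePoem(c("critical", "critical", "normal_no_het", "normal_no_het"))  # 1
#' computePoem(c("normal_het", "normal_het", "normal_no_het", "normal_no_het"))  # 4
computePoem <- function(assessments, sequenceId = "sequence1") {
  if (is.character(assessments)) {
    assessments <- clipStateAssessment(assessments)
    if (!is.list(assessments)) assessments <- list(assessments)
  }
  if (!is.list(assessments) || length(assessments) != 4L ||
      !all(vapply(assessments, is, TRUE, class2 = "ClipAssessment"))) {
    stop(sprintf(
      "a POEM score is derived from exactly 4 clip assessments (got %d)",
      length(assessments)), call. = FALSE)
  }
  grades <- vapply(assessments, flowGrade, character(1))
  het <- vapply(assessments, heterogeneity, character(1))
  C <- sum(grades == "critically_impaired")
  I <- sum(grades == "impaired")
  H <- sum(het == "present")
  score <- if (C >= 2L) {
    1L
  } else if (C + I >= 2L) {
    2L
  } else if (H == 4L) {
    3L
  } else if (H >= 2L) {
    4L
  } else {
    5L
  }
  new("SequenceAssessment",
    sequenceId = as.character(sequenceId),
    clipAssessments = assessments,
    poemScore = score,
    label = unname(.POEM_LABELS[as.character(score)])
  )
}
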