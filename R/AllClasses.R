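#' @import methods
#' @importFrom stats aggregate anova aov coef complete.cases cor lm median
#'   p.adjust pchisq pf pnorm qf quantile rbinom rlnorm runif sd setNames var
NULL

## ---------------------------------------------------------------------------
## ScoringConfig
## ---------------------------------------------------------------------------

#' @rdname ScoringConfig
#' @export
setClass("ScoringConfig",
  slots = c(
    normalUpper = "numeric",
    criticalLower = "numeric",
    hetDeviantThreshold = "integer",
    stoppedCategories = "character"
  )
)

setValidity("ScoringConfig", function(object) {
  msg <- character()
  nu <- object@normalUpper
  cl <- object@criticalLower
  if (length(nu) != 1L || !is.finite(nu) || length(cl) != 1L || !is.finite(cl) ||
      !(0 < nu && nu <= cl && cl < 1)) {
    msg <- c(msg, "band boundaries must satisfy 0 < normalUpper <= criticalLower < 1")
  }
  if (length(object@hetDeviantThreshold) != 1L || object@hetDeviantThreshold < 0L) {
    msg <- c(msg, "hetDeviantThreshold must be a single non-negative integer")
  }
  if (!all(object@stoppedCategories %in% .FLOW_CATEGORIES)) {
    msg <- c(msg, "stoppedCategories must be a subset of the four flow categories")
  }
  if (length(msg)) msg else TRUE
})

#' Scoring configuration for POEM clip assessment
#'
#' Holds the thresholds of the POEM grading rules: the flow bands (normal
#' below \code{normalUpper}, impaired between the bounds inclusive,
#' critically impaired above \code{criticalLower}), the heterogeneity rule
#' (heterogeneity is present when strictly more than
#' \code{hetDeviantThreshold} segments flow differently from the remainder),
#' and which flow categories count as "sluggish/stopped".
#'
#' Defaults follow the published grade definitions: bands at 25\% and 50\%
#' of vessel segments, heterogeneity threshold of 5 segments, and
#' \code{absent}, \code{intermittent} and \code{sluggish} counted as
#' stopped (an intermittently flowing segment is stopped part of the time;
#' the set is configurable because the grade table says only
#' "sluggish/stopped").
#'
#' @param normalUpper Upper bound (exclusive) of the normal-flow band, as a
#'   fraction of stopped segments. Default 0.25.
#' @param criticalLower Lower bound (exclusive) of the critically-impaired
#'   band. Default 0.50. Fractions equal to either bound are impaired.
#' @param hetDeviantThreshold Heterogeneity is present when the number of
#'   deviant segments is strictly greater than this count. Default 5.
#' @param stoppedCategories Flow categories counted as sluggish/stopped.
#' @return A \code{ScoringConfig} object.
#' @export
#' @examples
#' ScoringConfig()
#' ScoringConfig(stoppedCategories = c("absent", "sluggish"))
ScoringConfig <- function(normalUpper = 0.25, criticalLower = 0.50,
                          hetDeviantThreshold = 5L,
                          stoppedCategories = c("absent", "intermittent", "sluggish")) {
  new("ScoringConfig",
    normalUpper = as.numeric(normalUpper),
    criticalLower = as.numeric(criticalLower),
    hetDeviantThreshold = as.integer(hetDeviantThreshold),
    stoppedCategories = .normalizeCategory(stoppedCategories, "stoppedCategories")
  )
}

setMethod("show", "ScoringConfig", function(object) {
  cat("ScoringConfig\n")
  cat(sprintf("  flow bands: normal < %.3g <= impaired <= %.3g < critically impaired\n",
              object@normalUpper, object@criticalLower))
  cat(sprintf("  heterogeneity: > %d deviant segments\n", object@hetDeviantThreshold))
  cat("  stopped categories:", paste(object@stoppedCategories, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## ClipAnnotation
## ---------------------------------------------------------------------------

#' @rdname ClipAnnotation
#' @export
setClass("ClipAnnotation",
  slots = c(
    clipId = "character",
    fieldWidth = "numeric",
    fieldHeight = "numeric",
    segments = "data.frame"
  )
)

setValidity("ClipAnnotation", function(object) {
  msg <- character()
  if (length(object@clipId) != 1L || is.na(object@clipId)) {
    msg <- c(msg, "clipId must be a single non-missing string")
  }
  w <- object@fieldWidth
  h <- object@fieldHeight
  if (length(w) != 1L || !is.finite(w) || w <= 0 ||
      length(h) != 1L || !is.finite(h) || h <= 0) {
    msg <- c(msg, "field dimensions must be single positive numbers")
  }
  seg <- object@segments
  need <- c("segment_id", "diameter_um", "flow_category", "polyline")
  if (!all(need %in% names(seg))) {
    msg <- c(msg, paste("segments must have columns:", paste(need, collapse = ", ")))
    return(msg)
  }
  if (nrow(seg)) {
    if (any(!is.finite(seg$diameter_um)) || any(seg$diameter_um <= 0)) {
      msg <- c(msg, "diameter_um must be positive for every segment")
    }
    if (!all(seg$flow_category %in% .FLOW_CATEGORIES)) {
      msg <- c(msg, "flow_category must be one of absent, intermittent, sluggish, continuous")
    }
    for (i in seq_len(nrow(seg))) {
      p <- seg$polyline[[i]]
      if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 2L || any(!is.finite(p))) {
        msg <- c(msg, sprintf("segment %s: polyline must be a finite n x 2 matrix with >= 2 points",
                              seg$segment_id[i]))
        next
      }
      d <- diff(p)
      if (any(rowSums(abs(d)) == 0)) {
        msg <- c(msg, sprintf("segment %s: consecutive polyline points must be distinct",
                              seg$segment_id[i]))
      }
      if (length(w) == 1L && is.finite(w) &&
          (any(p[, 1] < 0) || any(p[, 1] > w) || any(p[, 2] < 0) || any(p[, 2] > h))) {
        msg <- c(msg, sprintf("segment %s: polyline points outside the field of view",
                              seg$segment_id[i]))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Vessel-segment annotations for one video clip
#'
#' A \code{ClipAnnotation} bundles the segment-level annotation of a single
#' sublingual video-microscopy clip: the field-of-view size (micrometres,
#' origin top-left, y increasing downward) and one row per vessel segment
#' with its centerline polyline, diameter and four-category flow annotation.
#'
#' @param clipId Single string identifying the clip.
#' @param segments A \code{data.frame} with columns \code{segment_id},
#'   \code{diameter_um}, \code{flow_category}, and a list column
#'   \code{polyline} of n x 2 coordinate matrices (micrometres).
#' @param fieldWidth,fieldHeight Field-of-view dimensions in micrometres.
#' @return A validated \code{ClipAnnotation}.
#' @seealso \code{\link{assessClip}}, \code{\link{readClips}},
#'   \code{\link{simulateClip}}
#' @export
#' @examples
#' seg <- data.frame(segment_id = c("s1", "s2"),
#'                   diameter_um = c(8, 12),
#'                   flow_category = c("continuous", "sluggish"))
#' seg$polyline <- list(cbind(c(10, 100), c(10, 60)),
#'                      cbind(c(200, 350, 400), c(300, 320, 400)))
#' ClipAnnotation("clipA", seg)
ClipAnnotation <- function(clipId, segments, fieldWidth = 1000, fieldHeight = 750) {
  if (nrow(segments)) {
    segments$segment_id <- as.character(segments$segment_id)
    segments$flow_category <- .normalizeCategory(segments$flow_category)
  }
  rownames(segments) <- NULL
  new("ClipAnnotation",
    clipId = as.character(clipId),
    fieldWidth = as.numeric(fieldWidth),
    fieldHeight = as.numeric(fieldHeight),
    segments = segments
  )
}

setMethod("show", "ClipAnnotation", function(object) {
  cat(sprintf("ClipAnnotation '%s': %d segments in %g x %g um field\n",
              object@clipId, nrow(object@segments),
              object@fieldWidth, object@fieldHeight))
  if (nrow(object@segments)) {
    tab <- table(factor(object@segments$flow_category, levels = .FLOW_CATEGORIES))
    cat("  flow:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

## ---------------------------------------------------------------------------
## ClipAssessment
## ---------------------------------------------------------------------------

#' @rdname ClipAssessment
#' @export
setClass("ClipAssessment",
  slots = c(
    clipId = "character",
    stoppedFraction = "numeric",
    flowGrade = "character",
    heterogeneity = "character"
  )
)

setValidity("ClipAssessment", function(object) {
  msg <- character()
  f <- object@stoppedFraction
  if (length(f) != 1L || (!is.na(f) && (f < 0 || f > 1))) {
    msg <- c(msg, "stoppedFraction must be a single value in [0, 1] (or NA if unobserved)")
  }
  if (length(object@flowGrade) != 1L || !(object@flowGrade %in% .FLOW_GRADES)) {
    msg <- c(msg, "flowGrade must be one of normal, impaired, critically_impaired")
  }
  if (length(object@heterogeneity) != 1L || !(object@heterogeneity %in% .HET_LEVELS)) {
    msg <- c(msg, "heterogeneity must be 'present' or 'absent'")
  }
  if (length(object@flowGrade) == 1L && object@flowGrade %in% .FLOW_GRADES &&
      object@flowGrade != "normal" && identical(object@heterogeneity, "absent")) {
    msg <- c(msg, "heterogeneity is always present in impaired/critically impaired clips")
  }
  if (length(msg)) msg else TRUE
})

#' Per-clip POEM assessment
#'
#' The grading of one clip: its stopped-segment fraction (may be \code{NA}
#' when the clip was graded directly, e.g. by a human rater), its flow grade
#' and its heterogeneity status. Non-normal clips always carry
#' \code{heterogeneity = "present"}: heterogeneity was found to be universal
#' in impaired and critically impaired clips, so it is only an open question
#' for clips with normal flow.
#'
#' @param clipId Single string identifying the clip.
#' @param flowGrade One of \code{"normal"}, \code{"impaired"},
#'   \code{"critically_impaired"}.
#' @param heterogeneity \code{"present"} or \code{"absent"}; forced to
#'   \code{"present"} when the grade is not normal.
#' @param stoppedFraction Fraction of sluggish/stopped segments in
#'   \code{[0, 1]}, or \code{NA} when not measured.
#' @return A validated \code{ClipAssessment}.
#' @seealso \code{\link{assessClip}}, \code{\link{computePoem}}
#' @export
#' @examples
#' ClipAssessment("c1", "normal", heterogeneity = "absent", stoppedFraction = 0.1)
#' ClipAssessment("c2", "impaired")  # heterogeneity implied present
ClipAssessment <- function(clipId, flowGrade,
                           heterogeneity = c("present", "absent"),
                           stoppedFraction = NA_real_) {
  flowGrade <- match.arg(flowGrade, .FLOW_GRADES)
  heterogeneity <- if (flowGrade == "normal") match.arg(heterogeneity) else "present"
  new("ClipAssessment",
    clipId = as.character(clipId),
    stoppedFraction = as.numeric(stoppedFraction),
    flowGrade = flowGrade,
    heterogeneity = heterogeneity
  )
}

setMethod("show", "ClipAssessment", function(object) {
  cat(sprintf("ClipAssessment '%s': %s flow, heterogeneity %s",
              object@clipId, sub("_", " ", object@flowGrade), object@heterogeneity))
  if (!is.na(object@stoppedFraction)) {
    cat(sprintf(" (%.1f%% segments sluggish/stopped)", 100 * object@stoppedFraction))
  }
  cat("\n")
})

## ---------------------------------------------------------------------------
## SequenceAssessment
## ---------------------------------------------------------------------------

#' @rdname computePoem
#' @export
setClass("SequenceAssessment",
  slots = c(
    sequenceId = "character",
    clipAssessments = "list",
    poemScore = "integer",
    label = "character"
  )
)

setValidity("SequenceAssessment", function(object) {
  msg <- character()
  if (length(object@clipAssessments) != 4L ||
      !all(vapply(object@clipAssessments, is, TRUE, class2 = "ClipAssessment"))) {
    msg <- c(msg, "clipAssessments must be a list of exactly 4 ClipAssessment objects")
  }
  s <- object@poemScore
  if (length(s) != 1L || !(s %in% 1:5)) {
    msg <- c(msg, "poemScore must be an integer in 1..5")
  } else if (!identical(object@label, unname(.POEM_LABELS[as.character(s)]))) {
    msg <- c(msg, "label does not match the POEM score")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SequenceAssessment", function(object) {
  cat(sprintf("SequenceAssessment '%s': POEM score %d (%s)\n",
              object@sequenceId, object@poemScore, object@label))
  for (a in object@clipAssessments) {
    cat(sprintf("  %s: %s, het %s\n", a@clipId,
                sub("_", " ", a@flowGrade), a@heterogeneity))
  }
})

## ---------------------------------------------------------------------------
## RatingMatrix
## ---------------------------------------------------------------------------

#' @rdname RatingMatrix
#' @export
setClass("RatingMatrix", slots = c(scores = "matrix"))

setValidity("RatingMatrix", function(object) {
  m <- object@scores
  msg <- character()
  if (nrow(m) < 2L || ncol(m) < 2L) {
    msg <- c(msg, "need at least 2 items (rows) and 2 raters (columns)")
  }
  if (anyNA(m)) {
    msg <- c(msg, "rating matrix must be complete (no missing cells)")
  } else if (!all(m %in% 1:5)) {
    msg <- c(msg, "all scores must be integers in 1..5")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    msg <- c(msg, "scores must carry item rownames and rater colnames")
  }
  if (length(msg)) msg else TRUE
})

#' Items-by-raters ordinal rating matrix
#'
#' Complete matrix of POEM scores: one row per rated video sequence (item),
#' one column per rater, every cell an integer score 1-5. This is the input
#' to the agreement statistics (\code{\link{icc}},
#' \code{\link{errorScoreRegression}}). Incomplete matrices are rejected;
#' the intended study design is complete (every rater scores every item).
#'
#' @param scores Numeric matrix of scores in 1..5, items in rows, raters in
#'   columns. Dimnames are added (\code{item1..}, \code{rater1..}) if absent.
#' @return A validated \code{RatingMatrix}.
#' @export
#' @examples
#' m <- rbind(c(5, 4, 5), c(2, 2, 1), c(3, 3, 3), c(1, 2, 1))
#' RatingMatrix(m)
RatingMatrix <- function(scores) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (is.null(rownames(scores))) {
    rownames(scores) <- paste0("item", seq_len(nrow(scores)))
  }
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("rater", seq_len(ncol(scores)))
  }
  new("RatingMatrix", scores = scores)
}

setMethod("show", "RatingMatrix", function(object) {
  m <- object@scores
  cat(sprintf("RatingMatrix: %d items x %d raters (scores 1-5)\n", nrow(m), ncol(m)))
  print(m)
})
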