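#' Accessors for POEM domain objects
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{clipId} returns the clip identifier, \code{segments} the
#' segment-annotation table, \code{fieldDimensions} the field of view in
#' micrometres, \code{flowGrade} and \code{heterogeneity} the per-clip
#' grading, \code{poemScore} and \code{poemLabel} the overall sequence
#' result, \code{clipAssessments} the four per-clip assessments, and
#' \code{scores} the items-by-raters matrix of a \code{RatingMatrix}.
#'
#' @param x A package object of the documented class.
#' @return The accessed component; see the individual generics.
#' @name accessors
#' @aliases clipId segments fieldDimensions flowGrade heterogeneity
#'   poemScore poemLabel clipAssessments scores
NULL

#' @rdname accessors
#' @export
setGeneric("clipId", function(x) standardGeneric("clipId"))

#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname accessors
#' @export
setGeneric("fieldDimensions", function(x) standardGeneric("fieldDimensions"))

#' @rdname accessors
#' @export
setGeneric("flowGrade", function(x) standardGeneric("flowGrade"))

#' @rdname accessors
#' @export
setGeneric("heterogeneity", function(x) standardGeneric("heterogeneity"))

#' @rdname accessors
#' @export
setGeneric("poemScore", function(x) standardGeneric("poemScore"))

#' @rdname accessors
#' @export
setGeneric("poemLabel", function(x) standardGeneric("poemLabel"))

#' @rdname accessors
#' @export
setGeneric("clipAssessments", function(x) standardGeneric("clipAssessments"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname stoppedFraction
#' @export
setGeneric("stoppedFraction", function(x, config = ScoringConfig())
  standardGeneric("stoppedFraction"))

#' @rdname accessors
setMethod("clipId", "ClipAnnotation", function(x) x@clipId)
#' @rdname accessors
setMethod("clipId", "ClipAssessment", function(x) x@clipId)
#' @rdname accessors
setMethod("segments", "ClipAnnotation", function(x) x@segments)
#' @rdname accessors
setMethod("fieldDimensions", "ClipAnnotation", function(x)
  c(width_um = x@fieldWidth, height_um = x@fieldHeight))
#' @rdname accessors
setMethod("flowGrade", "ClipAssessment", function(x) x@flowGrade)
#' @rdname accessors
setMethod("heterogeneity", "ClipAssessment", function(x) x@heterogeneity)
#' @rdname accessors
setMethod("poemScore", "SequenceAssessment", function(x) x@poemScore)
#' @rdname accessors
setMethod("poemLabel", "SequenceAssessment", function(x) x@label)
#' @rdname accessors
setMethod("clipAssessments", "SequenceAssessment", function(x) x@clipAssessments)
#' @rdname accessors
setMethod("scores", "RatingMatrix", function(x) x@scores)
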