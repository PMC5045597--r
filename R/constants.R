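## Ordinal flow vocabulary shared by every module. Order matters: it is the
## ordinal scale behind the 0-3 flow score (absent worst, continuous best).
.FLOW_CATEGORIES <- c("absent", "intermittent", "sluggish", "continuous")

.FLOW_GRADES <- c("normal", "impaired", "critically_impaired")

.HET_LEVELS <- c("present", "absent")

## Table of POEM score -> microcirculatory function label.
.POEM_LABELS <- c(
  "1" = "critically impaired",
  "2" = "impaired",
  "3" = "normal with marked heterogeneity",
  "4" = "normal with mild heterogeneity",
  "5" = "normal with no heterogeneity"
)

## Clip states ordered worst -> best, used by the rater-noise model and the
## monotonicity properties: degrading a clip moves it one step left.
.CLIP_STATES <- c("critical", "impaired", "normal_het", "normal_no_het")

#' Flow categories recognized by the package
#'
#' The four-point ordinal flow vocabulary used for vessel-segment
#' annotation, ordered from worst (\code{absent}) to best
#' (\code{continuous}).
#'
#' @return Character vector of the four flow categories.
#' @export
#' @examples
#' flowCategories()
flowCategories <- function() .FLOW_CATEGORIES

#' POEM score labels
#'
#' The microcirculatory function label attached to each overall POEM score.
#'
#' @return Named character vector: names are scores "1".."5".
#' @export
#' @examples
#' poemLabels()["2"]
poemLabels <- function() .POEM_LABELS

## internal: normalize and validate a flow category vector
.normalizeCategory <- function(x, context = "flow_category") {
  x <- tolower(trimws(as.character(x)))
  bad <- !(x %in% .FLOW_CATEGORIES)
  if (any(bad)) {
    stop(sprintf(
      "unknown %s value(s): %s (must be one of %s)",
      context,
      paste(unique(x[bad]), collapse = ", "),
      paste(.FLOW_CATEGORIES, collapse = ", ")
    ), call. = FALSE)
  }
  x
}
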