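## Consensus microcirculatory parameters: the traditional offline
## comparators computed from the same segment-level annotations.

.polylineLength <- function(p) sum(sqrt(rowSums(diff(p)^2)))

.fieldAreaMm2 <- function(clip) {
  area <- (clip@fieldWidth / 1000) * (clip@fieldHeight / 1000)
  if (!is.finite(area) || area <= 0) {
    stop(sprintf("clip '%s': field area must be positive", clip@clipId), call. = FALSE)
  }
  area
}

.smallVesselRows <- function(clip, smallVesselMaxDiameter) {
  clip@segments[clip@segments$diameter_um <= smallVesselMaxDiameter, , drop = FALSE]
}

#' Ordinal flow score of a flow category
#'
#' The semi-quantitative 0-3 flow scale behind the microcirculatory flow
#' index: absent = 0, intermittent = 1, sluggish = 2, continuous = 3.
#'
#' @param category Character vector of flow categories.
#' @return Integer vector of scores 0-3.
#' @export
#' @examples
#' flowScore(c("absent", "sluggish", "continuous"))
flowScore <- function(category) {
  category <- .normalizeCategory(category)
  match(category, .FLOW_CATEGORIES) - 1L
}

#' Total vessel density (TVD)
#'
#' Length density of small vessels: the summed centerline length of all
#' segments at or below the small-vessel diameter cutoff, divided by the
#' field area. Units mm/mm^2.
#'
#' @param clip A \code{\link{ClipAnnotation}}.
#' @param smallVesselMaxDiameter Small-vessel diameter cutoff in
#'   micrometres; default 20 (the conventional small-vessel definition).
#' @return TVD in mm/mm^2.
#' @export
#' @examples
#' seg <- data.frame(segment_id = "s1", diameter_um = 8,
#'                   flow_category = "continuous")
#' seg$polyline <- list(cbind(c(0, 1000), c(100, 100)))
#' totalVesselDensity(ClipAnnotation("c", seg))  # 1 mm in 0.75 mm^2
totalVesselDensity <- function(clip, smallVesselMaxDiameter = 20) {
  area <- .fieldAreaMm2(clip)
  seg <- .smallVesselRows(clip, smallVesselMaxDiameter)
  if (!nrow(seg)) return(0)
  lenMm <- sum(vapply(seg$polyline, .polylineLength, numeric(1))) / 1000
  lenMm / area
}

#' Proportion of perfused vessels (PPV)
#'
#' Fraction of small-vessel segments whose flow category counts as
#' perfused. By the usual convention \code{sluggish} and \code{continuous}
#' are perfused while \code{absent} and \code{intermittent} are not.
#'
#' @inheritParams totalVesselDensity
#' @param perfusedCategories Flow categories counted as perfused.
#' @return A fraction in \code{[0, 1]}.
#' @export
proportionPerfused <- function(clip, smallVesselMaxDiameter = 20,
                               perfusedCategories = c("sluggish", "continuous")) {
  perfusedCategories <- .normalizeCategory(perfusedCategories, "perfusedCategories")
  seg <- .smallVesselRows(clip, smallVesselMaxDiameter)
  if (!nrow(seg)) {
    stop(sprintf("clip '%s': PPV undefined, no small-vessel segments", clip@clipId),
         call. = FALSE)
  }
  mean(seg$flow_category %in% perfusedCategories)
}

#' Perfused vessel density (PVD)
#'
#' As \code{\link{totalVesselDensity}} but summing only the lengths of
#' perfused small-vessel segments. Units mm/mm^2; always \code{<= TVD}.
#'
#' @inheritParams proportionPerfused
#' @return PVD in mm/mm^2.
#' @export
perfusedVesselDensity <- function(clip, smallVesselMaxDiameter = 20,
                                  perfusedCategories = c("sluggish", "continuous")) {
  perfusedCategories <- .normalizeCategory(perfusedCategories, "perfusedCategories")
  area <- .fieldAreaMm2(clip)
  seg <- .smallVesselRows(clip, smallVesselMaxDiameter)
  seg <- seg[seg$flow_category %in% perfusedCategories, , drop = FALSE]
  if (!nrow(seg)) return(0)
  sum(vapply(seg$polyline, .polylineLength, numeric(1))) / 1000 / area
}

#' Microcirculatory flow index by the quadrant method (MFI)
#'
#' Superimposes a 2 x 2 quadrant grid on the field, assigns each segment to
#' the quadrant containing its centerline midpoint (midpoint by arc length),
#' scores each non-empty quadrant with the \code{\link{flowScore}} of its
#' predominant flow category (by segment count; ties broken towards the
#' lower score, a conservative grading), and returns the mean score over
#' non-empty quadrants. Empty quadrants are excluded from the mean rather
#' than scored 0, so sparse fields are not penalized.
#'
#' @param clip A \code{\link{ClipAnnotation}} with at least one segment.
#' @return MFI in \code{[0, 3]}.
#' @export
mfiQuadrant <- function(clip) {
  .checkNonEmptyClip(clip)
  mids <- t(vapply(clip@segments$polyline, .polylineMidpoint, numeric(2)))
  qx <- as.integer(mids[, 1] > clip@fieldWidth / 2)
  qy <- as.integer(mids[, 2] > clip@fieldHeight / 2)
  quadrant <- 1L + qx + 2L * qy
  qscores <- vapply(split(clip@segments$flow_category, quadrant), function(cats) {
    counts <- table(cats)
    winners <- names(counts)[counts == max(counts)]
    min(flowScore(winners))
  }, numeric(1))
  mean(qscores)
}

## midpoint of a polyline by arc length (not the middle vertex)
.polylineMidpoint <- function(p) {
  steps <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(steps))
  half <- cum[length(cum)] / 2
  i <- max(which(cum <= half))
  if (i >= nrow(p)) return(p[nrow(p), ])
  t <- (half - cum[i]) / steps[i]
  p[i, ] + t * (p[i + 1L, ] - p[i, ])
}

#' Microcirculatory heterogeneity index (MHI)
#'
#' Spread of the flow index across the clips of one patient/time point:
#' \code{(max(MFI) - min(MFI)) / mean(MFI)}. Zero exactly when all clip
#' MFIs are equal; invariant to rescaling all MFIs by a positive constant.
#'
#' @param mfis Numeric vector of at least two clip-level MFI values,
#'   typically the four clips of a sequence.
#' @return A non-negative number.
#' @export
#' @examples
#' mhi(c(3, 2, 2.75, 2.25))  # (3 - 2) / 2.5 = 0.4
mhi <- function(mfis) {
  if (length(mfis) < 2L || anyNA(mfis)) {
    stop("MHI needs at least two non-missing clip MFI values", call. = FALSE)
  }
  m <- mean(mfis)
  if (m <= 0) {
    stop("MHI undefined: mean MFI is zero", call. = FALSE)
  }
  (max(mfis) - min(mfis)) / m
}

#' Consensus parameters for a set of clips
#'
#' Convenience wrapper computing TVD, PVD, PPV and MFI for each clip and,
#' when the clips form sequences of four, the per-sequence MHI.
#'
#' @param clips A list of \code{\link{ClipAnnotation}} objects.
#' @param smallVesselMaxDiameter Diameter cutoff in micrometres.
#' @param perfusedCategories Flow categories counted as perfused.
#' @return A \code{data.frame} with one row per clip and columns
#'   \code{clip_id}, \code{tvd}, \code{pvd}, \code{ppv}, \code{mfi}.
#' @export
consensusParams <- function(clips, smallVesselMaxDiameter = 20,
                            perfusedCategories = c("sluggish", "continuous")) {
  rows <- lapply(clips, function(cl) {
    data.frame(
      clip_id = cl@clipId,
      tvd = totalVesselDensity(cl, smallVesselMaxDiameter),
      pvd = perfusedVesselDensity(cl, smallVesselMaxDiameter, perfusedCategories),
      ppv = proportionPerfused(cl, smallVesselMaxDiameter, perfusedCategories),
      mfi = mfiQuadrant(cl)
    )
  })
  do.call(rbind, rows)
}
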