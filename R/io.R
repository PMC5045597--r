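## Readers and writers for the package's plain-text interchange formats.
## CSV dialect: UTF-8, comma separator, header row, "." decimal point.
## JSON is the lossless canonical form.

#' @importFrom utils combn read.csv write.csv
NULL

.polylineToString <- function(p) {
  paste(sprintf("%g,%g", p[, 1], p[, 2]), collapse = ";")
}

.polylineFromString <- function(s, row) {
  pts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  if (length(pts) < 2L) {
    stop(sprintf("row %d, field 'polyline': need at least 2 points", row), call. = FALSE)
  }
  bad <- vapply(pts, function(xy) length(xy) != 2L || anyNA(suppressWarnings(as.numeric(xy))),
                logical(1))
  if (any(bad)) {
    stop(sprintf("row %d, field 'polyline': malformed coordinate pair", row), call. = FALSE)
  }
  m <- do.call(rbind, lapply(pts, as.numeric))
  colnames(m) <- NULL
  m
}

#' Read clip annotations
#'
#' Reads vessel-segment annotations from CSV (columns \code{clip_id},
#' \code{segment_id}, \code{diameter_um}, \code{flow_category},
#' \code{polyline} as semicolon-separated \code{"x,y"} pairs in
#' micrometres, optional \code{field_width_um}/\code{field_height_um}) or
#' from the equivalent JSON (an array of clip objects each carrying a
#' \code{segments} array). Flow categories are normalized to lower case.
#' Validation failures name the offending row and field.
#'
#' @param path Path to a \code{.csv} or \code{.json} file.
#' @param fieldWidth,fieldHeight Field dimensions (micrometres) used when
#'   the file does not carry them.
#' @return A named list of \code{\link{ClipAnnotation}} objects.
#' @export
readClips <- function(path, fieldWidth = 1000, fieldHeight = 750) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(.readClipsJSON(path, fieldWidth, fieldHeight))
  }
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("clip_id", "segment_id", "diameter_um", "flow_category", "polyline")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("clip CSV is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (!nrow(d)) stop("clip CSV contains no segment rows", call. = FALSE)
  for (i in seq_len(nrow(d))) {
    if (!is.finite(d$diameter_um[i]) || d$diameter_um[i] <= 0) {
      stop(sprintf("row %d, field 'diameter_um': must be positive", i), call. = FALSE)
    }
    cat_i <- tolower(trimws(d$flow_category[i]))
    if (!(cat_i %in% .FLOW_CATEGORIES)) {
      stop(sprintf("row %d, field 'flow_category': unknown category '%s'",
                   i, d$flow_category[i]), call. = FALSE)
    }
  }
  polylines <- lapply(seq_len(nrow(d)), function(i) .polylineFromString(d$polyline[i], i))
  hasW <- "field_width_um" %in% names(d)
  hasH <- "field_height_um" %in% names(d)
  out <- lapply(split(seq_len(nrow(d)), d$clip_id)[unique(d$clip_id)], function(rows) {
    seg <- data.frame(
      segment_id = as.character(d$segment_id[rows]),
      diameter_um = d$diameter_um[rows],
      flow_category = tolower(trimws(d$flow_category[rows])),
      stringsAsFactors = FALSE
    )
    seg$polyline <- polylines[rows]
    w <- if (hasW) d$field_width_um[rows[1]] else fieldWidth
    h <- if (hasH) d$field_height_um[rows[1]] else fieldHeight
    tryCatch(
      ClipAnnotation(d$clip_id[rows[1]], seg, w, h),
      error = function(e) stop(sprintf("clip '%s' (rows %s): %s",
                                       d$clip_id[rows[1]],
                                       paste(range(rows), collapse = "-"),
                                       conditionMessage(e)), call. = FALSE)
    )
  })
  out
}

.readClipsJSON <- function(path, fieldWidth, fieldHeight) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(j$clips)) j <- j$clips
  if (!length(j)) stop("clip JSON contains no clips", call. = FALSE)
  out <- lapply(j, function(cl) {
    segs <- cl$segments
    if (is.null(segs) || !length(segs)) {
      stop(sprintf("clip '%s': empty or missing segments array", cl$clip_id), call. = FALSE)
    }
    seg <- data.frame(
      segment_id = vapply(segs, function(s) as.character(s$segment_id), character(1)),
      diameter_um = vapply(segs, function(s) as.numeric(s$diameter_um), numeric(1)),
      flow_category = vapply(segs, function(s) tolower(trimws(s$flow_category)), character(1)),
      stringsAsFactors = FALSE
    )
    seg$polyline <- lapply(segs, function(s) {
      m <- do.call(rbind, lapply(s$polyline, function(pt) as.numeric(unlist(pt))))
      colnames(m) <- NULL
      m
    })
    ClipAnnotation(cl$clip_id,
                   seg,
                   cl$field_width_um %||% fieldWidth,
                   cl$field_height_um %||% fieldHeight)
  })
  names(out) <- vapply(out, clipId, character(1))
  out
}

#' Write clip annotations
#'
#' Inverse of \code{\link{readClips}}; the format is chosen from the file
#' extension (\code{.csv} or \code{.json}). Round-trips losslessly up to
#' numeric formatting.
#'
#' @param clips A \code{\link{ClipAnnotation}} or list of them.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeClips <- function(clips, path) {
  if (is(clips, "ClipAnnotation")) clips <- list(clips)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- lapply(clips, function(cl) {
      seg <- cl@segments
      list(
        clip_id = cl@clipId,
        field_width_um = cl@fieldWidth,
        field_height_um = cl@fieldHeight,
        segments = lapply(seq_len(nrow(seg)), function(i) list(
          segment_id = seg$segment_id[i],
          diameter_um = seg$diameter_um[i],
          flow_category = seg$flow_category[i],
          polyline = lapply(seq_len(nrow(seg$polyline[[i]])),
                            function(r) seg$polyline[[i]][r, ])
        ))
      )
    })
    jsonlite::write_json(list(clips = obj), path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- do.call(rbind, lapply(clips, function(cl) {
      seg <- cl@segments
      data.frame(
        clip_id = cl@clipId,
        segment_id = seg$segment_id,
        diameter_um = seg$diameter_um,
        flow_category = seg$flow_category,
        polyline = vapply(seg$polyline, .polylineToString, character(1)),
        field_width_um = cl@fieldWidth,
        field_height_um = cl@fieldHeight,
        stringsAsFactors = FALSE
      )
    }))
    write.csv(rows, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Read and write rating matrices
#'
#' Ratings CSV: first column the item (sequence) id, remaining columns one
#' per rater, cells integer POEM scores 1-5. Expert CSV: columns
#' \code{item_id}, \code{score}.
#'
#' @param path CSV path.
#' @return \code{readRatings}: a \code{\link{RatingMatrix}};
#'   \code{readExpert}: a named numeric vector of expert scores.
#' @export
readRatings <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 3L) stop("ratings CSV needs an item column plus >= 2 rater columns",
                         call. = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  RatingMatrix(m)
}

#' @rdname readRatings
#' @param ratings A \code{\link{RatingMatrix}}.
#' @export
writeRatings <- function(ratings, path) {
  m <- scores(ratings)
  d <- data.frame(item_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readRatings
#' @export
readExpert <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item_id", "score") %in% names(d))) {
    stop("expert CSV needs columns item_id, score", call. = FALSE)
  }
  setNames(as.numeric(d$score), as.character(d$item_id))
}

#' @rdname readRatings
#' @param expert Named numeric vector of expert scores.
#' @export
writeExpert <- function(expert, path) {
  write.csv(data.frame(item_id = names(expert), score = as.vector(expert)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a four-clip sequence manifest
#'
#' A sequence manifest is a JSON object with a \code{sequence_id} and a
#' \code{clips} array of exactly four references into a clip annotation
#' file (clip ids) or paths to clip files.
#'
#' @param path Path to the manifest JSON.
#' @return List with \code{sequence_id} and character vector \code{clips}.
#' @export
readSequenceManifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$sequence_id) || is.null(j$clips)) {
    stop("manifest must contain sequence_id and clips", call. = FALSE)
  }
  if (length(j$clips) != 4L) {
    stop(sprintf("manifest must reference exactly 4 clips (got %d)", length(j$clips)),
         call. = FALSE)
  }
  list(sequence_id = j$sequence_id, clips = as.character(j$clips))
}

#' Serialize a sequence assessment to JSON
#'
#' @param assessment A \code{SequenceAssessment} from
#'   \code{\link{computePoem}}.
#' @param path Optional output path; when \code{NULL} the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
assessmentToJSON <- function(assessment, path = NULL) {
  obj <- list(
    sequence_id = assessment@sequenceId,
    poem_score = assessment@poemScore,
    label = assessment@label,
    clips = lapply(assessment@clipAssessments, function(a) list(
      clip_id = a@clipId,
      flow_grade = a@flowGrade,
      heterogeneity = a@heterogeneity,
      stopped_fraction = if (is.na(a@stoppedFraction)) NULL else a@stoppedFraction
    ))
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
  }
}
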