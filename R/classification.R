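# Object-based classification of fixations and saccades.

#' Classification configuration
#'
#' @param object_threshold Fixations whose shortest object distance is
#'   strictly below this value (deg) are object fixations; default 1.5 deg
#'   (object radius ~1 deg plus foveal extent). Results are robust for
#'   thresholds between 1 and 2 deg.
#' @return An object of class `classification_config`.
#' @export
classification_config <- function(object_threshold = 1.5) {
  if (object_threshold < 0.5 || object_threshold > 3.0) {
    stop("object_threshold outside the sane range [0.5, 3.0] deg")
  }
  structure(list(object_threshold = object_threshold),
            class = "classification_config")
}

#' Shortest object distance of a fixation position
#'
#' Euclidean distance from a position to the nearest object centre; ties
#' are broken deterministically towards the lowest object id.
#'
#' @param x,y Fixation position in degrees.
#' @param layout A [stimulus_layout()].
#' @return Named list with `distance` (deg), `object` (id of the arg-min
#'   object) and `distances` (all object distances, named by id).
#' @export
shortest_object_distance <- function(x, y, layout) {
  obj <- layout$objects
  if (!nrow(obj)) stop("empty layout")
  d <- sqrt((obj$x - x)^2 + (obj$y - y)^2)
  names(d) <- obj$id
  i <- which.min(d)  # first minimum = lowest id (objects sorted by id)
  list(distance = d[[i]], object = obj$id[i], distances = d)
}

#' Label fixations as object or background fixations
#'
#' A fixation is an object fixation iff its shortest object distance is
#' strictly less than the threshold; its fixated object is the closest
#' object. Background fixations have no fixated object.
#'
#' @param fixations Fixation table from [extract_fixations()] (columns `x`,
#'   `y` at least).
#' @param layout A [stimulus_layout()].
#' @param cfg A [classification_config()].
#' @return The fixation table with added columns `shortest_obj_dist`,
#'   `fix_kind` (`"object"`/`"background"`) and `fixated_object` (`NA` for
#'   background fixations).
#' @export
classify_fixations <- function(fixations, layout,
                               cfg = classification_config()) {
  if (!nrow(fixations)) {
    fixations$shortest_obj_dist <- numeric(0)
    fixations$fix_kind <- character(0)
    fixations$fixated_object <- integer(0)
    return(fixations)
  }
  res <- lapply(seq_len(nrow(fixations)), function(i) {
    shortest_object_distance(fixations$x[i], fixations$y[i], layout)
  })
  fixations$shortest_obj_dist <- vapply(res, `[[`, numeric(1L), "distance")
  is_obj <- fixations$shortest_obj_dist < cfg$object_threshold
  fixations$fix_kind <- ifelse(is_obj, "object", "background")
  fixations$fixated_object <- ifelse(
    is_obj, vapply(res, `[[`, numeric(1L), "object"), NA)
  fixations
}

#' Classify saccades into the five types
#'
#' Assigns each saccade a type from the kinds and fixated objects of its
#' flanking fixations: intra-object (same object on both sides),
#' trans-object (two different objects), object-to-background,
#' background-to-object, or background-to-background. A saccade whose
#' preceding or following fixation is missing (removed by the drift rule or
#' the post-onset exclusion) is left unclassified (`NA`) and is excluded
#' from ratio statistics.
#'
#' @param saccades Saccade table (columns `onset`, `offset`).
#' @param labeled_fixations Output of [classify_fixations()] (columns
#'   `onset`, `offset`, `fix_kind`, `fixated_object`).
#' @param tol Temporal tolerance (s) when matching fixation boundaries to
#'   saccade boundaries.
#' @return The saccade table with an added factor column `saccade_type`.
#' @export
classify_saccades <- function(saccades, labeled_fixations, tol = 1e-6) {
  n <- nrow(saccades)
  type <- rep(NA_character_, n)
  if (n && nrow(labeled_fixations)) {
    for (i in seq_len(n)) {
      prev <- which(abs(labeled_fixations$offset - saccades$onset[i]) <= tol)
      nxt <- which(abs(labeled_fixations$onset - saccades$offset[i]) <= tol)
      if (length(prev) != 1L || length(nxt) != 1L) next
      pk <- labeled_fixations$fix_kind[prev]
      nk <- labeled_fixations$fix_kind[nxt]
      if (pk == "object" && nk == "object") {
        type[i] <- if (labeled_fixations$fixated_object[prev] ==
                         labeled_fixations$fixated_object[nxt])
          "intra_object" else "trans_object"
      } else if (pk == "object") {
        type[i] <- "object_to_background"
      } else if (nk == "object") {
        type[i] <- "background_to_object"
      } else {
        type[i] <- "background_to_background"
      }
    }
  }
  saccades$saccade_type <- factor(type, levels = SACCADE_TYPES)
  saccades
}
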