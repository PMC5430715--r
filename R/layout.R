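# Stimulus layouts: an image rectangle with circular object regions.

#' Construct a stimulus layout
#'
#' @param objects A data.frame with columns `id`, `x`, `y`, `radius`
#'   (degrees of visual angle; coordinates relative to the image centre).
#' @param width,height Image extent in degrees (default 34.8 x 26.1).
#' @param min_separation Required minimum pairwise distance between object
#'   centres (validation only).
#' @return An object of class `stimulus_layout`.
#' @export
stimulus_layout <- function(objects, width = 34.8, height = 26.1,
                            min_separation = 4.0) {
  stopifnot(is.data.frame(objects),
            all(c("id", "x", "y", "radius") %in% names(objects)))
  if (nrow(objects) < 1L) stop("layout must contain at least one object")
  if (any(abs(objects$x) > width / 2) || any(abs(objects$y) > height / 2)) {
    stop("object centres must lie inside the image bounds")
  }
  if (nrow(objects) > 1L) {
    d <- stats::dist(objects[, c("x", "y")])
    if (min(d) < min_separation - 1e-9) {
      stop(sprintf("object centres closer than %.2f deg", min_separation))
    }
  }
  structure(list(width = width, height = height,
                 objects = objects[order(objects$id), , drop = FALSE]),
            class = "stimulus_layout")
}

#' @export
print.stimulus_layout <- function(x, ...) {
  cat(sprintf("Stimulus layout %.1f x %.1f deg with %d object(s)\n",
              x$width, x$height, nrow(x$objects)))
  print(x$objects, row.names = FALSE)
  invisible(x)
}

#' Generate a random stimulus layout
#'
#' Places `n_objects` circular objects uniformly at random inside the image
#' bounds with all pairwise centre distances at least `min_separation`,
#' by rejection sampling. With `center_first = TRUE` the first object is
#' placed at the image centre (the object-at-center stimulus condition).
#'
#' @param n_objects Number of objects (default 5).
#' @param bounds Numeric length-2 `(width, height)` in degrees.
#' @param min_separation Minimum pairwise centre distance in degrees.
#' @param radius Object radius in degrees (~1 deg).
#' @param center_first Place object 1 at (0, 0)?
#' @param seed Optional integer seed.
#' @param max_attempts Rejection-sampling cap per object before the
#'   placement is declared infeasible.
#' @return A [stimulus_layout()].
#' @examples
#' generate_layout(5, seed = 1)
#' @export
generate_layout <- function(n_objects = 5L, bounds = c(34.8, 26.1),
                            min_separation = 4.0, radius = 1.0,
                            center_first = FALSE, seed = NULL,
                            max_attempts = 10000L) {
  if (n_objects < 1L) stop("n_objects must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  half_w <- bounds[1L] / 2 - radius
  half_h <- bounds[2L] / 2 - radius
  if (half_w <= 0 || half_h <= 0) stop("bounds too small for the radius")
  xs <- ys <- numeric(0L)
  for (k in seq_len(n_objects)) {
    if (k == 1L && center_first) {
      xs <- 0; ys <- 0
      next
    }
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      cx <- stats::runif(1L, -half_w, half_w)
      cy <- stats::runif(1L, -half_h, half_h)
      if (!length(xs) ||
          all((xs - cx)^2 + (ys - cy)^2 >= min_separation^2)) {
        xs <- c(xs, cx); ys <- c(ys, cy)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("placement failure: could not place object %d of ",
                          "%d with %.1f deg separation inside %.1f x %.1f ",
                          "deg after %d attempts"),
                   k, n_objects, min_separation, bounds[1L], bounds[2L],
                   max_attempts))
    }
  }
  stimulus_layout(data.frame(id = seq_len(n_objects), x = xs, y = ys,
                             radius = radius),
                  width = bounds[1L], height = bounds[2L],
                  min_separation = min_separation)
}

#' Read or write a stimulus layout as JSON
#'
#' @param layout A [stimulus_layout()].
#' @param path File path.
#' @return `read_layout` returns a [stimulus_layout()]; `write_layout`
#'   returns `path` invisibly.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(list(width = layout$width, height = layout$height,
                            objects = layout$objects),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("width", "height", "objects") %in% names(obj))) {
    stop("layout file must contain width, height and objects")
  }
  stimulus_layout(as.data.frame(obj$objects),
                  width = obj$width, height = obj$height)
}
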