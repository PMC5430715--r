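# Event-table I/O and the end-to-end pipeline driver.

EVENT_COLUMNS <- c("trial_id", "event_type", "onset_s", "offset_s",
                   "x_on", "y_on", "x_off", "y_off", "amplitude_deg",
                   "duration_s", "order", "shortest_obj_dist_deg",
                   "fix_kind", "fixated_object", "saccade_type")

#' Combine detected/classified events of one trial into the standard table
#'
#' @param fixations Labeled fixation table ([classify_fixations()] output).
#' @param saccades Classified saccade table ([classify_saccades()] output).
#' @param trial_id Trial identifier.
#' @return A data.frame in the standard event-table schema (one row per
#'   event, fixations and saccades interleaved in time order).
#' @export
events_table <- function(fixations, saccades, trial_id = 1L) {
  nf <- nrow(fixations)
  ns <- nrow(saccades)
  fx <- data.frame(trial_id = rep(trial_id, nf),
                   event_type = rep("fixation", nf),
                   onset_s = fixations$onset, offset_s = fixations$offset,
                   x_on = fixations$x, y_on = fixations$y,
                   x_off = fixations$x, y_off = fixations$y,
                   amplitude_deg = rep(NA_real_, nf),
                   duration_s = fixations$duration, order = fixations$order,
                   shortest_obj_dist_deg =
                     fixations$shortest_obj_dist %||% rep(NA_real_, nf),
                   fix_kind = fixations$fix_kind %||% rep(NA_character_, nf),
                   fixated_object =
                     fixations$fixated_object %||% rep(NA_real_, nf),
                   saccade_type = rep(NA_character_, nf))
  sc <- data.frame(trial_id = rep(trial_id, ns),
                   event_type = rep("saccade", ns),
                   onset_s = saccades$onset, offset_s = saccades$offset,
                   x_on = saccades$x_on, y_on = saccades$y_on,
                   x_off = saccades$x_off, y_off = saccades$y_off,
                   amplitude_deg = saccades$amplitude,
                   duration_s = saccades$duration, order = saccades$order,
                   shortest_obj_dist_deg = rep(NA_real_, ns),
                   fix_kind = rep(NA_character_, ns),
                   fixated_object = rep(NA_real_, ns),
                   saccade_type =
                     as.character(saccades$saccade_type %||%
                                    rep(NA_character_, ns)))
  out <- rbind(fx, sc)
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write an event table as TSV
#'
#' The schema is validated on read: all standard columns must be present,
#' `event_type` must be `fixation`/`saccade` and `saccade_type` one of the
#' five types (or empty).
#'
#' @param events Event table from [events_table()].
#' @param path File path.
#' @return `read_events` returns the validated table; `write_events`
#'   returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(EVENT_COLUMNS %in% names(events)))
  utils::write.table(events[, EVENT_COLUMNS], path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = "", stringsAsFactors = FALSE)
  missing <- setdiff(EVENT_COLUMNS, names(df))
  if (length(missing)) {
    stop("event table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!all(df$event_type %in% c("fixation", "saccade"))) {
    stop("unknown event_type value")
  }
  bad <- !is.na(df$saccade_type) & !(df$saccade_type %in% SACCADE_TYPES)
  if (any(bad)) {
    stop("unknown saccade_type value: ",
         paste(unique(df$saccade_type[bad]), collapse = ", "))
  }
  df
}

#' Pipeline configuration
#'
#' Bundles and validates the per-stage configurations of the synthetic
#' end-to-end pipeline. Unknown entries in the list arguments are rejected.
#'
#' @param model A [model_params()] object (the generating and fitted model
#'   family).
#' @param n_trials Number of synthetic trials.
#' @param layout A [stimulus_layout()] or `NULL` to generate one.
#' @param n_objects Objects in a generated layout.
#' @param center_first Passed to [generate_layout()].
#' @param render A [render_config()].
#' @param detection A [detection_config()].
#' @param classification A [classification_config()].
#' @param fit List with optional entries `grid_step` (default 0.05) and
#'   `norm` (`"L1"`/`"L2"`).
#' @param seed Master seed; every random stage derives its seed from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(model, n_trials = 20L, layout = NULL,
                            n_objects = 5L, center_first = TRUE,
                            render = render_config(),
                            detection = detection_config(),
                            classification = classification_config(),
                            fit = list(), seed = 1L) {
  stopifnot(inherits(model, "model_params"),
            inherits(render, "render_config"),
            inherits(detection, "detection_config"),
            inherits(classification, "classification_config"))
  unknown <- setdiff(names(fit), c("grid_step", "norm"))
  if (length(unknown)) {
    stop("unknown fit config entries: ", paste(unknown, collapse = ", "))
  }
  fit <- utils::modifyList(list(grid_step = 0.05, norm = "L1"), fit)
  structure(list(model = model, n_trials = as.integer(n_trials),
                 layout = layout, n_objects = n_objects,
                 center_first = center_first, render = render,
                 detection = detection, classification = classification,
                 fit = fit, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a layout and synthetic trials from the model, renders gaze
#' traces, detects and classifies eye events, computes the descriptive
#' statistics and per-order ratio curves, fits the switch and no-switch
#' models by grid search and compares them by AIC. All randomness derives
#' deterministically from the master seed.
#'
#' @param config A [pipeline_config()].
#' @return A list (class `pipeline_report`) with elements `layout`,
#'   `events` (full event table), `truths`, `ratio_curves`, `p_bg_hat`,
#'   `binned`, `object_counts`, `fit_switch`, `fit_noswitch`, `aic` and
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, config$n_trials + 1L)
  layout <- config$layout %||%
    generate_layout(config$n_objects,
                    bounds = c(34.8, 26.1),
                    center_first = config$center_first,
                    seed = stage_seeds[1L])
  all_events <- vector("list", config$n_trials)
  truths <- vector("list", config$n_trials)
  type_rows <- vector("list", config$n_trials)
  onset0 <- config$render$pre_stimulus_fixation
  for (tr in seq_len(config$n_trials)) {
    set.seed(stage_seeds[tr + 1L])
    truth <- generate_trial_events(config$model, layout)
    trace <- render_gaze_trace(truth, config$render)
    ev <- detect_events(trace, config$detection)
    fx <- classify_fixations(ev$fixations, layout, config$classification)
    sc <- classify_saccades(ev$saccades, fx)
    tab <- events_table(fx, sc, trial_id = tr)
    tab$onset_s <- tab$onset_s - onset0
    tab$offset_s <- tab$offset_s - onset0
    all_events[[tr]] <- tab
    truths[[tr]] <- truth
    type_rows[[tr]] <- data.frame(trial_id = tr,
                                  saccade_type = as.character(sc$saccade_type),
                                  stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, all_events)
  fixations <- events[events$event_type == "fixation", ]
  saccades <- events[events$event_type == "saccade", ]
  p_bg_hat <- mean(fixations$fix_kind == "background", na.rm = TRUE)
  types <- do.call(rbind, type_rows)
  # the first saccade after stimulus onset loses its preceding fixation to
  # the post-onset exclusion window, so trials contribute at most
  # n_fix - 2 classified saccades; fit over the orders the data cover
  r_emp <- saccade_type_ratios_by_order(types,
                                        max_order = config$model$n_fix - 1L)
  covered <- which(attr(r_emp, "n_at_order") > 0L)
  max_order <- max(covered)
  r_emp <- ratio_curves(unclass(r_emp)[seq_len(max_order), , drop = FALSE],
                        n_at_order = attr(r_emp, "n_at_order")[seq_len(max_order)])
  binned <- binned_eye_parameters(
    data.frame(onset = fixations$onset_s, duration = fixations$duration_s),
    data.frame(onset = saccades$onset_s, amplitude = saccades$amplitude_deg))
  object_counts <- fixated_object_counts(
    data.frame(trial_id = fixations$trial_id, onset = fixations$onset_s,
               fix_kind = fixations$fix_kind,
               fixated_object = fixations$fixated_object))
  fit_args <- list(r_emp = r_emp, p_bg_fixed = p_bg_hat,
                   n_fix = max_order + 1L,
                   initial_condition = config$model$initial_condition,
                   grid_step = config$fit$grid_step, norm = config$fit$norm)
  fit_switch <- tryCatch(
    do.call(grid_search_fit, c(fit_args, list(switch_model = TRUE))),
    error = function(e) stop("fit stage failed: ", conditionMessage(e)))
  fit_noswitch <- do.call(grid_search_fit,
                          c(fit_args, list(switch_model = FALSE)))
  aic <- aic_compare(types, fit_switch, fit_noswitch)
  structure(list(layout = layout, events = events, truths = truths,
                 ratio_curves = r_emp, p_bg_hat = p_bg_hat, binned = binned,
                 object_counts = object_counts, fit_switch = fit_switch,
                 fit_noswitch = fit_noswitch, aic = aic, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d trials, %d events, p_bg_hat = %.3f\n",
              x$config$n_trials, nrow(x$events), x$p_bg_hat))
  print(x$fit_switch)
  print(x$aic)
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' Events and ratio curves as TSV, the fit summary as JSON.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_events(report$events, file.path(dir, "events.tsv"))
  rc <- as.data.frame(unclass(report$ratio_curves))
  rc$order <- seq_len(nrow(rc))
  rc$n_at_order <- attr(report$ratio_curves, "n_at_order")
  utils::write.table(rc, file.path(dir, "ratio_curves.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  bp <- report$fit_switch$best_params
  jsonlite::write_json(list(
    p_bg_hat = report$p_bg_hat,
    best_params = list(p_sw = bp$p_sw, p_intra_e = bp$p_intra_e,
                       p_trans_e = bp$p_trans_e, p_intra_l = bp$p_intra_l,
                       p_trans_l = bp$p_trans_l),
    gof = if (is.finite(report$fit_switch$gof)) report$fit_switch$gof else
      "Inf",
    aic = report$aic),
    file.path(dir, "fit_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
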