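# Synthetic trials: ground-truth event sequences drawn from the generative
# model, spatialised onto a stimulus layout, and rendered into gaze traces.

#' Rendering configuration for synthetic gaze traces
#'
#' @param sampling_rate Samples per second (default 20000, matching scleral
#'   search-coil recordings).
#' @param position_noise_sd Gaussian position noise SD in degrees added to
#'   every sample (coil noise; 0 renders noise-free traces).
#' @param saccade_duration_intercept,saccade_duration_slope Main-sequence
#'   rule for saccade duration, `duration = intercept + slope * amplitude`
#'   (seconds, s/deg). The defaults (0.010 s, 0.0018 s/deg) keep the
#'   raised-cosine peak velocity above 30 deg/s and peak acceleration above
#'   8000 deg/s^2 for amplitudes >= 0.5 deg, and keep the displacement lost
#'   in the sub-threshold velocity flanks below 0.05 deg over 0.5-15 deg so
#'   detected endpoint amplitudes track the ground truth.
#' @param pre_stimulus_fixation Duration in seconds of the fixation rendered
#'   before stimulus onset (0.5 or 0.3 in the two task variants).
#' @return An object of class `render_config`.
#' @export
render_config <- function(sampling_rate = 20000, position_noise_sd = 0,
                          saccade_duration_intercept = 0.010,
                          saccade_duration_slope = 0.0018,
                          pre_stimulus_fixation = 0.5) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (position_noise_sd < 0) stop("position_noise_sd must be >= 0")
  structure(list(sampling_rate = sampling_rate,
                 position_noise_sd = position_noise_sd,
                 saccade_duration_intercept = saccade_duration_intercept,
                 saccade_duration_slope = saccade_duration_slope,
                 pre_stimulus_fixation = pre_stimulus_fixation),
            class = "render_config")
}

# Draw a point uniformly within a disk.
runif_disk <- function(cx, cy, radius) {
  r <- radius * sqrt(stats::runif(1L))
  a <- stats::runif(1L, 0, 2 * pi)
  c(cx + r * cos(a), cy + r * sin(a))
}

# Rejection-sample a background point whose shortest object distance lies in
# (lo, hi], anchored near a reference point so relocations stay plausible.
sample_background_point <- function(layout, near = c(0, 0), lo = 1.5,
                                    hi = 3.0, max_attempts = 10000L) {
  obj <- layout$objects
  half_w <- layout$width / 2
  half_h <- layout$height / 2
  for (a in seq_len(max_attempts)) {
    # widen the search around the anchor as attempts accumulate
    spread <- hi * (1 + a / 100)
    px <- near[1L] + stats::runif(1L, -spread, spread)
    py <- near[2L] + stats::runif(1L, -spread, spread)
    if (abs(px) > half_w || abs(py) > half_h) next
    d <- min(sqrt((obj$x - px)^2 + (obj$y - py)^2))
    if (d > lo && d <= hi) return(c(px, py))
  }
  stop("could not place a background fixation point")
}

#' Generate ground-truth events for one synthetic trial
#'
#' Simulates a state sequence from the two-mode model, spatialises it onto a
#' layout (an intra-state re-fixates a fresh point within the same object, a
#' trans-state moves to a uniformly chosen different object, and a
#' background flip relocates the fixation to a point whose shortest object
#' distance lies in (1.5, 3] deg) and draws fixation durations from a gamma
#' distribution whose mean increases linearly over the trial.
#'
#' @param params A [model_params()] object. Under an object start the first
#'   fixation is placed on the object closest to the image centre; under a
#'   background start it is placed on a background point near the centre.
#' @param layout A [stimulus_layout()] with at least 2 objects.
#' @param seed Optional integer seed.
#' @param duration_mean_start,duration_mean_slope Mean fixation duration at
#'   trial start (s) and its linear increase (s per s of trial time);
#'   defaults 0.15 s rising by 0.04 s/s emulate the observed growth from
#'   roughly 0.15 to 0.35 s over a 5 s trial.
#' @param duration_shape Gamma shape of fixation durations.
#' @param min_duration Floor on fixation durations (s).
#' @param first_fixation_min Floor on the first fixation duration (s);
#'   stands in for the saccadic response latency, so the first saccade
#'   starts after the post-onset exclusion window.
#' @param min_saccade_amplitude Minimum displacement (deg) between
#'   consecutive fixation positions, so every ground-truth saccade is large
#'   enough to be representable by the renderer and detector (default 0.5).
#' @return An object of class `trial_truth`: list with `fixation_positions`
#'   (n_fix x 2), `fixation_durations`, `fixation_labels` (0 = background),
#'   `saccade_types` (factor), `saccade_amplitudes`, `true_switch_step` and
#'   `seed`.
#' @export
generate_trial_events <- function(params, layout, seed = NULL,
                                  duration_mean_start = 0.15,
                                  duration_mean_slope = 0.04,
                                  duration_shape = 10,
                                  min_duration = 0.04,
                                  first_fixation_min = 0.2,
                                  min_saccade_amplitude = 0.5) {
  obj <- layout$objects
  if (nrow(obj) < 2L) stop("layout must contain at least 2 objects")
  if (!is.null(seed)) set.seed(seed)
  n_fix <- params$n_fix
  sim <- simulate_states_matrix(params, n_fix - 1L, 1L)
  states <- sim$states[1L, ]

  # putative object ids in the n-object world
  putative <- integer(n_fix)
  center_obj <- obj$id[which.min(obj$x^2 + obj$y^2)]
  if (params$initial_condition == "first_fixation_object") {
    putative[1L] <- center_obj
    start_at <- 1L
  } else {
    putative[1L] <- NA_integer_
    putative[2L] <- center_obj
    start_at <- 2L
  }
  if (n_fix > start_at) {
    for (i in (start_at + 1L):n_fix) {
      prev <- putative[i - 1L]
      if (states[i - 1L] == 1L && i - 1L >= start_at) {
        putative[i] <- prev
      } else {
        ids <- setdiff(obj$id, prev)
        putative[i] <- if (length(ids) == 1L) ids else sample(ids, 1L)
      }
    }
  }

  # background flips
  flip <- stats::runif(n_fix) < params$p_bg
  flip[1L] <- params$initial_condition == "first_fixation_background"
  labels <- ifelse(flip, 0L, putative)

  # spatialise; resample until each saccade displaces the gaze by at least
  # min_saccade_amplitude so all ground-truth events are detectable
  pos <- matrix(0, nrow = n_fix, ncol = 2L)
  for (i in seq_len(n_fix)) {
    for (attempt in 1:1000) {
      if (labels[i] == 0L || is.na(labels[i])) {
        labels[i] <- 0L
        anchor <- if (is.na(putative[i])) c(0, 0) else
          unlist(obj[obj$id == putative[i], c("x", "y")])
        cand <- sample_background_point(layout, near = anchor)
      } else {
        o <- obj[obj$id == labels[i], ]
        cand <- runif_disk(o$x, o$y, o$radius)
      }
      if (i == 1L || sum((cand - pos[i - 1L, ])^2) >=
            min_saccade_amplitude^2) break
    }
    pos[i, ] <- cand
  }

  # durations with time-increasing mean
  durations <- numeric(n_fix)
  t_now <- 0
  for (i in seq_len(n_fix)) {
    mu <- duration_mean_start + duration_mean_slope * t_now
    d <- stats::rgamma(1L, shape = duration_shape,
                       rate = duration_shape / mu)
    d <- max(d, min_duration)
    if (i == 1L) d <- max(d, first_fixation_min)
    durations[i] <- d
    t_now <- t_now + d
  }

  amps <- sqrt(rowSums((pos[-1L, , drop = FALSE] -
                          pos[-n_fix, , drop = FALSE])^2))
  prev <- labels[-n_fix]; nxt <- labels[-1L]
  type_code <- integer(n_fix - 1L)
  type_code[prev > 0L & nxt > 0L & prev == nxt] <- 1L
  type_code[prev > 0L & nxt > 0L & prev != nxt] <- 2L
  type_code[prev > 0L & nxt == 0L] <- 3L
  type_code[prev == 0L & nxt > 0L] <- 4L
  type_code[prev == 0L & nxt == 0L] <- 5L

  structure(list(fixation_positions = pos,
                 fixation_durations = durations,
                 fixation_labels = labels,
                 saccade_types = factor(SACCADE_TYPES[type_code],
                                        levels = SACCADE_TYPES),
                 saccade_amplitudes = amps,
                 true_switch_step = sim$switch_step[1L],
                 seed = seed),
            class = "trial_truth")
}

#' @export
print.trial_truth <- function(x, ...) {
  n <- length(x$fixation_durations)
  cat(sprintf("Synthetic trial: %d fixations, %d saccades, switch at step %s\n",
              n, n - 1L,
              if (is.na(x$true_switch_step)) "none (no switch)" else
                as.character(x$true_switch_step)))
  cat(sprintf("  %d object / %d background fixations; total duration %.2f s\n",
              sum(x$fixation_labels > 0L), sum(x$fixation_labels == 0L),
              sum(x$fixation_durations)))
  invisible(x)
}

#' Render a ground-truth trial into a gaze trace
#'
#' Builds a piecewise trace: stationary during fixations (plus optional
#' Gaussian noise) and raised-cosine velocity profiles during saccades,
#' whose durations follow the main-sequence rule of the [render_config()].
#' A pre-stimulus fixation is prepended at the first fixation position (the
#' subject is already fixating where the trial starts), and stimulus onset
#' is recorded at the end of that epoch.
#'
#' @param truth A `trial_truth` from [generate_trial_events()].
#' @param cfg A [render_config()].
#' @param seed Optional integer seed for the additive noise.
#' @return A [gaze_trace()].
#' @export
render_gaze_trace <- function(truth, cfg = render_config(), seed = NULL) {
  if (any(truth$fixation_durations <= 0)) stop("all durations must be > 0")
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg$sampling_rate
  pos <- truth$fixation_positions
  n_fix <- nrow(pos)
  amps <- truth$saccade_amplitudes
  sacc_dur <- cfg$saccade_duration_intercept +
    cfg$saccade_duration_slope * amps
  if (length(sacc_dur) && min(sacc_dur) * fs < 5) {
    stop("sampling rate too low: shortest saccade spans fewer than 5 samples")
  }

  # segment table: alternating fixation / saccade epochs
  durs <- c(cfg$pre_stimulus_fixation + truth$fixation_durations[1L],
            if (n_fix > 1L) as.vector(rbind(sacc_dur,
                                            truth$fixation_durations[-1L])))
  starts <- cumsum(c(0, durs[-length(durs)]))
  is_sacc <- c(FALSE, if (n_fix > 1L) rep(c(TRUE, FALSE), n_fix - 1L))
  fix_idx <- cumsum(!is_sacc)          # which fixation a segment belongs to

  total <- sum(durs)
  n_samp <- floor(total * fs) + 1L
  t <- (seq_len(n_samp) - 1L) / fs
  seg <- findInterval(t, starts)
  x <- numeric(n_samp); y <- numeric(n_samp)
  for (k in seq_along(durs)) {
    sel <- seg == k
    if (!any(sel)) next
    if (!is_sacc[k]) {
      x[sel] <- pos[fix_idx[k], 1L]
      y[sel] <- pos[fix_idx[k], 2L]
    } else {
      i <- fix_idx[k]                  # saccade from fixation i to i + 1
      tau <- t[sel] - starts[k]
      d <- durs[k]
      frac <- tau / d - sin(2 * pi * tau / d) / (2 * pi)
      x[sel] <- pos[i, 1L] + frac * (pos[i + 1L, 1L] - pos[i, 1L])
      y[sel] <- pos[i, 2L] + frac * (pos[i + 1L, 2L] - pos[i, 2L])
    }
  }
  if (cfg$position_noise_sd > 0) {
    x <- x + stats::rnorm(n_samp, sd = cfg$position_noise_sd)
    y <- y + stats::rnorm(n_samp, sd = cfg$position_noise_sd)
  }
  gaze_trace(t, x, y, sampling_rate = fs,
             stimulus_onset = cfg$pre_stimulus_fixation)
}
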