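# Saccade and fixation detection from gaze traces.
#
# Kinematics are estimated with Savitzky-Golay derivative filters; candidate
# saccades are maximal supra-threshold speed runs gated by an acceleration
# requirement and pruned by peak-velocity / peak-acceleration / duration /
# amplitude artifact rules. The remaining inter-saccade intervals become
# fixations unless the gaze drifts by more than 1 deg, and all events
# starting within 150 ms of stimulus onset are discarded.

#' Detection configuration
#'
#' Defaults follow standard coil-recording practice: a 10 ms second-order
#' Savitzky-Golay differentiator; saccade thresholds of 30 deg/s and
#' 8000 deg/s^2; artifact rejection above 1500 deg/s peak velocity or
#' 120000 deg/s^2 peak acceleration, outside 5-100 ms duration, or below
#' 0.1 deg displacement; a 1 deg fixation drift bound; and a 150 ms
#' post-onset exclusion window.
#'
#' @param sg_window Savitzky-Golay window length in seconds; converted to an
#'   odd number of samples at the trace's sampling rate (199 samples at
#'   20 kHz).
#' @param sg_polyorder Polynomial order of the filter.
#' @param vel_threshold,acc_threshold Saccade thresholds (deg/s, deg/s^2).
#' @param max_peak_vel,max_peak_acc Artifact rejection bounds.
#' @param min_duration,max_duration Admissible saccade durations (s).
#' @param min_amplitude Minimum endpoint displacement (deg).
#' @param fixation_max_drift Maximum gaze shift within a fixation (deg).
#' @param onset_exclusion Events with onset within this window after
#'   stimulus onset are discarded (s).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(sg_window = 0.010, sg_polyorder = 2L,
                             vel_threshold = 30, acc_threshold = 8000,
                             max_peak_vel = 1500, max_peak_acc = 120000,
                             min_duration = 0.005, max_duration = 0.100,
                             min_amplitude = 0.1, fixation_max_drift = 1.0,
                             onset_exclusion = 0.150) {
  if (min_duration >= max_duration) stop("min_duration must be < max_duration")
  vals <- c(sg_window, vel_threshold, acc_threshold, max_peak_vel,
            max_peak_acc, min_duration, max_duration, min_amplitude,
            fixation_max_drift)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  structure(list(sg_window = sg_window, sg_polyorder = as.integer(sg_polyorder),
                 vel_threshold = vel_threshold, acc_threshold = acc_threshold,
                 max_peak_vel = max_peak_vel, max_peak_acc = max_peak_acc,
                 min_duration = min_duration, max_duration = max_duration,
                 min_amplitude = min_amplitude,
                 fixation_max_drift = fixation_max_drift,
                 onset_exclusion = onset_exclusion),
            class = "detection_config")
}

# Odd filter length in samples for a window given in seconds; 10 ms at
# 20 kHz gives 199 samples.
sg_window_samples <- function(sg_window, sampling_rate) {
  n <- round(sg_window * sampling_rate)
  if (n %% 2L == 0L) n <- n - 1L
  max(n, 3L)
}

#' Estimate gaze speed and acceleration magnitude
#'
#' Per-axis first and second Savitzky-Golay derivatives of the gaze trace;
#' speed is the Euclidean norm of the velocity components, acceleration
#' magnitude the norm of the second derivatives. Samples within half a
#' filter window of either end carry incomplete windows and are flagged
#' invalid.
#'
#' @param trace A [gaze_trace()].
#' @param cfg A [detection_config()].
#' @return A data.frame with columns `t`, `speed` (deg/s), `acc` (deg/s^2)
#'   and `valid` (logical).
#' @export
estimate_kinematics <- function(trace, cfg = detection_config()) {
  fs <- attr(trace, "sampling_rate")
  n_win <- sg_window_samples(cfg$sg_window, fs)
  if (nrow(trace) < n_win) {
    stop("trace shorter than the Savitzky-Golay window")
  }
  dt <- 1 / fs
  vx <- signal::sgolayfilt(trace$x, p = cfg$sg_polyorder, n = n_win,
                           m = 1L, ts = dt)
  vy <- signal::sgolayfilt(trace$y, p = cfg$sg_polyorder, n = n_win,
                           m = 1L, ts = dt)
  ax <- signal::sgolayfilt(trace$x, p = cfg$sg_polyorder, n = n_win,
                           m = 2L, ts = dt)
  ay <- signal::sgolayfilt(trace$y, p = cfg$sg_polyorder, n = n_win,
                           m = 2L, ts = dt)
  half <- (n_win - 1L) %/% 2L
  valid <- rep(TRUE, nrow(trace))
  valid[seq_len(half)] <- FALSE
  valid[seq.int(nrow(trace) - half + 1L, nrow(trace))] <- FALSE
  data.frame(t = trace$t, speed = sqrt(vx^2 + vy^2),
             acc = sqrt(ax^2 + ay^2), valid = valid)
}

#' Detect saccades in a gaze trace
#'
#' Candidate segments are maximal runs of valid samples whose speed exceeds
#' `vel_threshold`; a candidate is kept only if its peak acceleration
#' magnitude exceeds `acc_threshold` (the acceleration criterion is applied
#' per segment because |acc| passes through zero at peak velocity inside
#' every saccade). Candidates are then discarded when peak speed or peak
#' acceleration exceed the artifact bounds, the duration falls outside
#' `[min_duration, max_duration]`, or the endpoint displacement is below
#' `min_amplitude`. Microsaccades are not distinguished from saccades.
#'
#' @param kin Kinematics from [estimate_kinematics()] on the same grid.
#' @param trace The [gaze_trace()].
#' @param cfg A [detection_config()].
#' @return A data.frame of saccade events: `onset`, `offset` (s), `x_on`,
#'   `y_on`, `x_off`, `y_off`, `amplitude` (deg), `peak_velocity` (deg/s),
#'   `duration` (s), `order` (1-based, in time order).
#' @export
detect_saccades <- function(kin, trace, cfg = detection_config()) {
  if (nrow(kin) != nrow(trace)) {
    stop("kinematics and trace must share the sample grid")
  }
  above <- kin$speed > cfg$vel_threshold & kin$valid
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  events <- list()
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    peak_v <- max(kin$speed[i0:i1])
    peak_a <- max(kin$acc[i0:i1])
    dur <- kin$t[i1] - kin$t[i0]
    disp <- sqrt((trace$x[i1] - trace$x[i0])^2 +
                   (trace$y[i1] - trace$y[i0])^2)
    if (peak_a <= cfg$acc_threshold) next
    if (peak_v > cfg$max_peak_vel || peak_a > cfg$max_peak_acc) next
    if (dur < cfg$min_duration || dur > cfg$max_duration) next
    if (disp < cfg$min_amplitude) next
    events[[length(events) + 1L]] <- data.frame(
      onset = kin$t[i0], offset = kin$t[i1],
      x_on = trace$x[i0], y_on = trace$y[i0],
      x_off = trace$x[i1], y_off = trace$y[i1],
      amplitude = disp, peak_velocity = peak_v, duration = dur)
  }
  if (!length(events)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      x_on = numeric(0), y_on = numeric(0),
                      x_off = numeric(0), y_off = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0),
                      duration = numeric(0), order = integer(0)))
  }
  out <- do.call(rbind, events)
  out <- out[order(out$onset), , drop = FALSE]
  out$order <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Maximum pairwise distance among 2-d points, via the convex hull.
max_pairwise_distance <- function(x, y) {
  if (length(x) < 2L) return(0)
  h <- unique(grDevices::chull(x, y))
  if (length(h) < 2L) return(0)
  max(stats::dist(cbind(x[h], y[h])))
}

#' Extract fixations between detected saccades
#'
#' Each interval between two successive saccades (plus the leading interval
#' after stimulus onset and the trailing interval before trace end) becomes
#' a fixation if the maximum pairwise gaze displacement within it stays at
#' or below `fixation_max_drift`. Fixations and saccades with onset within
#' `onset_exclusion` of stimulus onset (or before it) are then removed and
#' the survivors re-indexed.
#'
#' @param saccades Saccade table from [detect_saccades()].
#' @param trace The [gaze_trace()].
#' @param cfg A [detection_config()].
#' @return List with `fixations` (data.frame: `onset`, `offset`, `x`, `y`,
#'   `duration`, `order`) and `saccades` (the input table after the
#'   exclusion window, re-indexed).
#' @export
extract_fixations <- function(saccades, trace, cfg = detection_config()) {
  onset0 <- attr(trace, "stimulus_onset")
  t_end <- trace$t[nrow(trace)]
  if (nrow(saccades) > 1L &&
      any(saccades$onset[-1L] < saccades$offset[-nrow(saccades)])) {
    stop("overlapping saccade periods")
  }
  bounds_start <- c(onset0, saccades$offset)
  bounds_end <- c(saccades$onset, t_end)
  fixes <- list()
  for (k in seq_along(bounds_start)) {
    a <- bounds_start[k]; b <- bounds_end[k]
    if (b <= a) next
    sel <- trace$t >= a & trace$t <= b
    if (sum(sel) < 2L) next
    if (max_pairwise_distance(trace$x[sel], trace$y[sel]) >
        cfg$fixation_max_drift) next
    fixes[[length(fixes) + 1L]] <- data.frame(
      onset = a, offset = b,
      x = mean(trace$x[sel]), y = mean(trace$y[sel]), duration = b - a)
  }
  fixations <- if (length(fixes)) do.call(rbind, fixes) else
    data.frame(onset = numeric(0), offset = numeric(0), x = numeric(0),
               y = numeric(0), duration = numeric(0))
  cutoff <- onset0 + cfg$onset_exclusion
  fixations <- fixations[fixations$onset >= cutoff, , drop = FALSE]
  saccades <- saccades[saccades$onset >= cutoff, , drop = FALSE]
  fixations$order <- seq_len(nrow(fixations))
  saccades$order <- seq_len(nrow(saccades))
  rownames(fixations) <- rownames(saccades) <- NULL
  list(fixations = fixations, saccades = saccades)
}

#' Detect all eye events in a trace
#'
#' Convenience wrapper running [estimate_kinematics()], [detect_saccades()]
#' and [extract_fixations()].
#'
#' @param trace A [gaze_trace()].
#' @param cfg A [detection_config()].
#' @return As [extract_fixations()].
#' @export
detect_events <- function(trace, cfg = detection_config()) {
  kin <- estimate_kinematics(trace, cfg)
  sacc <- detect_saccades(kin, trace, cfg)
  extract_fixations(sacc, trace, cfg)
}
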