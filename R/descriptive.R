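# Descriptive dynamics: onset-time histograms, binned eye-event parameters,
# fixated-object counts, per-order type ratio curves, and the
# repetition-excess permutation test.

# Coerce saccade-type input (integer-code matrix from simulate_trials(), or
# long data.frame with trial_id/saccade_type in trial order) to a list of
# integer vectors of classified types per trial.
as_type_sequences <- function(trials) {
  if (is.matrix(trials)) {
    seqs <- lapply(seq_len(nrow(trials)), function(i) {
      v <- trials[i, ]
      v[!is.na(v)]
    })
  } else if (is.data.frame(trials)) {
    stopifnot(all(c("trial_id", "saccade_type") %in% names(trials)))
    v <- trials$saccade_type
    codes <- if (is.factor(v)) as.integer(v) else match(v, SACCADE_TYPES)
    seqs <- split(codes, trials$trial_id)
    seqs <- lapply(seqs, function(s) s[!is.na(s)])
  } else {
    stop("trials must be a matrix of type codes or a data.frame")
  }
  seqs
}

#' Onset-time histograms of eye events by type
#'
#' Counts of fixation onsets (by kind) and saccade onsets (by type) in
#' fixed-width time bins after stimulus onset, together with per-bin ratios
#' relative to the total count in the bin. Bins with no events yield `NA`
#' ratios (undefined, not zero).
#'
#' @param onsets Event onset times in seconds relative to stimulus onset
#'   (must be non-negative).
#' @param types Character/factor event label per onset (fixation kinds or
#'   saccade types).
#' @param bin Bin width in seconds (default 0.025).
#' @param t_max Upper edge of the last bin; defaults to the largest onset
#'   rounded up to a bin boundary.
#' @return A data.frame with columns `bin_start`, `bin_mid`, `type`,
#'   `count`, `total` and `ratio`.
#' @export
event_time_histograms <- function(onsets, types, bin = 0.025, t_max = NULL) {
  if (any(onsets < 0)) stop("onsets before stimulus onset are not allowed")
  if (is.null(t_max)) t_max <- ceiling(max(onsets) / bin) * bin
  edges <- seq(0, t_max, by = bin)
  if (max(onsets) >= edges[length(edges)]) {
    edges <- c(edges, edges[length(edges)] + bin)
  }
  idx <- findInterval(onsets, edges, rightmost.closed = FALSE)
  types <- as.character(types)
  lv <- unique(types)
  n_bins <- length(edges) - 1L
  counts <- table(factor(idx, levels = seq_len(n_bins)),
                  factor(types, levels = lv))
  total <- rowSums(counts)
  out <- expand.grid(bin = seq_len(n_bins), type = lv,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$bin_start <- edges[out$bin]
  out$bin_mid <- edges[out$bin] + bin / 2
  out$count <- as.vector(counts)
  out$total <- total[out$bin]
  out$ratio <- ifelse(out$total > 0, out$count / out$total, NA_real_)
  out[, c("bin_start", "bin_mid", "type", "count", "total", "ratio")]
}

# Per-bin mean and SEM of a value assigned to bins by onset time.
binned_mean_sem <- function(onsets, values, bin, t_max) {
  edges <- seq(0, t_max, by = bin)
  idx <- findInterval(onsets, edges, rightmost.closed = TRUE)
  idx[idx > length(edges) - 1L] <- length(edges) - 1L
  out <- data.frame(bin_start = edges[-length(edges)],
                    bin_mid = edges[-length(edges)] + bin / 2)
  grp <- factor(idx, levels = seq_len(length(edges) - 1L))
  out$count <- as.vector(table(grp))
  out$mean <- as.vector(tapply(values, grp, mean))
  sdv <- as.vector(tapply(values, grp, stats::sd))
  out$sem <- ifelse(out$count > 1L, sdv / sqrt(out$count), NA_real_)
  out
}

#' Binned time courses of fixation duration and saccade amplitude
#'
#' Mean and standard error of fixation durations and saccade amplitudes in
#' non-overlapping time bins by onset time (default 500 ms bins over 5 s),
#' the classic signature of the ambient-to-focal shift: durations grow
#' while amplitudes shrink.
#'
#' @param fixations Data.frame with `onset` (relative to stimulus onset)
#'   and `duration`.
#' @param saccades Data.frame with `onset` and `amplitude`.
#' @param bin Bin width in seconds (default 0.5).
#' @param t_max End of the analysis window in seconds (default 5).
#' @return List with data.frames `fixation_duration` and
#'   `saccade_amplitude`, each with `bin_start`, `bin_mid`, `count`,
#'   `mean`, `sem`.
#' @export
binned_eye_parameters <- function(fixations, saccades, bin = 0.5, t_max = 5) {
  list(fixation_duration = binned_mean_sem(fixations$onset,
                                           fixations$duration, bin, t_max),
       saccade_amplitude = binned_mean_sem(saccades$onset,
                                           saccades$amplitude, bin, t_max))
}

#' Fixated-object counts per trial interval
#'
#' For every trial and every fixed-length interval of the viewing period:
#' the number of distinct fixated objects, the number of fixations, and
#' fixations per object; then averaged over trials with SEM. A decreasing
#' object count with an increasing fixations-per-object ratio indicates the
#' shift from ambient scanning of many objects to focal examination of one.
#'
#' @param labeled_fixations Data.frame with `trial_id`, `onset` (relative
#'   to stimulus onset), `fix_kind` and `fixated_object`.
#' @param interval Interval length in seconds (default 1).
#' @param t_max End of the analysis window (default 5 s).
#' @return A data.frame with one row per interval: means and SEMs over
#'   trials of `n_objects`, `n_fixations` and `fix_per_object` (the latter
#'   averaged over trials with at least one fixated object).
#' @export
fixated_object_counts <- function(labeled_fixations, interval = 1.0,
                                  t_max = 5) {
  n_int <- ceiling(t_max / interval)
  trials <- unique(labeled_fixations$trial_id)
  per_trial <- array(NA_real_, dim = c(length(trials), n_int, 3L))
  for (ti in seq_along(trials)) {
    tf <- labeled_fixations[labeled_fixations$trial_id == trials[ti], ]
    iv <- pmin(floor(tf$onset / interval) + 1L, n_int)
    for (k in seq_len(n_int)) {
      sel <- iv == k
      objs <- tf$fixated_object[sel & tf$fix_kind == "object"]
      n_obj <- length(unique(objs[!is.na(objs)]))
      n_fix <- sum(sel)
      per_trial[ti, k, 1L] <- n_obj
      per_trial[ti, k, 2L] <- n_fix
      per_trial[ti, k, 3L] <- if (n_obj > 0L) n_fix / n_obj else NA_real_
    }
  }
  msem <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v),
      sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }
  out <- data.frame(interval_start = (seq_len(n_int) - 1L) * interval)
  stats_obj <- t(apply(per_trial[, , 1L, drop = FALSE], 2L, msem))
  stats_fix <- t(apply(per_trial[, , 2L, drop = FALSE], 2L, msem))
  stats_fpo <- t(apply(per_trial[, , 3L, drop = FALSE], 2L, msem))
  out$mean_objects <- stats_obj[, 1L]
  out$sem_objects <- stats_obj[, 2L]
  out$mean_fixations <- stats_fix[, 1L]
  out$sem_fixations <- stats_fix[, 2L]
  out$mean_fix_per_object <- stats_fpo[, 1L]
  out$sem_fix_per_object <- stats_fpo[, 2L]
  out
}

#' Empirical saccade-type ratio curves by saccade order
#'
#' The distribution of the i-th classified saccade's type over all trials
#' having at least i classified saccades, for i = 1 ... `max_order`.
#' Unclassified saccades (flanking fixation missing) are dropped and each
#' trial's classified saccades re-indexed before counting.
#'
#' @param trials Either an integer matrix of type codes (rows = trials,
#'   from [simulate_trials()]) or a data.frame with `trial_id` and
#'   `saccade_type` in within-trial order.
#' @param max_order Largest saccade order to keep.
#' @return A `ratio_curves` matrix (`max_order` x 5) with attribute
#'   `n_at_order`, the number of trials contributing at each order.
#' @export
saccade_type_ratios_by_order <- function(trials, max_order) {
  seqs <- as_type_sequences(trials)
  lens <- lengths(seqs)
  if (!any(lens >= 1L)) stop("no trial contributes a classified saccade")
  r <- matrix(0, nrow = max_order, ncol = 5L)
  n_at <- integer(max_order)
  for (i in seq_len(max_order)) {
    have <- lens >= i
    n_at[i] <- sum(have)
    if (n_at[i] > 0L) {
      ith <- vapply(seqs[have], `[[`, integer(1L), i)
      r[i, ] <- tabulate(ith, nbins = 5L) / n_at[i]
    } else {
      r[i, ] <- NA_real_
    }
  }
  ratio_curves(r, n_at_order = n_at)
}

#' Permutation test for repetition excess of saccade types
#'
#' Counts immediate same-type successions per saccade type and compares
#' them with a null distribution obtained by shuffling each trial's type
#' sequence (preserving per-trial type counts). A small one-sided p-value
#' indicates that repetitions of that type occur more often than expected
#' by chance, the sequential dependence that motivates type-specific
#' generation states. This is a within-trial permutation reading of the
#' chance expectation.
#'
#' @param trials As in [saccade_type_ratios_by_order()].
#' @param n_permutations Number of shuffles (>= 100).
#' @param seed Optional integer seed.
#' @return A data.frame with one row per saccade type: `observed`
#'   repetition count, `null_mean`, and one-sided `p_value`
#'   (`(1 + #{null >= observed}) / (n_permutations + 1)`).
#' @export
repetition_excess_test <- function(trials, n_permutations = 1000L,
                                   seed = NULL) {
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  seqs <- as_type_sequences(trials)
  seqs <- seqs[lengths(seqs) >= 2L]
  count_reps <- function(ss) {
    reps <- integer(5L)
    for (s in ss) {
      same <- s[-1L] == s[-length(s)]
      if (any(same)) {
        tab <- tabulate(s[-1L][same], nbins = 5L)
        reps <- reps + tab
      }
    }
    reps
  }
  obs <- count_reps(seqs)
  null <- matrix(0L, nrow = n_permutations, ncol = 5L)
  for (b in seq_len(n_permutations)) {
    null[b, ] <- count_reps(lapply(seqs, function(s)
      s[sample.int(length(s))]))
  }
  p <- vapply(1:5, function(k) {
    (1 + sum(null[, k] >= obs[k])) / (n_permutations + 1)
  }, numeric(1L))
  data.frame(saccade_type = SACCADE_TYPES, observed = obs,
             null_mean = colMeans(null), p_value = p)
}
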