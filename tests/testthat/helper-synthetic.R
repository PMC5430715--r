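# Shared fixtures: the two printed best-fit parameter vectors, controlled
# ground truths for the renderer, and brute-force oracles.

object_start_params <- function(n_fix = 21L) {
  model_params(p_sw = 0.20, p_intra_e = 0.00, p_trans_e = 1.00,
               p_intra_l = 0.90, p_trans_l = 0.55, p_bg = 0.23,
               n_fix = n_fix, initial_condition = "first_fixation_object")
}

background_start_params <- function(n_fix = 16L) {
  model_params(p_sw = 0.25, p_intra_e = 0.05, p_trans_e = 0.50,
               p_intra_l = 0.90, p_trans_l = 0.55, p_bg = 0.21,
               n_fix = n_fix,
               initial_condition = "first_fixation_background")
}

# A trial_truth with horizontal saccades of the given amplitudes and fixed
# fixation durations, for controlled renderer/detector tests.
step_truth <- function(amps, dur = 0.3) {
  n <- length(amps) + 1L
  pos <- matrix(0, n, 2L)
  for (i in seq_along(amps)) {
    pos[i + 1L, ] <- pos[i, ] + c(amps[i] * (-1)^(i + 1L), 0)
  }
  structure(list(fixation_positions = pos,
                 fixation_durations = rep(dur, n),
                 fixation_labels = rep(1L, n),
                 saccade_types = factor(rep("intra_object", n - 1L),
                                        levels = gazemodes:::SACCADE_TYPES),
                 saccade_amplitudes = abs(amps),
                 true_switch_step = NA_integer_, seed = NULL),
            class = "trial_truth")
}

# Brute-force probability of an observed type-code sequence given the
# switch step, by exhaustive enumeration of state and flip sequences.
# Independent of the package's forward pass.
brute_sequence_probability <- function(types, params, switch_at) {
  k <- length(types)
  n_fix <- k + 1L
  pi0 <- initial_state_distribution(params)
  b <- rep(params$p_bg, n_fix)
  b[1L] <- if (params$initial_condition == "first_fixation_object") 0 else 1
  total <- 0
  for (xi in 0:(2^k - 1L)) {
    x <- as.integer(intToBits(xi))[1:k] + 1L
    px <- pi0[[x[1L]]]
    if (k >= 2L) {
      for (i in 2:k) {
        ps <- if (i >= switch_at) c(params$p_intra_l, params$p_trans_l) else
          c(params$p_intra_e, params$p_trans_e)
        px <- px * if (x[i] == x[i - 1L]) ps[x[i - 1L]] else
          1 - ps[x[i - 1L]]
      }
    }
    if (px == 0) next
    for (fi in 0:(2^n_fix - 1L)) {
      f <- as.integer(intToBits(fi))[1:n_fix]   # 1 = background
      pf <- prod(ifelse(f == 1L, b, 1 - b))
      if (pf == 0) next
      emit <- vapply(1:k, function(i) {
        if (f[i] == 0L && f[i + 1L] == 0L) x[i]
        else if (f[i] == 0L) 3L
        else if (f[i + 1L] == 0L) 4L
        else 5L
      }, integer(1L))
      if (all(emit == types)) total <- total + px * pf
    }
  }
  total
}

# Brute-force expected type-ratio curves by enumerating all state and flip
# sequences with their probabilities (marginalising the switch step through
# the transition structure is avoided by enumerating mode paths as well).
# Feasible only for small n_fix; independent oracle for
# expected_ratio_curves().
brute_expected_curves <- function(params) {
  k <- params$n_fix - 1L
  # enumerate mode paths: switch step s in 2..k or never
  probs <- matrix(0, nrow = k, ncol = 5L)
  s_candidates <- c(if (k >= 2L) 2:k, Inf)
  prior <- vapply(s_candidates, function(s) {
    if (is.infinite(s)) (1 - params$p_sw)^(k - 1L)
    else params$p_sw * (1 - params$p_sw)^(s - 2L)
  }, numeric(1L))
  for (si in seq_along(s_candidates)) {
    s <- s_candidates[si]
    for (yi in 0:(5^k - 1L)) {
      y <- integer(k)
      z <- yi
      for (i in 1:k) {
        y[i] <- z %% 5L + 1L
        z <- z %/% 5L
      }
      p <- brute_sequence_probability(y, params, s)
      if (p > 0) {
        for (i in 1:k) {
          probs[i, y[i]] <- probs[i, y[i]] + prior[si] * p
        }
      }
    }
  }
  probs
}
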