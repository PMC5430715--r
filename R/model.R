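# Two-mode Markov model of saccade-sequence generation.
#
# Four saccade-generation states: {intra, trans} x {early, late}. The chain
# starts in the early mode, may switch once (and irreversibly) to the late
# mode with per-step probability p_sw, and within each mode repeats the
# current saccade type with a mode-specific stay probability. Fixation labels
# are derived in a two-object world and then corrupted to background
# fixations by independent flips with probability p_bg.

SACCADE_TYPES <- c("intra_object", "trans_object", "object_to_background",
                   "background_to_object", "background_to_background")

#' Model parameters for the two-mode saccade-generation model
#'
#' Bundles the six probabilities of the generative model together with the
#' trial length and the initial-fixation condition.
#'
#' @param p_sw Per-step probability of the one-way switch from the early
#'   (ambient) to the late (focal) mode.
#' @param p_intra_e,p_trans_e Stay probabilities of the intra- and trans-state
#'   in the early mode.
#' @param p_intra_l,p_trans_l Stay probabilities in the late mode.
#' @param p_bg Probability that a fixation is flipped to a background
#'   fixation (saccadic-error rate).
#' @param n_fix Number of fixations per simulated trial (>= 2). 21 matches
#'   the object-at-center condition, 16 the background-start condition.
#' @param initial_condition Either `"first_fixation_object"` (the trial
#'   starts on an object; the first fixation is protected from flipping) or
#'   `"first_fixation_background"` (the first fixation is forced to be a
#'   background fixation).
#' @return An object of class `model_params`.
#' @examples
#' model_params(p_sw = 0.2, p_intra_e = 0, p_trans_e = 1,
#'              p_intra_l = 0.9, p_trans_l = 0.55, p_bg = 0.23, n_fix = 21)
#' @export
model_params <- function(p_sw, p_intra_e, p_trans_e, p_intra_l, p_trans_l,
                         p_bg, n_fix = 21L,
                         initial_condition = c("first_fixation_object",
                                               "first_fixation_background")) {
  initial_condition <- match.arg(initial_condition)
  probs <- c(p_sw = p_sw, p_intra_e = p_intra_e, p_trans_e = p_trans_e,
             p_intra_l = p_intra_l, p_trans_l = p_trans_l, p_bg = p_bg)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all model probabilities must lie in [0, 1]")
  }
  n_fix <- as.integer(n_fix)
  if (is.na(n_fix) || n_fix < 2L) stop("n_fix must be an integer >= 2")
  structure(list(p_sw = p_sw, p_intra_e = p_intra_e, p_trans_e = p_trans_e,
                 p_intra_l = p_intra_l, p_trans_l = p_trans_l, p_bg = p_bg,
                 n_fix = n_fix, initial_condition = initial_condition),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-mode saccade-generation model parameters\n")
  cat(sprintf("  p_sw = %.3f   (expected switch time %s saccades)\n",
              x$p_sw,
              if (x$p_sw > 0) format(1 / x$p_sw, digits = 4) else "Inf"))
  cat(sprintf("  early mode: p_intra^E = %.3f, p_trans^E = %.3f\n",
              x$p_intra_e, x$p_trans_e))
  cat(sprintf("  late mode:  p_intra^L = %.3f, p_trans^L = %.3f\n",
              x$p_intra_l, x$p_trans_l))
  cat(sprintf("  p_bg = %.3f, n_fix = %d, start: %s\n",
              x$p_bg, x$n_fix, x$initial_condition))
  invisible(x)
}

#' Stationary initial distribution of the early-mode chain
#'
#' Probability that the first generation state is the intra- or the
#' trans-state: the asymptotic occupancies of an infinitely long chain run
#' under the early-mode transition rule,
#' `P(intra) = (1 - p_trans_e) / (2 - p_intra_e - p_trans_e)`.
#'
#' @param params A [model_params()] object.
#' @return Named numeric vector `c(intra = ..., trans = ...)` summing to 1.
#' @export
initial_state_distribution <- function(params) {
  den <- 2 - params$p_intra_e - params$p_trans_e
  if (den <= 0) {
    stop("degenerate early mode: p_intra_e = p_trans_e = 1 has no ",
         "stationary distribution")
  }
  p_intra <- (1 - params$p_trans_e) / den
  c(intra = p_intra, trans = 1 - p_intra)
}

#' Expected number of saccades generated before the mode switch
#'
#' The switch is a Bernoulli process with success probability `p_sw`, so the
#' number of saccades generated in the early mode (switch trials until the
#' first success) is geometric with mean `1 / p_sw`.
#'
#' @param p_sw Switch probability in (0, 1]. `p_sw = 0` returns `Inf` (no
#'   switch ever occurs).
#' @return Expected saccade count before the switch.
#' @examples
#' expected_switch_step(0.2)  # 5
#' @export
expected_switch_step <- function(p_sw) {
  if (!is.numeric(p_sw) || length(p_sw) != 1L || is.na(p_sw) ||
      p_sw < 0 || p_sw > 1) {
    stop("p_sw must be a single probability in [0, 1]")
  }
  if (p_sw == 0) return(Inf)
  1 / p_sw
}

# Vectorised simulation of n state sequences, each n_steps long.
# Returns integer matrices: states (1 = intra, 2 = trans) and modes
# (1 = early, 2 = late), plus switch_step (first step in the late mode,
# NA when no switch occurred within the sequence; minimum value 2).
simulate_states_matrix <- function(params, n_steps, n) {
  pi0 <- initial_state_distribution(params)
  states <- matrix(0L, nrow = n, ncol = n_steps)
  modes <- matrix(1L, nrow = n, ncol = n_steps)
  states[, 1L] <- ifelse(stats::runif(n) < pi0[["intra"]], 1L, 2L)
  late <- rep(FALSE, n)
  if (n_steps >= 2L) {
    for (j in 2:n_steps) {
      # Switch decision for sequences still in the early mode; the state at
      # the switch step is already generated with late-mode stay
      # probabilities.
      late <- late | (!late & stats::runif(n) < params$p_sw)
      modes[, j] <- ifelse(late, 2L, 1L)
      prev <- states[, j - 1L]
      p_stay <- ifelse(late,
                       ifelse(prev == 1L, params$p_intra_l, params$p_trans_l),
                       ifelse(prev == 1L, params$p_intra_e, params$p_trans_e))
      stay <- stats::runif(n) < p_stay
      states[, j] <- ifelse(stay, prev, 3L - prev)
    }
  }
  n_late <- as.integer(rowSums(modes == 2L))  # the late mode is absorbing
  first_late <- ifelse(n_late == 0L, NA_integer_,
                       as.integer(n_steps) - n_late + 1L)
  list(states = states, modes = modes, switch_step = first_late)
}

#' Simulate one sequence of saccade-generation states
#'
#' Draws the first state from [initial_state_distribution()] in the early
#' mode; at each later step the mode switches irreversibly to the late mode
#' with probability `p_sw` (so the first opportunity to be in the late mode
#' is step 2), and the state repeats with the stay probability of the mode
#' governing that step.
#'
#' @param params A [model_params()] object.
#' @param n_steps Number of states (saccades) to generate, >= 1.
#' @param seed Optional integer seed.
#' @return A list of class `state_sequence` with elements `state` (character,
#'   `"intra"`/`"trans"`), `mode` (`"early"`/`"late"`) and `switch_step`
#'   (first step in the late mode, or `NA` if the switch did not occur
#'   within the sequence). `switch_step - 1` is the number of saccades
#'   generated before the switch, whose expectation is `1 / p_sw`.
#' @export
simulate_state_sequence <- function(params, n_steps, seed = NULL) {
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_states_matrix(params, n_steps, 1L)
  structure(list(state = c("intra", "trans")[sim$states[1L, ]],
                 mode = c("early", "late")[sim$modes[1L, ]],
                 switch_step = sim$switch_step[1L]),
            class = "state_sequence")
}

# Putative object identities (two-object world) from a state matrix.
# For an object start, fixation 1 is on object 1 and state j relates
# fixations j and j+1. For a background start, fixation 1 is background,
# fixation 2 is on object 1, and states from step 2 onwards toggle objects.
putative_objects_matrix <- function(states, initial_condition) {
  n <- nrow(states)
  n_steps <- ncol(states)
  objects <- matrix(1L, nrow = n, ncol = n_steps + 1L)
  if (initial_condition == "first_fixation_object") {
    toggles <- states == 2L
    objects[, -1L] <- 1L + (t(apply(toggles, 1L, cumsum)) %% 2L)
  } else {
    objects[, 1L] <- NA_integer_  # background, no putative object
    if (n_steps >= 2L) {
      toggles <- states[, -1L, drop = FALSE] == 2L
      cum <- t(apply(toggles, 1L, cumsum))
      objects[, -(1:2)] <- 1L + (cum %% 2L)
    }
  }
  objects
}

# Derive simulated fixation labels and saccade types for a matrix of state
# sequences. Returns labels (integer: 0 background, otherwise object id) and
# types (integer codes into SACCADE_TYPES).
flip_and_classify_matrix <- function(states, params) {
  n <- nrow(states)
  n_fix <- ncol(states) + 1L
  objects <- putative_objects_matrix(states, params$initial_condition)
  flip <- matrix(stats::runif(n * n_fix) < params$p_bg, nrow = n)
  if (params$initial_condition == "first_fixation_object") {
    flip[, 1L] <- FALSE  # first fixation protected
  } else {
    flip[, 1L] <- TRUE   # first fixation forced to background
  }
  labels <- objects
  labels[flip] <- 0L
  prev <- labels[, -n_fix, drop = FALSE]
  nxt <- labels[, -1L, drop = FALSE]
  types <- matrix(NA_integer_, nrow = n, ncol = n_fix - 1L)
  types[prev > 0L & nxt > 0L & prev == nxt] <- 1L
  types[prev > 0L & nxt > 0L & prev != nxt] <- 2L
  types[prev > 0L & nxt == 0L] <- 3L
  types[prev == 0L & nxt > 0L] <- 4L
  types[prev == 0L & nxt == 0L] <- 5L
  list(labels = labels, types = types)
}

#' Derive fixation labels and saccade types from a state sequence
#'
#' Maps a sequence of generation states onto the two-object world: an
#' intra-state keeps the current object, a trans-state moves to the other
#' one. Each fixation is then independently flipped to a background fixation
#' with probability `p_bg` (the first fixation is protected under an object
#' start and forced to background under a background start), and saccade
#' types are re-derived from the flipped sequence exactly as empirical
#' saccades are classified.
#'
#' @param states A `state_sequence` from [simulate_state_sequence()].
#' @param params A [model_params()] object; `length(states$state)` must equal
#'   `params$n_fix - 1`.
#' @param seed Optional integer seed for the flips.
#' @return List with `putative_labels` (object ids before flipping; `NA` for
#'   the forced initial background fixation), `fixation_labels` (0 =
#'   background, otherwise object id) and `saccade_types` (factor with the
#'   five type levels).
#' @export
states_to_fixation_sequence <- function(states, params, seed = NULL) {
  n_steps <- length(states$state)
  if (n_steps != params$n_fix - 1L) {
    stop("state sequence length must equal n_fix - 1")
  }
  if (!is.null(seed)) set.seed(seed)
  smat <- matrix(match(states$state, c("intra", "trans")), nrow = 1L)
  res <- flip_and_classify_matrix(smat, params)
  putative <- putative_objects_matrix(smat, params$initial_condition)
  list(putative_labels = putative[1L, ],
       fixation_labels = res$labels[1L, ],
       saccade_types = factor(SACCADE_TYPES[res$types[1L, ]],
                              levels = SACCADE_TYPES))
}

#' Simulate many trials of the generative model
#'
#' Vectorised simulation of `n_trials` trials of `params$n_fix` fixations
#' each; the workhorse behind [simulate_ratio_curves()] and the synthetic
#' suite.
#'
#' @param params A [model_params()] object.
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @return List with `states` (`n_trials` x `n_fix - 1` integer matrix,
#'   1 = intra, 2 = trans), `switch_step` (integer vector, `NA` = no switch
#'   within the trial), `fixation_labels` (`n_trials` x `n_fix`; 0 =
#'   background) and `saccade_types` (`n_trials` x `n_fix - 1` integer codes
#'   into the five types, level order intra, trans, object-to-background,
#'   background-to-object, background-to-background).
#' @export
simulate_trials <- function(params, n_trials, seed = NULL) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_states_matrix(params, params$n_fix - 1L, n_trials)
  fc <- flip_and_classify_matrix(sim$states, params)
  list(states = sim$states, switch_step = sim$switch_step,
       fixation_labels = fc$labels, saccade_types = fc$types)
}

#' Monte Carlo saccade-type ratio curves
#'
#' Empirical per-order frequencies of the five saccade types over simulated
#' trials; converges to [expected_ratio_curves()] as `n_trials` grows.
#'
#' @inheritParams simulate_trials
#' @return A `ratio_curves` matrix (`n_fix - 1` rows, 5 type columns) with
#'   attribute `n_at_order` (here `n_trials` at every order).
#' @export
simulate_ratio_curves <- function(params, n_trials, seed = NULL) {
  sim <- simulate_trials(params, n_trials, seed)
  n_ord <- ncol(sim$saccade_types)
  r <- t(vapply(seq_len(n_ord), function(i) {
    tabulate(sim$saccade_types[, i], nbins = 5L) / n_trials
  }, numeric(5L)))
  ratio_curves(r, n_at_order = rep(n_trials, n_ord))
}

# Construct a ratio_curves object: orders x 5 matrix with type columns.
ratio_curves <- function(r, n_at_order) {
  r <- as.matrix(r)
  colnames(r) <- SACCADE_TYPES
  rownames(r) <- NULL
  structure(r, n_at_order = as.integer(n_at_order),
            class = c("ratio_curves", "matrix", "array"))
}

#' @export
print.ratio_curves <- function(x, ...) {
  cat(sprintf("Saccade-type ratio curves over %d saccade orders\n", nrow(x)))
  m <- unclass(x)
  attr(m, "n_at_order") <- NULL
  print(round(m, 4L), ...)
  invisible(x)
}

# Per-order flip probabilities of the n_fix fixations.
flip_probabilities <- function(params) {
  bbar <- rep(params$p_bg, params$n_fix)
  bbar[1L] <- if (params$initial_condition == "first_fixation_object") 0 else 1
  bbar
}

# Per-order probability that the generation state is the intra-state,
# propagating the joint (mode, state) distribution.
putative_intra_curve <- function(params, n_steps) {
  pi0 <- initial_state_distribution(params)
  d <- c(ei = pi0[["intra"]], et = pi0[["trans"]], li = 0, lt = 0)
  s <- numeric(n_steps)
  s[1L] <- d[["ei"]] + d[["li"]]
  p <- params
  if (n_steps >= 2L) {
    for (j in 2:n_steps) {
      ei <- (1 - p$p_sw) * (d[["ei"]] * p$p_intra_e +
                              d[["et"]] * (1 - p$p_trans_e))
      et <- (1 - p$p_sw) * (d[["et"]] * p$p_trans_e +
                              d[["ei"]] * (1 - p$p_intra_e))
      li <- d[["li"]] * p$p_intra_l + d[["lt"]] * (1 - p$p_trans_l) +
        p$p_sw * (d[["ei"]] * p$p_intra_l + d[["et"]] * (1 - p$p_trans_l))
      lt <- d[["lt"]] * p$p_trans_l + d[["li"]] * (1 - p$p_intra_l) +
        p$p_sw * (d[["et"]] * p$p_trans_l + d[["ei"]] * (1 - p$p_intra_l))
      d <- c(ei = ei, et = et, li = li, lt = lt)
      s[j] <- ei + li
    }
  }
  s
}

#' Exact expected saccade-type ratio curves
#'
#' Closed-form expectation of the per-order type probabilities: the joint
#' (mode, state) distribution is propagated step by step, and the putative
#' intra/trans probability at each order is combined with the independent
#' background-flip indicators of the flanking fixations. Writing `b_i` for
#' the flip probability of fixation `i` and `c_i = 1 - b_i`:
#' `P(intra_i) = P(state_i = intra) c_i c_{i+1}`,
#' `P(trans_i) = P(state_i = trans) c_i c_{i+1}`,
#' `P(obj->bg) = c_i b_{i+1}`, `P(bg->obj) = b_i c_{i+1}`,
#' `P(bg->bg) = b_i b_{i+1}`.
#'
#' @param params A [model_params()] object.
#' @return A `ratio_curves` matrix with `n_fix - 1` rows whose rows each sum
#'   to 1 exactly.
#' @export
expected_ratio_curves <- function(params) {
  n_ord <- params$n_fix - 1L
  s <- putative_intra_curve(params, n_ord)
  bbar <- flip_probabilities(params)
  b_i <- bbar[seq_len(n_ord)]
  b_n <- bbar[seq_len(n_ord) + 1L]
  c_i <- 1 - b_i
  c_n <- 1 - b_n
  q <- cbind(s * c_i * c_n, (1 - s) * c_i * c_n,
             c_i * b_n, b_i * c_n, b_i * b_n)
  ratio_curves(q, n_at_order = rep(NA_integer_, n_ord))
}
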