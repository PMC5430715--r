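# The two-mode Markov chain: initial distribution, switch dynamics,
# fixation-sequence derivation and the exact expected curves.

test_that("initial state distribution follows the stationary formula", {
  p <- model_params(0.2, 0.1, 0.9, 0.5, 0.5, 0.2, n_fix = 5)
  expect_equal(initial_state_distribution(p),
               c(intra = 0.1, trans = 0.9))

  p_sym <- model_params(0.2, 0.7, 0.7, 0.5, 0.5, 0.2, n_fix = 5)
  expect_equal(initial_state_distribution(p_sym),
               c(intra = 0.5, trans = 0.5))

  p_edge <- model_params(0.2, 0.0, 1.0, 0.5, 0.5, 0.2, n_fix = 5)
  expect_equal(initial_state_distribution(p_edge),
               c(intra = 0.0, trans = 1.0))

  p_deg <- model_params(0.2, 1.0, 1.0, 0.5, 0.5, 0.2, n_fix = 5)
  expect_error(initial_state_distribution(p_deg), "degenerate")
})

test_that("expected switch time is the geometric mean 1/p_sw", {
  expect_equal(expected_switch_step(0.2), 5)
  expect_equal(expected_switch_step(1.0), 1)
  expect_equal(expected_switch_step(0.1), 10)
  expect_identical(expected_switch_step(0), Inf)
  expect_error(expected_switch_step(1.5), "probability")
})

test_that("switch dynamics: one-way, first opportunity at step 2", {
  p0 <- model_params(0, 0.6, 0.7, 0.8, 0.3, 0.2, n_fix = 11)
  s0 <- simulate_state_sequence(p0, 10, seed = 1)
  expect_true(all(s0$mode == "early"))
  expect_true(is.na(s0$switch_step))

  p1 <- model_params(1, 0.6, 0.7, 0.8, 0.3, 0.2, n_fix = 11)
  for (seed in 1:5) {
    s1 <- simulate_state_sequence(p1, 10, seed = seed)
    expect_identical(s1$switch_step, 2L)
  }

  # irreversibility over many sequences
  p <- model_params(0.3, 0.6, 0.7, 0.8, 0.3, 0.2, n_fix = 16)
  sim <- simulate_trials(p, 2000, seed = 4)
  set.seed(4)
  msim <- gazemodes:::simulate_states_matrix(p, 15, 2000)
  runs <- apply(msim$modes, 1L, function(m) length(rle(m)$lengths))
  expect_true(all(runs <= 2L))  # early block then late block, never back
})

test_that("mean saccades before the switch matches 1/p_sw", {
  for (p_sw in c(0.1, 0.2, 0.5)) {
    p <- model_params(p_sw, 0.6, 0.7, 0.8, 0.3, 0.2, n_fix = 121)
    sim <- simulate_trials(p, 20000, seed = round(1000 * p_sw))
    m <- mean(sim$switch_step - 1, na.rm = TRUE)
    se <- sqrt((1 - p_sw) / p_sw^2 / sum(!is.na(sim$switch_step)))
    expect_lt(abs(m - 1 / p_sw), 4 * se + 0.01)
  }
})

test_that("fixation sequences follow the two-object rules and the flips", {
  mk_states <- function(v) {
    structure(list(state = v, mode = rep("early", length(v)),
                   switch_step = NA_integer_), class = "state_sequence")
  }
  p_obj <- model_params(0, 1, 1, 1, 1, p_bg = 0, n_fix = 6)
  all_intra <- mk_states(rep("intra", 5))
  fs <- states_to_fixation_sequence(all_intra, p_obj, seed = 1)
  expect_equal(fs$fixation_labels, rep(1L, 6))
  expect_true(all(fs$saccade_types == "intra_object"))

  all_trans <- mk_states(rep("trans", 5))
  fs2 <- states_to_fixation_sequence(all_trans, p_obj, seed = 1)
  expect_equal(fs2$fixation_labels, rep(c(1L, 2L), 3))
  expect_true(all(fs2$saccade_types == "trans_object"))

  p_flip <- model_params(0, 1, 1, 1, 1, p_bg = 1, n_fix = 6)
  fs3 <- states_to_fixation_sequence(all_trans, p_flip, seed = 1)
  expect_equal(as.character(fs3$saccade_types),
               c("object_to_background",
                 rep("background_to_background", 4)))

  expect_error(states_to_fixation_sequence(mk_states(rep("intra", 3)),
                                           p_obj), "n_fix - 1")
})

test_that("background-start trials begin with background-involving types", {
  p <- background_start_params()
  sim <- simulate_trials(p, 500, seed = 9)
  first <- sim$saccade_types[, 1L]
  expect_true(all(first %in% c(4L, 5L)))  # bg->obj or bg->bg only
})

test_that("exact expected curves are probability vectors and match the
           pinned-chain and flip-algebra hand cases", {
  p <- model_params(0.3, 0.4, 0.6, 0.9, 0.2, p_bg = 0.15, n_fix = 12)
  q <- expected_ratio_curves(p)
  expect_equal(rowSums(unclass(q)), rep(1, 11), tolerance = 1e-12)

  # chain pinned to the trans state
  p_pin <- model_params(0, 0, 1, 1, 1, p_bg = 0, n_fix = 8)
  q_pin <- unclass(expected_ratio_curves(p_pin))
  expect_equal(q_pin, matrix(rep(c(0, 1, 0, 0, 0), each = 7), ncol = 5),
               ignore_attr = TRUE)

  # flip algebra at order 1 with a protected first fixation
  p_flip <- model_params(0.2, 0.5, 0.5, 0.5, 0.5, p_bg = 0.2, n_fix = 6)
  q1 <- unclass(expected_ratio_curves(p_flip))[1L, ]
  expect_equal(unname(q1[3L]), 0.2)            # object -> background
  expect_equal(unname(q1[4L] + q1[5L]), 0)     # background -> * impossible
})

test_that("exact expected curves agree with exhaustive enumeration", {
  set.seed(11)
  for (rep in 1:3) {
    p <- model_params(runif(1), runif(1), runif(1), runif(1), runif(1),
                      p_bg = runif(1, 0, 0.5), n_fix = 4,
                      initial_condition = sample(
                        c("first_fixation_object",
                          "first_fixation_background"), 1))
    q <- unclass(expected_ratio_curves(p))
    q_brute <- brute_expected_curves(p)
    expect_equal(q, q_brute, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("with p_sw = 1 the curves equal a pure late-mode chain started
           from the early-mode initial distribution", {
  p <- model_params(1, 0.3, 0.8, 0.9, 0.2, p_bg = 0.1, n_fix = 10)
  q <- unclass(expected_ratio_curves(p))
  # independent re-derivation: two-state late chain, early-mode start
  s <- numeric(9)
  s[1] <- (1 - p$p_trans_e) / (2 - p$p_intra_e - p$p_trans_e)
  for (j in 2:9) {
    s[j] <- s[j - 1] * p$p_intra_l + (1 - s[j - 1]) * (1 - p$p_trans_l)
  }
  b <- c(0, rep(p$p_bg, 9))
  ci <- 1 - b[1:9]; cn <- 1 - rep(p$p_bg, 9)
  expect_equal(q[, 1], s * ci * cn, tolerance = 1e-12)
  expect_equal(q[, 2], (1 - s) * ci * cn, tolerance = 1e-12)
})

test_that("Monte Carlo ratio curves converge to the exact expectation", {
  p <- model_params(0.25, 0.2, 0.7, 0.85, 0.4, p_bg = 0.2, n_fix = 16)
  q <- unclass(expected_ratio_curves(p))
  gaps <- vapply(c(1e3, 1e4), function(n) {
    mc <- unclass(simulate_ratio_curves(p, n, seed = 123))
    max(abs(mc - q))
  }, numeric(1))
  expect_lt(gaps[2], gaps[1])          # shrinking Monte Carlo error
  expect_lt(gaps[2], 0.03)
})

test_that("crossover of intra and trans ratios comes earlier for larger
           p_sw", {
  base <- function(p_sw) {
    model_params(p_sw, 0.1, 0.9, 0.6, 0.4, p_bg = 0.2, n_fix = 21)
  }
  crossover <- function(q) which(q[, 1] > q[, 2])[1L]
  c_fast <- crossover(unclass(expected_ratio_curves(base(0.5))))
  c_slow <- crossover(unclass(expected_ratio_curves(base(0.1))))
  expect_lt(c_fast, c_slow)
})

test_that("simulation is reproducible under a fixed seed", {
  p <- object_start_params()
  a <- simulate_trials(p, 50, seed = 77)
  b <- simulate_trials(p, 50, seed = 77)
  expect_identical(a, b)
})
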