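# GoF measure, grid search, AIC comparison and switch-posterior inference.

test_that("the GoF measure follows the inverse-mean-deviation formula", {
  p <- object_start_params(n_fix = 3L)
  q <- expected_ratio_curves(p)
  expect_identical(goodness_of_fit(q, q, 3), Inf)

  # deviations with L1 norms (1, 0) over two orders -> GoF = 2
  r_emp <- ratio_curves(rbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0)), c(1, 1))
  r_sim <- ratio_curves(rbind(c(0.5, 0.5, 0, 0, 0), c(0, 1, 0, 0, 0)),
                        c(NA, NA))
  expect_equal(goodness_of_fit(r_emp, r_sim, 3), 2.0)

  # homogeneity: scaling deviations by c divides the GoF by c
  r_half <- ratio_curves(rbind(c(0.75, 0.25, 0, 0, 0), c(0, 1, 0, 0, 0)),
                         c(1, 1))
  expect_equal(goodness_of_fit(r_half, r_sim, 3),
               2 * goodness_of_fit(r_emp, r_sim, 3))

  expect_error(goodness_of_fit(r_emp, r_sim, 5), "orders")
  expect_error(grid_search_fit(r_emp, 0.2, 3, grid_step = 0.03), "evenly")
})

test_that("the grid kernel matches the exact curves computed in R", {
  # dual route: C++ grid deviation vs deviation from expected_ratio_curves
  set.seed(13)
  g <- seq(0, 1, by = 0.05)
  emp <- unclass(simulate_ratio_curves(object_start_params(), 500, seed = 14))
  bbar <- c(0, rep(0.23, 20))
  dev <- gazemodes:::grid_mean_dev(emp, bbar, g, 1L)
  dim(dev) <- rep(21L, 5L)
  for (rep in 1:10) {
    idx <- sample(21, 5, replace = TRUE)
    p <- model_params(g[idx[1]], g[idx[2]], g[idx[3]], g[idx[4]], g[idx[5]],
                      p_bg = 0.23, n_fix = 21)
    q <- tryCatch(unclass(expected_ratio_curves(p)), error = function(e) NULL)
    if (is.null(q)) next  # degenerate early mode, R route refuses
    d_r <- mean(rowSums(abs(emp - q)))
    expect_equal(dev[idx[1], idx[2], idx[3], idx[4], idx[5]], d_r,
                 tolerance = 1e-12)
  }
})

test_that("self-consistent curves are recovered exactly with infinite GoF", {
  p_true <- model_params(0.25, 0.10, 0.85, 0.90, 0.40, p_bg = 0.2,
                         n_fix = 16)
  r_emp <- expected_ratio_curves(p_true)
  attr(r_emp, "n_at_order") <- rep(1000L, 15L)
  fit <- grid_search_fit(r_emp, 0.2, 16)
  bp <- fit$best_params
  expect_equal(c(bp$p_sw, bp$p_intra_e, bp$p_trans_e, bp$p_intra_l,
                 bp$p_trans_l), c(0.25, 0.10, 0.85, 0.90, 0.40))
  expect_identical(fit$gof, Inf)
  expect_equal(fit$gof_profile$gof[fit$gof_profile$p_sw == 0.25], Inf)
})

test_that("pure late-mode data put the profile maximum at p_sw = 1", {
  p1 <- model_params(1, 0.3, 0.8, 0.85, 0.45, p_bg = 0.2, n_fix = 16)
  sim <- simulate_ratio_curves(p1, 20000, seed = 15)
  fit <- grid_search_fit(sim, 0.2, 16)
  expect_equal(fit$best_params$p_sw, 1.0)
})

test_that("the GoF profile drops sharply at p_sw = 0 on switching data", {
  sim <- simulate_trials(object_start_params(), 5000, seed = 16)
  r <- saccade_type_ratios_by_order(sim$saccade_types, 20)
  fit <- grid_search_fit(r, 0.23, 21)
  pr <- fit$gof_profile
  expect_equal(fit$best_params$p_sw, 0.20)
  expect_lt(pr$gof[pr$p_sw == 0], 0.35 * max(pr$gof))
})

test_that("the late-mode plane is high only below the diagonal for focal
           late dynamics", {
  sim <- simulate_trials(object_start_params(), 5000, seed = 17)
  r <- saccade_type_ratios_by_order(sim$saccade_types, 20)
  fit <- grid_search_fit(r, 0.23, 21)
  plane <- fit$gof_plane_late
  g <- as.numeric(rownames(plane))
  above <- plane[outer(g, g, function(a, b) a < b)]   # p_intra^L < p_trans^L
  below <- plane[outer(g, g, function(a, b) a > b)]
  expect_gt(max(below), 2 * max(above))
})

test_that("parameter recovery at the object-start printed vector", {
  for (seed in 1:3) {
    sim <- simulate_trials(object_start_params(), 10000, seed = 100 + seed)
    r <- saccade_type_ratios_by_order(sim$saccade_types, 20)
    fit <- grid_search_fit(r, 0.23, 21)
    bp <- fit$best_params
    expect_equal(c(bp$p_sw, bp$p_intra_e, bp$p_trans_e, bp$p_intra_l,
                   bp$p_trans_l), c(0.20, 0.00, 1.00, 0.90, 0.55))
  }
})

test_that("sequence log-likelihood: hand cases and additivity", {
  p <- model_params(0.5, 0.5, 0.5, 0.5, 0.5, p_bg = 0, n_fix = 3)
  # with no flips and a symmetric chain, q_1 = (0.5, 0.5, 0, 0, 0)
  one <- matrix(1L, 1, 1)
  expect_equal(sequence_log_likelihood(one, p), log(0.5))

  # deterministic chain matching the data exactly: log-likelihood 0
  p_det <- model_params(0, 0, 1, 1, 1, p_bg = 0, n_fix = 4)
  tr <- matrix(2L, 1, 3)
  expect_equal(sequence_log_likelihood(tr, p_det), 0)

  # additivity over identical trials
  p2 <- object_start_params()
  sim <- simulate_trials(p2, 1, seed = 18)
  single <- sequence_log_likelihood(sim$saccade_types, p2)
  five <- sequence_log_likelihood(
    sim$saccade_types[rep(1, 5), , drop = FALSE], p2)
  expect_equal(five, 5 * single)

  # impossible observation reports -Inf
  expect_identical(sequence_log_likelihood(matrix(3L, 1, 1), p_det), -Inf)
  expect_error(sequence_log_likelihood(matrix(1L, 0, 0), p_det), "no trials")
})

test_that("AIC prefers the generating model class", {
  # switching data
  simH <- simulate_trials(object_start_params(), 2000, seed = 19)
  rH <- saccade_type_ratios_by_order(simH$saccade_types, 20)
  fs <- grid_search_fit(rH, 0.23, 21)
  fn <- grid_search_fit(rH, 0.23, 21, switch_model = FALSE)
  cmp <- aic_compare(simH$saccade_types, fs, fn)
  expect_true(cmp$preferred[cmp$model == "switch"])
  expect_equal(cmp$k, c(5L, 2L))
  expect_equal(cmp$aic, 2 * cmp$k - 2 * cmp$log_likelihood)

  # stationary data: the 6-point parameter penalty decides
  p0 <- model_params(0, 0.6, 0.4, 0.6, 0.4, p_bg = 0.23, n_fix = 21)
  sim0 <- simulate_trials(p0, 2000, seed = 20)
  r0 <- saccade_type_ratios_by_order(sim0$saccade_types, 20)
  cmp0 <- aic_compare(sim0$saccade_types,
                      grid_search_fit(r0, 0.23, 21),
                      grid_search_fit(r0, 0.23, 21, switch_model = FALSE))
  expect_true(cmp0$preferred[cmp0$model == "no_switch"])

  expect_error(aic_compare(sim0$saccade_types, fn, fs), "switch fit first")
})

test_that("switch-posterior forward pass equals brute-force enumeration", {
  p <- model_params(0.3, 0.7, 0.6, 0.9, 0.2, p_bg = 0.25, n_fix = 6)
  types <- c(2L, 3L, 4L, 1L, 1L)
  for (s in c(2:5, Inf)) {
    expect_equal(gazemodes:::forward_sequence_probability(types, p, s),
                 brute_sequence_probability(types, p, s),
                 tolerance = 1e-12)
  }
})

test_that("switch-posterior: MAP step, normalisation and degenerate cases", {
  # deterministic chain: trans,trans then intra forever pins the switch
  pd <- model_params(0.2, 0, 1, 1, 0, p_bg = 0, n_fix = 6)
  post <- infer_switch_posterior(
    c("trans_object", "trans_object", "intra_object", "intra_object",
      "intra_object"), pd)
  expect_equal(attr(post, "map_step"), 3)
  expect_equal(sum(post$posterior), 1)

  # early == late: posterior equals the (truncated) geometric prior
  pe <- model_params(0.3, 0.6, 0.4, 0.6, 0.4, p_bg = 0.2, n_fix = 6)
  sim <- simulate_trials(pe, 1, seed = 2)
  post2 <- infer_switch_posterior(
    gazemodes:::SACCADE_TYPES[sim$saccade_types[1, ]], pe)
  expect_equal(post2$posterior, post2$prior, tolerance = 1e-12)

  # normalisation over random parameter draws
  set.seed(23)
  for (i in 1:25) {
    p <- model_params(runif(1, 0.05, 0.95), runif(1), runif(1), runif(1),
                      runif(1), p_bg = runif(1, 0.05, 0.5), n_fix = 8)
    sim <- simulate_trials(p, 1)
    post <- infer_switch_posterior(
      gazemodes:::SACCADE_TYPES[sim$saccade_types[1, ]], p)
    expect_equal(sum(post$posterior), 1, tolerance = 1e-9)
  }

  # model inconsistent with the observation
  p0 <- model_params(0.2, 0.5, 0.5, 0.5, 0.5, p_bg = 0, n_fix = 4)
  expect_error(infer_switch_posterior(
    c("intra_object", "object_to_background", "background_to_object"), p0),
    "zero probability")
})
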