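# Goodness-of-fit, exhaustive grid search, AIC model comparison and
# single-trial switch-time inference.

# Deviation between two curves under the configured norm; both are
# (n_ord x 5) matrices.
curve_deviation <- function(r_emp, r_sim, norm = c("L1", "L2")) {
  norm <- match.arg(norm)
  d <- r_emp - r_sim
  per_order <- if (norm == "L1") rowSums(abs(d)) else sqrt(rowSums(d^2))
  mean(per_order)
}

#' Goodness of fit between empirical and model type-ratio curves
#'
#' The inverse of the mean (over saccade orders 1 ... `n_fix - 1`) norm of
#' the difference between the empirical 5-vector of saccade-type ratios and
#' the model's expected 5-vector at each order. Larger is better; perfect
#' agreement returns `Inf`.
#'
#' @param r_emp Empirical `ratio_curves` (from
#'   [saccade_type_ratios_by_order()]).
#' @param r_sim Model curves (from [expected_ratio_curves()] or
#'   [simulate_ratio_curves()]).
#' @param n_fix Fixations per trial; both curves must cover orders
#'   1 ... `n_fix - 1`.
#' @param norm `"L1"` (default) or `"L2"` norm over the 5 components.
#' @return The scalar GoF value (dimensionless, `>= 0`, possibly `Inf`).
#' @export
goodness_of_fit <- function(r_emp, r_sim, n_fix, norm = c("L1", "L2")) {
  n_ord <- n_fix - 1L
  if (nrow(r_emp) < n_ord || nrow(r_sim) < n_ord) {
    stop("curves must be defined for orders 1 ... n_fix - 1")
  }
  r_emp <- r_emp[seq_len(n_ord), , drop = FALSE]
  r_sim <- r_sim[seq_len(n_ord), , drop = FALSE]
  if (anyNA(r_emp)) stop("empirical curves contain undefined orders")
  1 / curve_deviation(r_emp, r_sim, norm)
}

grid_values <- function(grid_step) {
  n <- 1 / grid_step
  if (abs(n - round(n)) > 1e-9) stop("grid_step must divide 1 evenly")
  seq(0, 1, length.out = round(n) + 1L)
}

#' Exhaustive grid-search fit of the two-mode model
#'
#' Evaluates the GoF over all combinations of
#' `(p_sw, p_intra_e, p_trans_e, p_intra_l, p_trans_l)` on a regular grid
#' (step 0.05 by default, hence 21^5 combinations) with the background-flip
#' probability held fixed at its empirical value, using the exact expected
#' ratio curves so the arg-max is deterministic given the data. Ties are
#' broken lexicographically (smallest `p_sw` first, then the remaining
#' parameters in the listed order) and reported. With
#' `switch_model = FALSE` the model has no switch (`p_sw = 0`): one mode
#' governs the whole trial and only its two stay probabilities are free.
#'
#' @param r_emp Empirical `ratio_curves` covering orders 1 ... `n_fix - 1`.
#' @param p_bg_fixed Background-flip probability, pre-set to the empirical
#'   proportion of background fixations.
#' @param n_fix Fixations per trial.
#' @param initial_condition As in [model_params()].
#' @param grid_step Grid resolution; must divide 1 evenly.
#' @param norm GoF norm, `"L1"` (default) or `"L2"`.
#' @param switch_model Fit the full switching model (`TRUE`) or the
#'   no-switch variant (`FALSE`).
#' @return An object of class `fit_result`: list with `best_params`
#'   ([model_params()]), `gof`, `gof_profile` (data.frame `p_sw` vs maximal
#'   GoF at that `p_sw`; switch model only), `gof_plane_early` and
#'   `gof_plane_late` (GoF matrices over the stay-probability planes with
#'   the other parameters at their best values), `k_effective` (5 or 2),
#'   `n_ties` and `norm`.
#' @export
grid_search_fit <- function(r_emp, p_bg_fixed, n_fix,
                            initial_condition = c("first_fixation_object",
                                                  "first_fixation_background"),
                            grid_step = 0.05, norm = c("L1", "L2"),
                            switch_model = TRUE) {
  initial_condition <- match.arg(initial_condition)
  norm <- match.arg(norm)
  n_ord <- n_fix - 1L
  if (nrow(r_emp) < n_ord) stop("r_emp must cover orders 1 ... n_fix - 1")
  emp <- unclass(r_emp)[seq_len(n_ord), , drop = FALSE]
  attr(emp, "n_at_order") <- NULL
  if (anyNA(emp)) stop("empirical curves contain undefined orders")
  g <- grid_values(grid_step)
  G <- length(g)
  bbar <- rep(p_bg_fixed, n_fix)
  bbar[1L] <- if (initial_condition == "first_fixation_object") 0 else 1

  if (!switch_model) {
    return(grid_search_noswitch(emp, p_bg_fixed, n_fix, initial_condition,
                                g, norm, bbar))
  }

  dev <- grid_mean_dev(emp, bbar, g, if (norm == "L1") 1L else 2L)
  dev[dev < 1e-12] <- 0  # below numerical noise: perfect agreement
  dim(dev) <- rep(G, 5L)
  min_dev <- min(dev)
  ties <- which(dev == min_dev)
  tie_idx <- arrayInd(ties, dim(dev))
  ord <- do.call(order, as.data.frame(tie_idx))
  best <- tie_idx[ord[1L], ]
  best_params <- model_params(
    p_sw = g[best[1L]], p_intra_e = g[best[2L]], p_trans_e = g[best[3L]],
    p_intra_l = g[best[4L]], p_trans_l = g[best[5L]],
    p_bg = p_bg_fixed, n_fix = n_fix, initial_condition = initial_condition)
  profile <- data.frame(
    p_sw = g,
    gof = 1 / apply(matrix(dev, nrow = G), 1L, min))
  plane_early <- 1 / dev[best[1L], , , best[4L], best[5L]]
  plane_late <- 1 / dev[best[1L], best[2L], best[3L], , ]
  dimnames(plane_early) <- list(p_intra_e = g, p_trans_e = g)
  dimnames(plane_late) <- list(p_intra_l = g, p_trans_l = g)
  structure(list(best_params = best_params, gof = 1 / min_dev,
                 gof_profile = profile, gof_plane_early = plane_early,
                 gof_plane_late = plane_late, k_effective = 5L,
                 n_ties = length(ties), norm = norm,
                 switch_model = TRUE),
            class = "fit_result")
}

# No-switch variant: a single mode governs the whole trial; grid over its
# two stay probabilities. Pure R: the putative intra-curve of a two-state
# chain started from its own stationary distribution.
grid_search_noswitch <- function(emp, p_bg_fixed, n_fix, initial_condition,
                                 g, norm, bbar) {
  n_ord <- n_fix - 1L
  G <- length(g)
  c_i <- (1 - bbar[seq_len(n_ord)])
  c_n <- (1 - bbar[seq_len(n_ord) + 1L])
  cc <- c_i * c_n
  dconst <- abs(c_i * bbar[seq_len(n_ord) + 1L] - emp[, 3L]) +
    abs(bbar[seq_len(n_ord)] * c_n - emp[, 4L]) +
    abs(bbar[seq_len(n_ord)] * bbar[seq_len(n_ord) + 1L] - emp[, 5L])
  dconst2 <- (c_i * bbar[seq_len(n_ord) + 1L] - emp[, 3L])^2 +
    (bbar[seq_len(n_ord)] * c_n - emp[, 4L])^2 +
    (bbar[seq_len(n_ord)] * bbar[seq_len(n_ord) + 1L] - emp[, 5L])^2
  dev <- matrix(NA_real_, nrow = G, ncol = G,
                dimnames = list(p_intra = g, p_trans = g))
  for (a in seq_len(G)) {
    for (b in seq_len(G)) {
      p_i <- g[a]; p_t <- g[b]
      den <- 2 - p_i - p_t
      s <- numeric(n_ord)
      s[1L] <- if (den > 0) (1 - p_t) / den else 0.5
      if (n_ord >= 2L) {
        for (j in 2:n_ord) s[j] <- s[j - 1L] * p_i + (1 - s[j - 1L]) * (1 - p_t)
      }
      d1 <- s * cc - emp[, 1L]
      d2 <- (1 - s) * cc - emp[, 2L]
      per_order <- if (norm == "L1") abs(d1) + abs(d2) + dconst else
        sqrt(d1^2 + d2^2 + dconst2)
      dev[a, b] <- mean(per_order)
    }
  }
  dev[dev < 1e-12] <- 0
  min_dev <- min(dev)
  ties <- which(dev == min_dev)
  tie_idx <- arrayInd(ties, dim(dev))
  ord <- do.call(order, as.data.frame(tie_idx))
  best <- tie_idx[ord[1L], ]
  best_params <- model_params(
    p_sw = 0, p_intra_e = g[best[1L]], p_trans_e = g[best[2L]],
    p_intra_l = g[best[1L]], p_trans_l = g[best[2L]],
    p_bg = p_bg_fixed, n_fix = n_fix, initial_condition = initial_condition)
  structure(list(best_params = best_params, gof = 1 / min_dev,
                 gof_profile = NULL, gof_plane_early = 1 / dev,
                 gof_plane_late = NULL, k_effective = 2L,
                 n_ties = length(ties), norm = norm,
                 switch_model = FALSE),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$best_params
  cat(sprintf("Grid-search fit (%s model, %s norm)\n",
              if (x$switch_model) "switch" else "no-switch", x$norm))
  cat(sprintf("  best: p_sw=%.2f (p_intra^E,p_trans^E)=(%.2f,%.2f) ",
              p$p_sw, p$p_intra_e, p$p_trans_e))
  cat(sprintf("(p_intra^L,p_trans^L)=(%.2f,%.2f)\n", p$p_intra_l, p$p_trans_l))
  cat(sprintf("  GoF = %s, effective parameters = %d%s\n",
              format(x$gof, digits = 5L), x$k_effective,
              if (x$n_ties > 1L)
                sprintf(" (%d tied grid points, lexicographic tie-break)",
                        x$n_ties) else ""))
  invisible(x)
}

#' Log-likelihood of observed saccade-type sequences under the model
#'
#' Independent-across-orders marginal likelihood: the log probability of
#' each trial's i-th saccade type under the model's expected type
#' distribution at order i, summed over saccades and trials. An observed
#' type with zero model probability contributes `-Inf`.
#'
#' @param trials As in [saccade_type_ratios_by_order()].
#' @param params A [model_params()] object.
#' @return Total log-likelihood in nats.
#' @export
sequence_log_likelihood <- function(trials, params) {
  seqs <- as_type_sequences(trials)
  if (!length(seqs)) stop("no trials supplied")
  q <- unclass(expected_ratio_curves(params))
  ll <- 0
  for (s in seqs) {
    if (!length(s)) next
    if (length(s) > nrow(q)) {
      stop("trial has more saccades than n_fix - 1")
    }
    pr <- q[cbind(seq_along(s), s)]
    ll <- ll + sum(log(pr))
  }
  ll
}

#' Compare switch and no-switch models by AIC
#'
#' `AIC = 2k - 2 ln L` with `k = 5` effective parameters for the switching
#' model and `k = 2` for the no-switch model (`p_sw` fixed at 0 leaves a
#' single mode whose two stay probabilities are free); `p_bg` is excluded
#' in both because it is pre-set to the empirical background proportion.
#'
#' @param trials As in [saccade_type_ratios_by_order()]; the data both fits
#'   were computed on.
#' @param fit_switch,fit_noswitch `fit_result` objects from
#'   [grid_search_fit()] with `switch_model = TRUE` and `FALSE`.
#' @return A data.frame with one row per model: `model`, `k`,
#'   `log_likelihood`, `aic`, `preferred`.
#' @export
aic_compare <- function(trials, fit_switch, fit_noswitch) {
  if (!isTRUE(fit_switch$switch_model) ||
      !isFALSE(fit_noswitch$switch_model)) {
    stop("pass the switch fit first and the no-switch fit second")
  }
  ll_s <- sequence_log_likelihood(trials, fit_switch$best_params)
  ll_n <- sequence_log_likelihood(trials, fit_noswitch$best_params)
  aic_s <- 2 * fit_switch$k_effective - 2 * ll_s
  aic_n <- 2 * fit_noswitch$k_effective - 2 * ll_n
  data.frame(model = c("switch", "no_switch"),
             k = c(fit_switch$k_effective, fit_noswitch$k_effective),
             log_likelihood = c(ll_s, ll_n),
             aic = c(aic_s, aic_n),
             preferred = c(aic_s <= aic_n, aic_n < aic_s))
}

#' Posterior distribution of the switch step for a single trial
#'
#' Bayesian inversion of the generative model for one observed saccade-type
#' sequence: the prior over the switch step s is the geometric switch-time
#' mass (`P(s) = p_sw (1-p_sw)^(s-2)` for s = 2, ..., plus the
#' complementary "no switch within the trial" event), the likelihood is the
#' exact probability of the observed sequence with early-mode dynamics
#' before s and late-mode dynamics from s on, computed by a forward pass
#' over the joint hidden variable (putative state, background-flip status
#' of the current fixation).
#'
#' @param trial_types Character or factor vector of one trial's saccade
#'   types (length <= `n_fix - 1`).
#' @param params A [model_params()] object.
#' @return An object of class `switch_posterior`: data.frame with columns
#'   `switch_step` (2 ... `n_fix - 1` and `NA` for no switch within the
#'   trial), `prior`, `likelihood` and `posterior`; attribute `map_step`
#'   holds the maximum-a-posteriori step.
#' @export
infer_switch_posterior <- function(trial_types, params) {
  types <- if (is.factor(trial_types)) as.integer(trial_types) else
    match(as.character(trial_types), SACCADE_TYPES)
  if (anyNA(types)) stop("unknown saccade type in trial_types")
  k <- length(types)
  if (k > params$n_fix - 1L) stop("trial longer than n_fix - 1 saccades")
  n_fix <- params$n_fix
  steps <- if (n_fix >= 3L) 2:(n_fix - 1L) else integer(0)
  prior <- c(params$p_sw * (1 - params$p_sw)^(steps - 2L),
             (1 - params$p_sw)^(n_fix - 2L))
  lik <- vapply(c(steps, Inf), function(s) {
    forward_sequence_probability(types, params, s)
  }, numeric(1L))
  joint <- prior * lik
  total <- sum(joint)
  if (total <= 0) {
    stop("observed sequence has zero probability under these parameters")
  }
  post <- joint / total
  out <- data.frame(switch_step = c(steps, NA), prior = prior,
                    likelihood = lik, posterior = post)
  map_step <- out$switch_step[which.max(out$posterior)]
  structure(out, map_step = map_step, class = c("switch_posterior",
                                                "data.frame"))
}

#' @export
print.switch_posterior <- function(x, ...) {
  cat("Posterior over the ambient-to-focal switch step\n")
  print(as.data.frame(round(as.matrix(x), 6L)), row.names = FALSE)
  ms <- attr(x, "map_step")
  cat(sprintf("MAP switch step: %s\n",
              if (is.na(ms)) "no switch within trial" else ms))
  invisible(x)
}

# Forward pass: probability of an observed type-code sequence given the
# switch occurs at step switch_at (Inf = never within the trial).
forward_sequence_probability <- function(types, params, switch_at) {
  k <- length(types)
  pi0 <- initial_state_distribution(params)
  b <- flip_probabilities(params)
  # alpha[x, f]: joint mass of (state generating the next saccade = x,
  # flip status f of the current fixation), before emitting that saccade.
  # f = 1: object fixation, f = 2: background fixation.
  alpha <- outer(c(pi0[["intra"]], pi0[["trans"]]),
                 c(1 - b[1L], b[1L]))
  for (i in seq_len(k)) {
    bf <- b[i + 1L]                       # flip prob of fixation i + 1
    fnext <- c(1 - bf, bf)
    y <- types[i]
    # emission: y given (x_i, f_i, f_{i+1})
    new_alpha <- matrix(0, 2L, 2L)
    for (x in 1:2) {
      for (f in 1:2) {
        for (f2 in 1:2) {
          emit <- if (f == 1L && f2 == 1L) {
            as.numeric(y == x)            # intra (1) or trans (2)
          } else if (f == 1L && f2 == 2L) {
            as.numeric(y == 3L)
          } else if (f == 2L && f2 == 1L) {
            as.numeric(y == 4L)
          } else {
            as.numeric(y == 5L)
          }
          if (emit > 0) {
            new_alpha[x, f2] <- new_alpha[x, f2] +
              alpha[x, f] * fnext[f2] * emit
          }
        }
      }
    }
    # propagate the state for the next saccade (if any)
    if (i < k) {
      late <- (i + 1L) >= switch_at
      p_stay <- if (late) c(params$p_intra_l, params$p_trans_l) else
        c(params$p_intra_e, params$p_trans_e)
      trans <- rbind(c(p_stay[1L], 1 - p_stay[1L]),
                     c(1 - p_stay[2L], p_stay[2L]))
      new_alpha <- t(trans) %*% new_alpha
    }
    alpha <- new_alpha
  }
  sum(alpha)
}
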