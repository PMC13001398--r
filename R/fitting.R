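# Per-participant maximum-likelihood fitting of the single learners,
# BIC, and model-comparison summaries.
#
# Optimization contract: derivative-free bound-constrained minimization.
# Parameters are mapped to the real line by a logistic box transform and
# minimized with Nelder-Mead; restarts are drawn uniformly within bounds.

PROB_FLOOR <- 1e-12

#' Parameter bounds used for fitting
#'
#' Learning rates, discounts, trace decay and prior reachability are kept
#' in \[0.01, 0.99\] and the Boltzmann temperature in \[0.005, 5\], so the
#' softmax stays finite and learning non-degenerate.
#'
#' @param model `"mb"` or `"mf"`.
#' @param condition Condition label; the Visual-Haptic MB learner exposes
#'   only `gamma` and `tau`, the haptic/navigation MB learner also
#'   `alpha` and `p0`.
#' @return List with numeric vectors `lower` and `upper`, named by
#'   parameter.
#' @export
param_bounds <- function(model = c("mb", "mf"), condition) {
  model <- match.arg(model)
  condition <- match.arg(condition, CONDITIONS)
  unit <- c(0.01, 0.99)
  tau <- c(0.005, 5)
  if (model == "mb") {
    if (condition == "visual_haptic")
      list(lower = c(gamma = unit[1], tau = tau[1]),
           upper = c(gamma = unit[2], tau = tau[2]))
    else
      list(lower = c(alpha = unit[1], gamma = unit[1], p0 = unit[1],
                     tau = tau[1]),
           upper = c(alpha = unit[2], gamma = unit[2], p0 = unit[2],
                     tau = tau[2]))
  } else {
    list(lower = c(alpha = unit[1], gamma = unit[1], lambda = unit[1],
                   tau = tau[1]),
         upper = c(alpha = unit[2], gamma = unit[2], lambda = unit[2],
                   tau = tau[2]))
  }
}

.to_box <- function(z, lower, upper) lower + (upper - lower) * plogis(z)
.from_box <- function(theta, lower, upper)
  qlogis(pmin(pmax((theta - lower) / (upper - lower), 1e-8), 1 - 1e-8))

#' Negative log-likelihood of a single learner on recorded behaviour
#'
#' One likelihood term per executed step: minus the log-probability the
#' teacher-forced learner assigns to the participant's action among the
#' actions leading to reachable states. Per-step probabilities are
#' floored at 1e-12 before the log; the number of floored steps is
#' attached as an attribute.
#'
#' @param model `"mb"` or `"mf"`.
#' @param params Named parameter list (see [step_probabilities()]).
#' @param steps Single-participant step records.
#' @param mazes Named list of `maze` objects.
#' @param weights Optional per-step weights (used by the EM M-steps).
#' @param ... Passed to [step_probabilities()].
#' @return Negative log-likelihood (attribute `floored`: floored-step
#'   count).
#' @export
nll_single <- function(model, params, steps, mazes, weights = NULL, ...) {
  p <- step_probabilities(model, params, steps, mazes, ...)
  if (is.null(weights)) weights <- rep(1, length(p))
  structure(-sum(weights * log(pmax(p, PROB_FLOOR))),
            floored = sum(p < PROB_FLOOR))
}

.nll_packed <- function(model, params, pk, weights = NULL, ...) {
  p <- .replay_packed(model, params, pk, ...)
  if (is.null(weights)) return(-sum(log(pmax(p, PROB_FLOOR))))
  -sum(weights * log(pmax(p, PROB_FLOOR)))
}

# Core bound-constrained Nelder-Mead over an arbitrary objective in
# parameter space. `starts` is a list of named start vectors.
.optim_box <- function(objective, starts, lower, upper,
                       maxit = 300L, reltol = 1e-8) {
  k <- length(lower)
  runs <- lapply(starts, function(theta0) {
    z0 <- .from_box(theta0[names(lower)], lower, upper)
    fn <- function(z) objective(.to_box(setNames(z, names(lower)),
                                        lower, upper))
    if (k == 1) {
      res <- optim(z0, fn, method = "Brent",
                   lower = -15, upper = 15)
    } else {
      res <- optim(z0, fn, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol))
    }
    list(params = .to_box(setNames(res$par, names(lower)), lower, upper),
         value = res$value, convergence = res$convergence)
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  best$restart_values <- vals
  best
}

#' Fit a single learner to one participant by maximum likelihood
#'
#' Minimizes the teacher-forced negative log-likelihood with a
#' derivative-free bound-constrained optimizer, taking the best of
#' `n_restarts` runs started uniformly at random within the bounds (the
#' per-restart objective values are retained for flat-landscape
#' diagnostics).
#'
#' @param model `"mb"` or `"mf"`.
#' @param steps Single-participant step records.
#' @param mazes Named list of `maze` objects.
#' @param n_restarts Number of optimization runs (default 10).
#' @param seed Optional RNG seed for the restart draws.
#' @param bounds Optional bounds list overriding [param_bounds()].
#' @param maxit,reltol Nelder-Mead controls.
#' @param ... Passed to [nll_single()].
#' @return An `rl_fit` object: `model`, `condition`, `participant`,
#'   `params`, `nll`, `loglik`, `n_steps`, `n_params`, `bic`,
#'   `restart_nlls`, `floored_steps`.
#' @export
fit_single <- function(model = c("mb", "mf"), steps, mazes,
                       n_restarts = 10L, seed = NULL, bounds = NULL,
                       maxit = 250L, reltol = 1e-7, ...) {
  model <- match.arg(model)
  condition <- unique(steps$condition)
  if (length(condition) > 1) stop("multiple conditions in step records")
  if (is.null(bounds)) bounds <- param_bounds(model, condition)
  if (!is.null(seed)) set.seed(seed)
  pk <- .pack_replay(steps, mazes)
  lower <- bounds$lower
  upper <- bounds$upper
  k <- length(lower)
  starts <- lapply(seq_len(n_restarts), function(i)
    setNames(runif(k, lower, upper), names(lower)))
  objective <- function(theta)
    .nll_packed(model, as.list(theta), pk, ...)
  best <- .optim_box(objective, starts, lower, upper, maxit = maxit,
                     reltol = reltol)
  n_steps <- nrow(steps)
  final <- nll_single(model, as.list(best$params), steps, mazes, ...)
  structure(list(model = model, condition = condition,
                 participant = unique(steps$participant),
                 params = as.list(best$params), nll = as.numeric(final),
                 loglik = -as.numeric(final), n_steps = n_steps,
                 n_params = k, bic = bic(as.numeric(final), k, n_steps),
                 restart_nlls = best$restart_values,
                 floored_steps = attr(final, "floored")),
            class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s, participant %s): nll %.2f, BIC %.1f over %d steps\n",
              toupper(x$model), x$condition, x$participant, x$nll, x$bic,
              x$n_steps))
  cat("  params:", paste(sprintf("%s=%.4g", names(x$params),
                                 unlist(x$params)), collapse = ", "), "\n")
  invisible(x)
}

#' Bayesian Information Criterion
#'
#' `2 * nll + n_params * log(n_steps)`, with `n_steps` the number of
#' executed-step likelihood terms for the participant.
#'
#' @param nll Negative log-likelihood.
#' @param n_params Number of free parameters.
#' @param n_steps Number of likelihood terms (> 0).
#' @return BIC value.
#' @export
bic <- function(nll, n_params, n_steps) {
  if (n_steps <= 0) stop("n_steps must be positive")
  2 * nll + n_params * log(n_steps)
}

#' Overall BIC summed across participants
#'
#' @param fits List of `rl_fit` / `hybrid_fit` objects (possibly mixed
#'   models).
#' @return Data frame with one row per model: summed BIC, total steps,
#'   participant count. Step-wise-weight fits (no BIC) are excluded.
#' @export
overall_bic <- function(fits) {
  model <- vapply(fits, function(f) f$model, character(1))
  bics <- vapply(fits, function(f)
    if (is.null(f$bic)) NA_real_ else f$bic, numeric(1))
  n <- vapply(fits, function(f) f$n_steps, numeric(1))
  keep <- !is.na(bics)
  agg <- aggregate(list(bic = bics[keep], n_steps = n[keep]),
                   by = list(model = model[keep]), FUN = sum)
  cnt <- as.data.frame(table(model = model[keep]),
                       responseName = "n_participants")
  merge(agg, cnt, by = "model")
}

#' Mean likelihood per step as a function of trial
#'
#' Averages the fitted model's per-step action probability within each
#' trial position, together with the random baseline (uniform over
#' reachable actions at each step).
#'
#' @param fit An `rl_fit` or `hybrid_fit` object.
#' @param steps The step records the fit was computed on.
#' @param mazes Named list of `maze` objects.
#' @return Data frame with columns `model`, `trial`, `mean_likelihood`,
#'   including `"random"` baseline rows.
#' @export
per_trial_likelihood_curve <- function(fit, steps, mazes) {
  p <- fitted_step_probabilities(fit, steps, mazes)
  base <- 1 / .n_reachable(steps, mazes)
  rbind(
    data.frame(model = fit$model,
               trial = sort(unique(steps$trial)),
               mean_likelihood = as.numeric(
                 tapply(p, steps$trial, mean))),
    data.frame(model = "random",
               trial = sort(unique(steps$trial)),
               mean_likelihood = as.numeric(
                 tapply(base, steps$trial, mean))))
}

#' Per-step probabilities under a fitted model
#'
#' @param fit An `rl_fit` or `hybrid_fit`.
#' @param steps,mazes Data the fit applies to.
#' @return Numeric vector of per-step probabilities of the observed
#'   actions (mixture probabilities for hybrid fits).
#' @export
fitted_step_probabilities <- function(fit, steps, mazes) {
  if (inherits(fit, "hybrid_fit")) {
    p_mb <- step_probabilities("mb", fit$theta_mb, steps, mazes)
    p_mf <- step_probabilities("mf", fit$theta_mf, steps, mazes)
    w <- hybrid_weights(fit, steps$trial)
    (1 - w) * p_mb + w * p_mf
  } else {
    step_probabilities(fit$model, fit$params, steps, mazes)
  }
}

#' Fit and compare models across a cohort
#'
#' Fits the requested models to every participant in `steps` and returns
#' the per-participant fits plus the overall-BIC comparison table.
#'
#' @param steps Multi-participant step records.
#' @param mazes Named list of `maze` objects.
#' @param models Character vector among `"mb"`, `"mf"`, `"hc"`, `"hd"`,
#'   `"hs"`.
#' @param seed Optional seed for restart draws.
#' @param ... Passed to [fit_single()] / [fit_hybrid_em()].
#' @return List with `fits` (participant x model list) and `bic_table`.
#' @export
compare_models <- function(steps, mazes,
                           models = c("mb", "mf", "hc", "hd"),
                           seed = NULL, ...) {
  participants <- unique(steps$participant)
  fits <- list()
  for (p in participants) {
    sp <- steps[steps$participant == p, ]
    singles <- list()
    for (mdl in intersect(c("mb", "mf"), models)) {
      singles[[mdl]] <- fit_single(mdl, sp, mazes, seed = seed, ...)
      fits[[paste(p, mdl, sep = ".")]] <- singles[[mdl]]
    }
    hybrids <- intersect(c("hc", "hd", "hs"), models)
    if (length(hybrids) > 0) {
      init <- if (all(c("mb", "mf") %in% names(singles)))
        list(theta_mb = singles$mb$params, theta_mf = singles$mf$params)
      else NULL
      for (mdl in hybrids)
        fits[[paste(p, mdl, sep = ".")]] <-
          fit_hybrid_em(sp, mazes, model = mdl, init = init, seed = seed,
                        ...)
    }
  }
  list(fits = fits, bic_table = overall_bic(fits))
}
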