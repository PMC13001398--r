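# Hybrid mixture models over the MB and MF policies.
#
# Each step's action is generated by exactly one algorithm; the MF weight
# w_t is the prior probability that it was the model-free one. Three
# weight structures: constant (HC, w = sigmoid(b0)), trial-logistic (HD,
# w = sigmoid(b0 + b1 * trial)), and free per step (HS). Fitted by EM on
# the observed-data log-likelihood.

.sigma <- function(x) plogis(x)
.logit <- function(p) qlogis(p)

Q_CLAMP <- 1e-6

#' Mixture likelihood of one step
#'
#' `(1 - w) p_mb + w p_mf`, elementwise.
#'
#' @param p_mb,p_mf Per-step action probabilities under each learner.
#' @param w MF weight(s) in \[0, 1\].
#' @return Convex combination.
#' @export
mixture_step_likelihood <- function(p_mb, p_mf, w) {
  (1 - w) * p_mb + w * p_mf
}

#' E-step: posterior responsibility of the MF algorithm
#'
#' `q_t = w_t p_mf / ((1 - w_t) p_mb + w_t p_mf)` per step.
#'
#' @inheritParams mixture_step_likelihood
#' @return Responsibilities in \[0, 1\].
#' @export
e_step <- function(p_mb, p_mf, w) {
  den <- mixture_step_likelihood(p_mb, p_mf, w)
  bad <- which(den <= 0)
  if (length(bad) > 0)
    stop("degenerate step: both likelihoods zero at step ", bad[1])
  w * p_mf / den
}

#' M-step for the mixture-weight structure
#'
#' HC: closed form `b0 = logit(mean(q))`. HD: logistic regression of the
#' responsibilities on the trial index (fractional-response Bernoulli
#' likelihood, solved by IRLS). HS: weights copied from the
#' responsibilities. Responsibilities are clamped to
#' \[1e-6, 1 - 1e-6\] before logits, with a warning when the HC mean sits
#' on the boundary.
#'
#' @param model `"hc"`, `"hd"` or `"hs"`.
#' @param q Responsibilities from the E-step.
#' @param trial 1-based trial index (within maze) per step; HD predictor.
#' @return List with `model`, `b0`, `b1` (HD), `w` (per-step weights).
#' @export
m_step_weights <- function(model = c("hc", "hd", "hs"), q, trial = NULL) {
  model <- match.arg(model)
  if (model == "hs")
    return(list(model = "hs", w = q))
  qc <- pmin(pmax(q, Q_CLAMP), 1 - Q_CLAMP)
  if (model == "hc") {
    qbar <- mean(qc)
    if (mean(q) <= 0 || mean(q) >= 1)
      warning("mean responsibility at boundary; clamped before logit")
    b0 <- .logit(qbar)
    return(list(model = "hc", b0 = b0, w = rep(.sigma(b0), length(q))))
  }
  if (is.null(trial)) stop("trial index required for the HD weight fit")
  fit <- suppressWarnings(
    glm(qc ~ trial, family = quasibinomial(link = "logit"),
        control = glm.control(epsilon = 1e-12, maxit = 200)))
  b <- coef(fit)
  list(model = "hd", b0 = unname(b[1]), b1 = unname(b[2]),
       w = .sigma(b[1] + b[2] * trial))
}

#' Responsibility-weighted M-step for one learner's parameters
#'
#' Maximizes the weighted log-likelihood
#' `sum_t u_t log p(a_t | model, theta)` (u = 1 - q for MB, u = q for MF)
#' with the same bounded derivative-free optimizer as single-model
#' fitting, warm-started at the previous iterate with jittered restarts.
#'
#' @param model `"mb"` or `"mf"`.
#' @param q Responsibilities.
#' @param steps,mazes Data.
#' @param start Previous parameter iterate (named list).
#' @param n_restarts Total starts (first is the warm start).
#' @param maxit,reltol Optimizer controls.
#' @return List with `params` and `value` (weighted NLL at optimum).
#' @export
m_step_theta <- function(model, q, steps, mazes, start, n_restarts = 3L,
                         maxit = 120L, reltol = 1e-7, packed = NULL) {
  if (is.null(packed)) packed <- .pack_replay(steps, mazes)
  bounds <- param_bounds(model, packed$condition)
  lower <- bounds$lower
  upper <- bounds$upper
  weights <- if (model == "mb") 1 - q else q
  objective <- function(theta)
    .nll_packed(model, as.list(theta), packed, weights = weights)
  theta0 <- unlist(start)[names(lower)]
  starts <- c(list(theta0),
              lapply(seq_len(max(0L, n_restarts - 1L)), function(i) {
                z <- .from_box(theta0, lower, upper) + rnorm(length(lower),
                                                             0, 0.25)
                .to_box(z, lower, upper)
              }))
  best <- .optim_box(objective, starts, lower, upper, maxit = maxit,
                     reltol = reltol)
  list(params = as.list(best$params), value = best$value)
}

#' MF weights of a hybrid fit at given trial indices
#'
#' @param fit A `hybrid_fit`.
#' @param trial Trial index per step (ignored for HS, whose per-step
#'   weights are stored).
#' @return Numeric vector of weights.
#' @export
hybrid_weights <- function(fit, trial) {
  switch(fit$weights$model,
         hc = rep(.sigma(fit$weights$b0), length(trial)),
         hd = .sigma(fit$weights$b0 + fit$weights$b1 * trial),
         hs = fit$weights$w)
}

#' Fit a hybrid model by Expectation-Maximization
#'
#' Initialization follows the standard scheme: all MF weights at 0.5
#' (`b0 = 0`, and `b1 = 0` for HD) and learner parameters from
#' independently fitted single MB and MF models. Each EM iteration
#' computes teacher-forced per-step probabilities under the current
#' learner parameters, takes the E-step responsibilities, refits the
#' weight structure and both learners' parameters, and stops when the
#' relative change of the observed-data log-likelihood falls below `tol`
#' (default 1e-4) or after `max_iter` iterations.
#'
#' @param steps Single-participant step records.
#' @param mazes Named list of `maze` objects.
#' @param model `"hc"`, `"hd"` or `"hs"`.
#' @param init Optional list with `theta_mb`, `theta_mf` to skip the
#'   single-model initialization fits.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param n_restarts Restarts for the initialization single fits.
#' @param m_restarts Restarts (warm + jittered) for each theta M-step.
#' @param seed Optional seed for all restart draws.
#' @param theta_update Set `FALSE` to keep learner parameters fixed at
#'   their initial values (weights-only EM).
#' @param ... Ignored.
#' @return A `hybrid_fit`: `model`, `condition`, `participant`,
#'   `theta_mb`, `theta_mf`, `weights`, `q`, `trial`, `loglik`,
#'   `loglik_trace`, `n_steps`, `n_params`, `bic` (NA for HS),
#'   `converged`, `n_iter`.
#' @export
fit_hybrid_em <- function(steps, mazes, model = c("hc", "hd", "hs"),
                          init = NULL, tol = 1e-4, max_iter = 200L,
                          n_restarts = 10L, m_restarts = 3L, seed = NULL,
                          theta_update = TRUE, ...) {
  model <- match.arg(model)
  condition <- unique(steps$condition)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    fit_mb <- fit_single("mb", steps, mazes, n_restarts = n_restarts)
    fit_mf <- fit_single("mf", steps, mazes, n_restarts = n_restarts)
    init <- list(theta_mb = fit_mb$params, theta_mf = fit_mf$params)
  }
  theta_mb <- init$theta_mb
  theta_mf <- init$theta_mf
  trial <- as.integer(steps$trial)
  n <- nrow(steps)
  w <- rep(0.5, n)
  weights <- switch(model,
                    hc = list(model = "hc", b0 = 0, w = w),
                    hd = list(model = "hd", b0 = 0, b1 = 0, w = w),
                    hs = list(model = "hs", w = w))
  pk <- .pack_replay(steps, mazes)
  p_mb <- .replay_packed("mb", theta_mb, pk)
  p_mf <- .replay_packed("mf", theta_mf, pk)
  ll_trace <- numeric(0)
  converged <- FALSE
  q <- NULL
  for (iter in seq_len(max_iter)) {
    ll <- sum(log(pmax(mixture_step_likelihood(p_mb, p_mf, weights$w),
                       PROB_FLOOR)))
    ll_trace <- c(ll_trace, ll)
    if (iter > 1 &&
        abs(ll - ll_trace[iter - 1]) <
          tol * max(1, abs(ll_trace[iter - 1]))) {
      converged <- TRUE
      break
    }
    q <- e_step(p_mb, p_mf, weights$w)
    weights <- m_step_weights(model, q, trial)
    if (theta_update) {
      mb_step <- m_step_theta("mb", q, steps, mazes, theta_mb,
                              n_restarts = m_restarts, packed = pk)
      mf_step <- m_step_theta("mf", q, steps, mazes, theta_mf,
                              n_restarts = m_restarts, packed = pk)
      theta_mb <- mb_step$params
      theta_mf <- mf_step$params
      p_mb <- .replay_packed("mb", theta_mb, pk)
      p_mf <- .replay_packed("mf", theta_mf, pk)
    }
  }
  if (!converged && max_iter > 1)
    warning("EM did not converge within ", max_iter, " iterations")
  ll <- sum(log(pmax(mixture_step_likelihood(p_mb, p_mf, weights$w),
                     PROB_FLOOR)))
  q <- e_step(p_mb, p_mf, weights$w)
  k_weights <- switch(model, hc = 1L, hd = 2L, hs = NA_integer_)
  n_params <- length(theta_mb) + length(theta_mf) + k_weights
  structure(list(model = model, condition = condition,
                 participant = unique(steps$participant),
                 theta_mb = theta_mb, theta_mf = theta_mf,
                 weights = weights, q = q, trial = trial,
                 loglik = ll, loglik_trace = ll_trace, n_steps = n,
                 n_params = n_params,
                 bic = if (model == "hs") NA_real_
                       else bic(-ll, n_params, n),
                 converged = converged, n_iter = length(ll_trace)),
            class = "hybrid_fit")
}

#' @export
print.hybrid_fit <- function(x, ...) {
  cat(sprintf("%s hybrid fit (%s, participant %s): loglik %.2f over %d steps, %d EM iterations%s\n",
              toupper(x$model), x$condition, x$participant, x$loglik,
              x$n_steps, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  if (x$model == "hc")
    cat(sprintf("  b0 = %.4g (w = %.3f)\n", x$weights$b0,
                .sigma(x$weights$b0)))
  if (x$model == "hd")
    cat(sprintf("  b0 = %.4g, b1 = %.4g\n", x$weights$b0, x$weights$b1))
  if (!is.na(x$bic)) cat(sprintf("  BIC = %.1f\n", x$bic))
  invisible(x)
}

#' Write a hybrid fit to JSON
#'
#' Exports parameters, weight structure, per-step weights and
#' responsibilities, the likelihood trace and the convergence flag.
#'
#' @param fit A `hybrid_fit`.
#' @param path Output file.
#' @export
write_hybrid_fit <- function(fit, path) {
  obj <- unclass(fit)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              na = "null"), path)
  invisible(path)
}
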