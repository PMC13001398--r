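test_that("mixture likelihood and E-step arithmetic", {
  expect_equal(mixture_step_likelihood(0.8, 0.4, 0.25), 0.7)
  expect_equal(mixture_step_likelihood(0.8, 0.4, 0), 0.8)
  expect_equal(mixture_step_likelihood(0.8, 0.4, 1), 0.4)
  expect_equal(e_step(0.2, 0.6, 0.5), 0.75)
  expect_equal(e_step(0.3, 0.3, 0.42), 0.42) # equal likelihoods keep prior
  expect_equal(e_step(0.2, 0.6, 0), 0)
  expect_error(e_step(0, 0, 0.5), "degenerate")
})

test_that("weight M-steps: closed form, flat slope, elementwise copy", {
  q <- rep(0.75, 40)
  hc <- m_step_weights("hc", q)
  expect_equal(hc$b0, log(3), tolerance = 1e-9)
  expect_equal(unique(hc$w), 0.75, tolerance = 1e-9)
  # responsibilities constant across trials give a flat HD schedule
  trial <- rep(1:10, each = 20)
  hd <- m_step_weights("hd", rep(0.6, 200), trial)
  expect_equal(hd$b1, 0, tolerance = 1e-7)
  expect_equal(unique(round(hd$w, 9)), 0.6)
  # increasing responsibilities give a positive slope
  q_inc <- plogis(-2 + 0.4 * trial) # exact logistic pattern
  hd2 <- m_step_weights("hd", q_inc, trial)
  expect_equal(hd2$b0, -2, tolerance = 1e-5)
  expect_equal(hd2$b1, 0.4, tolerance = 1e-5)
  # HS copies
  q3 <- runif(17)
  expect_identical(m_step_weights("hs", q3)$w, q3)
  # boundary mean responsibility is clamped with a warning
  expect_warning(out <- m_step_weights("hc", rep(1, 5)), "boundary")
  expect_lt(out$b0, Inf)
})

test_that("theta M-step collapses to single fits at extreme q", {
  co <- tiny_cohort(n_mazes = 3L, n_trials = 6L, model = "hd", seed = 31)
  set.seed(1)
  single_mb <- fit_single("mb", co$steps, co$mazes, n_restarts = 4,
                          seed = 5)
  n <- nrow(co$steps)
  # all q = 0: the MB M-step objective equals the plain MB NLL
  set.seed(5)
  mstep <- m_step_theta("mb", rep(0, n), co$steps, co$mazes,
                        start = single_mb$params, n_restarts = 2)
  expect_equal(mstep$value, single_mb$nll, tolerance = 1e-4)
  expect_equal(unlist(mstep$params), unlist(single_mb$params),
               tolerance = 0.05)
  # mixed q: optimum cannot be worse than the single-fit parameters
  q <- runif(n, 0.2, 0.8)
  w_mb <- 1 - q
  at_single <- nll_single("mb", single_mb$params, co$steps, co$mazes,
                          weights = w_mb)
  opt <- m_step_theta("mb", q, co$steps, co$mazes,
                      start = single_mb$params, n_restarts = 2)
  expect_lte(opt$value, as.numeric(at_single) + 1e-6)
})

test_that("EM log-likelihood is non-decreasing and recovers structure", {
  co <- tiny_cohort(n_mazes = 4L, n_trials = 10L, model = "hd", seed = 32)
  for (model in c("hc", "hd", "hs")) {
    fit <- fit_hybrid_em(co$steps, co$mazes, model, seed = 7,
                         n_restarts = 4)
    expect_monotone_nondecreasing(fit$loglik_trace)
    expect_true(all(fit$q >= 0 & fit$q <= 1))
    expect_true(all(hybrid_weights(fit, fit$trial) >= 0 &
                      hybrid_weights(fit, fit$trial) <= 1))
  }
})

test_that("the lower bound is tight at the E-step posterior", {
  # with q the exact posterior, sum[(1-q)log p_mb + q log p_mf] minus
  # sum KL(q || w) equals the observed-data log-likelihood
  co <- tiny_cohort(n_mazes = 3L, n_trials = 6L, model = "hd", seed = 33)
  p_mb <- step_probabilities("mb", list(gamma = .9, tau = .06),
                             co$steps, co$mazes)
  p_mf <- step_probabilities("mf",
                             list(alpha = .5, gamma = .9, lambda = .7,
                                  tau = .06), co$steps, co$mazes)
  w <- plogis(-1 + 0.2 * co$steps$trial)
  ll <- sum(log(mixture_step_likelihood(p_mb, p_mf, w)))
  q <- e_step(p_mb, p_mf, w)
  weighted <- sum((1 - q) * log(p_mb) + q * log(p_mf))
  kl <- sum(q * log(q / w) + (1 - q) * log((1 - q) / (1 - w)))
  expect_equal(weighted - kl, ll, tolerance = 1e-8)
  # for any other q' the bound is strictly below the log-likelihood
  q2 <- pmin(pmax(q + runif(length(q), -0.2, 0.2), 0.01), 0.99)
  weighted2 <- sum((1 - q2) * log(p_mb) + q2 * log(p_mf))
  kl2 <- sum(q2 * log(q2 / w) + (1 - q2) * log((1 - q2) / (1 - w)))
  expect_lt(weighted2 - kl2, ll)
})

test_that("HC is nested in HD: HD attains at least HC's log-likelihood", {
  co <- tiny_cohort(n_mazes = 4L, n_trials = 10L, model = "hd", seed = 34)
  init <- list(theta_mb = list(gamma = .9, tau = .05),
               theta_mf = list(alpha = .5, gamma = .9, lambda = .7,
                               tau = .05))
  hc <- fit_hybrid_em(co$steps, co$mazes, "hc", init = init, seed = 8,
                      theta_update = FALSE)
  hd <- fit_hybrid_em(co$steps, co$mazes, "hd", init = init, seed = 8,
                      theta_update = FALSE)
  expect_gte(hd$loglik, hc$loglik - 1e-6)
  # nesting bound on BIC: HD pays exactly one extra parameter
  expect_lte(hd$bic, hc$bic + log(hd$n_steps) + 1e-6)
})

test_that("step-wise weights track the generating schedule", {
  co <- generate_cohort(synth_config(n_participants = 1L, model = "hd",
                                     seed = 38))
  fit <- fit_hybrid_em(co$steps, co$mazes, "hs", seed = 11,
                       n_restarts = 6)
  w_hat <- as.numeric(tapply(fit$weights$w, fit$trial, mean))
  w_true <- co$truth$P01$w_trial
  expect_lt(mean(abs(w_hat - w_true)), 0.15)
  expect_gt(cor(w_hat, w_true, method = "spearman"), 0.9)
})

test_that("pure-MB data yields a small constant MF weight", {
  # a residual MF share persists even on pure-MB data because the MF
  # learner imitates the repeated MB-generated paths (and profits from
  # MB value ties on revisited states), so the fitted weight is small
  # but not zero
  co <- generate_cohort(synth_config(n_participants = 1L, n_mazes = 15L,
                                     model = "mb", seed = 35))
  expect_gt(nrow(co$steps), 1000) # enough evidence
  fit <- fit_hybrid_em(co$steps, co$mazes, "hc", seed = 9,
                       n_restarts = 4)
  expect_lt(plogis(fit$weights$b0), 0.2)
  # and the pure-MF counterpart sits far higher
  co_mf <- generate_cohort(synth_config(n_participants = 1L,
                                        n_mazes = 6L, model = "mf",
                                        seed = 37))
  fit_mf <- fit_hybrid_em(co_mf$steps, co_mf$mazes, "hc", seed = 9,
                          n_restarts = 4)
  expect_gt(plogis(fit_mf$weights$b0), 0.6)
})

test_that("hybrid fit JSON export round-trips key fields", {
  co <- tiny_cohort(n_mazes = 2L, n_trials = 4L, seed = 36)
  fit <- fit_hybrid_em(co$steps, co$mazes, "hc", seed = 10,
                       init = list(theta_mb = list(gamma = .9, tau = .05),
                                   theta_mf = list(alpha = .5, gamma = .9,
                                                   lambda = .7,
                                                   tau = .05)),
                       theta_update = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_hybrid_fit(fit, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(back$weights$b0, fit$weights$b0, tolerance = 1e-8)
  expect_identical(back$converged, fit$converged)
})
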