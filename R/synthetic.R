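# Synthetic mazes, agents and cohorts with known ground truth. The
# generator emulates the behavioural study design: per participant, a
# shared ordered set of 25 mazes on a 10 x 10 grid, 10 trials per maze
# from distinct start cells to a fixed target, grid-step records with
# block contacts produced by the same closed-loop protocol as
# autonomous simulation.

#' Generate a random solvable maze
#'
#' Rejection-samples block placements at the requested density until the
#' target is reachable from every start (at most 1000 attempts).
#' Deterministic given `seed`.
#'
#' @param width,height Grid size (default 10 x 10).
#' @param density Fraction of cells blocked, in \[0, 0.4\].
#' @param n_starts Number of distinct start cells (default 10, one per
#'   trial).
#' @param seed Optional seed; `NULL` uses the ambient RNG stream.
#' @param id Maze identifier.
#' @return A validated `maze`.
#' @export
generate_maze <- function(width = 10L, height = 10L, density = 0.25,
                          n_starts = 10L, seed = NULL, id = "maze") {
  if (density < 0 || density > 0.4)
    stop("density must be in [0, 0.4]")
  if (!is.null(seed)) set.seed(seed)
  n <- width * height
  n_block <- round(density * n)
  for (attempt in seq_len(1000L)) {
    blk_idx <- sample.int(n, n_block)
    open_idx <- setdiff(seq_len(n), blk_idx)
    if (length(open_idx) < n_starts + 1) next
    pick <- sample(open_idx, n_starts + 1)
    target_idx <- pick[1]
    start_idx <- pick[-1]
    blocked <- rep(FALSE, n)
    blocked[blk_idx] <- TRUE
    fake <- list(width = width, height = height)
    m <- tryCatch(
      maze(matrix(blocked, width, height), cell_xy(fake, start_idx),
           cell_xy(fake, target_idx), id = id),
      error = function(e) NULL)
    if (is.null(m)) next
    if (validate_maze(m)$valid) return(m)
  }
  stop("could not generate a solvable maze in 1000 attempts")
}

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the behavioural study design: 18 participants, 25
#' mazes on a 10 x 10 grid, 10 trials per maze, and hybrid ground-truth
#' agents whose MF weight follows a trial-logistic schedule.
#'
#' @param n_participants Cohort size (default 18).
#' @param n_mazes Mazes per participant (default 25; the maze set is
#'   shared by all participants, as in the study).
#' @param n_trials Trials per maze (default 10).
#' @param width,height Grid size.
#' @param density Maze block density target.
#' @param condition Condition label.
#' @param model Ground-truth generator: `"mb"`, `"mf"`, `"hc"`, `"hd"`
#'   or `"hs"` (`"hs"` uses the per-trial schedule like HD; its per-step
#'   weights are the schedule values).
#' @param theta_mb,theta_mf True learner parameters.
#' @param b0,b1 True weight-schedule parameters (`w = sigmoid(b0 + b1 *
#'   trial)`; `b1` ignored for HC).
#' @param b0_sd Between-participant SD of the intercept `b0` (0 for a
#'   homogeneous cohort).
#' @param duration_intercept,duration_slope,duration_shape Gamma model of
#'   step durations: mean `intercept + slope * w_t` seconds, shape
#'   `duration_shape`; set `duration_intercept = NA` to omit durations.
#' @param max_steps Step cap per trial (default 88).
#' @param seed Master seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_participants = 18L, n_mazes = 25L,
                         n_trials = 10L, width = 10L, height = 10L,
                         density = 0.25, condition = "visual_haptic",
                         model = "hd",
                         theta_mb = NULL, theta_mf = NULL,
                         b0 = -1, b1 = 0.2, b0_sd = 0,
                         duration_intercept = 1.1,
                         duration_slope = -0.8, duration_shape = 12,
                         max_steps = 88L, seed = 1L) {
  condition <- match.arg(condition, CONDITIONS)
  model <- match.arg(model, c("mb", "mf", "hc", "hd", "hs"))
  if (is.null(theta_mb)) {
    theta_mb <- list(gamma = 0.9, tau = 0.05)
    if (condition != "visual_haptic") {
      theta_mb$alpha <- 0.5
      theta_mb$p0 <- 0.5
    }
  }
  if (is.null(theta_mf))
    theta_mf <- list(alpha = 0.5, gamma = 0.9, lambda = 0.7, tau = 0.05)
  structure(list(n_participants = as.integer(n_participants),
                 n_mazes = as.integer(n_mazes),
                 n_trials = as.integer(n_trials),
                 width = as.integer(width), height = as.integer(height),
                 density = density, condition = condition, model = model,
                 theta_mb = theta_mb, theta_mf = theta_mf,
                 b0 = b0, b1 = b1, b0_sd = b0_sd,
                 duration_intercept = duration_intercept,
                 duration_slope = duration_slope,
                 duration_shape = duration_shape,
                 max_steps = as.integer(max_steps),
                 seed = as.integer(seed)),
            class = "synth_config")
}

.schedule_w <- function(model, b0, b1, trials) {
  switch(model,
         mb = rep(0, length(trials)),
         mf = rep(1, length(trials)),
         hc = rep(.sigma(b0), length(trials)),
         hd = ,
         hs = .sigma(b0 + b1 * trials))
}

#' Generate a full synthetic cohort with known ground truth
#'
#' Builds a shared maze set, then simulates each participant's ground
#' truth agent closed-loop over all mazes and trials, producing step
#' records in the behavioural schema (contacts included; durations drawn
#' from the configured gamma model, whose mean is linked to the true MF
#' weight).
#'
#' @param config A `synth_config`.
#' @return List of class `synth_cohort`: `steps` (step records for all
#'   participants), `mazes` (named list), `truth` (per-participant true
#'   parameters and weight schedules), `config`.
#' @export
generate_cohort <- function(config) {
  set.seed(config$seed)
  mazes <- lapply(seq_len(config$n_mazes), function(i)
    generate_maze(config$width, config$height, config$density,
                  n_starts = config$n_trials,
                  id = sprintf("M%02d", i)))
  names(mazes) <- vapply(mazes, function(m) m$id, character(1))
  trials <- seq_len(config$n_trials)
  steps <- NULL
  truth <- list()
  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", i)
    b0_i <- config$b0 + if (config$b0_sd > 0) rnorm(1, 0, config$b0_sd)
                        else 0
    w_trial <- .schedule_w(config$model, b0_i, config$b1, trials)
    agent <- switch(config$model,
      mb = agent_spec("mb", config$condition, theta_mb = config$theta_mb),
      mf = agent_spec("mf", config$condition, theta_mf = config$theta_mf),
      agent_spec("hybrid", config$condition, theta_mb = config$theta_mb,
                 theta_mf = config$theta_mf, w_trial = w_trial))
    sim <- simulate_experiment(agent, mazes, n_trials = config$n_trials,
                               n_reps = 1L, max_steps = config$max_steps,
                               record_steps = TRUE, participant = pid)
    st <- sim$steps
    st$rep <- NULL
    w_step <- w_trial[st$trial]
    if (!is.na(config$duration_intercept)) {
      mu <- pmax(config$duration_intercept +
                   config$duration_slope * w_step, 0.05)
      st$duration <- rgamma(nrow(st), shape = config$duration_shape,
                            rate = config$duration_shape / mu)
    }
    steps <- rbind(steps, st)
    truth[[pid]] <- list(model = config$model,
                         theta_mb = config$theta_mb,
                         theta_mf = config$theta_mf,
                         b0 = b0_i, b1 = config$b1, w_trial = w_trial)
  }
  structure(list(steps = steps, mazes = mazes, truth = truth,
                 config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d participants, %d mazes x %d trials (%s, %s ground truth), %d steps\n",
              x$config$n_participants, x$config$n_mazes,
              x$config$n_trials, x$config$condition, x$config$model,
              nrow(x$steps)))
  invisible(x)
}

#' Parameter- and model-recovery suite
#'
#' Runs (a) sign recovery of the HD logit slope `b1` on single-participant
#' cohorts generated at each value of `b1_values`, and (b) a model
#' recovery confusion matrix over generators MB, MF and HC, classifying
#' each synthetic dataset by the lowest-BIC fitted class.
#'
#' @param base_config Template `synth_config` (its `n_participants` is
#'   forced to 1 per replicate).
#' @param b1_values True slopes for the sign-recovery arm.
#' @param n_per_value Replicates per slope value.
#' @param generators Generator classes for the confusion arm.
#' @param n_confusion Replicates per generator class.
#' @param n_restarts Restarts for the single-model fits.
#' @param seed Master seed.
#' @return List of class `recovery_report`: `hd_recovery` data frame
#'   (true and fitted b0/b1), `b1_sign_rate`, `confusion` matrix,
#'   `confusion_diag`.
#' @export
recovery_suite <- function(base_config = synth_config(),
                           b1_values = c(0.1, 0.2, 0.4),
                           n_per_value = 5L,
                           generators = c("mb", "mf", "hc"),
                           n_confusion = 4L, n_restarts = 10L,
                           seed = 1L) {
  hd_rows <- NULL
  rep_seed <- seed
  for (b1 in b1_values) {
    for (r in seq_len(n_per_value)) {
      rep_seed <- rep_seed + 1L
      cfg <- base_config
      cfg$n_participants <- 1L
      cfg$model <- "hd"
      cfg$b1 <- b1
      cfg$seed <- rep_seed
      co <- generate_cohort(cfg)
      fit <- fit_hybrid_em(co$steps, co$mazes, model = "hd",
                           n_restarts = n_restarts, seed = rep_seed)
      hd_rows <- rbind(hd_rows, data.frame(
        true_b0 = cfg$b0, true_b1 = b1,
        fitted_b0 = fit$weights$b0, fitted_b1 = fit$weights$b1,
        converged = fit$converged, seed = rep_seed))
    }
  }
  sign_rate <- mean(sign(hd_rows$fitted_b1) == sign(hd_rows$true_b1))
  confusion <- matrix(0L, length(generators), length(generators),
                      dimnames = list(true = generators,
                                      fitted = generators))
  for (g in generators) {
    for (r in seq_len(n_confusion)) {
      rep_seed <- rep_seed + 1L
      cfg <- base_config
      cfg$n_participants <- 1L
      cfg$model <- g
      cfg$seed <- rep_seed
      co <- generate_cohort(cfg)
      cmp <- compare_models(co$steps, co$mazes, models = generators,
                            seed = rep_seed, n_restarts = n_restarts)
      tab <- cmp$bic_table
      best <- tab$model[which.min(tab$bic)]
      confusion[g, best] <- confusion[g, best] + 1L
    }
  }
  structure(list(hd_recovery = hd_rows, b1_sign_rate = sign_rate,
                 confusion = confusion,
                 confusion_diag = diag(confusion) /
                   pmax(rowSums(confusion), 1)),
            class = "recovery_report")
}

#' Write a recovery report as CSV tables plus a text summary
#'
#' @param report A `recovery_report` from [recovery_suite()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_recovery_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("hd_recovery.csv", "confusion.csv",
                            "recovery_summary.txt"))
  write.csv(report$hd_recovery, paths[1], row.names = FALSE)
  write.csv(as.data.frame(report$confusion), paths[2])
  con <- file(paths[3], "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(paths)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("HD slope sign recovery: %.0f%% over %d replicates\n",
              100 * x$b1_sign_rate, nrow(x$hd_recovery)))
  cat("model recovery confusion (rows = generator):\n")
  print(x$confusion)
  invisible(x)
}
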