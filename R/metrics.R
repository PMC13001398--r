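# Behavioural metrics, step-wise covariates, weight summaries and
# heatmap binning. These feed descriptive analyses; inferential
# statistics (mixed models, t-tests) are left to downstream tools, which
# consume the exported long tables.

#' Step-wise covariates: state familiarity and goal distance
#'
#' For every recorded step, the number of visits to the current state
#' (cumulative count of entries within the same participant and maze,
#' across all its trials, including the current entry — so the first
#' entry counts 1) and the Manhattan distance from the current state to
#' the target.
#'
#' @param steps Step records (one or more participants).
#' @param mazes Named list of `maze` objects.
#' @return `steps` with columns `visits` and `distance` appended.
#' @export
stepwise_covariates <- function(steps, mazes) {
  key <- paste(steps$participant, steps$maze)
  state <- paste(key, steps$x, steps$y)
  visits <- integer(nrow(steps))
  counter <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(steps))) {
    k <- state[i]
    v <- if (is.null(counter[[k]])) 1L else counter[[k]] + 1L
    counter[[k]] <- v
    visits[i] <- v
  }
  tx <- vapply(steps$maze, function(id) mazes[[id]]$target[1], integer(1))
  ty <- vapply(steps$maze, function(id) mazes[[id]]$target[2], integer(1))
  steps$visits <- visits
  steps$distance <- abs(steps$x - tx) + abs(steps$y - ty)
  steps
}

#' Per-trial mean MF weight of hybrid fits
#'
#' HC/HD weights come from the parametric schedule; HS weights are the
#' empirical per-trial means of the fitted step-wise weights.
#'
#' @param fits List of `hybrid_fit` objects (one per participant, any
#'   mixture of models).
#' @param n_trials Number of trial positions (default 10).
#' @return Tidy data frame: `participant`, `model`, `trial`, `mf_weight`.
#' @export
weight_trial_summary <- function(fits, n_trials = 10L) {
  out <- NULL
  trials <- seq_len(n_trials)
  for (fit in fits) {
    w <- switch(fit$weights$model,
                hc = rep(.sigma(fit$weights$b0), n_trials),
                hd = .sigma(fit$weights$b0 + fit$weights$b1 * trials),
                hs = as.numeric(tapply(fit$weights$w, fit$trial,
                                       mean))[trials])
    out <- rbind(out, data.frame(participant = fit$participant,
                                 model = fit$model, trial = trials,
                                 mf_weight = w))
  }
  out
}

#' Bin step-wise MF weights over visits x distance
#'
#' @param w Per-step MF weights.
#' @param visits,distance Step-wise covariates (from
#'   [stepwise_covariates()]).
#' @param visit_breaks,dist_breaks Bin edges (right-closed); defaults bin
#'   each integer value (visits from 1, distance from 0) up to 10/15
#'   with an overflow bin.
#' @return Data frame of non-empty bins: bin labels, mean weight, `n`.
#' @export
bin_weights <- function(w, visits, distance,
                        visit_breaks = c(0:10, Inf),
                        dist_breaks = c(-1, 0:15, Inf)) {
  if (length(w) == 0) return(data.frame())
  vb <- cut(visits, visit_breaks)
  db <- cut(distance, dist_breaks)
  agg <- aggregate(list(mean_weight = w),
                   by = list(visits_bin = vb, distance_bin = db),
                   FUN = mean)
  n <- aggregate(list(n = w),
                 by = list(visits_bin = vb, distance_bin = db),
                 FUN = length)
  merge(agg, n, by = c("visits_bin", "distance_bin"))
}

#' Per-participant behavioural metrics and weight correlations
#'
#' Mean path length (steps per trial), proportion of no-block-contact
#' steps, mean duration of no-block-contact steps (NA when durations are
#' absent), and the overall MF weight (mean of the fit's per-step or
#' scheduled weights), averaged across trials and mazes per participant;
#' plus Pearson correlations between the overall MF weight and each
#' metric.
#'
#' @param steps Multi-participant step records.
#' @param fits Optional named list of `hybrid_fit`s keyed by participant
#'   (or a plain list; participants matched by the fit's field).
#' @return List with `metrics` (one row per participant) and
#'   `correlations` (metric, Pearson r, n).
#' @export
behavioural_metrics <- function(steps, fits = NULL) {
  fit_by_p <- list()
  if (!is.null(fits))
    for (f in fits) fit_by_p[[f$participant]] <- f
  no_contact <- steps$contacts == "" | is.na(steps$contacts)
  out <- NULL
  for (p in unique(steps$participant)) {
    sp <- steps[steps$participant == p, ]
    nc <- no_contact[steps$participant == p]
    trial_lengths <- tapply(sp$step, paste(sp$maze, sp$trial), max)
    dur <- sp$duration[nc]
    dur <- dur[!is.na(dur)]
    fit <- fit_by_p[[p]]
    w <- if (is.null(fit)) NA_real_
         else mean(hybrid_weights(fit, fit$trial))
    out <- rbind(out, data.frame(
      participant = p,
      mean_path_length = mean(trial_lengths),
      prop_no_contact = mean(nc),
      mean_time_per_step = if (length(dur) > 0) mean(dur) else NA_real_,
      mf_weight = w))
  }
  cors <- NULL
  for (metric in c("mean_path_length", "prop_no_contact",
                   "mean_time_per_step")) {
    ok <- complete.cases(out[, c("mf_weight", metric)])
    r <- if (sum(ok) >= 3) cor(out$mf_weight[ok], out[[metric]][ok])
         else NA_real_
    cors <- rbind(cors, data.frame(metric = metric, r = r, n = sum(ok)))
  }
  list(metrics = out, correlations = cors)
}

#' Write the standard report tables of a fitted cohort
#'
#' Emits `weights_by_trial.csv`, `stepwise_long.csv`,
#' `heatmap_bins.csv` and `participant_metrics.csv` under `dir`.
#'
#' @param steps Multi-participant step records.
#' @param mazes Named list of `maze` objects.
#' @param fits List of `hybrid_fit` objects (one per participant).
#' @param dir Output directory (created if needed).
#' @param n_trials Trial positions per maze.
#' @return Invisibly, the list of written paths.
#' @export
write_report_tables <- function(steps, mazes, fits, dir,
                                n_trials = 10L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fit_by_p <- list()
  for (f in fits) fit_by_p[[f$participant]] <- f
  long <- stepwise_covariates(steps, mazes)
  long$mf_weight <- NA_real_
  for (p in names(fit_by_p)) {
    sel <- long$participant == p
    long$mf_weight[sel] <- hybrid_weights(fit_by_p[[p]],
                                          long$trial[sel])
  }
  wt <- weight_trial_summary(fits, n_trials)
  ok <- !is.na(long$mf_weight)
  bins <- bin_weights(long$mf_weight[ok], long$visits[ok],
                      long$distance[ok])
  bm <- behavioural_metrics(steps, fits)
  paths <- file.path(dir, c("weights_by_trial.csv", "stepwise_long.csv",
                            "heatmap_bins.csv",
                            "participant_metrics.csv"))
  write.csv(wt, paths[1], row.names = FALSE)
  write.csv(long, paths[2], row.names = FALSE)
  write.csv(bins, paths[3], row.names = FALSE)
  write.csv(bm$metrics, paths[4], row.names = FALSE)
  invisible(paths)
}
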