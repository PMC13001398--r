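# Shared fixtures and independent oracles for the test suite. The
# oracles here are deliberately written as plain R compositions of the
# exported single-event operations (or from first principles), so they
# exercise the compiled replay/simulation cores against independent
# code paths.

open_maze <- function(width = 10L, height = 10L, target = c(9, 9),
                      starts = cbind(0, 0), id = "open") {
  maze(matrix(FALSE, width, height), starts, target, id = id)
}

# small maze with a vertical wall and a winding gap
wall_maze <- function() {
  maze_from_text(c("....#....T",
                   "....#.....",
                   "....#.....",
                   "....#.....",
                   "..........",
                   "....#.....",
                   "....#.....",
                   "S...#.....",
                   "....#.....",
                   "S...#....."),
                 id = "wall")
}

tiny_cohort <- function(n_participants = 1L, n_mazes = 4L, n_trials = 10L,
                        model = "hd", condition = "visual_haptic",
                        seed = 1L, ...) {
  generate_cohort(synth_config(n_participants = n_participants,
                               n_mazes = n_mazes, n_trials = n_trials,
                               model = model, condition = condition,
                               seed = seed, ...))
}

.mazerl_succ <- function(m, s, a) {
  xy <- cell_xy(m, s)
  nx <- xy[1] + c(N = 0, E = 1, S = 0, W = -1)[[a]]
  ny <- xy[2] + c(N = 1, E = 0, S = -1, W = 0)[[a]]
  if (nx < 0 || nx >= m$width || ny < 0 || ny >= m$height)
    return(NA_integer_)
  as.integer(nx + ny * m$width + 1)
}

# Dense synchronous Bellman sweeps written independently in plain R.
brute_value_iteration <- function(m, T, gamma, n_sweeps = 400L) {
  n <- m$width * m$height
  tgt <- cell_index(m, m$target)
  V <- numeric(n)
  for (it in seq_len(n_sweeps)) {
    Vn <- numeric(n)
    for (s in seq_len(n)) {
      if (s == tgt) next
      xy <- cell_xy(m, s)
      best <- 0
      for (a in c("N", "E", "S", "W")) {
        nx <- xy[1] + c(N = 0, E = 1, S = 0, W = -1)[[a]]
        ny <- xy[2] + c(N = 1, E = 0, S = -1, W = 0)[[a]]
        if (nx < 0 || nx >= m$width || ny < 0 || ny >= m$height) next
        sp <- nx + ny * m$width + 1
        r <- as.numeric(sp == tgt)
        v <- T[s, a] * (r + gamma * V[sp])
        if (v > best) best <- v
      }
      Vn[s] <- best
    }
    V <- Vn
  }
  V
}

# Teacher-forced replay oracle composed from the exported per-event ops.
reference_step_probs <- function(model, params, steps, mazes) {
  cond <- unique(steps$condition)
  n_steps <- nrow(steps)
  out <- numeric(n_steps)
  key <- paste(steps$participant, steps$maze)
  tkey <- paste(key, steps$trial)
  prev_key <- c("", key[-n_steps])
  prev_tkey <- c("", tkey[-n_steps])
  T <- NULL
  Q <- NULL
  e <- NULL
  for (i in seq_len(n_steps)) {
    m <- mazes[[steps$maze[i]]]
    s <- c(steps$x[i], steps$y[i])
    a <- steps$action[i]
    s_next <- s + c(c(N = 0, E = 1, S = 0, W = -1)[[a]],
                    c(N = 1, E = 0, S = -1, W = 0)[[a]])
    new_maze <- key[i] != prev_key[i]
    new_trial <- tkey[i] != prev_tkey[i]
    if (model == "mb") {
      if (new_maze) T <- init_transition(cond, m, params$p0)
      if (cond == "navigation" && new_trial)
        T <- navigation_visibility_update(T, m, s, first_step = TRUE,
                                          alpha = params$alpha)
      V <- value_iteration(m, T, params$gamma, tol = 1e-10,
                           max_iter = 5000)
      acts <- reachable_actions(m, s)
      out[i] <- mb_policy(m, T, V, s, params$gamma, params$tau,
                          actions = acts)[[a]]
      if (cond != "visual_haptic") {
        for (ca in strsplit(steps$contacts[i], "")[[1]]) {
          cs <- s + c(c(N = 0, E = 1, S = 0, W = -1)[[ca]],
                      c(N = 1, E = 0, S = -1, W = 0)[[ca]])
          T <- update_transition(T, m, cs, 0, params$alpha)
        }
        T <- update_transition(T, m, s_next, 1, params$alpha)
        if (cond == "navigation")
          T <- navigation_visibility_update(T, m, s_next, heading = a,
                                            first_step = FALSE,
                                            alpha = params$alpha)
      }
    } else {
      if (new_maze || is.null(Q)) Q <- init_q(m)
      if (new_trial) e <- init_q(m)
      acts <- reachable_actions(m, s)
      out[i] <- mf_policy(Q, m, s, params$tau, actions = acts)[[a]]
      r <- as.numeric(all(s_next == m$target))
      upd <- update_q(Q, e, m, s, a, r, s_next, params)
      Q <- upd$Q
      e <- upd$e
    }
  }
  out
}

# Exact absorbing-chain solve of the uniform random walk with step cap:
# success probability and expected (capped) path length.
chain_random_baseline <- function(m, start, max_steps) {
  n <- m$width * m$height
  tgt <- cell_index(m, m$target)
  open <- which(!as.vector(m$blocked))
  P <- matrix(0, n, n)
  for (s in open) {
    if (s == tgt) { P[s, s] <- 1; next }
    acts <- suppressWarnings(reachable_actions(m, cell_xy(m, s)))
    if (length(acts) == 0) { P[s, s] <- 1; next } # isolated open cell
    for (a in acts) {
      xy <- cell_xy(m, s)
      sp <- (xy[1] + c(N = 0, E = 1, S = 0, W = -1)[[a]]) +
        (xy[2] + c(N = 1, E = 0, S = -1, W = 0)[[a]]) * m$width + 1
      P[s, sp] <- P[s, sp] + 1 / length(acts)
    }
  }
  v <- numeric(n)
  v[cell_index(m, start)] <- 1
  p_hit <- numeric(max_steps)
  for (k in seq_len(max_steps)) {
    v <- as.numeric(v %*% P)
    p_hit[k] <- v[tgt]
  }
  success <- p_hit[max_steps]
  p_at <- diff(c(0, p_hit))
  expected_length <- sum(seq_len(max_steps) * p_at) +
    max_steps * (1 - success)
  list(success = success, expected_length = expected_length)
}

expect_monotone_nondecreasing <- function(x, slack = 1e-10) {
  testthat::expect_true(all(diff(x) >= -slack))
}
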