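test_that("transition initialization per condition", {
  m <- wall_maze()
  Tv <- init_transition("visual_haptic", m)
  # action into a block is 0, into an open cell 1, off-grid 0
  s <- cell_index(m, c(3, 2)) # (4,2) is blocked
  expect_identical(unname(Tv[s, "E"]), 0)
  expect_identical(unname(Tv[s, "N"]), 1)
  expect_identical(unname(Tv[cell_index(m, c(0, 0)), "S"]), 0)
  Th <- init_transition("haptic", m, p0 = 0.7)
  expect_identical(unname(Th[s, "E"]), 0.7)
  expect_identical(unname(Th[s, "W"]), 0.7)
  expect_identical(unname(Th[cell_index(m, c(0, 0)), "W"]), 0)
  expect_error(init_transition("haptic", m), "p0 is required")
})

test_that("transition update moves incoming pairs toward the observation", {
  m <- open_maze()
  T <- init_transition("haptic", m, p0 = 0.5)
  T1 <- update_transition(T, m, c(4, 4), 1, 0.2)
  # the four pairs leading into (4,4)
  expect_equal(unname(T1[cell_index(m, c(4, 3)), "N"]), 0.6)
  expect_equal(unname(T1[cell_index(m, c(4, 5)), "S"]), 0.6)
  expect_equal(unname(T1[cell_index(m, c(3, 4)), "E"]), 0.6)
  expect_equal(unname(T1[cell_index(m, c(5, 4)), "W"]), 0.6)
  # untouched elsewhere
  expect_equal(unname(T1[cell_index(m, c(0, 0)), "N"]), 0.5)
  T0 <- update_transition(T, m, c(4, 4), 0, 0.2)
  expect_equal(unname(T0[cell_index(m, c(4, 3)), "N"]), 0.4)
  # two consecutive h=1 observations: 1 - (1-alpha)^2 (1-p0)
  T2 <- update_transition(T1, m, c(4, 4), 1, 0.2)
  expect_equal(unname(T2[cell_index(m, c(4, 3)), "N"]), 1 - (1 - 0.2)^2 * 0.5)
  expect_equal(unname(T2[cell_index(m, c(4, 3)), "N"]), 0.68)
  expect_error(update_transition(T, m, c(4, 4), 1, 1.2), "alpha")
})

test_that("transition values stay in [0,1] under random event sequences", {
  m <- wall_maze()
  set.seed(9)
  T <- init_transition("haptic", m, p0 = 0.5)
  for (i in 1:200) {
    cell <- cell_xy(m, sample(100, 1))
    T <- update_transition(T, m, cell, sample(0:1, 1), runif(1, 0.05, 0.95))
    expect_true(all(T >= 0 & T <= 1))
  }
})

test_that("value iteration closed form on the obstacle-free maze", {
  m <- open_maze()
  d <- manhattan(cell_xy(m, 1:100), m$target)
  for (gamma in c(0.3, 0.5, 0.9)) {
    V <- value_iteration(m, gamma = gamma, tol = 1e-12, max_iter = 5000)
    expect_equal(V[d > 0], gamma^(d[d > 0] - 1), tolerance = 1e-9)
    expect_identical(V[d == 0], 0) # terminating target
  }
  # a state adjacent to the target has V = 1 for any gamma
  adj <- which(d == 1)
  V <- value_iteration(m, gamma = 0.123, tol = 1e-12, max_iter = 5000)
  expect_equal(V[adj], rep(1, length(adj)))
})

test_that("value iteration matches a dense brute-force sweep on random T", {
  set.seed(21)
  for (k in 1:5) {
    blk <- matrix(runif(25) < 0.2, 5, 5)
    open_cells <- which(!blk)
    fake <- list(width = 5L, height = 5L)
    pick <- sample(open_cells, 2)
    m <- tryCatch(maze(blk, cell_xy(fake, pick[2]), cell_xy(fake, pick[1])),
                  error = function(e) NULL)
    if (is.null(m)) next
    T <- init_transition("haptic", m, p0 = 0.6)
    T[T > 0] <- runif(sum(T > 0))
    V <- value_iteration(m, T, gamma = 0.85, tol = 1e-12, max_iter = 5000)
    Vb <- brute_value_iteration(m, T, 0.85, n_sweeps = 300)
    expect_lt(max(abs(V - Vb)), 1e-10)
  }
})

test_that("value-iteration residuals contract at rate <= gamma", {
  m <- wall_maze()
  T <- init_transition("haptic", m, p0 = 0.5)
  gamma <- 0.9
  V <- value_iteration(m, T, gamma, tol = 1e-10, max_iter = 5000)
  res <- attr(V, "residual_trace")
  ratios <- res[-1] / res[-length(res)]
  expect_true(all(ratios[res[-length(res)] > 1e-12] <= gamma + 1e-9))
})

test_that("non-convergence raises a diagnostic error with the residual", {
  m <- open_maze()
  expect_error(value_iteration(m, gamma = 0.99, max_iter = 2L),
               "did not converge")
})

test_that("MB softmax policy arithmetic and limits", {
  m <- open_maze(3, 3, target = c(2, 2), starts = cbind(0, 0))
  # craft T and V so two actions have action values 1 and 0.25
  T <- true_transition(m)
  V <- value_iteration(m, T, gamma = 0.5)
  # at (1,2): N off-grid, E leads to target (value 1), S has value
  # gamma * V(1,1) = 0.5^2 = 0.25, W has 0.5 * V(0,2) = 0.25
  p <- mb_policy(m, T, V, c(1, 2), gamma = 0.5, tau = 0.25,
                 actions = c("E", "S"))
  expect_equal(unname(p), c(1 / (1 + exp(-3)), exp(-3) / (1 + exp(-3))),
               tolerance = 1e-9)
  expect_equal(unname(p[1]), 0.95257, tolerance = 1e-4)
  # equal values give a uniform distribution
  p_flat <- mb_policy(m, T, V, c(1, 2), gamma = 0.5, tau = 0.25,
                      actions = c("S", "W"))
  expect_equal(unname(p_flat), c(0.5, 0.5))
  # large tau flattens toward uniform
  p_hot <- mb_policy(m, T, V, c(1, 2), gamma = 0.5, tau = 100,
                     actions = c("E", "S"))
  expect_lt(abs(p_hot[["E"]] - 0.5), 0.01)
  expect_true(p_hot[["E"]] > 0.5) # still monotone in value
  expect_error(mb_policy(m, T, V, c(1, 2), 0.5, tau = 0), "tau")
})

test_that("policy probabilities sum to one across states and action sets", {
  m <- wall_maze()
  T <- true_transition(m)
  V <- value_iteration(m, T, gamma = 0.9)
  for (s in which(!as.vector(m$blocked))) {
    xy <- cell_xy(m, s)
    if (all(xy == m$target)) next
    acts <- suppressWarnings(reachable_actions(m, xy))
    if (length(acts) == 0) next
    expect_equal(sum(mb_policy(m, T, V, xy, 0.9, 0.1, acts)), 1,
                 tolerance = 1e-12)
    expect_equal(sum(mb_policy(m, T, V, xy, 0.9, 2,
                               in_bounds_actions(m, xy))), 1,
                 tolerance = 1e-12)
  }
})

test_that("greedy policy with the true map walks a shortest path", {
  set.seed(33)
  for (k in 1:5) {
    m <- generate_maze(density = 0.25, id = sprintf("g%d", k))
    T <- true_transition(m)
    V <- value_iteration(m, T, gamma = 0.9, tol = 1e-10, max_iter = 5000)
    d0 <- shortest_path_lengths(m)
    for (i in seq_len(nrow(m$starts))) {
      s <- m$starts[i, ]
      len <- 0
      while (!all(s == m$target) && len <= 100) {
        p <- mb_policy(m, T, V, s, 0.9, 0.001)
        a <- names(p)[which.max(p)]
        s <- s + c(c(N = 0, E = 1, S = 0, W = -1)[[a]],
                   c(N = 1, E = 0, S = -1, W = 0)[[a]])
        len <- len + 1
      }
      expect_equal(len, as.numeric(d0[i]))
    }
  }
})

test_that("navigation visibility updates observe the right cells", {
  m <- wall_maze()
  alpha <- 0.5
  T <- init_transition("navigation", m, p0 = 0.5)
  # first step at an interior cell: all 9 cells of the 3x3 observed
  T1 <- navigation_visibility_update(T, m, c(7, 7), first_step = TRUE,
                                     alpha = alpha)
  changed <- which(T1 != T, arr.ind = TRUE)
  touched_cells <- unique(vapply(seq_len(nrow(changed)), function(i) {
    s <- changed[i, 1]
    a <- colnames(T)[changed[i, 2]]
    .mazerl_succ(m, s, a)
  }, integer(1)))
  expect_setequal(touched_cells,
                  as.integer(cell_index(m, as.matrix(
                    expand.grid(x = 6:8, y = 6:8)))))
  # subsequent step heading N into (4,4): front row is (3,5),(4,5),(5,5)
  T2 <- navigation_visibility_update(T, m, c(4, 4), heading = "N",
                                     first_step = FALSE, alpha = alpha)
  changed2 <- which(T2 != T, arr.ind = TRUE)
  touched2 <- unique(vapply(seq_len(nrow(changed2)), function(i)
    .mazerl_succ(m, changed2[i, 1], colnames(T)[changed2[i, 2]]),
    integer(1)))
  expect_setequal(touched2,
                  as.integer(cell_index(m, rbind(c(3, 5), c(4, 5),
                                                 c(5, 5)))))
  # edge cell: off-grid flanks are skipped
  T3 <- navigation_visibility_update(T, m, c(0, 3), heading = "N",
                                     first_step = FALSE, alpha = alpha)
  changed3 <- which(T3 != T, arr.ind = TRUE)
  touched3 <- unique(vapply(seq_len(nrow(changed3)), function(i)
    .mazerl_succ(m, changed3[i, 1], colnames(T)[changed3[i, 2]]),
    integer(1)))
  expect_setequal(touched3,
                  as.integer(cell_index(m, rbind(c(0, 4), c(1, 4)))))
  expect_error(navigation_visibility_update(T, m, c(4, 4),
                                            first_step = FALSE,
                                            alpha = alpha),
               "heading")
})

test_that("value map reports the per-cell maximum action value", {
  m <- open_maze(5, 5, target = c(4, 4), starts = cbind(0, 0))
  map <- mb_value_map(m, gamma = 0.5)
  expect_equal(dim(map), c(5, 5))
  # a cell at distance d has best action value 0.5^(d-1)
  expect_equal(map[1, 1], 0.5^(manhattan(c(0, 0), c(4, 4)) - 1))
  expect_equal(map[5, 4], 1) # adjacent to target
})
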