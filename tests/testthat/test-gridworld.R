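test_that("boundary geometry of in-bounds and reachable actions", {
  m <- open_maze()
  expect_setequal(in_bounds_actions(m, c(0, 0)), c("N", "E"))
  expect_setequal(in_bounds_actions(m, c(4, 4)), c("N", "E", "S", "W"))
  expect_setequal(in_bounds_actions(m, c(0, 5)), c("N", "E", "S"))
  expect_error(in_bounds_actions(m, c(10, 0)), "out of bounds")

  # blocked north neighbour removes N only
  blk <- matrix(FALSE, 10, 10)
  blk[5, 6] <- TRUE # cell (4,5) blocks N from (4,4)
  mb <- maze(blk, cbind(0, 0), c(9, 9))
  expect_setequal(reachable_actions(mb, c(4, 4)), c("E", "S", "W"))
  expect_setequal(reachable_actions(m, c(4, 4)), c("N", "E", "S", "W"))

  # three blocks plus the corner boundary leave a singleton set
  blk2 <- matrix(FALSE, 10, 10)
  blk2[2, 1] <- TRUE # (1,0): E from (0,0)
  m2 <- maze(blk2, cbind(5, 5), c(9, 9))
  expect_identical(reachable_actions(m2, c(0, 0)), "N")

  # fully walled-in cell flags an empty set
  blk3 <- matrix(FALSE, 10, 10)
  blk3[1, 2] <- TRUE
  blk3[2, 1] <- TRUE
  m3 <- maze(blk3, cbind(5, 5), c(9, 9))
  expect_warning(out <- reachable_actions(m3, c(0, 0)), "walled in")
  expect_length(out, 0)
})

test_that("reachable actions are a subset of in-bounds actions everywhere", {
  set.seed(42)
  for (k in 1:5) {
    m <- generate_maze(density = 0.3, id = sprintf("m%d", k))
    for (s in seq_len(100)) {
      xy <- cell_xy(m, s)
      if (m$blocked[xy[1] + 1, xy[2] + 1]) next
      ra <- suppressWarnings(reachable_actions(m, xy))
      expect_true(all(ra %in% in_bounds_actions(m, xy)))
    }
  }
})

test_that("manhattan distance values and metric properties", {
  expect_identical(manhattan(c(0, 0), c(3, 4)), 7L)
  expect_identical(manhattan(c(2, 5), c(2, 5)), 0L)
  expect_identical(manhattan(c(9, 0), c(0, 9)), 18L)
  set.seed(7)
  pts <- matrix(sample(0:9, 300, replace = TRUE), ncol = 2)
  for (i in seq_len(50)) {
    a <- pts[3 * i - 2, ]
    b <- pts[3 * i - 1, ]
    cc <- pts[3 * i, ]
    expect_identical(manhattan(a, b), manhattan(b, a))
    expect_identical(manhattan(a, b) == 0L, all(a == b))
    expect_true(manhattan(a, cc) <= manhattan(a, b) + manhattan(b, cc))
  }
})

test_that("maze invariants are enforced at construction", {
  blk <- matrix(FALSE, 10, 10)
  blk[10, 10] <- TRUE
  expect_error(maze(blk, cbind(0, 0), c(9, 9)), "target cell is blocked")
  expect_error(maze(matrix(FALSE, 10, 10), cbind(9, 9), c(9, 9)),
               "coincides with the target")
  expect_error(maze(matrix(FALSE, 10, 10), cbind(0, 0), c(10, 3)),
               "out of bounds")
})

test_that("validate_maze agrees with an independent flood-fill oracle", {
  skip_if_not_installed("igraph")
  set.seed(11)
  n_checked <- 0
  for (k in 1:200) {
    # raw random mazes (not rejection-sampled), so invalid ones occur
    blk <- matrix(runif(100) < 0.35, 10, 10)
    open_cells <- which(!blk)
    if (length(open_cells) < 3) next
    pick <- sample(open_cells, 3)
    fake <- list(width = 10L, height = 10L)
    xy <- cell_xy(fake, pick)
    m <- tryCatch(maze(blk, xy[2:3, , drop = FALSE], xy[1, ]),
                  error = function(e) NULL)
    if (is.null(m)) next
    rep <- validate_maze(m)
    # oracle: igraph connectivity over the open-cell lattice
    edges <- NULL
    for (s in open_cells) {
      x <- (s - 1) %% 10
      y <- (s - 1) %/% 10
      if (x < 9 && !blk[x + 2, y + 1]) edges <- c(edges, s, s + 1)
      if (y < 9 && !blk[x + 1, y + 2]) edges <- c(edges, s, s + 10)
    }
    g <- igraph::make_graph(edges, n = 100, directed = FALSE)
    comp <- igraph::components(g)$membership
    ok <- comp[cell_index(m, m$starts)] == comp[cell_index(m, m$target)]
    expect_identical(rep$valid, all(ok))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)
})

test_that("shortest path lengths match igraph distances on a winding maze", {
  skip_if_not_installed("igraph")
  m <- wall_maze()
  expect_true(validate_maze(m)$valid)
  edges <- NULL
  for (s in which(!as.vector(m$blocked))) {
    x <- (s - 1) %% 10
    y <- (s - 1) %/% 10
    if (x < 9 && !m$blocked[x + 2, y + 1]) edges <- c(edges, s, s + 1)
    if (y < 9 && !m$blocked[x + 1, y + 2]) edges <- c(edges, s, s + 10)
  }
  g <- igraph::make_graph(edges, n = 100, directed = FALSE)
  d <- igraph::distances(g, v = cell_index(m, m$starts),
                         to = cell_index(m, m$target))
  expect_equal(shortest_path_lengths(m), as.numeric(d))
})

test_that("maze JSON round-trips identically, including a 25-maze set", {
  set.seed(3)
  mazes <- lapply(1:25, function(i)
    generate_maze(density = 0.25, id = sprintf("M%02d", i)))
  names(mazes) <- sprintf("M%02d", 1:25)
  path <- withr::local_tempfile(fileext = ".json")
  write_maze(mazes, path)
  back <- read_maze(path)
  expect_identical(names(back), names(mazes))
  for (id in names(mazes)) {
    expect_identical(back[[id]]$blocked, mazes[[id]]$blocked)
    expect_identical(back[[id]]$starts, mazes[[id]]$starts)
    expect_identical(back[[id]]$target, mazes[[id]]$target)
  }
  # single maze round trip
  write_maze(mazes[[1]], path)
  one <- read_maze(path)
  expect_identical(one$blocked, mazes[[1]]$blocked)
})

test_that("step-record IO round-trips and rejects schema violations", {
  co <- tiny_cohort(n_mazes = 2L, n_trials = 3L, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_step_records(co$steps, path)
  back <- read_step_records(path, mazes = co$mazes)
  expect_equal(back$contacts, co$steps$contacts)
  expect_equal(back$x, co$steps$x)
  expect_equal(back$duration, co$steps$duration, tolerance = 1e-9)

  # empty contacts field reads as empty string
  expect_true(all(back$contacts[nchar(back$contacts) == 0] == ""))

  # action into a block is rejected with the row named
  bad <- co$steps
  m <- co$mazes[[bad$maze[1]]]
  blocked_cells <- which(as.vector(m$blocked))
  xy <- cell_xy(m, blocked_cells[1])
  # fabricate a row whose action walks into that block
  row <- bad[1, ]
  row$x <- xy[1]
  row$y <- xy[2] - 1
  row$action <- "N"
  if (row$y >= 0) {
    bad2 <- rbind(row, bad[-1, ])
    expect_error(validate_step_records(bad2, co$mazes), "row 1")
  }

  # unknown condition label
  bad3 <- co$steps
  bad3$condition[2] <- "telepathic"
  write_step_records(bad3, path)
  expect_error(read_step_records(path), "condition")

  # non-monotone step index
  bad4 <- co$steps
  tkey <- paste(bad4$participant, bad4$maze, bad4$trial)
  i2 <- which(duplicated(tkey))[1] # second step of some trial
  bad4$step[i2] <- bad4$step[i2 - 1]
  write_step_records(bad4, path)
  expect_error(read_step_records(path), "non-monotone")
})

test_that("the packaged synthetic fixture set loads and validates", {
  maze_file <- system.file("extdata", "synthetic_mazes.json",
                           package = "mazerl")
  step_file <- system.file("extdata", "synthetic_steps.csv",
                           package = "mazerl")
  mazes <- read_maze(maze_file)
  expect_length(mazes, 3)
  for (m in mazes) expect_true(validate_maze(m)$valid)
  steps <- read_step_records(step_file, mazes = mazes)
  expect_equal(length(unique(steps$participant)), 2)
  expect_true(all(steps$condition == "haptic"))
})
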