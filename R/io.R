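# Maze JSON and step-record table I/O.
#
# Maze JSON: {"id", "width", "height", "grid": [[0/1,...],...], "starts":
# [[x,y],...], "target": [x,y]} with grid rows listed south to north and
# 1 marking a blocked cell. A file may hold a single object or an array.
#
# Step tables are CSV/TSV with header columns participant, condition,
# maze, trial, step, x, y, action, contacts, duration. `contacts` is a
# compact direction string ("NW" = tried north, then west, before the
# executed action); empty means no block contact on that step.

.maze_to_list <- function(m) {
  grid <- lapply(seq_len(m$height), function(r)
    as.integer(m$blocked[, r])) # row r = y = r - 1, south to north
  list(id = m$id, width = m$width, height = m$height, grid = grid,
       starts = lapply(seq_len(nrow(m$starts)),
                       function(i) as.integer(m$starts[i, ])),
       target = as.integer(m$target))
}

.maze_from_list <- function(obj) {
  need <- c("id", "width", "height", "grid", "starts", "target")
  miss <- setdiff(need, names(obj))
  if (length(miss) > 0)
    stop("maze JSON missing field(s): ", paste(miss, collapse = ", "))
  width <- as.integer(obj$width)
  height <- as.integer(obj$height)
  grid <- obj$grid
  if (length(grid) != height || any(lengths(grid) != width))
    stop(sprintf("maze '%s': grid is not %d rows of %d values",
                 obj$id, height, width))
  blocked <- matrix(FALSE, width, height)
  for (r in seq_len(height)) blocked[, r] <- as.logical(unlist(grid[[r]]))
  starts <- do.call(rbind, lapply(obj$starts, as.integer))
  maze(blocked, starts, as.integer(obj$target), id = obj$id)
}

#' Write mazes to a JSON file
#'
#' @param m A `maze` or a list of mazes.
#' @param path Output file.
#' @export
write_maze <- function(m, path) {
  obj <- if (inherits(m, "maze")) .maze_to_list(m)
         else lapply(m, .maze_to_list)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read mazes from a JSON file
#'
#' @param path JSON file written by [write_maze()] (single object or
#'   array).
#' @return A `maze`, or a named list of mazes if the file holds an array.
#' @export
read_maze <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(obj$grid)) return(.maze_from_list(obj))
  out <- lapply(obj, .maze_from_list)
  names(out) <- vapply(out, function(m) m$id, character(1))
  out
}

.parse_contacts <- function(txt) {
  txt[is.na(txt)] <- ""
  lapply(strsplit(txt, ""), function(ch) {
    if (length(ch) == 0) character(0) else ch
  })
}

.step_columns <- c("participant", "condition", "maze", "trial", "step",
                   "x", "y", "action", "contacts", "duration")

#' Write step records to a delimited table
#'
#' @param steps Step-record data frame (see [read_step_records()]).
#' @param path Output file.
#' @param sep Field separator ("," or tab).
#' @export
write_step_records <- function(steps, path, sep = ",") {
  steps <- steps[, .step_columns]
  write.table(steps, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Read and validate step records
#'
#' Reads a delimited step table and checks the schema: known condition
#' labels, actions in N/E/S/W, contacts strings over N/E/S/W, and
#' strictly increasing step indices (with non-decreasing trials) within
#' each (participant, maze) block. If `mazes` is supplied the physical
#' checks of [validate_step_records()] are applied as well. Violations
#' are reported with the offending row numbers.
#'
#' @param path Input file.
#' @param mazes Optional named list of `maze` objects for physical
#'   validation.
#' @param sep Field separator.
#' @return A data frame with columns participant, condition, maze, trial,
#'   step, x, y, action, contacts, duration.
#' @export
read_step_records <- function(path, mazes = NULL, sep = ",") {
  steps <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                    colClasses = list(participant = "character",
                                      condition = "character",
                                      maze = "character",
                                      action = "character",
                                      contacts = "character"))
  miss <- setdiff(.step_columns, names(steps))
  if (length(miss) > 0)
    stop("step table missing column(s): ", paste(miss, collapse = ", "))
  steps <- steps[, .step_columns]
  steps$contacts[is.na(steps$contacts)] <- ""
  .check_step_schema(steps)
  if (!is.null(mazes)) validate_step_records(steps, mazes)
  steps
}

.check_step_schema <- function(steps) {
  rows <- seq_len(nrow(steps))
  bad <- rows[!(steps$condition %in% CONDITIONS)]
  if (length(bad) > 0)
    stop("unknown condition label at row(s) ", paste(head(bad, 5),
         collapse = ", "))
  bad <- rows[!(steps$action %in% ACTIONS)]
  if (length(bad) > 0)
    stop("invalid action at row(s) ", paste(head(bad, 5), collapse = ", "))
  ok_contacts <- vapply(.parse_contacts(steps$contacts),
                        function(ch) all(ch %in% ACTIONS), logical(1))
  bad <- rows[!ok_contacts]
  if (length(bad) > 0)
    stop("invalid contacts string at row(s) ", paste(head(bad, 5),
         collapse = ", "))
  key <- paste(steps$participant, steps$maze)
  for (k in unique(key)) {
    idx <- which(key == k)
    tr <- steps$trial[idx]
    st <- steps$step[idx]
    if (any(diff(tr) < 0))
      stop("non-monotone trial index at row ",
           idx[which(diff(tr) < 0)[1] + 1])
    same <- diff(tr) == 0
    if (any(diff(st)[same] <= 0))
      stop("non-monotone step index at row ",
           idx[which(same & diff(st) <= 0)[1] + 1])
  }
  invisible(TRUE)
}

#' Physically validate step records against their mazes
#'
#' Checks, per row, that the state is an open in-bounds cell, that the
#' executed action leads to an open in-bounds cell, and that every listed
#' contact's intended cell is blocked.
#'
#' @param steps Step-record data frame.
#' @param mazes Named list of `maze` objects (names matching
#'   `steps$maze`).
#' @return Invisibly `TRUE`; stops with the offending row number
#'   otherwise.
#' @export
validate_step_records <- function(steps, mazes) {
  contacts <- .parse_contacts(steps$contacts)
  for (i in seq_len(nrow(steps))) {
    m <- mazes[[steps$maze[i]]]
    if (is.null(m)) stop("unknown maze id at row ", i)
    x <- steps$x[i]; y <- steps$y[i]
    if (x < 0 || x >= m$width || y < 0 || y >= m$height)
      stop("state out of bounds at row ", i)
    if (m$blocked[x + 1, y + 1]) stop("state on a blocked cell at row ", i)
    a <- steps$action[i]
    nx <- x + ACTION_DX[[a]]; ny <- y + ACTION_DY[[a]]
    if (nx < 0 || nx >= m$width || ny < 0 || ny >= m$height)
      stop("executed action leaves the grid at row ", i)
    if (m$blocked[nx + 1, ny + 1])
      stop("executed action leads into a block at row ", i)
    for (ca in contacts[[i]]) {
      cx <- x + ACTION_DX[[ca]]; cy <- y + ACTION_DY[[ca]]
      if (cx < 0 || cx >= m$width || cy < 0 || cy >= m$height ||
          !m$blocked[cx + 1, cy + 1])
        stop("contact into a non-blocked cell at row ", i)
    }
  }
  invisible(TRUE)
}
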