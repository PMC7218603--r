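# Headings are absolute compass directions on the map grid; rows grow
# southward so "N" decreases the row index.
HEADINGS <- c("N", "E", "S", "W")

heading_delta <- function(h) {
  switch(h, N = c(-1L, 0L), S = c(1L, 0L), E = c(0L, 1L), W = c(0L, -1L))
}

# Relative direction -> quarter-turns clockwise from the current heading.
direction_turn <- function(direction) {
  switch(direction, forward = 0L, right = 1L, backward = 2L, left = 3L,
         stop("direction must be forward/backward/left/right",
              call. = FALSE))
}

#' Construct a roadmap grid
#'
#' A roadmap is a rectangular street grid on which the patient navigates
#' by relative directions. It carries exactly seven named locations (e.g.
#' butcher, park, school), a start cell and heading, a destination, and --
#' at the high difficulty level -- one-way streets: directed edges that may
#' only be traversed in the stored direction. Cells are indexed 1..n in
#' row-major order.
#'
#' @param nrow,ncol Grid dimensions (each >= 2).
#' @param locations Named integer vector of exactly 7 distinct cells; names
#'   are location labels and must include `destination`.
#' @param start_cell Cell index where the patient starts.
#' @param start_heading One of `"N"`, `"E"`, `"S"`, `"W"`.
#' @param destination Label of the target location.
#' @param one_way Optional data frame with columns `from`, `to`: streets
#'   traversable only from `from` to `to` (cells must be grid-adjacent).
#' @param distractors Character vector of decorative distractor kinds
#'   (metadata only; rendering is out of scope).
#' @return A list of class `dt_roadmap`.
#' @export
roadmap_map <- function(nrow, ncol, locations, start_cell, start_heading,
                        destination, one_way = NULL,
                        distractors = character(0)) {
  nrow <- check_int_range(nrow, 2L, 100L, "nrow")
  ncol <- check_int_range(ncol, 2L, 100L, "ncol")
  n <- nrow * ncol
  if (length(locations) != 7L || anyDuplicated(locations) ||
      is.null(names(locations)) || anyDuplicated(names(locations)) ||
      any(locations < 1L | locations > n)) {
    stop("locations must be 7 distinct named cells on the grid",
         call. = FALSE)
  }
  if (!destination %in% names(locations)) {
    stop("destination must be one of the location labels", call. = FALSE)
  }
  start_cell <- check_int_range(start_cell, 1L, n, "start_cell")
  start_heading <- match.arg(start_heading, HEADINGS)
  if (!is.null(one_way)) {
    stopifnot(is.data.frame(one_way), all(c("from", "to") %in%
                                            names(one_way)))
  }
  m <- structure(
    list(nrow = nrow, ncol = ncol, locations = locations,
         start_cell = start_cell, start_heading = start_heading,
         destination = destination, one_way = one_way,
         distractors = distractors),
    class = "dt_roadmap"
  )
  if (!roadmap_reachable(m)) {
    stop("destination not reachable from start under one-way constraints",
         call. = FALSE)
  }
  m
}

cell_rc <- function(map, cell) {
  c((cell - 1L) %/% map$ncol + 1L, (cell - 1L) %% map$ncol + 1L)
}

rc_cell <- function(map, r, c) as.integer((r - 1L) * map$ncol + c)

# Is traveling from -> to blocked by a one-way street?
one_way_blocked <- function(map, from, to) {
  ow <- map$one_way
  if (is.null(ow) || nrow(ow) == 0L) return(FALSE)
  # an edge listed as (a, b) may only be traversed a -> b
  listed_rev <- any(ow$from == to & ow$to == from)
  listed_fwd <- any(ow$from == from & ow$to == to)
  listed_rev && !listed_fwd
}

#' Take one navigation step on a roadmap
#'
#' The patient states a direction relative to their own current heading
#' ("forward", "backward", "to the left", "to the right"); the engine
#' translates it to an absolute direction, advances one cell, and updates
#' the heading to the direction of movement (so "backward" reverses the
#' heading). A move off the grid or against a one-way street does not move
#' the patient; it is recorded as a route mistake.
#'
#' @param state List with `cell` and `heading` (use
#'   `list(cell = map$start_cell, heading = map$start_heading)` to start).
#' @param direction One of `"forward"`, `"backward"`, `"left"`, `"right"`.
#' @param map A `dt_roadmap`.
#' @return The new state: list with `cell`, `heading`, `moved` (logical),
#'   and `mistake` (logical). On a rejected move `cell` and `heading` are
#'   unchanged.
#' @examples
#' m <- roadmap_map(4, 4, c(a=1,b=2,c=3,d=4,e=5,f=6,g=16),
#'                  start_cell = 13, start_heading = "N",
#'                  destination = "a")
#' s <- roadmap_step(list(cell = 13, heading = "N"), "forward", m)
#' s$cell  # 9: one cell north
#' @export
roadmap_step <- function(state, direction, map) {
  stopifnot(inherits(map, "dt_roadmap"))
  state$cell <- as.integer(state$cell)
  heading <- match.arg(state$heading, HEADINGS)
  turn <- direction_turn(match.arg(direction,
                                   c("forward", "backward", "left",
                                     "right")))
  abs_dir <- HEADINGS[(match(heading, HEADINGS) - 1L + turn) %% 4L + 1L]
  d <- heading_delta(abs_dir)
  rc <- cell_rc(map, state$cell)
  r2 <- rc[1] + d[1]; c2 <- rc[2] + d[2]
  if (r2 < 1L || r2 > map$nrow || c2 < 1L || c2 > map$ncol) {
    return(list(cell = state$cell, heading = state$heading,
                moved = FALSE, mistake = TRUE))
  }
  to <- rc_cell(map, r2, c2)
  if (one_way_blocked(map, state$cell, to)) {
    return(list(cell = state$cell, heading = state$heading,
                moved = FALSE, mistake = TRUE))
  }
  list(cell = to, heading = abs_dir, moved = TRUE, mistake = FALSE)
}

#' Score a roadmap trajectory
#'
#' The assignment is passed only with the correct location and a correct
#' route: the trajectory must end on the destination cell with zero route
#' mistakes (rejected moves). Ending anywhere else, or reaching the
#' destination after a rejected move, fails.
#'
#' @param trajectory Character vector of relative directions.
#' @param map A `dt_roadmap`.
#' @return List with `pass` (logical), `n_mistakes`, `final_cell`, and
#'   `reached_destination`.
#' @export
score_roadmap <- function(trajectory, map) {
  stopifnot(inherits(map, "dt_roadmap"))
  state <- list(cell = map$start_cell, heading = map$start_heading)
  n_mistakes <- 0L
  for (d in trajectory) {
    state <- roadmap_step(state, d, map)
    if (state$mistake) n_mistakes <- n_mistakes + 1L
  }
  dest_cell <- unname(map$locations[[map$destination]])
  reached <- state$cell == dest_cell
  list(pass = reached && n_mistakes == 0L,
       n_mistakes = n_mistakes,
       final_cell = state$cell,
       reached_destination = reached)
}

# Breadth-first search respecting one-way streets; used to validate that
# generated maps are solvable.
roadmap_reachable <- function(map, from = map$start_cell,
                              to = unname(map$locations[[map$destination]])) {
  n <- map$nrow * map$ncol
  seen <- logical(n)
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    if (cur == to) return(TRUE)
    rc <- cell_rc(map, cur)
    for (h in HEADINGS) {
      d <- heading_delta(h)
      r2 <- rc[1] + d[1]; c2 <- rc[2] + d[2]
      if (r2 < 1L || r2 > map$nrow || c2 < 1L || c2 > map$ncol) next
      nxt <- rc_cell(map, r2, c2)
      if (!seen[nxt] && !one_way_blocked(map, cur, nxt)) {
        seen[nxt] <- TRUE
        queue <- c(queue, nxt)
      }
    }
  }
  FALSE
}

#' Find a mistake-free route on a roadmap
#'
#' Shortest legal path from the start to the destination, returned as the
#' relative directions a patient would state. Used by simulated responders
#' and as a solvability oracle.
#'
#' @param map A `dt_roadmap`.
#' @return Character vector of relative directions, or `NULL` if the
#'   destination is unreachable.
#' @export
roadmap_solve <- function(map) {
  stopifnot(inherits(map, "dt_roadmap"))
  dest <- unname(map$locations[[map$destination]])
  # BFS over (cell, heading) states since relative moves depend on heading
  key <- function(cell, heading) paste0(cell, ":", heading)
  start <- list(cell = map$start_cell, heading = map$start_heading)
  queue <- list(list(state = start, path = character(0)))
  seen <- new.env(parent = emptyenv())
  assign(key(start$cell, start$heading), TRUE, envir = seen)
  dirs <- c("forward", "left", "right", "backward")
  while (length(queue)) {
    node <- queue[[1L]]; queue <- queue[-1L]
    if (node$state$cell == dest) return(node$path)
    for (d in dirs) {
      nxt <- roadmap_step(node$state, d, map)
      if (!nxt$moved) next
      k <- key(nxt$cell, nxt$heading)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <-
          list(state = nxt, path = c(node$path, d))
      }
    }
  }
  NULL
}
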