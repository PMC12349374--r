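DIR_DELTA <- list(UP = c(0L, -1L), DOWN = c(0L, 1L),
                  LEFT = c(-1L, 0L), RIGHT = c(1L, 0L))

#' Maze definition
#'
#' A discrete grid world mirroring the therapy display: cells are addressed
#' by 0-based `(x, y)` with y increasing downward. A maze has a start cell,
#' a finish region, a set of blocked (wall) cells and numbered zones; three
#' ordered checkpoints (two zone ids plus the finish line, written `"F"`)
#' define the timing targets of one level.
#'
#' @param level Level number, 1-5.
#' @param width,height Grid extent in cells (the physical display is
#'   128 x 64; fixture layouts use smaller grids).
#' @param walls `n x 2` integer matrix of blocked cells (may be empty).
#' @param start Length-2 start cell; must not be a wall.
#' @param finish `m x 2` matrix of finish cells (non-empty, reachable from
#'   `start`).
#' @param zones Named list mapping zone id (e.g. `"2"`) to an `m x 2`
#'   matrix of member cells. Zones must not overlap.
#' @param checkpoints Character vector of length 3: two zone ids present in
#'   `zones`, then `"F"`.
#' @return An object of class `"maze"`.
#' @export
maze <- function(level, width, height, walls, start, finish, zones,
                 checkpoints) {
  stopifnot(length(level) == 1L, level >= 1, level <= 5,
            width >= 2, height >= 2)
  walls <- as_cell_matrix(walls)
  finish <- as_cell_matrix(finish)
  start <- as.integer(start)
  if (nrow(finish) == 0L) stop("finish region must be non-empty", call. = FALSE)
  if (length(checkpoints) != 3L || checkpoints[3] != "F") {
    stop("checkpoints must be two zone ids followed by \"F\"", call. = FALSE)
  }
  zones <- lapply(zones, as_cell_matrix)
  missing_z <- setdiff(checkpoints[1:2], names(zones))
  if (length(missing_z) > 0L) {
    stop(sprintf("checkpoint zone(s) %s not defined in zones",
                 paste(missing_z, collapse = ", ")), call. = FALSE)
  }

  wall_m <- matrix(FALSE, nrow = width, ncol = height)
  if (nrow(walls) > 0L) wall_m[walls + 1L] <- TRUE
  finish_m <- matrix(FALSE, nrow = width, ncol = height)
  finish_m[finish + 1L] <- TRUE
  zone_m <- matrix(NA_character_, nrow = width, ncol = height)
  for (zid in names(zones)) {
    idx <- zones[[zid]] + 1L
    if (any(!is.na(zone_m[idx]))) {
      stop(sprintf("zone %s overlaps another zone", zid), call. = FALSE)
    }
    zone_m[idx] <- zid
  }

  m <- structure(list(level = as.integer(level), width = as.integer(width),
                      height = as.integer(height), walls = walls,
                      start = start, finish = finish, zones = zones,
                      checkpoints = as.character(checkpoints),
                      wall_m = wall_m, finish_m = finish_m, zone_m = zone_m),
                 class = "maze")
  if (is_wall(m, start)) stop("start cell is a wall", call. = FALSE)
  if (!any(apply(finish, 1, function(f) !is_wall(m, f)))) {
    stop("finish region is entirely walled", call. = FALSE)
  }
  if (is.null(shortest_path(m, start, finish))) {
    stop("finish region is not reachable from start", call. = FALSE)
  }
  m
}

as_cell_matrix <- function(cells) {
  if (is.null(cells) || (is.list(cells) && length(cells) == 0L)) {
    return(matrix(integer(0), ncol = 2))
  }
  m <- as_point_matrix(cells)
  storage.mode(m) <- "integer"
  m
}

in_bounds <- function(maze, cell) {
  cell[1] >= 0L && cell[1] < maze$width && cell[2] >= 0L && cell[2] < maze$height
}

is_wall <- function(maze, cell) {
  !in_bounds(maze, cell) || maze$wall_m[cell[1] + 1L, cell[2] + 1L]
}

zone_at <- function(maze, cell) {
  if (!in_bounds(maze, cell)) return(NA_character_)
  maze$zone_m[cell[1] + 1L, cell[2] + 1L]
}

in_finish <- function(maze, cell) {
  in_bounds(maze, cell) && maze$finish_m[cell[1] + 1L, cell[2] + 1L]
}

#' Checkpoint zones per level
#'
#' The fixed mapping of the five therapy levels to their three timing
#' checkpoints (two numbered zones, then the finish line).
#'
#' @param level Integer 1-5.
#' @return Character vector of length 3, e.g. `c("2", "4", "F")`.
#' @export
checkpoints_for_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level != as.integer(level) || level < 1 || level > 5) {
    stop("level must be an integer between 1 and 5", call. = FALSE)
  }
  map <- list(`1` = c("2", "4", "F"), `2` = c("3", "7", "F"),
              `3` = c("6", "11", "F"), `4` = c("3", "7", "F"),
              `5` = c("9", "6", "F"))
  map[[as.character(as.integer(level))]]
}

#' Ball state
#'
#' @param pos Length-2 cell position (0-based).
#' @param step Cells moved per simulation tick (>= 1).
#' @param tick_ms Milliseconds per tick (> 0).
#' @return An object of class `"ball_state"`.
#' @export
ball_state <- function(pos, step = 1L, tick_ms = 100) {
  stopifnot(length(pos) == 2L, step >= 1, tick_ms > 0)
  structure(list(pos = as.integer(pos), step = as.integer(step),
                 tick_ms = tick_ms),
            class = "ball_state")
}

empty_events <- function() {
  tibble::tibble(kind = character(), t_ms = numeric(), zone_id = character())
}

#' Advance the ball by one command tick
#'
#' `"STAY"` leaves the position unchanged and emits no events. A
#' directional command attempts to move `ball$step` cells; if any
#' traversed cell is a wall (or out of bounds) the ball stops at the last
#' free cell and exactly one `COLLISION` event is emitted for the tick.
#' Moving into a numbered zone emits `ZONE_ENTER`; if that zone is the
#' pending checkpoint a `CHECKPOINT` event is also emitted; moving into
#' the finish region emits `FINISH`.
#'
#' @param maze A [maze()].
#' @param ball A [ball_state()].
#' @param cmd One of `"UP"`, `"DOWN"`, `"LEFT"`, `"RIGHT"`, `"STAY"`.
#' @param pending The pending checkpoint zone id (or `NULL` when
#'   checkpoint tracking is handled by the caller).
#' @param t_ms Elapsed milliseconds to stamp on emitted events.
#' @return A list with elements `ball` (updated state) and `events`
#'   (tibble with columns `kind`, `t_ms`, `zone_id`).
#' @export
maze_step <- function(maze, ball, cmd, pending = NULL, t_ms = 0) {
  stopifnot(inherits(maze, "maze"), inherits(ball, "ball_state"))
  cmd <- match.arg(cmd, COMMANDS)
  if (cmd == "STAY") {
    return(list(ball = ball, events = empty_events()))
  }
  delta <- DIR_DELTA[[cmd]]
  pos <- ball$pos
  collided <- FALSE
  for (i in seq_len(ball$step)) {
    nxt <- pos + delta
    if (is_wall(maze, nxt)) {
      collided <- TRUE
      break
    }
    pos <- nxt
  }
  ev <- list()
  if (collided) {
    ev[[length(ev) + 1L]] <- tibble::tibble(kind = "COLLISION", t_ms = t_ms,
                                            zone_id = NA_character_)
  }
  z_from <- zone_at(maze, ball$pos)
  z_to <- zone_at(maze, pos)
  if (!is.na(z_to) && (is.na(z_from) || z_from != z_to)) {
    ev[[length(ev) + 1L]] <- tibble::tibble(kind = "ZONE_ENTER", t_ms = t_ms,
                                            zone_id = z_to)
    if (!is.null(pending) && pending != "F" && z_to == pending) {
      ev[[length(ev) + 1L]] <- tibble::tibble(kind = "CHECKPOINT", t_ms = t_ms,
                                              zone_id = z_to)
    }
  }
  if (in_finish(maze, pos) && !in_finish(maze, ball$pos)) {
    ev[[length(ev) + 1L]] <- tibble::tibble(kind = "FINISH", t_ms = t_ms,
                                            zone_id = NA_character_)
  }
  new_ball <- ball
  new_ball$pos <- pos
  list(ball = new_ball,
       events = if (length(ev)) do.call(rbind, ev) else empty_events())
}

#' Run one maze level from a command stream
#'
#' Consumes commands tick by tick until the ball reaches the finish region
#' or the stream is exhausted (an aborted level: progress so far is
#' recorded, `total_ms` is `NA`). Event times are `ticks_elapsed x tick_ms`
#' measured from level start.
#'
#' @param maze A [maze()].
#' @param commands Character vector of commands.
#' @param tick_ms Milliseconds per tick.
#' @param step Cells per tick.
#' @param collect_telemetry If `TRUE`, a per-tick telemetry tibble is
#'   attached (`t_ms`, `level`, `errors`, `ball_x`, `ball_y`, `dist_mm`,
#'   `cmd`).
#' @param dist_mm Optional per-tick distance readings recycled into the
#'   telemetry.
#' @return An object of class `"level_result"`: `level`,
#'   `checkpoint_times` (length 3, ms, `NA` when not reached), `total_ms`,
#'   `errors`, `ticks`, `tick_ms`, `completed`, `events`, `telemetry`.
#' @export
run_level <- function(maze, commands, tick_ms = 100, step = 1L,
                      collect_telemetry = FALSE, dist_mm = NULL) {
  stopifnot(inherits(maze, "maze"))
  ball <- ball_state(maze$start, step = step, tick_ms = tick_ms)
  pending_idx <- 1L
  cps <- maze$checkpoints
  cp_times <- rep(NA_real_, 3L)
  errors <- 0L
  all_events <- list()
  telem <- if (collect_telemetry) vector("list", length(commands)) else NULL
  ticks <- 0L
  completed <- FALSE
  for (i in seq_along(commands)) {
    ticks <- i
    t_now <- i * tick_ms
    pending <- if (pending_idx <= 3L) cps[pending_idx] else NULL
    res <- maze_step(maze, ball, commands[i], pending = pending, t_ms = t_now)
    ball <- res$ball
    ev <- res$events
    if (nrow(ev) > 0L) {
      errors <- errors + sum(ev$kind == "COLLISION")
      if (any(ev$kind == "CHECKPOINT") && pending_idx <= 2L) {
        cp_times[pending_idx] <- t_now
        pending_idx <- pending_idx + 1L
      }
      all_events[[length(all_events) + 1L]] <- ev
    }
    if (collect_telemetry) {
      telem[[i]] <- tibble::tibble(
        t_ms = t_now, level = maze$level, errors = errors,
        ball_x = ball$pos[1], ball_y = ball$pos[2],
        dist_mm = if (is.null(dist_mm)) NA_real_ else
          dist_mm[(i - 1L) %% length(dist_mm) + 1L],
        cmd = commands[i])
    }
    if (nrow(ev) > 0L && any(ev$kind == "FINISH")) {
      cp_times[3L] <- t_now
      completed <- TRUE
      break
    }
  }
  structure(list(
    level = maze$level,
    checkpoint_times = cp_times,
    total_ms = if (completed) cp_times[3L] else NA_real_,
    errors = errors,
    ticks = ticks,
    tick_ms = tick_ms,
    completed = completed,
    events = if (length(all_events)) do.call(rbind, all_events)
             else empty_events(),
    telemetry = if (collect_telemetry)
      do.call(rbind, telem[!vapply(telem, is.null, logical(1))]) else NULL
  ), class = "level_result")
}

#' Run a full therapy session over ordered maze levels
#'
#' Levels are played in order; if a level is not completed (its command
#' stream runs out) the session is aborted there and the progress made up
#' to the last level is recorded.
#'
#' @param mazes List of [maze()] objects ordered by level.
#' @param command_source Either a list of command vectors (one per level)
#'   or a function `function(maze)` returning the command vector for that
#'   level (e.g. [maze_bot()]).
#' @param user_id,mode,started_at Session metadata; `mode` is canonicalized
#'   with [therapy_mode()].
#' @param gaze Optional gaze trace tibble attached to the record.
#' @param dist_mm Optional distance readings (mm) attached to the record.
#' @inheritParams run_level
#' @return An object of class `"session_record"` with fields `user_id`,
#'   `mode`, `started_at`, `levels` (list of `level_result`), `gaze`,
#'   `dist_mm`, `completed`.
#' @export
run_session <- function(mazes, command_source, tick_ms = 100, step = 1L,
                        user_id = NA_character_, mode = "Bin",
                        started_at = NA_character_, gaze = NULL,
                        dist_mm = NULL, collect_telemetry = FALSE) {
  mode <- therapy_mode(mode)
  results <- list()
  for (i in seq_along(mazes)) {
    m <- mazes[[i]]
    if (!is.function(command_source) && i > length(command_source)) break
    cmds <- if (is.function(command_source)) command_source(m)
            else command_source[[i]]
    if (is.null(cmds)) break
    lr <- run_level(m, cmds, tick_ms = tick_ms, step = step,
                    collect_telemetry = collect_telemetry, dist_mm = dist_mm)
    results[[length(results) + 1L]] <- lr
    if (!lr$completed) break
  }
  structure(list(user_id = user_id, mode = mode, started_at = started_at,
                 levels = results, gaze = gaze, dist_mm = dist_mm,
                 completed = length(results) == length(mazes) &&
                   all(vapply(results, function(r) r$completed, logical(1)))),
            class = "session_record")
}

# breadth-first shortest path on the grid; targets is an m x 2 matrix.
# Returns the command sequence, or NULL when unreachable.
shortest_path <- function(maze, from, targets) {
  w <- maze$width; h <- maze$height
  idx <- function(cell) cell[1] + 1L + cell[2] * w
  target_set <- rep(FALSE, w * h)
  for (i in seq_len(nrow(targets))) {
    tc <- targets[i, ]
    if (!is_wall(maze, tc)) target_set[idx(tc)] <- TRUE
  }
  if (!any(target_set)) return(NULL)
  if (target_set[idx(from)]) return(character(0))
  prev <- rep(NA_integer_, w * h)
  prev_cmd <- rep(NA_character_, w * h)
  visited <- rep(FALSE, w * h)
  visited[idx(from)] <- TRUE
  queue <- idx(from)
  dirs <- names(DIR_DELTA)
  while (length(queue) > 0L) {
    cur <- queue[1L]
    queue <- queue[-1L]
    cx <- (cur - 1L) %% w
    cy <- (cur - 1L) %/% w
    for (d in dirs) {
      nxt <- c(cx, cy) + DIR_DELTA[[d]]
      if (is_wall(maze, nxt)) next
      ni <- idx(nxt)
      if (visited[ni]) next
      visited[ni] <- TRUE
      prev[ni] <- cur
      prev_cmd[ni] <- d
      if (target_set[ni]) {
        cmds <- character(0)
        node <- ni
        while (!is.na(prev[node])) {
          cmds <- c(prev_cmd[node], cmds)
          node <- prev[node]
        }
        return(cmds)
      }
      queue <- c(queue, ni)
    }
  }
  NULL
}
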