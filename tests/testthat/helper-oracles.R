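# independent oracles and tiny fixtures used across the suite

# exhaustive minimum enclosing circle: try every circle defined by a pair
# (as diameter) or a triple (circumcircle) of points, keep the smallest
# one that covers the whole set
brute_force_mec <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  if (n == 1L) return(list(center = pts[1, ], radius = 0))
  covers <- function(center, radius) {
    all(sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2) <=
          radius + tol)
  }
  best <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    center <- (pts[i, ] + pts[j, ]) / 2
    radius <- sqrt(sum((pts[i, ] - center)^2))
    if (covers(center, radius) &&
        (is.null(best) || radius < best$radius)) {
      best <- list(center = center, radius = radius)
    }
  }
  if (n >= 3L) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- pts[i, ]; b <- pts[j, ]; ccc <- pts[k, ]
      d <- 2 * (a[1] * (b[2] - ccc[2]) + b[1] * (ccc[2] - a[2]) +
                  ccc[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(ccc^2)
      center <- c(
        (a2 * (b[2] - ccc[2]) + b2 * (ccc[2] - a[2]) + c2 * (a[2] - b[2])) / d,
        (a2 * (ccc[1] - b[1]) + b2 * (a[1] - ccc[1]) + c2 * (b[1] - a[1])) / d)
      radius <- sqrt(sum((a - center)^2))
      if (covers(center, radius) &&
          (is.null(best) || radius < best$radius)) {
        best <- list(center = center, radius = radius)
      }
    }
  }
  best
}

# reference single-step command interpreter: replays a command log and
# counts blocked moves, independent of the engine's event machinery
replay_errors <- function(m, commands, stop_at_finish = TRUE) {
  pos <- m$start
  errors <- 0L
  blocked <- function(cell) {
    cell[1] < 0 || cell[1] >= m$width || cell[2] < 0 || cell[2] >= m$height ||
      any(m$walls[, 1] == cell[1] & m$walls[, 2] == cell[2])
  }
  deltas <- list(UP = c(0, -1), DOWN = c(0, 1), LEFT = c(-1, 0),
                 RIGHT = c(1, 0))
  for (cmd in commands) {
    if (cmd == "STAY") next
    nxt <- pos + deltas[[cmd]]
    if (blocked(nxt)) errors <- errors + 1L else pos <- nxt
    if (stop_at_finish &&
        any(m$finish[, 1] == pos[1] & m$finish[, 2] == pos[2])) break
  }
  list(pos = pos, errors = errors)
}

# 5x5 test maze: one interior wall column with a gap, start left,
# finish right, two single-cell checkpoint zones
tiny_maze <- function() {
  maze(level = 1, width = 5, height = 5,
       walls = rbind(c(2, 0), c(2, 1), c(2, 3), c(2, 4)),
       start = c(0, 2),
       finish = rbind(c(4, 2)),
       zones = list(`2` = rbind(c(1, 2)), `4` = rbind(c(3, 2))),
       checkpoints = c("2", "4", "F"))
}

# straight walled corridor: 10 moves from start to finish
corridor_maze <- function() {
  maze(level = 1, width = 12, height = 3,
       walls = cbind(rep(0:11, 2), rep(c(0, 2), each = 12)),
       start = c(0, 1), finish = rbind(c(10, 1)),
       zones = list(`2` = rbind(c(3, 1)), `4` = rbind(c(6, 1))),
       checkpoints = c("2", "4", "F"))
}

random_gaze_sample <- function(lat, ap) {
  tibble::tibble(t_ms = 0, ratio_right = lat, ratio_V_right = ap,
                 ratio_left = lat, ratio_V_left = ap,
                 ratio_bin = lat, ratio_V_bin = ap, dist_mm = NA_real_)
}

# pick n collision-script ticks for maze_bot: clean-path positions that
# face at least one wall, shifted to account for earlier insertions
bump_script <- function(m, n) {
  cmds <- maze_bot(m)
  deltas <- list(UP = c(0, -1), DOWN = c(0, 1), LEFT = c(-1, 0),
                 RIGHT = c(1, 0))
  blocked <- function(cell) {
    cell[1] < 0 || cell[1] >= m$width || cell[2] < 0 || cell[2] >= m$height ||
      any(m$walls[, 1] == cell[1] & m$walls[, 2] == cell[2])
  }
  pos <- m$start
  ks <- integer(0)
  for (k in seq_along(cmds)) {
    if (any(vapply(deltas, function(d) blocked(pos + d), logical(1)))) {
      ks <- c(ks, k)
    }
    if (length(ks) == n) break
    pos <- pos + deltas[[cmds[k]]]
  }
  stopifnot(length(ks) == n)
  data.frame(tick = ks + seq_len(n) - 1L, dir = NA)
}
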