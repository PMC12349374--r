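#' Synthetic eye geometry
#'
#' Fixed contour landmarks used to render synthetic landmark frames. The
#' defaults place a right eye of width 0.12 and height 0.06 (normalized
#' image units) left of the image midline and mirror it for the left eye
#' — proportions typical of a face-mesh detection at 40-50 cm. The iris
#' radius must be smaller than half of both extents so the rendered iris
#' stays inside the contour box.
#'
#' @param side `"right"` or `"left"` selects the mirrored default.
#' @param outer,inner,upper,lower Optional landmark overrides
#'   (length-2 numeric).
#' @param iris_radius Iris circle radius in normalized units.
#' @return An object of class `"eye_geometry"`.
#' @export
eye_geometry <- function(side = c("right", "left"), outer = NULL,
                         inner = NULL, upper = NULL, lower = NULL,
                         iris_radius = 0.02) {
  side <- match.arg(side)
  if (side == "right") {
    if (is.null(outer)) outer <- c(0.30, 0.50)
    if (is.null(inner)) inner <- c(0.42, 0.50)
    if (is.null(upper)) upper <- c(0.36, 0.47)
    if (is.null(lower)) lower <- c(0.36, 0.53)
  } else {
    if (is.null(outer)) outer <- c(0.70, 0.50)
    if (is.null(inner)) inner <- c(0.58, 0.50)
    if (is.null(upper)) upper <- c(0.64, 0.47)
    if (is.null(lower)) lower <- c(0.64, 0.53)
  }
  width <- abs(inner[1] - outer[1])
  height <- abs(lower[2] - upper[2])
  if (width <= 0 || height <= 0) {
    stop("eye geometry must have positive width and height", call. = FALSE)
  }
  if (iris_radius >= width / 2 || iris_radius >= height / 2) {
    stop("iris_radius must be smaller than half the eye extents",
         call. = FALSE)
  }
  structure(list(side = side, outer = outer, inner = inner, upper = upper,
                 lower = lower, iris_radius = iris_radius,
                 width = width, height = height),
            class = "eye_geometry")
}

# place the pupil so the gaze module recovers (lat, ap) exactly
pupil_from_ratios <- function(lat, ap, geom) {
  sgn <- sign(geom$inner[1] - geom$outer[1])
  c(geom$outer[1] + sgn * lat * geom$width,
    geom$upper[2] + (-ap) * geom$height)
}

render_eye <- function(lat, ap, geom, jitter = c(0, 0)) {
  p <- pupil_from_ratios(lat, ap, geom) + jitter
  ang <- c(0, 0.5, 1, 1.5) * pi
  iris <- cbind(p[1] + geom$iris_radius * cos(ang),
                p[2] + geom$iris_radius * sin(ang))
  eye_landmarks(iris, geom$outer, geom$inner, geom$upper, geom$lower)
}

#' Render landmark frames from programmed gaze ratios
#'
#' The inverse of the gaze module's ratio construction: each (lateral,
#' anteroposterior) pair is turned into a pupil position inside the eye
#' contour and the iris is rendered as 4 points on the iris circle, so
#' that [gaze_sample()] recovers the programmed ratios exactly in the
#' noise-free case. Optional Gaussian noise jitters the pupil *position*
#' (not the ratios), scaled so that `noise_sd` is the induced standard
#' deviation in ratio units on each axis.
#'
#' @param ratios A data frame with columns `lat_right`, `ap_right`,
#'   `lat_left`, `ap_left` (one row per frame), or a single length-2
#'   vector `c(lat, ap)` applied to both eyes.
#' @param geom_right,geom_left [eye_geometry()] objects.
#' @param sample_hz Sampling rate; timestamps are `round(1000 * i / hz)`.
#' @param t0_ms Timestamp of the first frame.
#' @param noise_sd Length-2 numeric: ratio-unit noise on the lateral and
#'   anteroposterior axes.
#' @param dist_mm Optional distance reading stamped on every frame.
#' @return A list of [landmark_frame()] objects.
#' @export
landmark_frames_from_ratios <- function(ratios,
                                        geom_right = eye_geometry("right"),
                                        geom_left = eye_geometry("left"),
                                        sample_hz = 30, t0_ms = 0,
                                        noise_sd = c(0, 0),
                                        dist_mm = NULL) {
  if (is.numeric(ratios) && length(ratios) == 2L) {
    ratios <- data.frame(lat_right = ratios[1], ap_right = ratios[2],
                         lat_left = ratios[1], ap_left = ratios[2])
  }
  need <- c("lat_right", "ap_right", "lat_left", "ap_left")
  miss <- setdiff(need, names(ratios))
  if (length(miss) > 0L) {
    stop(sprintf("ratios is missing column(s) %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  lat_ok <- all(ratios$lat_right >= 0 & ratios$lat_right <= 1 &
                ratios$lat_left >= 0 & ratios$lat_left <= 1)
  ap_ok <- all(ratios$ap_right >= -1 & ratios$ap_right <= 0 &
               ratios$ap_left >= -1 & ratios$ap_left <= 0)
  if (!lat_ok || !ap_ok) {
    stop("programmed ratios outside legal ranges ([0,1] lateral, [-1,0] anteroposterior)",
         call. = FALSE)
  }
  n <- nrow(ratios)
  noise_sd <- rep(noise_sd, length.out = 2L)
  jit <- function(geom) {
    if (all(noise_sd == 0)) {
      matrix(0, nrow = n, ncol = 2)
    } else {
      cbind(stats::rnorm(n, 0, noise_sd[1] * geom$width),
            stats::rnorm(n, 0, noise_sd[2] * geom$height))
    }
  }
  jr <- jit(geom_right)
  jl <- jit(geom_left)
  lapply(seq_len(n), function(i) {
    landmark_frame(
      t_ms = t0_ms + round(1000 * (i - 1) / sample_hz),
      right = render_eye(ratios$lat_right[i], ratios$ap_right[i], geom_right,
                         jr[i, ]),
      left = render_eye(ratios$lat_left[i], ratios$ap_left[i], geom_left,
                        jl[i, ]),
      dist_mm = dist_mm)
  })
}

#' Specification of a synthetic gaze trace
#'
#' Describes sinusoidal lateral and anteroposterior pupil trajectories
#' with optional per-eye offsets and additive pupil-position noise. With
#' a fixed `seed`, generation is fully reproducible.
#'
#' @param duration_s Trace duration in seconds.
#' @param sample_hz Sampling rate (the original device's rate is not
#'   published; 30 Hz is the default here).
#' @param lat,ap Waveform descriptions: lists with elements `center`,
#'   `amplitude`, `period_s` and optional `phase` (radians).
#' @param noise_sd Length-2 ratio-unit noise (lateral, anteroposterior).
#' @param seed Integer RNG seed.
#' @param binocular_offset List with optional `lat_center`, `ap_center`
#'   (added to the left eye's centers) and `phase` (added to the left
#'   eye's phases), to emulate non-co-occurring binocular extremes.
#' @return An object of class `"trace_spec"`.
#' @export
trace_spec <- function(duration_s = 10, sample_hz = 30,
                       lat = list(center = 0.5, amplitude = 0.2,
                                  period_s = 4, phase = 0),
                       ap = list(center = -0.5, amplitude = 0.15,
                                 period_s = 5, phase = 0),
                       noise_sd = c(0, 0), seed = 1L,
                       binocular_offset = list(lat_center = 0, ap_center = 0,
                                               phase = 0)) {
  stopifnot(duration_s > 0, sample_hz > 0)
  wave_ok <- function(w, lo, hi) {
    w$phase <- w$phase %||% 0
    if (w$center - abs(w$amplitude) < lo || w$center + abs(w$amplitude) > hi) {
      stop("waveform amplitude pushes ratios outside legal range",
           call. = FALSE)
    }
    w
  }
  off <- list(lat_center = binocular_offset$lat_center %||% 0,
              ap_center = binocular_offset$ap_center %||% 0,
              phase = binocular_offset$phase %||% 0)
  lat2 <- lat; lat2$center <- lat$center + off$lat_center
  ap2 <- ap; ap2$center <- ap$center + off$ap_center
  structure(list(duration_s = duration_s, sample_hz = sample_hz,
                 lat = wave_ok(lat, 0, 1), ap = wave_ok(ap, -1, 0),
                 noise_sd = rep(noise_sd, length.out = 2L),
                 seed = as.integer(seed),
                 binocular_offset = off,
                 lat_left = wave_ok(lat2, 0, 1), ap_left = wave_ok(ap2, -1, 0)),
            class = "trace_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

eval_wave <- function(w, t_s) {
  w$center + w$amplitude * sin(2 * pi * t_s / w$period_s + (w$phase %||% 0))
}

#' Generate a synthetic gaze trace
#'
#' Evaluates the waveforms of a [trace_spec()] on a regular time grid,
#' renders landmark frames via [landmark_frames_from_ratios()], and
#' returns both the frames and the programmed ground-truth ratios.
#'
#' @param spec A [trace_spec()].
#' @param geom_right,geom_left [eye_geometry()] objects.
#' @param dist_mm Optional distance stamped on frames.
#' @return List with elements `frames` (landmark frames) and `truth`
#'   (tibble: `t_ms`, `lat_right`, `ap_right`, `lat_left`, `ap_left`).
#' @export
generate_trace <- function(spec, geom_right = eye_geometry("right"),
                           geom_left = eye_geometry("left"), dist_mm = NULL) {
  stopifnot(inherits(spec, "trace_spec"))
  n <- max(1L, floor(spec$duration_s * spec$sample_hz))
  t_s <- (seq_len(n) - 1) / spec$sample_hz
  phase_off <- spec$binocular_offset$phase
  lat_l <- spec$lat_left; lat_l$phase <- (lat_l$phase %||% 0) + phase_off
  ap_l <- spec$ap_left; ap_l$phase <- (ap_l$phase %||% 0) + phase_off
  truth <- tibble::tibble(
    t_ms = round(1000 * t_s),
    lat_right = eval_wave(spec$lat, t_s),
    ap_right = eval_wave(spec$ap, t_s),
    lat_left = eval_wave(lat_l, t_s),
    ap_left = eval_wave(ap_l, t_s))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  frames <- withr_seed(
    landmark_frames_from_ratios(truth, geom_right, geom_left,
                                sample_hz = spec$sample_hz,
                                noise_sd = spec$noise_sd, dist_mm = dist_mm))
  list(frames = frames, truth = truth)
}

#' Generate the fixation validation protocol
#'
#' Emulates the five-point fixation protocol used to validate tracking:
#' each trial fixates three anteroposterior targets in sequence (top,
#' center, bottom) and, in separate trials, three lateral targets (right,
#' center, left), holding each point for `dwell_s` seconds; the whole
#' protocol is repeated `trials` times per axis.
#'
#' @param trials Repeats per axis (default 5).
#' @param dwell_s Seconds of steady gaze per fixation point (default 10).
#' @param sample_hz Sampling rate.
#' @param targets_lat Named lateral targets `(right, center, left)` in
#'   ratio units.
#' @param targets_ap Named anteroposterior targets `(top, center, bottom)`.
#' @param noise_sd Length-2 ratio-unit fixation jitter.
#' @param seed Integer RNG seed.
#' @param user Optional user label attached to the output.
#' @return List with `frames` (landmark frames over the whole protocol)
#'   and `labels` (tibble: `t_ms`, `user`, `axis` (`"AP"`/`"LAT"`),
#'   `trial`, `segment`, `target_lat`, `target_ap`).
#' @export
generate_fixation_protocol <- function(trials = 5, dwell_s = 10,
                                       sample_hz = 30,
                                       targets_lat = c(right = 0.75,
                                                       center = 0.5,
                                                       left = 0.25),
                                       targets_ap = c(top = -0.25,
                                                      center = -0.5,
                                                      bottom = -0.75),
                                       noise_sd = c(0, 0), seed = 1L,
                                       user = "synthetic") {
  n_seg <- max(1L, floor(dwell_s * sample_hz))
  schedule <- list()
  for (trial in seq_len(trials)) {
    for (seg in names(targets_ap)) {
      schedule[[length(schedule) + 1L]] <- list(
        axis = "AP", trial = trial, segment = seg,
        lat = 0.5, ap = unname(targets_ap[seg]))
    }
  }
  for (trial in seq_len(trials)) {
    for (seg in names(targets_lat)) {
      schedule[[length(schedule) + 1L]] <- list(
        axis = "LAT", trial = trial, segment = seg,
        lat = unname(targets_lat[seg]), ap = -0.5)
    }
  }
  n_total <- length(schedule) * n_seg
  idx <- rep(seq_along(schedule), each = n_seg)
  labels <- tibble::tibble(
    t_ms = round(1000 * (seq_len(n_total) - 1) / sample_hz),
    user = user,
    axis = vapply(schedule, `[[`, character(1), "axis")[idx],
    trial = vapply(schedule, `[[`, numeric(1), "trial")[idx],
    segment = vapply(schedule, `[[`, character(1), "segment")[idx],
    target_lat = vapply(schedule, `[[`, numeric(1), "lat")[idx],
    target_ap = vapply(schedule, `[[`, numeric(1), "ap")[idx])
  ratios <- data.frame(lat_right = labels$target_lat,
                       ap_right = labels$target_ap,
                       lat_left = labels$target_lat,
                       ap_left = labels$target_ap)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  frames <- landmark_frames_from_ratios(ratios, sample_hz = sample_hz,
                                        noise_sd = noise_sd)
  list(frames = frames, labels = labels)
}

#' Scripted maze-solving bot
#'
#' Plans a shortest command path from start through the level's two
#' checkpoint zones to the finish, then splices in scripted wall-bump
#' commands so a session has a known, exact collision count: replaying
#' the returned stream through [run_level()] yields
#' `errors == nrow(collision_script)` and
#' `total_ms == (path length + bumps) x tick_ms`.
#'
#' @param m A [maze()].
#' @param collision_script Optional data frame with columns `tick`
#'   (1-based position of the bump in the emitted stream, strictly
#'   increasing) and `dir` (a direction, or `NA` to auto-pick any
#'   wall-facing direction at that point).
#' @param step Cells per tick used when validating bumps (default 1).
#' @return Character vector of commands.
#' @export
maze_bot <- function(m, collision_script = NULL, step = 1L) {
  stopifnot(inherits(m, "maze"))
  waypoints <- m$checkpoints
  pos_targets <- list(m$zones[[waypoints[1]]], m$zones[[waypoints[2]]],
                      m$finish)
  cmds <- character(0)
  pos <- m$start
  for (tgt in pos_targets) {
    leg <- shortest_path(m, pos, tgt)
    if (is.null(leg)) stop("maze is not solvable through its checkpoints",
                           call. = FALSE)
    for (d in leg) pos <- pos + DIR_DELTA[[d]]
    cmds <- c(cmds, leg)
  }
  if (is.null(collision_script) || nrow(collision_script) == 0L) {
    return(cmds)
  }
  ticks <- collision_script$tick
  dirs <- as.character(collision_script$dir)
  if (is.unsorted(ticks, strictly = TRUE)) {
    stop("collision_script ticks must be strictly increasing", call. = FALSE)
  }
  if (any(ticks < 1L) || any(ticks > length(cmds) + seq_along(ticks))) {
    stop("collision_script ticks fall outside the command stream",
         call. = FALSE)
  }
  sim_pos <- function(commands, upto) {
    p <- m$start
    for (cmd in head(commands, upto)) {
      delta <- DIR_DELTA[[cmd]]
      for (k in seq_len(step)) {
        nxt <- p + delta
        if (is_wall(m, nxt)) break
        p <- nxt
      }
    }
    p
  }
  for (j in seq_along(ticks)) {
    tk <- ticks[j]
    p <- sim_pos(cmds, tk - 1L)
    blocked <- names(DIR_DELTA)[vapply(names(DIR_DELTA), function(d) {
      is_wall(m, p + DIR_DELTA[[d]])
    }, logical(1))]
    d <- dirs[j]
    if (is.na(d) || d == "auto") {
      if (length(blocked) == 0L) {
        stop(sprintf("no wall-facing direction at tick %d", tk), call. = FALSE)
      }
      d <- blocked[1]
    } else if (!(d %in% blocked)) {
      stop(sprintf("scripted bump at tick %d (%s) does not face a wall",
                   tk, d), call. = FALSE)
    }
    cmds <- append(cmds, d, after = tk - 1L)
  }
  cmds
}
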