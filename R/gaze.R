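#' Therapy modes
#'
#' Canonicalizes a therapy-mode label. Sessions are run binocularly
#' (`"Bin"`, both eyes tracked and averaged) or monocularly with the healthy
#' eye covered: `"Mon-Izq"` tracks the left eye only, `"Mon-Der"` the right
#' eye only. The Spanish-origin labels are the canonical on-disk forms;
#' English aliases are accepted on input.
#'
#' @param mode A mode label: `"Bin"`, `"Mon-Izq"`, `"Mon-Der"`, or an alias
#'   (`"binocular"`, `"left"`, `"monocular-left"`, `"right"`, ...).
#' @return Canonical mode string.
#' @export
therapy_mode <- function(mode) {
  if (!is.character(mode) || length(mode) != 1L) {
    stop("mode must be a single string", call. = FALSE)
  }
  key <- tolower(gsub("[ _]", "-", mode))
  out <- switch(key,
    "bin" = , "binocular" = , "b" = "Bin",
    "mon-izq" = , "monocular-left" = , "left" = , "l" = "Mon-Izq",
    "mon-der" = , "monocular-right" = , "right" = , "r" = "Mon-Der",
    NULL)
  if (is.null(out)) {
    stop(sprintf("unknown therapy mode '%s'", mode), call. = FALSE)
  }
  out
}

#' Pupil center of one eye
#'
#' The pupil is located at the center of the minimum enclosing circle of
#' the four iris landmarks.
#'
#' @param eye An [eye_landmarks()] object.
#' @return Numeric length-2 vector `(x, y)`.
#' @export
pupil_center <- function(eye) {
  stopifnot(inherits(eye, "eye_landmarks"))
  min_enclosing_circle(eye$iris)$center
}

clamp <- function(x, lo, hi, what = "ratio") {
  if (x < lo || x > hi) {
    warning(sprintf("%s %.4f outside [%g, %g]; clamped (landmark jitter?)",
                    what, x, lo, hi), call. = FALSE)
    x <- min(max(x, lo), hi)
  }
  x
}

#' Lateral gaze ratio
#'
#' Normalized horizontal pupil position within the eye: the horizontal
#' distance from the pupil to the external (outer) eye corner divided by
#' the maximum horizontal distance between the two corners. 0 places the
#' pupil at the outer corner, 1 at the inner corner. Values marginally
#' outside `[0, 1]` (landmark jitter) are clamped with a warning.
#'
#' @param pupil Length-2 numeric pupil position.
#' @param eye An [eye_landmarks()] object.
#' @return Ratio in `[0, 1]`.
#' @export
lateral_ratio <- function(pupil, eye) {
  stopifnot(inherits(eye, "eye_landmarks"))
  width <- abs(eye$inner_corner[1] - eye$outer_corner[1])
  if (width == 0) stop("degenerate eye geometry: zero eye width", call. = FALSE)
  clamp(abs(pupil[1] - eye$outer_corner[1]) / width, 0, 1, "lateral ratio")
}

#' Anteroposterior gaze ratio
#'
#' Normalized vertical pupil position, reported as a negative ratio: the
#' vertical distance from the pupil to the upper eyelid landmark, divided
#' by the eye height, negated. 0 places the pupil at the upper landmark,
#' -1 at the lower landmark; mid-height gaze yields -0.5. Values
#' marginally outside `[-1, 0]` are clamped with a warning.
#'
#' @inheritParams lateral_ratio
#' @return Ratio in `[-1, 0]`.
#' @export
anteroposterior_ratio <- function(pupil, eye) {
  stopifnot(inherits(eye, "eye_landmarks"))
  height <- abs(eye$lower[2] - eye$upper[2])
  if (height == 0) {
    stop("degenerate eye geometry: zero eye height", call. = FALSE)
  }
  clamp(-abs(pupil[2] - eye$upper[2]) / height, -1, 0, "anteroposterior ratio")
}

#' Gaze sample from one landmark frame
#'
#' Computes per-eye lateral and anteroposterior ratios from a landmark
#' frame. In binocular mode both eyes are populated together with their
#' pointwise arithmetic means (`ratio_bin`, `ratio_V_bin`); in a monocular
#' mode only the therapy eye's ratios are populated and the other eye's
#' fields (and the binocular means) are `NA`.
#'
#' @param frame A [landmark_frame()].
#' @param mode Therapy mode, see [therapy_mode()].
#' @return A one-row [tibble::tibble] with columns `t_ms`, `ratio_right`,
#'   `ratio_V_right`, `ratio_left`, `ratio_V_left`, `ratio_bin`,
#'   `ratio_V_bin`, `dist_mm`.
#' @export
gaze_sample <- function(frame, mode = "Bin") {
  stopifnot(inherits(frame, "landmark_frame"))
  mode <- therapy_mode(mode)
  eye_ratios <- function(eye) {
    p <- pupil_center(eye)
    c(lat = lateral_ratio(p, eye), ap = anteroposterior_ratio(p, eye))
  }
  rr <- c(lat = NA_real_, ap = NA_real_)
  ll <- rr
  if (mode %in% c("Bin", "Mon-Der")) rr <- eye_ratios(frame$right)
  if (mode %in% c("Bin", "Mon-Izq")) ll <- eye_ratios(frame$left)
  bin_lat <- if (mode == "Bin") (rr[["lat"]] + ll[["lat"]]) / 2 else NA_real_
  bin_ap <- if (mode == "Bin") (rr[["ap"]] + ll[["ap"]]) / 2 else NA_real_
  tibble::tibble(
    t_ms = frame$t_ms,
    ratio_right = rr[["lat"]], ratio_V_right = rr[["ap"]],
    ratio_left = ll[["lat"]], ratio_V_left = ll[["ap"]],
    ratio_bin = bin_lat, ratio_V_bin = bin_ap,
    dist_mm = if (is.null(frame$dist_mm)) NA_real_ else frame$dist_mm
  )
}

#' Gaze trace from a stream of landmark frames
#'
#' @param frames A list of [landmark_frame()] objects with non-decreasing
#'   timestamps.
#' @inheritParams gaze_sample
#' @return A [tibble::tibble], one row per frame (see [gaze_sample()]).
#' @export
gaze_trace <- function(frames, mode = "Bin") {
  mode <- therapy_mode(mode)
  if (length(frames) == 0L) {
    return(tibble::tibble(
      t_ms = numeric(), ratio_right = numeric(), ratio_V_right = numeric(),
      ratio_left = numeric(), ratio_V_left = numeric(),
      ratio_bin = numeric(), ratio_V_bin = numeric(), dist_mm = numeric()
    ))
  }
  t_prev <- -Inf
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (f$t_ms < t_prev) {
      stop(sprintf("timestamps must be non-decreasing (frame %d)", i),
           call. = FALSE)
    }
    t_prev <- f$t_ms
    rows[[i]] <- gaze_sample(f, mode)
  }
  do.call(rbind, rows)
}
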