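#' Eye landmark set
#'
#' Bundles the per-eye landmarks consumed by the gaze estimator: the four
#' iris-contour points produced upstream by a face-mesh model (indices
#' 469-472 for the right eye, 474-477 for the left in the standard
#' 468+10-point mesh) plus four eye-contour landmarks. Coordinates are
#' normalized image coordinates with y increasing downward.
#'
#' @param iris A list of exactly 4 points (length-2 numeric vectors) or a
#'   `4 x 2` matrix.
#' @param outer_corner,inner_corner External and internal eye-corner
#'   landmarks (length-2 numeric vectors). Must differ in x.
#' @param upper,lower Upper and lower eyelid landmarks; `upper[2] < lower[2]`
#'   under the y-down convention.
#' @return An object of class `"eye_landmarks"`.
#' @export
eye_landmarks <- function(iris, outer_corner, inner_corner, upper, lower) {
  iris <- as_point_matrix(iris)
  if (nrow(iris) != 4L) {
    stop("iris must contain exactly 4 points", call. = FALSE)
  }
  for (nm in c("outer_corner", "inner_corner", "upper", "lower")) {
    p <- get(nm)
    if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p))) {
      stop(sprintf("%s must be a finite numeric vector of length 2", nm),
           call. = FALSE)
    }
  }
  if (!all(is.finite(iris))) {
    stop("iris coordinates must be finite", call. = FALSE)
  }
  if (outer_corner[1] == inner_corner[1]) {
    stop("degenerate eye geometry: zero eye width", call. = FALSE)
  }
  if (upper[2] >= lower[2]) {
    stop("degenerate eye geometry: upper landmark must be above lower (y-down)",
         call. = FALSE)
  }
  structure(list(iris = iris,
                 outer_corner = as.numeric(outer_corner),
                 inner_corner = as.numeric(inner_corner),
                 upper = as.numeric(upper),
                 lower = as.numeric(lower)),
            class = "eye_landmarks")
}

#' One timestamped frame of binocular landmarks
#'
#' @param t_ms Integer timestamp in milliseconds.
#' @param left,right [eye_landmarks()] objects.
#' @param dist_mm Optional distance-sensor reading in millimetres
#'   (`NULL` when no sensor reading accompanies the frame).
#' @return An object of class `"landmark_frame"`.
#' @export
landmark_frame <- function(t_ms, left, right, dist_mm = NULL) {
  if (!is.numeric(t_ms) || length(t_ms) != 1L || !is.finite(t_ms)) {
    stop("t_ms must be a finite scalar", call. = FALSE)
  }
  if (!inherits(left, "eye_landmarks") || !inherits(right, "eye_landmarks")) {
    stop("left and right must be eye_landmarks objects", call. = FALSE)
  }
  if (!is.null(dist_mm)) {
    if (!is.numeric(dist_mm) || length(dist_mm) != 1L || is.na(dist_mm)) {
      stop("dist_mm must be a numeric scalar or NULL", call. = FALSE)
    }
    if (dist_mm < 0) stop("dist_mm must be non-negative", call. = FALSE)
  }
  structure(list(t_ms = as.numeric(t_ms), left = left, right = right,
                 dist_mm = dist_mm),
            class = "landmark_frame")
}
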