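#' Minimum enclosing circle of a point set
#'
#' Computes the smallest circle containing every input point using Welzl's
#' recursive algorithm. This is the primitive behind pupil localization:
#' the four iris landmarks of one eye are enclosed and the circle's center
#' is taken as the pupil position.
#'
#' @param points Points in normalized image coordinates: either an `n x 2`
#'   numeric matrix or a list of length-2 numeric vectors. `1 <= n <= 16`.
#' @return A list of class `"mec_circle"` with elements `center`
#'   (numeric length 2) and `radius` (non-negative scalar). Every input
#'   point lies within `radius + 1e-9` of `center`.
#' @examples
#' min_enclosing_circle(rbind(c(0, 0), c(2, 0)))
#' @export
min_enclosing_circle <- function(points) {
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n < 1L) {
    stop("min_enclosing_circle() requires at least one point", call. = FALSE)
  }
  if (n > 16L) {
    stop("min_enclosing_circle() supports at most 16 points", call. = FALSE)
  }
  if (!all(is.finite(pts))) {
    stop("all point coordinates must be finite", call. = FALSE)
  }
  # deterministic shuffle keeps the expected-linear behaviour of Welzl
  # without introducing run-to-run nondeterminism
  ord <- order(pts[, 1], pts[, 2])
  circ <- welzl(pts[ord, , drop = FALSE], matrix(numeric(0), ncol = 2))
  structure(list(center = circ$center, radius = circ$radius),
            class = "mec_circle")
}

#' @export
print.mec_circle <- function(x, ...) {
  cat(sprintf("<circle center=(%.6g, %.6g) radius=%.6g>\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 2L) stop("points must have two columns", call. = FALSE)
    return(points)
  }
  if (is.numeric(points) && length(points) == 2L) {
    return(matrix(points, ncol = 2))
  }
  if (is.list(points)) {
    if (length(points) == 0L) {
      return(matrix(numeric(0), ncol = 2))
    }
    if (!all(vapply(points, function(p) is.numeric(p) && length(p) == 2L,
                    logical(1)))) {
      stop("each point must be a numeric vector of length 2", call. = FALSE)
    }
    return(do.call(rbind, points))
  }
  stop("points must be an n x 2 matrix or a list of length-2 vectors",
       call. = FALSE)
}

MEC_EPS <- 1e-9

circle_contains <- function(circ, p, eps = MEC_EPS) {
  dx <- p[1] - circ$center[1]
  dy <- p[2] - circ$center[2]
  sqrt(dx * dx + dy * dy) <= circ$radius + eps
}

circle_from_1 <- function(p) list(center = as.numeric(p), radius = 0)

circle_from_2 <- function(p, q) {
  center <- (as.numeric(p) + as.numeric(q)) / 2
  list(center = center, radius = sqrt(sum((p - center)^2)))
}

# circumcircle of three points; NULL when (near-)collinear
circle_from_3 <- function(a, b, c) {
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14) return(NULL)
  a2 <- ax * ax + ay * ay
  b2 <- bx * bx + by * by
  c2 <- cx * cx + cy * cy
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  center <- c(ux, uy)
  list(center = center, radius = sqrt(sum((a - center)^2)))
}

# smallest circle with all boundary points of `R` on its rim
circle_trivial <- function(R) {
  n <- nrow(R)
  if (n == 0L) return(list(center = c(0, 0), radius = -1))
  if (n == 1L) return(circle_from_1(R[1, ]))
  if (n == 2L) return(circle_from_2(R[1, ], R[2, ]))
  # three boundary points: try each pair first (handles obtuse/collinear)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      circ <- circle_from_2(R[i, ], R[j, ])
      k <- setdiff(1:3, c(i, j))
      if (circle_contains(circ, R[k, ])) return(circ)
    }
  }
  circ <- circle_from_3(R[1, ], R[2, ], R[3, ])
  if (is.null(circ)) {
    # collinear: widest pair
    best <- circle_from_2(R[1, ], R[2, ])
    for (pair in list(c(1, 3), c(2, 3))) {
      cand <- circle_from_2(R[pair[1], ], R[pair[2], ])
      if (cand$radius > best$radius) best <- cand
    }
    return(best)
  }
  circ
}

welzl <- function(P, R) {
  if (nrow(P) == 0L || nrow(R) == 3L) {
    return(circle_trivial(R))
  }
  p <- P[nrow(P), ]
  circ <- welzl(P[-nrow(P), , drop = FALSE], R)
  if (circ$radius >= 0 && circle_contains(circ, p)) {
    return(circ)
  }
  welzl(P[-nrow(P), , drop = FALSE], rbind(R, p))
}
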