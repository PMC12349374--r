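SIGNAL_COLS <- c(LD = "ratio_right", AD = "ratio_V_right",
                 LI = "ratio_left", AI = "ratio_V_left",
                 LB = "ratio_bin", AB = "ratio_V_bin")

#' Displacement extremes of a gaze trace
#'
#' Per-signal maxima and minima over time. Signals are named by axis and
#' eye: `L`/`A` = lateral / anteroposterior, `D`/`I`/`B` = right / left /
#' binocular. Binocular extremes are taken over the pointwise-mean signal
#' (not the mean of per-eye extremes), so when per-eye extremes do not
#' co-occur in time the binocular extreme is strictly less extreme than
#' that mean. Monocular sessions return only the tracked eye's signals.
#'
#' @param trace A gaze trace tibble (see [gaze_trace()]).
#' @param mode Therapy mode.
#' @return Tibble with columns `signal`, `max`, `min`.
#' @export
displacement_extremes <- function(trace, mode = "Bin") {
  mode <- therapy_mode(mode)
  if (is.null(trace) || nrow(trace) == 0L) {
    stop("displacement_extremes() requires a non-empty trace", call. = FALSE)
  }
  signals <- switch(mode,
    "Bin" = names(SIGNAL_COLS),
    "Mon-Izq" = c("LI", "AI"),
    "Mon-Der" = c("LD", "AD"))
  rows <- lapply(signals, function(s) {
    v <- trace[[SIGNAL_COLS[[s]]]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      stop(sprintf("trace carries no values for signal %s in mode %s",
                   s, mode), call. = FALSE)
    }
    tibble::tibble(signal = s, max = max(v), min = min(v))
  })
  do.call(rbind, rows)
}

#' Ellipse parameters from displacement extremes
#'
#' The session ellipse is centered at the midpoints of the lateral and
#' anteroposterior ranges with semi-axes equal to the half-ranges, so a
#' wider sweep of the eye draws a larger ellipse.
#'
#' @param x_min,x_max Lateral extremes (`x_min <= x_max`).
#' @param y_min,y_max Anteroposterior extremes (`y_min <= y_max`).
#' @return An object of class `"ellipse_params"`: `center_x`, `center_y`,
#'   `semi_axis_x`, `semi_axis_y`.
#' @export
ellipse_from_extremes <- function(x_min, x_max, y_min, y_max) {
  if (x_min > x_max || y_min > y_max) {
    stop("inverted extremes: min must not exceed max", call. = FALSE)
  }
  structure(list(center_x = (x_min + x_max) / 2,
                 center_y = (y_min + y_max) / 2,
                 semi_axis_x = (x_max - x_min) / 2,
                 semi_axis_y = (y_max - y_min) / 2),
            class = "ellipse_params")
}

#' Session ellipse from a gaze trace
#'
#' Convenience wrapper: extremes of the chosen lateral/anteroposterior
#' signal pair feed [ellipse_from_extremes()].
#'
#' @param trace A gaze trace tibble.
#' @param eye `"binocular"`, `"right"` or `"left"`.
#' @return An `"ellipse_params"` object.
#' @export
session_ellipse <- function(trace, eye = c("binocular", "right", "left")) {
  eye <- match.arg(eye)
  cols <- switch(eye,
    binocular = c("ratio_bin", "ratio_V_bin"),
    right = c("ratio_right", "ratio_V_right"),
    left = c("ratio_left", "ratio_V_left"))
  lat <- trace[[cols[1]]]
  ap <- trace[[cols[2]]]
  lat <- lat[!is.na(lat)]; ap <- ap[!is.na(ap)]
  if (length(lat) == 0L || length(ap) == 0L) {
    stop(sprintf("trace carries no %s signal", eye), call. = FALSE)
  }
  ellipse_from_extremes(min(lat), max(lat), min(ap), max(ap))
}

#' Performance ratio (milliseconds per error)
#'
#' Total maze completion time divided by the number of wall collisions,
#' rounded to 2 decimals; a higher value means fewer errors per unit time.
#' A zero-error session has no defined ratio and yields `NA` (exports
#' render it as an empty cell).
#'
#' @param total_ms Total completion time(s), ms (> 0).
#' @param errors Collision count(s) (>= 0). Vectorized.
#' @return Numeric vector of ratios (ms/E), `NA` where `errors == 0`.
#' @export
performance_ratio <- function(total_ms, errors) {
  if (any(total_ms <= 0, na.rm = TRUE)) {
    stop("total_ms must be positive", call. = FALSE)
  }
  if (any(errors < 0, na.rm = TRUE)) {
    stop("errors must be non-negative", call. = FALSE)
  }
  out <- ifelse(errors == 0, NA_real_, round(total_ms / errors, 2))
  as.numeric(out)
}

#' Per-segment gaze statistics
#'
#' Sample mean, sample standard deviation (n-1 denominator) and
#' coefficient of variation (`100 * sd / |mean|`) of each eye's lateral
#' and anteroposterior ratios within named time windows. The standard
#' segments are `HD` (rightward lateral sweep), `HI` (leftward lateral
#' sweep) and `V` (upward anteroposterior sweep); see [segment_windows()]
#' for deriving them from a level's checkpoint events.
#'
#' @param trace A gaze trace tibble.
#' @param windows Named list: segment name to a two-column matrix (or
#'   single `c(start, end)` vector) of closed time intervals in ms.
#' @return Tibble with columns `segment`, `eye`, `mean_lat`, `sd_lat`,
#'   `cv_lat`, `mean_ap`, `sd_ap`, `cv_ap`. Windows holding fewer than two
#'   samples yield `NA` standard deviations; a zero mean yields `NA` CV.
#' @export
segment_stats <- function(trace, windows) {
  stopifnot(is.list(windows), length(windows) > 0L)
  one <- function(vals) {
    vals <- vals[!is.na(vals)]
    m <- if (length(vals)) mean(vals) else NA_real_
    s <- if (length(vals) >= 2L) sd(vals) else NA_real_
    cv <- if (!is.na(s) && !is.na(m) && m != 0) 100 * s / abs(m) else NA_real_
    c(mean = m, sd = s, cv = cv)
  }
  rows <- list()
  for (seg in names(windows)) {
    iv <- windows[[seg]]
    if (is.numeric(iv) && is.null(dim(iv))) iv <- matrix(iv, ncol = 2)
    keep <- rep(FALSE, nrow(trace))
    for (k in seq_len(nrow(iv))) {
      keep <- keep | (trace$t_ms >= iv[k, 1] & trace$t_ms <= iv[k, 2])
    }
    sub <- trace[keep, , drop = FALSE]
    for (eye in c("right", "left")) {
      lat <- one(sub[[paste0("ratio_", eye)]])
      ap <- one(sub[[paste0("ratio_V_", eye)]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        segment = seg, eye = eye,
        mean_lat = lat[["mean"]], sd_lat = lat[["sd"]], cv_lat = lat[["cv"]],
        mean_ap = ap[["mean"]], sd_ap = ap[["sd"]], cv_ap = ap[["cv"]])
    }
  }
  do.call(rbind, rows)
}

#' Segment windows from a level's checkpoint events
#'
#' Splits a level's time span at its two checkpoint times: `[0, CHKP1]`
#' is the first sweep (`HD`), `(CHKP1, CHKP2]` the second (`HI`) and
#' `(CHKP2, finish]` the final sweep (`V`). The original segment
#' boundaries are not published; this checkpoint-based split is the
#' package's convention.
#'
#' @param level_result A `level_result` from [run_level()] with all three
#'   checkpoints reached.
#' @return Named list of `c(start, end)` windows in ms.
#' @export
segment_windows <- function(level_result) {
  ct <- level_result$checkpoint_times
  if (anyNA(ct)) {
    stop("segment windows require a completed level with both checkpoints",
         call. = FALSE)
  }
  list(HD = c(0, ct[1]),
       HI = c(ct[1] + level_result$tick_ms, ct[2]),
       V = c(ct[2] + level_result$tick_ms, ct[3]))
}

fmt2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))

#' Export displacement extremes in the session-table layout
#'
#' Writes one row per session with the standard column header
#' `ID, LD Max, AD Max, LI Max, AI Max, LB Max, AB Max, LD Min, AD Min,
#' LI Min, AI Min, LB Min, AB Min, Operation`; signals absent from a
#' monocular session are rendered as `-`.
#'
#' @param sessions A list of lists, each with elements `id`, `extremes`
#'   (from [displacement_extremes()]) and `mode`.
#' @param path Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
export_displacement_csv <- function(sessions, path) {
  all_sig <- names(SIGNAL_COLS)
  rows <- lapply(sessions, function(s) {
    ex <- s$extremes
    get <- function(sig, what) {
      i <- match(sig, ex$signal)
      if (is.na(i)) "-" else sprintf("%.2f", ex[[what]][i])
    }
    vals <- c(list(ID = s$id),
              setNames(lapply(all_sig, get, what = "max"),
                       paste(all_sig, "Max")),
              setNames(lapply(all_sig, get, what = "min"),
                       paste(all_sig, "Min")),
              list(Operation = therapy_mode(s$mode)))
    as.data.frame(vals, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export level results in the therapy-session-table layout
#'
#' Header: `ID, Level, Time-CHKP-1 (ms), Time-CHKP-2 (ms),
#' Total Time (ms), Errors, Performance Ratio (ms/E)`. Ratios are
#' computed from the unrounded totals; zero-error sessions leave the
#' ratio cell empty.
#'
#' @param sessions A list of lists, each with elements `id` and `result`
#'   (a `level_result`).
#' @param path Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
export_session_csv <- function(sessions, path) {
  rows <- lapply(sessions, function(s) {
    r <- s$result
    data.frame(
      ID = s$id, Level = r$level,
      `Time-CHKP-1 (ms)` = fmt2(r$checkpoint_times[1]),
      `Time-CHKP-2 (ms)` = fmt2(r$checkpoint_times[2]),
      `Total Time (ms)` = fmt2(r$total_ms),
      Errors = r$errors,
      `Performance Ratio (ms/E)` = fmt2(
        if (is.na(r$total_ms)) NA_real_
        else performance_ratio(r$total_ms, r$errors)),
      check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
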