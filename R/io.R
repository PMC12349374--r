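#' Write a landmark stream as JSON Lines
#'
#' One frame per line:
#' `{"t_ms": int, "left": {"iris": [[x,y] x 4], "outer": [x,y],
#' "inner": [x,y], "upper": [x,y], "lower": [x,y]}, "right": {...},
#' "dist_mm": float|null}`. Coordinates are normalized image coordinates,
#' y increasing downward.
#'
#' @param frames List of [landmark_frame()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_stream <- function(frames, path) {
  eye_json <- function(eye) {
    list(iris = lapply(1:4, function(i) eye$iris[i, ]),
         outer = eye$outer_corner, inner = eye$inner_corner,
         upper = eye$upper, lower = eye$lower)
  }
  lines <- vapply(frames, function(f) {
    jsonlite::toJSON(list(
      t_ms = f$t_ms,
      left = eye_json(f$left),
      right = eye_json(f$right),
      dist_mm = f$dist_mm
    ), auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

parse_eye <- function(obj, line_no, side) {
  need <- c("iris", "outer", "inner", "upper", "lower")
  miss <- setdiff(need, names(obj))
  if (length(miss) > 0L) {
    stop(sprintf("line %d: %s eye missing field(s) %s", line_no, side,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  iris <- obj$iris
  if (is.list(iris)) iris <- do.call(rbind, lapply(iris, as.numeric))
  if (!is.matrix(iris) || nrow(iris) != 4L || ncol(iris) != 2L) {
    stop(sprintf("line %d: %s eye iris must contain exactly 4 [x,y] points",
                 line_no, side), call. = FALSE)
  }
  eye_landmarks(iris, as.numeric(obj$outer), as.numeric(obj$inner),
                as.numeric(obj$upper), as.numeric(obj$lower))
}

#' Read a landmark stream from JSON Lines
#'
#' Parses and validates the format written by [write_landmark_stream()].
#' Malformed lines raise an error naming the line number.
#'
#' @param path Input file path.
#' @return List of [landmark_frame()] objects (empty list for an empty
#'   file).
#' @export
read_landmark_stream <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("landmark stream not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  frames <- vector("list", length(lines))
  t_prev <- -Inf
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop(sprintf("line %d: invalid JSON (%s)", i,
                                   conditionMessage(e)), call. = FALSE)
                    })
    for (f in c("t_ms", "left", "right")) {
      if (is.null(obj[[f]])) {
        stop(sprintf("line %d: missing field '%s'", i, f), call. = FALSE)
      }
    }
    frame <- tryCatch(
      landmark_frame(obj$t_ms,
                     left = parse_eye(obj$left, i, "left"),
                     right = parse_eye(obj$right, i, "right"),
                     dist_mm = if (is.null(obj$dist_mm)) NULL
                               else as.numeric(obj$dist_mm)),
      error = function(e) {
        msg <- conditionMessage(e)
        if (grepl("^line ", msg)) stop(e)
        stop(sprintf("line %d: %s", i, msg), call. = FALSE)
      })
    if (frame$t_ms < t_prev) {
      stop(sprintf("line %d: timestamps must be non-decreasing", i),
           call. = FALSE)
    }
    t_prev <- frame$t_ms
    frames[[i]] <- frame
  }
  frames
}

#' Read / write a maze definition as JSON
#'
#' Schema: `{"level": int, "width": int, "height": int,
#' "walls": [[x,y],...], "start": [x,y], "finish": [[x,y],...],
#' "zones": {"2": [[x,y],...], ...}, "checkpoints": [2, 4, "F"]}` with
#' 0-based cells.
#'
#' @param path JSON file path.
#' @return [read_maze()] returns a [maze()]; [write_maze()] returns `path`
#'   invisibly.
#' @export
read_maze <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("maze file not found: %s", path), call. = FALSE)
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cells <- function(x) {
    if (is.null(x) || length(x) == 0L) return(matrix(integer(0), ncol = 2))
    if (is.matrix(x)) return(x)
    do.call(rbind, lapply(x, as.integer))
  }
  maze(level = obj$level, width = obj$width, height = obj$height,
       walls = cells(obj$walls), start = as.integer(obj$start),
       finish = cells(obj$finish),
       zones = lapply(obj$zones, cells),
       checkpoints = as.character(unlist(obj$checkpoints)))
}

#' @rdname read_maze
#' @param m A [maze()] object.
#' @export
write_maze <- function(m, path) {
  stopifnot(inherits(m, "maze"))
  rows <- function(mat) lapply(seq_len(nrow(mat)), function(i) mat[i, ])
  obj <- list(level = m$level, width = m$width, height = m$height,
              walls = rows(m$walls), start = m$start,
              finish = rows(m$finish),
              zones = lapply(m$zones, rows),
              checkpoints = as.list(m$checkpoints))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Packaged fixture maze for one therapy level
#'
#' Loads one of the five synthetic maze layouts shipped with the package
#' (the original device's layouts are not published; these are
#' purpose-built stand-ins of increasing complexity whose zone numbering
#' matches the published checkpoint mapping, see
#' [checkpoints_for_level()]).
#'
#' @param level Integer 1-5.
#' @return A [maze()] object.
#' @export
fixture_maze <- function(level) {
  checkpoints_for_level(level)  # validates range
  path <- system.file("extdata", "mazes", sprintf("level%d.json", level),
                      package = "gazemaze", mustWork = TRUE)
  read_maze(path)
}

#' Write per-tick telemetry as JSON Lines
#'
#' Message schema mirrors the device's live payload:
#' `{"t_ms": int, "level": int, "errors": int, "ball": [x,y],
#' "dist_mm": float|null, "cmd": "UP|DOWN|LEFT|RIGHT|STAY"}`.
#'
#' @param telemetry Telemetry tibble from [run_level()]
#'   (`collect_telemetry = TRUE`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(telemetry, path) {
  lines <- vapply(seq_len(nrow(telemetry)), function(i) {
    r <- telemetry[i, ]
    jsonlite::toJSON(list(t_ms = r$t_ms, level = r$level, errors = r$errors,
                          ball = c(r$ball_x, r$ball_y),
                          dist_mm = if (is.na(r$dist_mm)) NULL else r$dist_mm,
                          cmd = r$cmd),
                     auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration file
#'
#' YAML configuration with a `control` section
#' (`lat_center`, `ap_center`, `band_lat`, `band_ap`, `margin`, `iqr_k`,
#' `distance_min_mm`, `distance_max_mm`); missing keys fall back to the
#' shipped defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(control = list(
    lat_center = 0.5, ap_center = -0.5, band_lat = 0.12, band_ap = 0.12,
    margin = 0.10, iqr_k = 1.5, distance_min_mm = 400, distance_max_mm = 500))
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  out <- defaults
  for (section in names(user)) {
    if (is.list(user[[section]])) {
      for (key in names(user[[section]])) {
        out[[section]][[key]] <- user[[section]][[key]]
      }
    } else {
      out[[section]] <- user[[section]]
    }
  }
  out
}

#' Read a therapy-session results table
#'
#' Parses the session-table layout `ID, Level, Time-CHKP-1 (ms),
#' Time-CHKP-2 (ms), Total Time (ms), Errors, Performance Ratio (ms/E)`
#' (thousands separators tolerated). The ratio column is optional.
#'
#' @param path CSV file path.
#' @return Tibble with columns `id`, `level`, `chkp1_ms`, `chkp2_ms`,
#'   `total_ms`, `errors`, `ratio` (`NA` when absent).
#' @export
read_session_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("session file not found: %s", path), call. = FALSE)
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nml <- tolower(names(df))
  num <- function(pattern) {
    i <- grep(pattern, nml)[1]
    if (is.na(i)) return(rep(NA_real_, nrow(df)))
    as.numeric(gsub(",", "", as.character(df[[i]])))
  }
  out <- tibble::tibble(
    id = df[[grep("^id$", nml)[1]]],
    level = num("^level$"),
    chkp1_ms = num("chkp-?1"),
    chkp2_ms = num("chkp-?2"),
    total_ms = num("total"),
    errors = num("^errors$"),
    ratio = num("ratio"))
  if (anyNA(out$total_ms) || anyNA(out$errors)) {
    stop("session table is missing total time or error values", call. = FALSE)
  }
  out
}

#' Packaged therapy-session results fixture
#'
#' The published level-2 therapy-session table (17 rows: checkpoint
#' times, total times, collision counts and performance ratios), shipped
#' as a CSV fixture.
#'
#' @return Tibble as returned by [read_session_csv()].
#' @export
session_results_fixture <- function() {
  read_session_csv(system.file("extdata", "session_results.csv",
                               package = "gazemaze", mustWork = TRUE))
}
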