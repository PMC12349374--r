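COMMANDS <- c("UP", "DOWN", "LEFT", "RIGHT", "STAY")

#' Five-zone gaze thresholds
#'
#' The eye region is divided in ratio space into a central rectangle
#' (gaze there leaves the ball stationary) and four surrounding zones
#' mapped to the four directional commands. The lateral ratio grows from
#' the outer toward the inner eye corner, so values above `lat_left` fall
#' in the LEFT zone and below `lat_right` in the RIGHT zone; the
#' anteroposterior ratio is negative with 0 at the upper eyelid, so values
#' above `ap_up` fall in the UP zone and below `ap_down` in the DOWN zone.
#'
#' Defaults (center 0.5 / -0.5, half-width 0.12) are the shipped
#' configuration; [calibrate_thresholds()] overrides them per user.
#'
#' @param lat_center,ap_center Calibration centers for the lateral and
#'   anteroposterior ratios.
#' @param band_lat,band_ap Half-widths of the central band on each axis.
#' @return An object of class `"zone_thresholds"` with fields
#'   `lat_center`, `ap_center`, `band_lat`, `band_ap`, `lat_left`,
#'   `lat_right`, `ap_up`, `ap_down`.
#' @export
zone_thresholds <- function(lat_center = 0.5, ap_center = -0.5,
                            band_lat = 0.12, band_ap = 0.12) {
  stopifnot(band_lat > 0, band_ap > 0,
            lat_center >= 0, lat_center <= 1,
            ap_center >= -1, ap_center <= 0)
  thr <- list(lat_center = lat_center, ap_center = ap_center,
              band_lat = band_lat, band_ap = band_ap,
              lat_left = lat_center + band_lat,
              lat_right = lat_center - band_lat,
              ap_up = ap_center + band_ap,
              ap_down = ap_center - band_ap)
  structure(thr, class = "zone_thresholds")
}

controlling_ratios <- function(sample, mode) {
  mode <- therapy_mode(mode)
  cols <- switch(mode,
    "Bin" = c("ratio_bin", "ratio_V_bin"),
    "Mon-Izq" = c("ratio_left", "ratio_V_left"),
    "Mon-Der" = c("ratio_right", "ratio_V_right"))
  lat <- sample[[cols[1]]][1]
  ap <- sample[[cols[2]]][1]
  if (is.null(lat) || is.null(ap) || is.na(lat) || is.na(ap)) {
    stop(sprintf("sample carries no controlling ratios for mode %s", mode),
         call. = FALSE)
  }
  c(lat = lat, ap = ap)
}

#' Classify a gaze sample into a maze command
#'
#' Returns `"STAY"` iff both controlling ratios lie strictly inside the
#' central band. Otherwise the command follows the dominant deviation:
#' each axis deviation is normalized by its band half-width and the axis
#' with the larger normalized deviation wins, ties resolving to the
#' lateral axis.
#'
#' @param sample A one-row gaze sample (see [gaze_sample()]).
#' @param thr A [zone_thresholds()] object.
#' @param mode Therapy mode; the controlling signal is the binocular mean
#'   in `"Bin"` mode and the therapy eye otherwise.
#' @return One of `"UP"`, `"DOWN"`, `"LEFT"`, `"RIGHT"`, `"STAY"`.
#' @export
classify_zone <- function(sample, thr, mode = "Bin") {
  stopifnot(inherits(thr, "zone_thresholds"))
  r <- controlling_ratios(sample, mode)
  dev_lat <- r[["lat"]] - thr$lat_center
  dev_ap <- r[["ap"]] - thr$ap_center
  inside_lat <- abs(dev_lat) < thr$band_lat
  inside_ap <- abs(dev_ap) < thr$band_ap
  if (inside_lat && inside_ap) {
    return("STAY")
  }
  n_lat <- abs(dev_lat) / thr$band_lat
  n_ap <- abs(dev_ap) / thr$band_ap
  if (n_lat >= n_ap) {
    if (dev_lat > 0) "LEFT" else "RIGHT"
  } else {
    if (dev_ap > 0) "UP" else "DOWN"
  }
}

#' Adaptive threshold calibration from a central-fixation baseline
#'
#' Centers are the per-axis medians of the baseline ratios; each band
#' half-width is `max(margin, iqr_k * IQR)` of that axis, so a jittery
#' user gets a proportionally wider dead zone while a steady user keeps
#' the floor `margin`.
#'
#' @param baseline A gaze trace (see [gaze_trace()]) of at least 10 samples
#'   recorded while the user fixates the screen center.
#' @param margin Minimum band half-width (ratio units). Default 0.10.
#' @param iqr_k Multiplier on the interquartile range. Default 1.5.
#' @param mode Therapy mode selecting the controlling signal.
#' @return A [zone_thresholds()] object.
#' @export
calibrate_thresholds <- function(baseline, margin = 0.10, iqr_k = 1.5,
                                 mode = "Bin") {
  if (is.null(baseline) || nrow(baseline) < 10L) {
    stop("calibration requires at least 10 baseline samples", call. = FALSE)
  }
  mode <- therapy_mode(mode)
  cols <- switch(mode,
    "Bin" = c("ratio_bin", "ratio_V_bin"),
    "Mon-Izq" = c("ratio_left", "ratio_V_left"),
    "Mon-Der" = c("ratio_right", "ratio_V_right"))
  lat <- baseline[[cols[1]]]
  ap <- baseline[[cols[2]]]
  if (anyNA(lat) || anyNA(ap)) {
    stop("baseline trace is missing controlling ratios for this mode",
         call. = FALSE)
  }
  zone_thresholds(
    lat_center = median(lat), ap_center = median(ap),
    band_lat = max(margin, iqr_k * IQR(lat)),
    band_ap = max(margin, iqr_k * IQR(ap))
  )
}

#' Distance gate for session start
#'
#' A session may start only when the user sits 40-50 cm from the device;
#' both endpoints are inclusive.
#'
#' @param distance_mm Sensor distance reading in millimetres.
#' @param min_mm,max_mm Gate endpoints (default 400 and 500 mm).
#' @return `TRUE` iff `min_mm <= distance_mm <= max_mm`.
#' @export
session_ready <- function(distance_mm, min_mm = 400, max_mm = 500) {
  if (!is.numeric(distance_mm) || length(distance_mm) != 1L ||
      is.na(distance_mm)) {
    stop("distance_mm must be a numeric scalar", call. = FALSE)
  }
  if (distance_mm < 0) stop("distance_mm must be non-negative", call. = FALSE)
  distance_mm >= min_mm && distance_mm <= max_mm
}
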