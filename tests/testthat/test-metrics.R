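sin_trace <- function(n = 300, c_lat = 0.5, a_lat = 0.2, c_ap = -0.5,
                      a_ap = 0.15) {
  t <- seq(0, 4 * pi, length.out = n)
  tibble::tibble(
    t_ms = seq_len(n) * 33,
    ratio_right = c_lat + a_lat * sin(t),
    ratio_V_right = c_ap + a_ap * cos(t),
    ratio_left = c_lat + a_lat * sin(t),
    ratio_V_left = c_ap + a_ap * cos(t),
    ratio_bin = c_lat + a_lat * sin(t),
    ratio_V_bin = c_ap + a_ap * cos(t),
    dist_mm = NA_real_)
}

test_that("displacement extremes recover programmed amplitudes", {
  const <- random_gaze_sample(0.4, -0.6)
  ex <- displacement_extremes(const, "Bin")
  expect_equal(ex$max, ex$min)

  tr <- sin_trace()
  ex2 <- displacement_extremes(tr, "Bin")
  expect_equal(ex2$max[ex2$signal == "LD"], 0.7, tolerance = 1e-3)
  expect_equal(ex2$min[ex2$signal == "LD"], 0.3, tolerance = 1e-3)
  expect_equal(ex2$max[ex2$signal == "AD"], -0.35, tolerance = 1e-3)
  expect_equal(ex2$min[ex2$signal == "AD"], -0.65, tolerance = 1e-3)

  mon <- displacement_extremes(tr, "Mon-Izq")
  expect_setequal(mon$signal, c("LI", "AI"))

  expect_error(displacement_extremes(tr[0, ], "Bin"), "non-empty")
})

test_that("binocular extremes are taken over the pointwise mean signal", {
  # per-eye minima at different times: binocular minimum exceeds the
  # mean of per-eye minima
  tr <- tibble::tibble(
    t_ms = c(0, 33, 66),
    ratio_right = c(0.03, 0.50, 0.71),
    ratio_left = c(0.60, 0.29, 0.90),
    ratio_V_right = c(-0.5, -0.5, -0.5),
    ratio_V_left = c(-0.5, -0.5, -0.5))
  tr$ratio_bin <- (tr$ratio_right + tr$ratio_left) / 2
  tr$ratio_V_bin <- (tr$ratio_V_right + tr$ratio_V_left) / 2
  ex <- displacement_extremes(tr, "Bin")
  lb_min <- ex$min[ex$signal == "LB"]
  expect_gt(lb_min, (0.03 + 0.29) / 2)
})

test_that("extremes of a subtrace lie within the full-trace extremes", {
  tr <- sin_trace()
  full <- displacement_extremes(tr, "Bin")
  sub <- displacement_extremes(tr[50:150, ], "Bin")
  expect_true(all(sub$max <= full$max + 1e-12))
  expect_true(all(sub$min >= full$min - 1e-12))
})

test_that("ellipse parameters are midpoints and half-ranges", {
  e <- ellipse_from_extremes(0.27, 0.85, -0.78, -0.40)
  expect_equal(e$center_x, 0.56)
  expect_equal(e$center_y, -0.59)
  expect_equal(e$semi_axis_x, 0.29)
  expect_equal(e$semi_axis_y, 0.19)

  deg <- ellipse_from_extremes(0.5, 0.5, -0.6, -0.4)
  expect_equal(deg$semi_axis_x, 0)

  circ <- ellipse_from_extremes(-0.3, 0.3, -0.3, 0.3)
  expect_equal(circ$center_x, 0)
  expect_equal(circ$semi_axis_x, circ$semi_axis_y)

  expect_error(ellipse_from_extremes(0.9, 0.1, -1, 0), "inverted")

  # area is zero iff one signal is constant
  expect_equal(pi * deg$semi_axis_x * deg$semi_axis_y, 0)
  e2 <- session_ellipse(sin_trace(), "binocular")
  expect_gt(pi * e2$semi_axis_x * e2$semi_axis_y, 0)
})

test_that("performance ratio divides unrounded totals and guards zero errors", {
  expect_equal(performance_ratio(94997.36, 34), 2794.04)
  expect_equal(performance_ratio(93404.82, 2), 46702.41)
  expect_true(is.na(performance_ratio(1000, 0)))
  expect_error(performance_ratio(-5, 3), "positive")
  expect_error(performance_ratio(100, -1), "non-negative")
})

test_that("segment statistics use the sample (n-1) convention", {
  tr <- tibble::tibble(
    t_ms = c(0, 100, 200),
    ratio_right = c(0.4, 0.5, 0.6), ratio_V_right = c(-0.5, -0.5, -0.5),
    ratio_left = c(0.4, 0.5, 0.6), ratio_V_left = c(-0.45, -0.5, -0.55),
    ratio_bin = NA_real_, ratio_V_bin = NA_real_, dist_mm = NA_real_)
  st <- segment_stats(tr, list(HD = c(0, 200)))
  r <- st[st$eye == "right", ]
  expect_equal(r$mean_lat, 0.5)
  expect_equal(r$sd_lat, 0.1)
  expect_equal(r$cv_lat, 100 * 0.1 / 0.5)
  # constant segment: sd 0, CV 0
  expect_equal(r$sd_ap, 0)
  expect_equal(r$cv_ap, 0)

  # CV convention: positive for negative means (|mean| denominator)
  l <- st[st$eye == "left", ]
  expect_equal(l$mean_ap, -0.5)
  expect_equal(l$cv_ap, 100 * l$sd_ap / 0.5)
  expect_gt(l$cv_ap, 0)

  # CV invariant under sign flip
  tr_flip <- tr
  tr_flip$ratio_V_left <- -tr$ratio_V_left
  st_flip <- segment_stats(tr_flip, list(HD = c(0, 200)))
  expect_equal(st_flip$cv_ap[st_flip$eye == "left"], l$cv_ap)

  # windows with fewer than two samples yield undefined sd
  st1 <- segment_stats(tr, list(V = c(0, 50)))
  expect_true(is.na(st1$sd_lat[st1$eye == "right"]))
})

test_that("segment windows split a level at its checkpoints", {
  m <- corridor_maze()
  res <- run_level(m, rep("RIGHT", 12), tick_ms = 100)
  w <- segment_windows(res)
  expect_equal(w$HD, c(0, 300))
  expect_equal(w$HI, c(400, 600))
  expect_equal(w$V, c(700, 1000))
})

test_that("export layouts match the published table headers", {
  tr <- sin_trace()
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- export_displacement_csv(
    list(list(id = 1, extremes = displacement_extremes(tr, "Bin"),
              mode = "Bin"),
         list(id = 5, extremes = displacement_extremes(tr, "Mon-Izq"),
              mode = "Mon-Izq")),
    tmp)
  expect_equal(names(df)[1:3], c("ID", "LD Max", "AD Max"))
  expect_equal(names(df)[14], "Operation")
  expect_equal(df$Operation, c("Bin", "Mon-Izq"))
  expect_equal(df[["LD Max"]][2], "-")  # untracked eye rendered as dash

  m <- corridor_maze()
  res <- run_level(m, rep("RIGHT", 12), tick_ms = 100)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  df2 <- export_session_csv(list(list(id = 1, result = res)), tmp2)
  expect_equal(names(df2),
               c("ID", "Level", "Time-CHKP-1 (ms)", "Time-CHKP-2 (ms)",
                 "Total Time (ms)", "Errors", "Performance Ratio (ms/E)"))
  expect_equal(df2$`Performance Ratio (ms/E)`, "")  # zero errors: empty cell
})
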