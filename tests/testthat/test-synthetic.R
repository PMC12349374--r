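test_that("ratio rendering round-trips exactly without noise", {
  fr <- landmark_frames_from_ratios(c(0.5, -0.5))[[1]]
  s <- gaze_sample(fr, "Bin")
  expect_equal(s$ratio_right, 0.5, tolerance = 1e-12)
  expect_equal(s$ratio_V_right, -0.5, tolerance = 1e-12)
  expect_equal(s$ratio_left, 0.5, tolerance = 1e-12)

  # lateral ramp is recovered as the same ramp
  ramp <- seq(0.05, 0.95, length.out = 40)
  tr <- gaze_trace(landmark_frames_from_ratios(
    data.frame(lat_right = ramp, ap_right = -0.5,
               lat_left = ramp, ap_left = -0.5)), "Bin")
  expect_equal(tr$ratio_right, ramp, tolerance = 1e-9)
  expect_equal(tr$ratio_left, ramp, tolerance = 1e-9)

  expect_error(landmark_frames_from_ratios(c(1.2, -0.5)), "legal ranges")
})

test_that("pupil-position noise propagates to ratios at the stated level", {
  spec <- trace_spec(duration_s = 30, sample_hz = 30,
                     noise_sd = c(0.01, 0.01), seed = 123)
  tr <- generate_trace(spec)
  got <- gaze_trace(tr$frames, "Bin")
  rmse <- sqrt(mean((got$ratio_right - tr$truth$lat_right)^2))
  expect_lt(abs(rmse - 0.01), 0.002)  # within 20% of the programmed sd
  rmse_ap <- sqrt(mean((got$ratio_V_right - tr$truth$ap_right)^2))
  expect_lt(abs(rmse_ap - 0.01), 0.002)
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- trace_spec(noise_sd = c(0.02, 0.02), seed = 77)
  t1 <- generate_trace(spec)
  t2 <- generate_trace(spec)
  expect_identical(t1, t2)
  t3 <- generate_trace(trace_spec(noise_sd = c(0.02, 0.02), seed = 78))
  expect_false(identical(t1$frames, t3$frames))
})

test_that("the fixation protocol has the published shape", {
  prot <- generate_fixation_protocol(trials = 5, dwell_s = 2, sample_hz = 10,
                                     seed = 3)
  lab <- prot$labels
  # 5 trials x 2 axes x 3 segments x (2 s x 10 Hz)
  expect_equal(nrow(lab), 5 * 2 * 3 * 20)
  expect_setequal(unique(lab$axis), c("AP", "LAT"))
  expect_setequal(unique(lab$segment[lab$axis == "AP"]),
                  c("top", "center", "bottom"))
  expect_setequal(unique(lab$segment[lab$axis == "LAT"]),
                  c("right", "center", "left"))
  expect_equal(max(lab$trial), 5)

  # zero noise: variables orthogonal to the exercised axis have zero
  # variance (the exercised variable's spread reflects its three targets)
  tr <- gaze_trace(prot$frames, "Bin")
  stats <- fixation_validation_stats(tr, lab)
  lat_in_ap <- stats$axis == "AP" & stats$variable %in% c("ratio_right",
                                                          "ratio_left")
  ap_in_lat <- stats$axis == "LAT" & stats$variable %in% c("ratio_V_right",
                                                           "ratio_V_left")
  expect_true(all(stats$sd[lat_in_ap | ap_in_lat] < 1e-12))
  expect_true(all(stats$cv_percent[lat_in_ap | ap_in_lat] < 1e-9))

  # a single shared fixation target collapses every CV to zero
  prot0 <- generate_fixation_protocol(
    trials = 2, dwell_s = 1, sample_hz = 10,
    targets_lat = c(right = 0.5, center = 0.5, left = 0.5),
    targets_ap = c(top = -0.5, center = -0.5, bottom = -0.5), seed = 4)
  st0 <- fixation_validation_stats(gaze_trace(prot0$frames, "Bin"),
                                   prot0$labels)
  expect_true(all(st0$sd < 1e-12))
})

test_that("programmed fixation jitter is recovered as the matching CV", {
  prot <- generate_fixation_protocol(trials = 5, dwell_s = 4, sample_hz = 30,
                                     targets_lat = c(right = 0.45,
                                                     center = 0.45,
                                                     left = 0.45),
                                     targets_ap = c(top = -0.45,
                                                    center = -0.45,
                                                    bottom = -0.45),
                                     noise_sd = c(0.03, 0.03), seed = 9)
  tr <- gaze_trace(prot$frames, "Bin")
  stats <- fixation_validation_stats(tr, prot$labels)
  lat_right <- stats[stats$variable == "ratio_right" & stats$axis == "LAT", ]
  # sigma/mu = 0.03/0.45 = 6.67%
  expect_equal(lat_right$cv_percent, 100 * 0.03 / 0.45, tolerance = 0.08 * 6.7)
})

test_that("non-co-occurring per-eye minima leave the binocular minimum above their mean", {
  # left and right eyes sweep in antiphase, so their minima never co-occur
  spec <- trace_spec(duration_s = 8, sample_hz = 30,
                     binocular_offset = list(phase = pi), seed = 2)
  tr <- generate_trace(spec)
  g <- gaze_trace(tr$frames, "Bin")
  expect_gt(min(g$ratio_bin),
            (min(g$ratio_left) + min(g$ratio_right)) / 2 + 0.01)
})

test_that("maze_bot honours its collision script and tick accounting", {
  for (lvl in c(1, 4)) {
    m <- fixture_maze(lvl)
    clean <- maze_bot(m)
    res0 <- run_level(m, clean, tick_ms = 100)
    expect_true(res0$completed)
    expect_equal(res0$errors, 0)

    script <- data.frame(tick = c(2, 6, 11), dir = NA)
    cmds <- maze_bot(m, script)
    res3 <- run_level(m, cmds, tick_ms = 100)
    expect_equal(res3$errors, 3)
    expect_equal(res3$total_ms, (length(clean) + 3) * 100)
  }
  m <- fixture_maze(1)
  expect_error(maze_bot(m, data.frame(tick = c(5, 2), dir = NA)),
               "strictly increasing")
  expect_error(maze_bot(m, data.frame(tick = 2, dir = "LEFT")),
               "does not face a wall")
})
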