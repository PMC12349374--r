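# closed-form normal equations, independent of lm()
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  p <- 2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p)
}

test_that("OLS regression matches the normal-equations oracle", {
  x <- 1:6
  y <- c(3.1, 4.9, 7.2, 8.8, 11.4, 12.9)
  got <- linear_regression(x, y)
  want <- ols_oracle(x, y)
  expect_equal(got$slope, want$slope, tolerance = 1e-10)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
  expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
})

test_that("regression handles exact and degenerate fits", {
  x <- 1:5
  perfect <- linear_regression(x, 2 * x + 1)
  expect_equal(perfect$slope, 2, tolerance = 1e-12)
  expect_equal(perfect$intercept, 1, tolerance = 1e-12)
  expect_equal(perfect$r_squared, 1, tolerance = 1e-12)

  flat <- linear_regression(x, rep(4, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$p_value, 1)

  expect_error(linear_regression(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(linear_regression(1, 2), "at least 2")
  two <- linear_regression(1:2, c(5, 9))
  expect_true(is.na(two$p_value))
  expect_equal(two$slope, 4)
})

test_that("r_squared equals squared Pearson correlation; p is affine-invariant", {
  set.seed(21)
  for (rep in 1:10) {
    x <- 1:8
    y <- 0.5 * x + stats::rnorm(8)
    got <- linear_regression(x, y)
    expect_equal(got$r_squared, stats::cor(x, y)^2, tolerance = 1e-12)
    rescaled <- linear_regression(x, 1000 * y + 37)
    expect_equal(got$p_value, rescaled$p_value, tolerance = 1e-10)
  }
})

# textbook balanced two-factor SS decomposition
anova_ss_oracle <- function(df) {
  g <- mean(df$value)
  users <- unique(df$user); movs <- unique(df$movement)
  n_rep <- nrow(df) / (length(users) * length(movs))
  ss_user <- sum(vapply(users, function(u) {
    length(movs) * n_rep * (mean(df$value[df$user == u]) - g)^2
  }, numeric(1)))
  ss_mov <- sum(vapply(movs, function(m) {
    length(users) * n_rep * (mean(df$value[df$movement == m]) - g)^2
  }, numeric(1)))
  ss_cells <- 0
  for (u in users) for (m in movs) {
    cm <- mean(df$value[df$user == u & df$movement == m])
    ss_cells <- ss_cells + n_rep * (cm - g)^2
  }
  ss_int <- ss_cells - ss_user - ss_mov
  ss_tot <- sum((df$value - g)^2)
  list(user = ss_user, movement = ss_mov, interaction = ss_int,
       error = ss_tot - ss_cells, total = ss_tot)
}

make_anova_data <- function(user_effects, mov_effect = 0, n_rep = 5,
                            sd = 0.02, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(user = names(user_effects), movement = c("LAT", "AP"),
                      rep = seq_len(n_rep), stringsAsFactors = FALSE)
  grid$value <- 0.5 + user_effects[grid$user] +
    ifelse(grid$movement == "LAT", mov_effect / 2, -mov_effect / 2) +
    stats::rnorm(nrow(grid), 0, sd)
  grid
}

test_that("two-way ANOVA reproduces the textbook SS decomposition", {
  df <- make_anova_data(c(u1 = 0.02, u2 = -0.01), n_rep = 2, seed = 4)
  got <- two_way_anova(df)
  want <- anova_ss_oracle(df)
  expect_equal(got$ss[got$factor == "user"], want$user, tolerance = 1e-9)
  expect_equal(got$ss[got$factor == "movement"], want$movement,
               tolerance = 1e-9)
  expect_equal(got$ss[got$factor == "interaction"], want$interaction,
               tolerance = 1e-9)
  expect_equal(sum(got$ss), want$total, tolerance = 1e-9)
})

test_that("ANOVA rejects unbalanced designs and detects injected effects", {
  same <- expand.grid(user = c("a", "b"), movement = c("LAT", "AP"),
                      rep = 1:3, stringsAsFactors = FALSE)
  same$value <- 0.5
  res0 <- two_way_anova(same)
  expect_equal(res0$F[res0$factor != "residual"], c(0, 0, 0))

  unbal <- make_anova_data(c(u1 = 0, u2 = 0), n_rep = 2, seed = 6)
  unbal <- rbind(unbal,
                 data.frame(user = "u1", movement = "LAT", rep = 3,
                            value = 0.5))
  expect_error(two_way_anova(unbal), "unbalanced")
  single <- make_anova_data(c(u1 = 0, u2 = 0), n_rep = 1, seed = 6)
  expect_error(two_way_anova(single), "2 replicates")

  # user main effect injected, no movement effect: F(User) dominates
  df <- make_anova_data(c(u1 = 0.05, u2 = -0.02, u3 = 0.03, u4 = -0.06),
                        mov_effect = 0, n_rep = 5, sd = 0.02, seed = 8)
  res <- two_way_anova(df)
  expect_gt(res$F[res$factor == "user"], res$F[res$factor == "movement"])
  expect_lt(res$p_value[res$factor == "user"], 0.01)
})

test_that("fixation validation emits one row per user, axis and variable", {
  rows <- list()
  for (u in 1:2) {
    prot <- generate_fixation_protocol(trials = 2, dwell_s = 1,
                                       sample_hz = 10,
                                       noise_sd = c(0.02, 0.02),
                                       seed = 30 + u,
                                       user = sprintf("user%d", u))
    tr <- gaze_trace(prot$frames, "Bin")
    rows[[u]] <- fixation_validation_stats(tr, prot$labels)
  }
  st <- do.call(rbind, rows)
  expect_equal(nrow(st), 2 * 2 * 4)  # users x axes x variables
  expect_true(all(st$sd >= 0))
  expect_true(all(st$cv_percent >= 0))
})

test_that("weekly report bundles ellipses, tables and regressions", {
  mazes <- lapply(1:2, fixture_maze)
  make_record <- function(i, extra_ticks) {
    spec <- trace_spec(duration_s = 3, sample_hz = 20, seed = 40 + i)
    tr <- generate_trace(spec)
    g <- gaze_trace(tr$frames, "Bin")
    cmds <- lapply(mazes, function(m) {
      c(maze_bot(m), rep("STAY", extra_ticks))  # pad: STAY after finish is ignored
    })
    # slow sessions down by injecting STAY before the final approach
    cmds <- lapply(cmds, function(cc) c(rep("STAY", extra_ticks), cc))
    run_session(mazes, cmds, user_id = sprintf("u%d", i), gaze = g)
  }
  # five sessions with linearly decreasing padding -> decreasing total time
  records <- lapply(1:5, function(i) make_record(i, extra_ticks = 6 * (5 - i)))
  dir <- withr::local_tempdir()
  bundle <- weekly_report(records, dir)
  expect_equal(bundle$n_sessions, 5)
  expect_lt(bundle$regressions$total_time$slope, 0)
  expect_gt(bundle$regressions$total_time$r_squared, 0.9)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "tables", "displacement.csv")))
  expect_true(file.exists(file.path(dir, "tables", "sessions.csv")))
  expect_true(file.exists(file.path(dir, "figures", "ellipses.svg")))
  expect_true(file.exists(file.path(dir, "figures", "regression.svg")))

  # reproducibility: identical inputs give an identical report.json
  dir2 <- withr::local_tempdir()
  weekly_report(records, dir2)
  expect_identical(readLines(file.path(dir, "report.json")),
                   readLines(file.path(dir2, "report.json")))

  # single session: ellipses present, regression omitted
  dir3 <- withr::local_tempdir()
  b1 <- weekly_report(records[1], dir3)
  expect_null(b1$regressions)
  expect_equal(length(b1$ellipses), 1)
})
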