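#' Ordinary least squares progress regression
#'
#' Fits `y ~ x` by ordinary least squares (session index against total
#' time or error count), returning the slope, intercept, coefficient of
#' determination and the two-sided p-value of the slope (t distribution,
#' n - 2 degrees of freedom). A constant response is reported as slope 0,
#' `r_squared` 0 and p-value 1.
#'
#' @param x Numeric predictor (e.g. session indices); not all equal.
#' @param y Numeric response, same length.
#' @return An object of class `"regression_result"`: `slope`, `intercept`,
#'   `r_squared`, `p_value` (`NA` when `n < 3`), `n`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("regression requires at least 2 points", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("degenerate predictor: x values are all equal", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    res <- list(slope = 0, intercept = y[1], r_squared = 0,
                p_value = if (n >= 3L) 1 else NA_real_, n = n)
    return(structure(res, class = "regression_result"))
  }
  fit <- lm(y ~ x)
  # summary.lm warns on numerically perfect fits; those are legitimate
  # inputs here (noise-free synthetic trends) and handled below
  sm <- suppressWarnings(summary(fit))
  p <- if (n >= 3L) unname(sm$coefficients["x", "Pr(>|t|)"]) else NA_real_
  # a numerically perfect fit has zero residual variance and an undefined
  # t statistic; report certainty directly
  if (n >= 3L && is.nan(p)) p <- if (coef(fit)[["x"]] == 0) 1 else 0
  structure(list(slope = unname(coef(fit)[["x"]]),
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 r_squared = sm$r.squared,
                 p_value = p, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope %.4g, intercept %.4g, R^2 %.4f, p %.4g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Two-way fixed-effects ANOVA (user x movement)
#'
#' Standard two-factor sums-of-squares decomposition with interaction on
#' a balanced design, as used to test whether recorded gaze ratios differ
#' between users and between movement axes.
#'
#' @param data Data frame with columns `user`, `movement` and `value`;
#'   the design must be balanced with at least 2 replicates per cell.
#' @return An object of class `"anova_result"`: a tibble with columns
#'   `factor` (`"user"`, `"movement"`, `"interaction"`, `"residual"`),
#'   `df`, `ss`, `F`, `p_value` (`F`/`p_value` are `NA` for the residual
#'   row).
#' @export
two_way_anova <- function(data) {
  need <- c("user", "movement", "value")
  if (!all(need %in% names(data))) {
    stop("data must have columns user, movement, value", call. = FALSE)
  }
  data$user <- factor(data$user)
  data$movement <- factor(data$movement)
  counts <- table(data$user, data$movement)
  if (length(unique(as.vector(counts))) != 1L) {
    stop("unbalanced design: every user x movement cell needs the same number of replicates",
         call. = FALSE)
  }
  if (counts[1] < 2L) {
    stop("design requires at least 2 replicates per cell", call. = FALSE)
  }
  fit <- aov(value ~ user * movement, data = data)
  tab <- suppressWarnings(anova(fit))  # constant-response case handled below
  # a constant response has no variance to partition: every statistic is a
  # 0/0 form (numerically, a ratio of rounding noise); report no evidence
  if (sum((data$value - mean(data$value))^2) < 1e-20) {
    not_resid <- rownames(tab) != "Residuals"
    tab$`F value`[not_resid] <- 0
    tab$`Pr(>F)`[not_resid] <- 1
  }
  rn <- rownames(tab)
  pick <- function(term) which(trimws(rn) == term)
  out <- tibble::tibble(
    factor = c("user", "movement", "interaction", "residual"),
    df = c(tab$Df[pick("user")], tab$Df[pick("movement")],
           tab$Df[pick("user:movement")], tab$Df[pick("Residuals")]),
    ss = c(tab$`Sum Sq`[pick("user")], tab$`Sum Sq`[pick("movement")],
           tab$`Sum Sq`[pick("user:movement")],
           tab$`Sum Sq`[pick("Residuals")]),
    F = c(tab$`F value`[pick("user")], tab$`F value`[pick("movement")],
          tab$`F value`[pick("user:movement")], NA_real_),
    p_value = c(tab$`Pr(>F)`[pick("user")], tab$`Pr(>F)`[pick("movement")],
                tab$`Pr(>F)`[pick("user:movement")], NA_real_))
  structure(out, class = c("anova_result", class(out)))
}

#' Fixation-validation statistics table
#'
#' Summarizes fixation-protocol traces per user and tracked variable in
#' the validation-table layout: mean, sample standard deviation and
#' coefficient of variation of `ratio_right`, `ratio_V_right`,
#' `ratio_left` and `ratio_V_left`, separately for the anteroposterior
#' and lateral trial blocks. Samples of a block are pooled across its
#' trials and dwell segments.
#'
#' @param trace A gaze trace tibble carrying the four ratio columns.
#' @param labels Protocol labels aligned row-for-row with `trace`
#'   (tibble with `user`, `axis`, `trial`, `segment`; see
#'   [generate_fixation_protocol()]).
#' @return Tibble with columns `axis`, `user`, `variable`, `mean`, `sd`,
#'   `cv_percent` (4 variables per user per axis).
#' @export
fixation_validation_stats <- function(trace, labels) {
  if (nrow(trace) != nrow(labels)) {
    stop("trace and labels must align row-for-row", call. = FALSE)
  }
  vars <- c("ratio_right", "ratio_V_right", "ratio_left", "ratio_V_left")
  rows <- list()
  for (ax in unique(labels$axis)) {
    for (u in unique(labels$user)) {
      keep <- labels$axis == ax & labels$user == u
      if (!any(keep)) next
      sub <- trace[keep, , drop = FALSE]
      for (v in vars) {
        vals <- sub[[v]]
        vals <- vals[!is.na(vals)]
        m <- mean(vals)
        s <- if (length(vals) >= 2L) sd(vals) else NA_real_
        rows[[length(rows) + 1L]] <- tibble::tibble(
          axis = ax, user = u, variable = v, mean = m, sd = s,
          cv_percent = if (!is.na(s) && m != 0) 100 * s / abs(m) else NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}

ellipse_points <- function(e, n = 120) {
  th <- seq(0, 2 * pi, length.out = n)
  data.frame(x = e$center_x + e$semi_axis_x * cos(th),
             y = e$center_y + e$semi_axis_y * sin(th))
}

#' Weekly report bundle
#'
#' Builds the session-over-session report: per-session ellipse parameters,
#' the displacement- and session-table CSVs, OLS regressions of total
#' time and errors against session index (omitted when fewer than two
#' complete sessions exist), and SVG figures (ellipses, displacement vs
#' time of the last session, regression line). All numbers are also
#' serialized to `report.json` so downstream checks can assert on data
#' rather than pixels.
#'
#' @param records List of `session_record` objects (see [run_session()]),
#'   each carrying a gaze trace.
#' @param dir Output directory (created if needed); receives
#'   `report.json`, `tables/*.csv`, `figures/*.svg`.
#' @return The report bundle (list), invisibly.
#' @export
weekly_report <- function(records, dir) {
  if (length(records) == 0L) stop("at least one session record is required",
                                  call. = FALSE)
  dir.create(file.path(dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "figures"), recursive = TRUE, showWarnings = FALSE)

  eye_for_mode <- function(mode) switch(mode, "Bin" = "binocular",
                                        "Mon-Izq" = "left", "Mon-Der" = "right")
  ellipses <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    e <- session_ellipse(r$gaze, eye_for_mode(r$mode))
    list(session = i, user_id = r$user_id, mode = r$mode,
         center_x = e$center_x, center_y = e$center_y,
         semi_axis_x = e$semi_axis_x, semi_axis_y = e$semi_axis_y)
  })

  totals <- vapply(records, function(r) {
    tm <- vapply(r$levels, function(l) l$total_ms, numeric(1))
    if (anyNA(tm)) NA_real_ else sum(tm)
  }, numeric(1))
  errs <- vapply(records, function(r) {
    sum(vapply(r$levels, function(l) l$errors, numeric(1)))
  }, numeric(1))
  idx <- seq_along(records)
  complete <- !is.na(totals)
  regressions <- NULL
  if (sum(complete) >= 2L) {
    regressions <- list(
      total_time = unclass(linear_regression(idx[complete], totals[complete])),
      errors = unclass(linear_regression(idx[complete], errs[complete])))
  }

  disp_sessions <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    list(id = if (is.na(r$user_id)) i else r$user_id,
         extremes = displacement_extremes(r$gaze, r$mode), mode = r$mode)
  })
  export_displacement_csv(disp_sessions,
                          file.path(dir, "tables", "displacement.csv"))
  lvl_sessions <- list()
  for (i in seq_along(records)) {
    r <- records[[i]]
    for (l in r$levels) {
      lvl_sessions[[length(lvl_sessions) + 1L]] <-
        list(id = if (is.na(r$user_id)) i else r$user_id, result = l)
    }
  }
  export_session_csv(lvl_sessions, file.path(dir, "tables", "sessions.csv"))

  # figures ---------------------------------------------------------------
  ell_df <- do.call(rbind, lapply(ellipses, function(e) {
    cbind(session = factor(e$session),
          ellipse_points(list(center_x = e$center_x, center_y = e$center_y,
                              semi_axis_x = e$semi_axis_x,
                              semi_axis_y = e$semi_axis_y)))
  }))
  save_svg <- function(p, name, width = 6, height = 4) {
    path <- file.path(dir, "figures", name)
    grDevices::svg(path, width = width, height = height)
    print(p)
    grDevices::dev.off()
    path
  }
  save_svg(
    ggplot2::ggplot(ell_df, ggplot2::aes(x = x, y = y, colour = session)) +
      ggplot2::geom_path() +
      ggplot2::labs(x = "lateral ratio", y = "anteroposterior ratio",
                    title = "Session displacement ellipses") +
      ggplot2::theme_minimal(),
    "ellipses.svg")

  last <- records[[length(records)]]
  disp_long <- do.call(rbind, lapply(names(SIGNAL_COLS), function(s) {
    v <- last$gaze[[SIGNAL_COLS[[s]]]]
    if (all(is.na(v))) return(NULL)
    data.frame(t_ms = last$gaze$t_ms, signal = s, value = v)
  }))
  save_svg(
    ggplot2::ggplot(disp_long, ggplot2::aes(x = t_ms, y = value,
                                            colour = signal)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (ms)", y = "ratio",
                    title = "Displacement vs time (last session)") +
      ggplot2::theme_minimal(),
    "displacement.svg")

  if (!is.null(regressions)) {
    reg_df <- data.frame(session = idx[complete], value = totals[complete])
    r <- regressions$total_time
    save_svg(
      ggplot2::ggplot(reg_df, ggplot2::aes(x = session, y = value)) +
        ggplot2::geom_point() +
        ggplot2::geom_abline(slope = r$slope, intercept = r$intercept,
                             colour = "steelblue") +
        ggplot2::labs(x = "session", y = "total time (ms)",
                      title = sprintf("Total time vs session (R^2 = %.3f, p = %.3g)",
                                      r$r_squared, r$p_value)) +
        ggplot2::theme_minimal(),
      "regression.svg")
  }

  bundle <- list(
    n_sessions = length(records),
    ellipses = ellipses,
    totals_ms = totals,
    errors = errs,
    regressions = regressions)
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(bundle)
}
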