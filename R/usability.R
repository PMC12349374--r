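#' System Usability Scale score of one questionnaire
#'
#' Standard SUS scoring: odd items contribute `value - 1`, even items
#' `5 - value`, and the summed contributions are scaled by 2.5 onto
#' 0-100. Any score derived from items is therefore a multiple of 2.5.
#'
#' @param items Exactly 10 integer Likert responses, each in 1..5,
#'   ordered q1..q10.
#' @return Score in `[0, 100]`.
#' @export
sus_score <- function(items) {
  if (length(items) != 10L) {
    stop("a SUS response has exactly 10 items", call. = FALSE)
  }
  if (anyNA(items) || !is.numeric(items) || any(items != as.integer(items)) ||
      any(items < 1) || any(items > 5)) {
    stop("SUS items must be integers in 1..5", call. = FALSE)
  }
  odd <- items[c(1, 3, 5, 7, 9)]
  even <- items[c(2, 4, 6, 8, 10)]
  (sum(odd - 1) + sum(5 - even)) * 2.5
}

#' SUS score category
#'
#' Scores are banded into three levels: 0-50 "Unacceptable", 51-68
#' "Marginal" (neutral opinion) and 69-100 "Acceptable"; boundaries are
#' implemented as `<= 50` / `<= 68` / `> 68`.
#'
#' @param score Score(s) in `[0, 100]`. Vectorized.
#' @return Character vector of categories.
#' @export
sus_category <- function(score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 100)) {
    stop("scores must lie in [0, 100]", call. = FALSE)
  }
  ifelse(score <= 50, "Unacceptable",
         ifelse(score <= 68, "Marginal", "Acceptable"))
}

trunc2 <- function(x) floor(x * 100 + 1e-9) / 100

#' Aggregate SUS scores over a cohort
#'
#' Mean, sample standard deviation (n-1), per-category counts and rates.
#' The acceptance and unacceptable rates are truncated (not rounded) to
#' two decimals; the marginal rate is the complement so the three rates
#' sum to 100.
#'
#' @param scores Numeric vector of SUS scores, or a data frame with a
#'   `score` column (e.g. from [read_sus_csv()]).
#' @return List: `n`, `mean`, `sd` (`NA` when `n < 2`), `counts` (named:
#'   Acceptable/Marginal/Unacceptable), `acceptance_rate_pct`,
#'   `marginal_rate_pct`, `unacceptable_rate_pct`.
#' @export
aggregate_sus <- function(scores) {
  if (is.data.frame(scores)) {
    if (!"score" %in% names(scores)) {
      stop("data frame input must have a 'score' column", call. = FALSE)
    }
    scores <- scores$score
  }
  scores <- as.numeric(scores)
  if (length(scores) == 0L || anyNA(scores)) {
    stop("at least one non-missing score is required", call. = FALSE)
  }
  n <- length(scores)
  cats <- factor(sus_category(scores),
                 levels = c("Acceptable", "Marginal", "Unacceptable"))
  counts <- table(cats)
  acc <- trunc2(100 * counts[["Acceptable"]] / n)
  unacc <- trunc2(100 * counts[["Unacceptable"]] / n)
  list(n = n,
       mean = mean(scores),
       sd = if (n >= 2L) sd(scores) else NA_real_,
       counts = setNames(as.integer(counts), names(counts)),
       acceptance_rate_pct = acc,
       marginal_rate_pct = 100 - acc - unacc,
       unacceptable_rate_pct = unacc)
}

#' Read a SUS survey table
#'
#' Accepts either item-level responses (columns `q1`..`q10`, scored with
#' [sus_score()]) or precomputed scores (a `Score` or `score` column, as
#' in the published survey-table layout `Id, Age, Sex, Visual Condition,
#' Score`). Scores not on the 2.5 grid that item-derived scores live on
#' are kept as-is but flagged in the `"off_grid"` attribute.
#'
#' @param path CSV file path.
#' @return Tibble with columns `id`, `age`, `sex`, `visual_condition`,
#'   `score` (columns absent from the file are `NA`).
#' @export
read_sus_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("SUS file not found: %s", path), call. = FALSE)
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nml <- tolower(names(df))
  col <- function(nm) if (nm %in% nml) df[[which(nml == nm)[1]]] else NA
  qcols <- paste0("q", 1:10)
  if (all(qcols %in% nml)) {
    items <- as.matrix(df[, match(qcols, nml)])
    score <- apply(items, 1, sus_score)
  } else if ("score" %in% nml) {
    score <- as.numeric(col("score"))
  } else {
    stop("SUS CSV must contain either q1..q10 item columns or a Score column",
         call. = FALSE)
  }
  out <- tibble::tibble(
    id = col("id"), age = col("age"), sex = col("sex"),
    visual_condition = col("visual condition"),
    score = score)
  if (all(is.na(out$visual_condition))) {
    out$visual_condition <- col("visual_condition")
  }
  attr(out, "off_grid") <- which(abs(score / 2.5 - round(score / 2.5)) > 1e-9)
  out
}

#' Packaged usability survey fixture
#'
#' The published 15-respondent usability survey (`Id, Age, Sex, Visual
#' Condition, Score`), shipped as a CSV fixture.
#'
#' @return Tibble as returned by [read_sus_csv()].
#' @export
sus_survey_fixture <- function() {
  read_sus_csv(system.file("extdata", "sus_survey.csv", package = "gazemaze",
                           mustWork = TRUE))
}
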