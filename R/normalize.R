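#' @name normalize
#' @title Per-analyte series, z-score adjustment and derived features
#'
#' @description
#' Analytes are analysed per (code, unit) pair — no unit conversions are ever
#' performed, to avoid batch effects between laboratory feeds. Values are
#' adjusted for sex and age by ordinary least squares and expressed as
#' z-scores (residuals divided by the residual standard deviation). Helpers
#' extract the latest value per person, categorise values against laboratory
#' reference ranges, and build nearest-date ratio features between two
#' analytes.
NULL

#' Split measurements into per-(analyte, unit) series
#'
#' @param measurements Measurements data.frame (typically windowed, i.e.
#'   carrying `days_before` and `role`).
#' @return Named list of data.frames, one per distinct (analyte_code, unit),
#'   names `"code|unit"`. Observation counts are conserved.
#' @export
split_by_unit <- function(measurements) {
  key <- paste(measurements$analyte_code, measurements$unit, sep = "|")
  split(measurements, key)
}

#' Sex/age-adjusted z-scores for one series
#'
#' Ordinary least squares of value on intercept, sex (optional) and age at
#' the measurement date; residuals are divided by the residual standard
#' deviation. Requires at least `min_n` observations and non-degenerate age
#' variation (and both sexes when `adjust_sex = TRUE`).
#'
#' @param series One series data.frame with columns `person_id`, `value`,
#'   `date`, `age` (age at measurement, years) and `sex`.
#' @param adjust_sex Include a sex indicator (set `FALSE` for single-sex
#'   sub-groups).
#' @param min_n Minimum observations (default 10, for a stable residual sd).
#' @return The input data.frame with an added `z` column, or `NULL` (with a
#'   message attribute via warning suppressed) when the design is degenerate.
#' @export
adjust_zscore <- function(series, adjust_sex = TRUE, min_n = 10) {
  if (nrow(series) < min_n) return(NULL)
  if (stats::var(series$age) == 0) return(NULL)
  if (adjust_sex) {
    if (length(unique(series$sex)) < 2) return(NULL)
    fit <- stats::lm(value ~ sex + age, data = series)
  } else {
    fit <- stats::lm(value ~ age, data = series)
  }
  r <- stats::residuals(fit)
  s <- stats::sd(r)
  if (!is.finite(s)) return(NULL)
  # a numerically perfect fit has no residual scale: all z are exactly 0
  if (s <= 1e-10 * max(stats::sd(series$value), 1)) {
    series$z <- 0
  } else {
    series$z <- as.numeric(r) / s
  }
  series
}

#' Attach age-at-measurement to windowed measurements
#'
#' Age at the measurement date given each person's birth year:
#' `floor((index_date - Jan 1 birth_year)/365.25) - days_before/365.25`.
#'
#' @param windowed Output of [window_filter()].
#' @param persons Persons data.frame (`person_id`, `sex`, `birth_year`).
#' @return `windowed` with added `sex` and `age` columns.
#' @export
attach_demographics <- function(windowed, persons) {
  m <- match(windowed$person_id, persons$person_id)
  windowed$sex <- persons$sex[m]
  jan1 <- as.Date(paste0(persons$birth_year[m], "-01-01"))
  age_idx <- floor(as.numeric(windowed$index_date - jan1) / 365.25)
  windowed$age <- age_idx - windowed$days_before / 365.25
  windowed
}

#' Latest observation per person
#'
#' Maximum date per person; ties on date are broken by the larger row
#' ordinal (later record in the stable input order), which is deterministic
#' across runs.
#'
#' @param series A series (or adjusted series) data.frame with `person_id`
#'   and `date`.
#' @return One row per person with at least one observation.
#' @export
latest_per_person <- function(series) {
  if (nrow(series) == 0L) return(series)
  ord <- order(series$person_id, series$date, seq_len(nrow(series)))
  s <- series[ord, , drop = FALSE]
  last <- !duplicated(s$person_id, fromLast = TRUE)
  out <- s[last, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorise a value against its reference range
#'
#' Boundaries are inclusive into "within" (a value at the limit is not
#' flagged). Either bound absent yields "unknown".
#'
#' @param value Numeric vector.
#' @param ref_low,ref_high Numeric vectors (NA = absent).
#' @return Character vector in `{below, within, above, unknown}`.
#' @export
categorize_reference <- function(value, ref_low, ref_high) {
  out <- rep("unknown", length(value))
  known <- !is.na(ref_low) & !is.na(ref_high)
  out[known & value < ref_low] <- "below"
  out[known & value > ref_high] <- "above"
  out[known & value >= ref_low & value <= ref_high] <- "within"
  out
}

#' Nearest-date ratio feature between two series
#'
#' For each person present in both series, the (a, b) observation pair
#' minimising `|date_a - date_b|` is chosen (ties broken by the later
#' max date); the feature is `value_a / value_b`, dated at the later of the
#' two dates. Persons whose chosen pair has a zero denominator are skipped
#' and reported.
#'
#' @param series_a,series_b Series data.frames (`person_id`, `date`,
#'   `value`).
#' @return data.frame `person_id`, `date`, `value` (the ratio), plus
#'   attribute `skipped` (person ids skipped for zero denominators).
#' @export
pair_ratio <- function(series_a, series_b) {
  ppl <- intersect(unique(series_a$person_id), unique(series_b$person_id))
  rows <- vector("list", length(ppl))
  skipped <- character(0)
  a_split <- split(series_a, series_a$person_id)
  b_split <- split(series_b, series_b$person_id)
  for (i in seq_along(ppl)) {
    a <- a_split[[ppl[i]]]
    b <- b_split[[ppl[i]]]
    gap <- abs(outer(as.numeric(a$date), as.numeric(b$date), "-"))
    later <- outer(as.numeric(a$date), as.numeric(b$date), pmax)
    best <- which(gap == min(gap), arr.ind = TRUE)
    if (nrow(best) > 1) {
      lt <- later[best]
      best <- best[order(-lt, best[, 1], best[, 2]), , drop = FALSE]
    }
    ia <- best[1, 1]; ib <- best[1, 2]
    if (b$value[ib] == 0) {
      skipped <- c(skipped, ppl[i])
      next
    }
    rows[[i]] <- data.frame(
      person_id = ppl[i],
      date = max(a$date[ia], b$date[ib]),
      value = a$value[ia] / b$value[ib],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(person_id = character(), date = as.Date(character()),
                      value = numeric(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}
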