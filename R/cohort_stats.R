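#' Clinical classification rules and descriptive cohort statistics
#'
#' Rule-based pieces of the evaluation system: the glucose diagnosis
#' rule, the elderly type-2 glycemic-control target table, year-on-year
#' trend differences in percentage points, proportion tabulations and
#' age/sex structure tables.
#'
#' @name cohort_stats
NULL

#' Diagnose diabetes from glucose measurements
#'
#' Diabetic iff fasting glucose >= 7.0 mmol/L or 2-hour postprandial
#' glucose >= 11.1 mmol/L; boundary values inclusive. Either measurement
#' may be absent (`NA`), but not both.
#'
#' @param fasting_mmol_L fasting glucose in mmol/L, or `NA`.
#' @param two_hour_mmol_L 2-hour postprandial glucose in mmol/L, or `NA`.
#' @return `"diabetic"` or `"not-diabetic"` (vectorized over inputs).
#' @examples
#' diagnose(7.0, NA)    # diabetic (boundary inclusive)
#' diagnose(6.9, 11.0)  # not-diabetic
#' @export
diagnose <- function(fasting_mmol_L = NA_real_, two_hour_mmol_L = NA_real_) {
  f <- as.numeric(fasting_mmol_L)
  h <- as.numeric(two_hour_mmol_L)
  n <- max(length(f), length(h))
  f <- rep_len(f, n)
  h <- rep_len(h, n)
  if (any(is.na(f) & is.na(h))) {
    stop("at least one of fasting and 2-hour glucose must be present",
         call. = FALSE)
  }
  if (any(f < 0, na.rm = TRUE) || any(h < 0, na.rm = TRUE)) {
    stop("glucose measurements must be non-negative", call. = FALSE)
  }
  pos <- (!is.na(f) & f >= 7.0) | (!is.na(h) & h >= 11.1)
  ifelse(pos, "diabetic", "not-diabetic")
}

#' Glycemic control targets for elderly type 2 diabetes
#'
#' The target table by health status: upper HbA1c threshold (%), fasting
#' or pre-meal glucose range and bedtime glucose range (both mmol/L).
#' Thresholds relax strictly from healthy to poor health.
#'
#' @return data frame with one row per health status.
#' @export
glycemic_target_table <- function() {
  data.frame(
    status = c("healthy", "moderate health", "poor health"),
    hba1c_max = c(7.5, 8.0, 8.5),
    fasting_lo = c(5.0, 5.0, 5.6),
    fasting_hi = c(7.2, 8.3, 10.0),
    bedtime_lo = c(5.0, 5.6, 6.1),
    bedtime_hi = c(8.3, 10.0, 11.1),
    stringsAsFactors = FALSE
  )
}

#' Look up glycemic targets for one health status
#'
#' @param status one of `"healthy"`, `"moderate health"`, `"poor health"`.
#' @return list with `hba1c_max` (%), `fasting` (length-2 range, mmol/L)
#'   and `bedtime` (length-2 range, mmol/L).
#' @examples
#' glycemic_targets("healthy")$hba1c_max  # 7.5
#' @export
glycemic_targets <- function(status) {
  tab <- glycemic_target_table()
  i <- match(status, tab$status)
  if (is.na(i)) {
    stop(sprintf("unknown health status `%s`; expected one of %s", status,
                 paste(tab$status, collapse = ", ")), call. = FALSE)
  }
  list(hba1c_max = tab$hba1c_max[i],
       fasting = c(tab$fasting_lo[i], tab$fasting_hi[i]),
       bedtime = c(tab$bedtime_lo[i], tab$bedtime_hi[i]))
}

#' Percentage-point change between two years of a proportion series
#'
#' `proportion(to_year) - proportion(from_year)`, rounded half away from
#' zero to 2 decimals.
#'
#' @param series data frame with columns `year` and `proportion` (%), or
#'   a named numeric vector (names = years).
#' @param from_year,to_year years present in the series.
#' @return signed percentage-point difference.
#' @examples
#' s <- data.frame(year = c(2015, 2018), proportion = c(28.76, 37.57))
#' trend_change(s, 2015, 2018)  # 8.81
#' @export
trend_change <- function(series, from_year, to_year) {
  if (!is.data.frame(series)) {
    series <- data.frame(year = as.numeric(names(series)),
                         proportion = as.numeric(series))
  }
  stopifnot(all(c("year", "proportion") %in% names(series)))
  if (any(series$proportion < 0 | series$proportion > 100)) {
    stop("proportions must lie in [0, 100]", call. = FALSE)
  }
  lookup <- function(y) {
    i <- match(y, series$year)
    if (is.na(i)) stop(sprintf("year %s not in series", y), call. = FALSE)
    series$proportion[i]
  }
  round_half_up(lookup(to_year) - lookup(from_year), 2)
}

#' Tabulate category proportions
#'
#' Converts labeled counts into percentages of the total, rounded half
#' away from zero to 2 decimals.
#'
#' @param counts named non-negative numeric vector with positive total.
#' @return data frame with columns `category`, `count`, `proportion`.
#' @examples
#' tabulate_proportions(c(a = 1, b = 1))  # 50 / 50
#' @export
tabulate_proportions <- function(counts) {
  counts <- unlist(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  data.frame(
    category = if (is.null(names(counts))) as.character(seq_along(counts))
               else names(counts),
    count = as.numeric(counts),
    proportion = round_half_up(100 * counts / total, 2),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Age/sex structure table
#'
#' Counts patients per decade age band (`[0,10)`, `[10,20)`, ...) and
#' sex; the grand total equals the cohort size.
#'
#' @param patients data frame with numeric `age` and a `sex` column.
#' @return contingency table (bands x sex); an all-zero 0-row table for
#'   empty input.
#' @export
age_sex_table <- function(patients) {
  stopifnot(is.data.frame(patients), all(c("age", "sex") %in% names(patients)))
  if (nrow(patients) == 0L) {
    return(table(band = factor(character(0)), sex = factor(character(0))))
  }
  if (any(patients$age < 0 | !is.finite(patients$age))) {
    stop("ages must be finite and non-negative", call. = FALSE)
  }
  top <- 10 * (max(patients$age) %/% 10 + 1)
  breaks <- seq(0, top, by = 10)
  band <- cut(patients$age, breaks = breaks, right = FALSE,
              labels = sprintf("[%d,%d)", utils::head(breaks, -1),
                               utils::tail(breaks, -1)))
  table(band = band, sex = patients$sex)
}
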