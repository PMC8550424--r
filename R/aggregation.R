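#' Percent change between two values
#'
#' `100 * (value_to - value_from) / value_from`, the signed percent change
#' from a baseline, e.g. a country's age-standardized DALY rate in 1990 vs
#' 2017. Carried at full precision; round only for display with
#' [format_percent()].
#'
#' @param value_from baseline value, strictly positive.
#' @param value_to comparison value, nonnegative.
#' @return signed percent (vectorised).
#' @examples
#' percent_change(6400.68, 8590.04)   # +34.21 after display rounding
#' @export
percent_change <- function(value_from, value_to) {
  if (any(!is.finite(value_from)) || any(value_from <= 0)) {
    stop("percent_change: baseline value_from must be > 0")
  }
  if (any(!is.finite(value_to)) || any(value_to < 0)) {
    stop("percent_change: value_to must be >= 0")
  }
  100 * (value_to - value_from) / value_from
}

#' Percent by which one value exceeds another
#'
#' `100 * (a - b) / b`: how much higher `a` is than the reference `b`, e.g.
#' a female rate relative to the male rate in the same country-year.
#' Identical formula to [percent_change()] with the reference as baseline,
#' kept as a separate verb because the two framings appear in different
#' statistics.
#'
#' @param a value compared, nonnegative.
#' @param b reference value, strictly positive.
#' @return signed percent (vectorised).
#' @export
percent_higher <- function(a, b) {
  if (any(!is.finite(b)) || any(b <= 0)) {
    stop("percent_higher: reference b must be > 0")
  }
  if (any(!is.finite(a)) || any(a < 0)) {
    stop("percent_higher: a must be >= 0")
  }
  100 * (a - b) / b
}

#' Ratio of two group sums
#'
#' @param sum_a,sum_b strictly positive totals.
#' @return `sum_a / sum_b`.
#' @export
group_ratio <- function(sum_a, sum_b) {
  if (any(!is.finite(sum_a)) || any(sum_a <= 0) ||
      any(!is.finite(sum_b)) || any(sum_b <= 0)) {
    stop("group_ratio: both sums must be > 0")
  }
  sum_a / sum_b
}

#' Display rounding, half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (so 0.125 at 2
#' decimals is 0.13, and -0.125 is -0.13), matching the printed two-decimal
#' percent statistics. Use only at presentation time.
#'
#' @param x numeric.
#' @param digits decimal places, default 2.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a percent for display
#'
#' @param x percent value at full precision.
#' @param digits decimal places, default 2.
#' @return character, e.g. `"34.21"`.
#' @export
format_percent <- function(x, digits = 2) {
  formatC(round_half_away(x, digits), format = "f", digits = digits)
}

.check_rate_slice <- function(records) {
  if (nrow(records) == 0L) return(invisible(NULL))
  if (!all(records$metric == "Rate")) {
    stop("records must be filtered to metric = 'Rate'")
  }
  if (!all(records$age == "Age-standardized")) {
    stop("records must be filtered to age = 'Age-standardized'")
  }
  if (length(unique(records$measure)) > 1L) {
    stop("records mix measures: ",
         paste(unique(records$measure), collapse = ", "))
  }
  invisible(NULL)
}

#' Sum age-standardized rates over an income group
#'
#' The per-year "group total" plotted in the stacked-bar burden figures: a
#' plain sum of the member countries' age-standardized rates for one year
#' and sex (not a population-weighted mean). Member countries absent from
#' the table contribute zero and are reported in `missing`.
#'
#' @param records burden records already filtered to `metric = "Rate"`,
#'   `age = "Age-standardized"`, one measure.
#' @param groups an `income_group_table` from [load_income_groups()].
#' @param class `"low"` or `"high"`.
#' @param year integer year.
#' @param sex `"Both"`, `"Male"` or `"Female"`.
#' @return list of class `group_year_sum`: `income_class`, `year`, `sex`,
#'   `total`, `n_contributing`, `missing` (character vector of absent
#'   members).
#' @export
sum_group_rate <- function(records, groups, class = c("low", "high"),
                           year, sex = "Both") {
  class <- match.arg(class)
  stopifnot(length(year) == 1L, length(sex) == 1L)
  .check_rate_slice(records)
  members <- income_members(groups, class)
  sub <- records[records$location %in% members &
                   records$year == year & records$sex == sex, , drop = FALSE]
  dup <- sub$location[duplicated(sub$location)]
  if (length(dup)) {
    stop("ambiguous input: duplicate rows for (location, year, sex): ",
         paste(unique(dup), collapse = ", "))
  }
  missing <- setdiff(members, sub$location)
  structure(list(income_class = class, year = as.integer(year), sex = sex,
                 total = sum(sub$val), n_contributing = nrow(sub),
                 missing = missing),
            class = "group_year_sum")
}

#' @export
print.group_year_sum <- function(x, ...) {
  cat(sprintf("Group sum of age-standardized rates: %s income, %d, %s\n",
              x$income_class, x$year, x$sex))
  cat(sprintf("  total = %.2f per 100,000 over %d countries\n",
              x$total, x$n_contributing))
  if (length(x$missing)) {
    cat("  missing members:", paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fraction of an income group with a directional sex gap
#'
#' Among member countries with both a Male and a Female age-standardized
#' rate in the given year, the fraction where the strict directional
#' inequality holds (ties count for neither direction). Countries with only
#' one sex present are excluded from the denominator and reported.
#'
#' @inheritParams sum_group_rate
#' @param direction `"female>male"` or `"male>female"`.
#' @return list of class `sex_dominance`: `fraction` in `[0, 1]`,
#'   `qualifying` (locations satisfying the inequality), `denominator`
#'   (count of countries with both sexes), `excluded` (one-sex-only
#'   locations).
#' @export
sex_dominance_fraction <- function(records, groups,
                                   class = c("low", "high"), year,
                                   direction = c("female>male",
                                                 "male>female")) {
  class <- match.arg(class)
  direction <- match.arg(direction)
  .check_rate_slice(records)
  members <- income_members(groups, class)
  sub <- records[records$location %in% members & records$year == year &
                   records$sex %in% c("Male", "Female"), , drop = FALSE]
  key <- paste(sub$location, sub$sex)
  if (anyDuplicated(key)) {
    stop("ambiguous input: duplicate (location, sex) rows for year ", year)
  }
  f <- sub$val[match(paste(members, "Female"), key)]
  m <- sub$val[match(paste(members, "Male"), key)]
  both <- !is.na(f) & !is.na(m)
  one_sex <- members[xor(is.na(f), is.na(m))]
  if (!any(both)) stop("no member country has both sex rows for year ", year)
  holds <- if (direction == "female>male") f[both] > m[both] else
    m[both] > f[both]
  structure(list(fraction = mean(holds), direction = direction,
                 income_class = class, year = as.integer(year),
                 qualifying = members[both][holds],
                 denominator = sum(both), excluded = one_sex),
            class = "sex_dominance")
}

#' @export
print.sex_dominance <- function(x, ...) {
  cat(sprintf("%s income, %d: %s in %d/%d countries (%.1f%%)\n",
              x$income_class, x$year, x$direction, length(x$qualifying),
              x$denominator, 100 * x$fraction))
  if (length(x$excluded)) {
    cat("  excluded (single sex present):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct an annual series
#'
#' @param years strictly increasing integer years.
#' @param values numeric values, same length.
#' @param label series label.
#' @return data.frame of class `annual_series` with columns `year`, `value`.
#' @export
annual_series <- function(years, values, label = "") {
  stopifnot(length(years) == length(values))
  years <- as.integer(years)
  if (is.unsorted(years, strictly = TRUE)) {
    stop("annual_series: years must be strictly increasing (no duplicates)")
  }
  structure(data.frame(year = years, value = as.numeric(values)),
            label = label, class = c("annual_series", "data.frame"))
}

#' Average annual percent change of an annual series
#'
#' The default (`method = "arithmetic"`) is the arithmetic mean of the
#' year-over-year percent changes, `100 * mean((v[t+1] - v[t]) / v[t])` —
#' the "+X% per year on average" statistic. `method = "geometric"` gives the
#' compound (CAGR) alternative `100 * ((v_m / v_1)^(1/(m-1)) - 1)`.
#'
#' @param series an [annual_series()] (or a data.frame with `year`,
#'   `value`), all values strictly positive, at least 2 points.
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return signed percent per year.
#' @export
average_annual_pct_change <- function(series,
                                      method = c("arithmetic",
                                                 "geometric")) {
  method <- match.arg(method)
  v <- series$value
  if (length(v) < 2L) stop("need at least 2 points")
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all series values must be > 0")
  }
  if (method == "arithmetic") {
    100 * mean(diff(v) / v[-length(v)])
  } else {
    100 * ((v[length(v)] / v[1])^(1 / (length(v) - 1)) - 1)
  }
}
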