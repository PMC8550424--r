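#' dalyvol: DALY burden trends and penalized-spline volatility
#'
#' Reads and validates burden-of-disease results tables, aggregates
#' age-standardized rates over World Bank income groups, and estimates the
#' volatility functional \eqn{\int \{f'(x)\}^2 dx} of DALY rate against the
#' socio-demographic index by penalized cubic B-spline regression with
#' BIC-selected smoothing and bootstrap confidence intervals.
#'
#' @keywords internal
"_PACKAGE"

## Canonical column set of the results-table dialect, in order.
.burden_cols <- c("measure", "location", "sex", "age", "cause",
                  "metric", "year", "val", "upper", "lower")

## GHDx export headers accepted as aliases for the short names.
.burden_aliases <- c(measure_name = "measure", location_name = "location",
                     sex_name = "sex", age_name = "age", cause_name = "cause",
                     metric_name = "metric", year = "year", val = "val",
                     upper = "upper", lower = "lower")

.valid_measures <- c("DALYs", "YLLs", "YLDs", "Incidence", "Prevalence")
.valid_sexes    <- c("Both", "Male", "Female")
.valid_metrics  <- c("Number", "Rate")

#' Read a burden results table
#'
#' Reads a long-format burden table in the GBD results-tool CSV dialect:
#' comma-delimited UTF-8 with a header row. Both the full GHDx column names
#' (`measure_name`, `location_name`, ...) and the short forms (`measure`,
#' `location`, ...) are accepted. Rows violating a record invariant (UI
#' ordering `lower <= val <= upper`, non-numeric `val`/`year`, year outside
#' the declared span, negative values, unknown enumerated labels) are
#' rejected with a row-indexed diagnostic; valid rows are returned in input
#' order.
#'
#' @param source path to a CSV file, or a connection.
#' @param year_span integer length-2, inclusive span of admissible years.
#' @param delimiter field delimiter, default comma.
#' @param strict if `TRUE` (default) rejected rows raise a warning listing
#'   each diagnostic; if any row is rejected and `strict = "error"`, reading
#'   fails.
#' @return a `data.frame` with columns `measure`, `location`, `sex`, `age`,
#'   `cause`, `metric`, `year`, `val`, `upper`, `lower`. Rejected-row
#'   diagnostics are attached as attribute `"rejected"` (a data.frame of row
#'   index and message; zero rows when all rows pass).
#' @seealso [write_burden_table()], [filter_records()]
#' @export
read_burden_table <- function(source, year_span = c(1990L, 2017L),
                              delimiter = ",", strict = TRUE) {
  stopifnot(length(year_span) == 2L, year_span[1] <= year_span[2])
  raw <- utils::read.csv(source, sep = delimiter, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8",
                         strip.white = TRUE)
  nm <- names(raw)
  hit <- nm %in% names(.burden_aliases)
  names(raw)[hit] <- unname(.burden_aliases[nm[hit]])
  missing_cols <- setdiff(.burden_cols, names(raw))
  if (length(missing_cols)) {
    stop("burden table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[.burden_cols]
  for (col in c("measure", "location", "sex", "age", "cause", "metric")) {
    raw[[col]] <- trimws(raw[[col]])
  }

  year  <- suppressWarnings(as.integer(raw$year))
  val   <- suppressWarnings(as.numeric(raw$val))
  upper <- suppressWarnings(as.numeric(raw$upper))
  lower <- suppressWarnings(as.numeric(raw$lower))

  msg <- character(nrow(raw))
  flag <- function(bad, text) {
    bad <- which(bad & !nzchar(msg))
    msg[bad] <<- text
  }
  flag(is.na(year) | year != suppressWarnings(as.numeric(raw$year)),
       "non-integer or missing year")
  flag(is.na(val), "non-numeric val")
  flag(is.na(upper) | is.na(lower), "non-numeric uncertainty bound")
  flag(!(raw$measure %in% .valid_measures), "unknown measure label")
  flag(!(raw$sex %in% .valid_sexes), "unknown sex label")
  flag(!(raw$metric %in% .valid_metrics), "unknown metric label")
  flag(!is.na(val) & val < 0, "negative val")
  flag(!is.na(lower) & !is.na(val) & !is.na(upper) &
         !(lower <= val & val <= upper),
       "uncertainty-interval ordering violated (need lower <= val <= upper)")
  flag(!is.na(year) & (year < year_span[1] | year > year_span[2]),
       sprintf("year outside declared span [%d, %d]",
               year_span[1], year_span[2]))

  bad <- nzchar(msg)
  rejected <- data.frame(row = which(bad), message = msg[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    diag_txt <- paste0("row ", rejected$row, ": ", rejected$message,
                       collapse = "\n  ")
    if (identical(strict, "error")) {
      stop("rejected ", nrow(rejected), " row(s):\n  ", diag_txt)
    }
    if (isTRUE(strict)) {
      warning("rejected ", nrow(rejected), " row(s):\n  ", diag_txt)
    }
  }

  out <- data.frame(measure = raw$measure, location = raw$location,
                    sex = raw$sex, age = raw$age, cause = raw$cause,
                    metric = raw$metric, year = year, val = val,
                    upper = upper, lower = lower,
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a burden results table
#'
#' Writes records in the same CSV dialect [read_burden_table()] reads, using
#' the full GHDx column names, so that a write-then-read round trip is
#' field-identical.
#'
#' @param records burden-record data.frame as returned by
#'   [read_burden_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_burden_table <- function(records, path) {
  stopifnot(all(.burden_cols %in% names(records)))
  out <- records[.burden_cols]
  names(out) <- names(.burden_aliases)[match(.burden_cols, .burden_aliases)]
  ## Full precision so numeric fields survive the round trip exactly.
  for (col in c("val", "upper", "lower")) {
    out[[col]] <- formatC(records[[col]], digits = 17, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Load the World Bank income-group classification
#'
#' With no override, returns the packaged classification of the 31 World
#' Bank low-income and 58 high-income countries and territories used
#' throughout the burden analysis. An override may be supplied as a
#' two-column CSV (`location`, `income_class`) or an equivalent data.frame.
#'
#' @param override optional path or data.frame replacing the packaged table.
#' @return a `data.frame` with columns `location` and `income_class`
#'   (`"low"` or `"high"`), class `income_group_table`.
#' @export
load_income_groups <- function(override = NULL) {
  if (is.null(override)) {
    src <- system.file("extdata", "income_groups.csv", package = "dalyvol",
                       mustWork = TRUE)
    tab <- utils::read.csv(src, stringsAsFactors = FALSE)
  } else if (is.data.frame(override)) {
    tab <- override
  } else {
    tab <- utils::read.csv(override, stringsAsFactors = FALSE,
                           strip.white = TRUE)
  }
  if (!all(c("location", "income_class") %in% names(tab))) {
    stop("income-group table needs columns 'location' and 'income_class'")
  }
  tab$location <- trimws(tab$location)
  tab$income_class <- trimws(tab$income_class)
  if (!all(tab$income_class %in% c("low", "high"))) {
    stop("income_class must be 'low' or 'high'")
  }
  dup <- tab$location[duplicated(tab$location)]
  if (length(dup)) {
    stop("duplicate location(s) in income-group table: ",
         paste(unique(dup), collapse = ", "))
  }
  tab <- tab[c("location", "income_class")]
  rownames(tab) <- NULL
  class(tab) <- c("income_group_table", "data.frame")
  tab
}

#' Member locations of one income class
#'
#' @param groups an `income_group_table`.
#' @param class `"low"` or `"high"`.
#' @return character vector of location names.
#' @export
income_members <- function(groups, class = c("low", "high")) {
  class <- match.arg(class)
  groups$location[groups$income_class == class]
}

#' Filter burden records on record fields
#'
#' Returns exactly the records matching every supplied predicate; predicates
#' left `NULL` match everything, so an empty call returns the input
#' unchanged. An empty result is valid.
#'
#' @param records burden-record data.frame.
#' @param measure,metric,sex,age,cause,locations character vectors of
#'   admissible values (exact match after the trimming done at read time).
#' @param years integer vector of years, or length-2 `c(from, to)` range
#'   when `years_as_range = TRUE`.
#' @param years_as_range interpret `years` as an inclusive range.
#' @return the matching subset, input order preserved.
#' @export
filter_records <- function(records, measure = NULL, metric = NULL,
                           sex = NULL, age = NULL, cause = NULL,
                           locations = NULL, years = NULL,
                           years_as_range = FALSE) {
  keep <- rep(TRUE, nrow(records))
  match_in <- function(field, values) {
    if (is.null(values)) return(NULL)
    keep <<- keep & records[[field]] %in% values
  }
  match_in("measure", measure)
  match_in("metric", metric)
  match_in("sex", sex)
  match_in("age", age)
  match_in("cause", cause)
  match_in("location", locations)
  if (!is.null(years)) {
    if (years_as_range) {
      stopifnot(length(years) == 2L)
      keep <- keep & records$year >= years[1] & records$year <= years[2]
    } else {
      keep <- keep & records$year %in% years
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
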