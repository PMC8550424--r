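#' Assemble a pipeline run configuration
#'
#' Collects the knobs shared by the pipeline stages ([cmd_simulate()],
#' [cmd_aggregate()], [cmd_trend()], [cmd_volatility()]) with the analysis
#' defaults: years 1990-2017, cubic basis with 3 interior knots, the
#' standard 61-point penalty grid, unit-penalty volatility convention, 1000
#' bootstrap replicates. Every output artifact embeds the seed and a hash
#' of the configuration so reruns are verifiably identical.
#'
#' @param input path to a burden CSV (aggregate/trend) or two-column
#'   `(x, y)` CSV (volatility).
#' @param income_groups optional override path for the income
#'   classification.
#' @param out_dir output directory, created if needed.
#' @param years inclusive year span.
#' @param degree,interior_knots basis configuration.
#' @param lambda_grid penalty grid.
#' @param convention `"unit-penalty"` or `"literal-lambda"`.
#' @param bootstrap_reps bootstrap replicate count.
#' @param seed integer seed used by every stochastic stage.
#' @param ... further fields stored verbatim (e.g. generator settings).
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, income_groups = NULL,
                       out_dir = ".", years = c(1990L, 2017L),
                       degree = 3L, interior_knots = 3L,
                       lambda_grid = default_lambda_grid(),
                       convention = "unit-penalty",
                       bootstrap_reps = 1000L, seed = 1L, ...) {
  stopifnot(length(years) == 2L, years[1] <= years[2])
  structure(list(input = input, income_groups = income_groups,
                 out_dir = out_dir, years = as.integer(years),
                 degree = as.integer(degree),
                 interior_knots = as.integer(interior_knots),
                 lambda_grid = lambda_grid, convention = convention,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed), ...),
            class = "run_config")
}

## Deterministic md5 of the canonical JSON encoding of the config.
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

.stamp <- function(config) {
  list(seed = config$seed, config_hash = .config_hash(config))
}

#' Simulate a synthetic burden world to disk
#'
#' Runs [gen_burden_table()] under the configuration and writes the burden
#' table (`burden_table.csv`, results-table dialect) and the ground-truth
#' ledger (`ledger.json`) to the output directory. The written table
#' re-reads cleanly through [read_burden_table()].
#'
#' @param config a [run_config()]; optional fields `pop` (a
#'   [population_spec()]) and `trends` (list with `low`, `high`
#'   [trend_spec()]s) override the defaults (31+58 countries; declining
#'   low-income trend from a class mean of 7879 per 100,000; U-shaped
#'   high-income trend from 120.7 with the 1998 minimum).
#' @return invisible list with the written paths and the generator output.
#' @export
cmd_simulate <- function(config) {
  out <- .ensure_dir(config$out_dir)
  pop <- if (!is.null(config$pop)) config$pop else population_spec()
  trends <- if (!is.null(config$trends)) config$trends else list(
    low = trend_spec("exponential-decline", start = 7879),
    high = trend_spec("u-shape", start = 120.7))
  years <- seq(config$years[1], config$years[2])
  sim <- gen_burden_table(pop, trends, years = years, seed = config$seed)
  table_path <- file.path(out, "burden_table.csv")
  ledger_path <- file.path(out, "ledger.json")
  write_burden_table(sim$records, table_path)
  ledger <- c(.stamp(config),
              list(group_sums = sim$ledger$group_sums,
                   dominance = sim$ledger$dominance,
                   planted_female_excess = lapply(
                     sim$ledger$planted_female_excess,
                     function(v) names(v)[v]),
                   sdi = sim$ledger$sdi))
  jsonlite::write_json(ledger, ledger_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(list(table = table_path, ledger = ledger_path, sim = sim))
}

#' Aggregate group-level rate sums from a burden table
#'
#' Reads the configured burden table, filters to age-standardized DALY
#' rates, and writes one [sum_group_rate()] row per (income class, year,
#' sex) to `group_sums.csv`, with a missing-country diagnostics report in
#' `aggregate_diagnostics.json`. An empty filtered input yields an empty
#' CSV with a header and a warning.
#'
#' @param config a [run_config()] with `input` set.
#' @return invisible list with the written paths and the sums data.frame.
#' @export
cmd_aggregate <- function(config) {
  out <- .ensure_dir(config$out_dir)
  records <- read_burden_table(config$input, year_span = config$years)
  groups <- load_income_groups(config$income_groups)
  slice <- filter_records(records, measure = "DALYs", metric = "Rate",
                          age = "Age-standardized")
  combos <- expand.grid(income_class = c("low", "high"),
                        year = sort(unique(slice$year)),
                        sex = c("Both", "Female", "Male"),
                        stringsAsFactors = FALSE)
  missing_report <- list()
  if (nrow(slice) == 0L) {
    warning("no age-standardized DALY rate records after filtering")
    sums <- data.frame(income_class = character(), year = integer(),
                       sex = character(), total = numeric(),
                       n_contributing = integer())
  } else {
    rows <- lapply(seq_len(nrow(combos)), function(i) {
      gs <- sum_group_rate(slice, groups, combos$income_class[i],
                           combos$year[i], combos$sex[i])
      if (length(gs$missing)) {
        key <- sprintf("%s_%d_%s", gs$income_class, gs$year, gs$sex)
        missing_report[[key]] <<- gs$missing
      }
      data.frame(income_class = gs$income_class, year = gs$year,
                 sex = gs$sex, total = gs$total,
                 n_contributing = gs$n_contributing)
    })
    sums <- do.call(rbind, rows)
    sums <- sums[order(sums$income_class, sums$sex, sums$year), ]
    rownames(sums) <- NULL
  }
  sums_path <- file.path(out, "group_sums.csv")
  diag_path <- file.path(out, "aggregate_diagnostics.json")
  utils::write.csv(sums, sums_path, row.names = FALSE)
  jsonlite::write_json(c(.stamp(config),
                         list(n_input_rows = nrow(records),
                              n_rate_rows = nrow(slice),
                              rejected_rows = attr(records, "rejected"),
                              missing_countries = missing_report)),
                       diag_path, auto_unbox = TRUE, digits = NA)
  invisible(list(sums = sums_path, diagnostics = diag_path, table = sums))
}

#' Trend statistics from a burden table
#'
#' Computes the descriptive trend statistics over the configured span and
#' writes them to `trend_stats.csv`: per-class percent change of the group
#' sum (first to last year), sex-dominance fractions in the first and last
#' years, per-country average annual percent change, and per-country
#' female-vs-male sex-gap percentages in the first and last years. Each row
#' carries the full-precision value and the two-decimal display value; a
#' statistic that fails (e.g. nonpositive baseline) becomes a row-level
#' error note and the run continues.
#'
#' @param config a [run_config()] with `input` set.
#' @return invisible list with the written path and the data.frame.
#' @export
cmd_trend <- function(config) {
  out <- .ensure_dir(config$out_dir)
  records <- read_burden_table(config$input, year_span = config$years)
  groups <- load_income_groups(config$income_groups)
  slice <- filter_records(records, measure = "DALYs", metric = "Rate",
                          age = "Age-standardized")
  yrs <- range(slice$year)
  rows <- list()
  add <- function(statistic, income_class = NA, location = NA, sex = NA,
                  year_from = NA, year_to = NA, expr) {
    note <- ""
    value <- tryCatch(expr, error = function(e) {
      note <<- paste0("error: ", conditionMessage(e))
      NA_real_
    })
    rows[[length(rows) + 1L]] <<- data.frame(
      statistic = statistic, income_class = income_class,
      location = location, sex = sex, year_from = year_from,
      year_to = year_to, value = value,
      display = if (is.na(value)) "" else format_percent(value),
      note = note, stringsAsFactors = FALSE)
  }

  for (cls in c("low", "high")) {
    s_from <- sum_group_rate(slice, groups, cls, yrs[1], "Both")$total
    s_to <- sum_group_rate(slice, groups, cls, yrs[2], "Both")$total
    add("group_sum_pct_change", cls, sex = "Both", year_from = yrs[1],
        year_to = yrs[2], expr = percent_change(s_from, s_to))
    for (yr in yrs) for (dir in c("female>male", "male>female")) {
      add(paste0("sex_dominance_", sub(">", "_gt_", dir)), cls,
          year_from = yr, year_to = yr,
          expr = 100 * sex_dominance_fraction(slice, groups, cls, yr,
                                              dir)$fraction)
    }
    for (loc in income_members(groups, cls)) {
      sub <- filter_records(slice, locations = loc, sex = "Both")
      sub <- sub[order(sub$year), ]
      if (nrow(sub) >= 2L) {
        add("average_annual_pct_change", cls, loc, "Both", yrs[1], yrs[2],
            expr = average_annual_pct_change(
              annual_series(sub$year, sub$val, loc)))
      }
      for (yr in yrs) {
        fv <- filter_records(slice, locations = loc, sex = "Female",
                             years = yr)$val
        mv <- filter_records(slice, locations = loc, sex = "Male",
                             years = yr)$val
        if (length(fv) == 1L && length(mv) == 1L) {
          add("sex_gap_pct_female_vs_male", cls, loc, year_from = yr,
              year_to = yr, expr = percent_higher(fv, mv))
        }
      }
    }
  }
  stats_df <- do.call(rbind, rows)
  path <- file.path(out, "trend_stats.csv")
  utils::write.csv(cbind(stats_df,
                         seed = config$seed,
                         config_hash = .config_hash(config)),
                   path, row.names = FALSE)
  invisible(list(stats = path, table = stats_df))
}

#' Penalized-spline volatility analysis of an (x, y) file
#'
#' Reads a two-column CSV (`x` = SDI in `[0, 1]`, `y` = DALY rate per
#' 100,000; headers `x`/`sdi` and `y`/`rate`/`val` are accepted), runs the
#' full spline pipeline with bootstrap, and writes `volatility_report.json`
#' (penalty, df, BIC, coefficients, knots, both volatility conventions,
#' CI, B, seed) plus `fitted_curve.csv` with the fitted function on a
#' 200-point grid over the x range.
#'
#' @param config a [run_config()] with `input` set.
#' @return invisible list with the written paths and the report list.
#' @export
cmd_volatility <- function(config) {
  out <- .ensure_dir(config$out_dir)
  raw <- utils::read.csv(config$input, strip.white = TRUE)
  names(raw) <- tolower(names(raw))
  xcol <- intersect(c("x", "sdi"), names(raw))[1]
  ycol <- intersect(c("y", "rate", "val", "daly_rate"), names(raw))[1]
  if (is.na(xcol) || is.na(ycol)) {
    stop("input needs an x/sdi column and a y/rate column")
  }
  x <- as.numeric(raw[[xcol]]); y <- as.numeric(raw[[ycol]])
  min_n <- config$degree + config$interior_knots + 2L
  if (length(unique(x)) < min_n) {
    stop("need at least ", min_n, " distinct x values for degree ",
         config$degree, " with ", config$interior_knots,
         " interior knots")
  }
  boot <- bootstrap_volatility(x, y, interior = config$interior_knots,
                               degree = config$degree,
                               grid = config$lambda_grid,
                               replicates = config$bootstrap_reps,
                               seed = config$seed,
                               convention = config$convention)
  fv <- fit_volatility(x, y, interior = config$interior_knots,
                       degree = config$degree, grid = config$lambda_grid)
  fit <- fv$fit
  report <- c(.stamp(config),
              list(m = fit$m, lambda_star = fv$lambda_star, df = fit$df,
                   bic = fit$bic, coefficients = fit$coefficients,
                   knots = fit$design$spec$interior,
                   boundary = fit$design$spec$boundary,
                   volatility_unit = fv$volatility_unit,
                   volatility_literal = fv$volatility_literal,
                   convention = config$convention, ci_low = boot$ci[1],
                   ci_high = boot$ci[2], B = boot$replicates,
                   bootstrap_scheme = boot$scheme,
                   redraws = boot$redraws))
  report_path <- file.path(out, "volatility_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  xg <- seq(fit$design$spec$boundary[1], fit$design$spec$boundary[2],
            length.out = 200)
  dg <- build_design(xg, fit$design$spec,
                     identifiability = fit$design$identifiability)
  curve <- data.frame(x = xg, fitted = drop(dg$matrix %*% fit$coefficients))
  curve_path <- file.path(out, "fitted_curve.csv")
  utils::write.csv(curve, curve_path, row.names = FALSE)
  invisible(list(report = report_path, curve = curve_path,
                 values = report))
}
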