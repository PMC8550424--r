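#' Specify a class-level temporal trend for synthetic burden rates
#'
#' Three shapes cover the observed group-level patterns: a steady geometric
#' decline (low-income pattern), a U shape that falls to a minimum in a
#' turning year and then rises (high-income pattern, default turning year
#' 1998), and a flat reference. Rates stay strictly positive for every year.
#'
#' @param shape `"exponential-decline"`, `"u-shape"` or `"flat"`.
#' @param start class-mean rate per 100,000 in the first year, > 0.
#' @param rate annual decline fraction for `"exponential-decline"`
#'   (default 0.0322, reproducing a 58.7% cumulative drop over 27 years).
#' @param drop_frac fractional drop from the first year to the turning-year
#'   minimum for `"u-shape"`, default 0.15.
#' @param end_ratio final-year value as a fraction of the first-year value
#'   for `"u-shape"`, default 0.9751 (a 2.49% cumulative decrease).
#' @param turning_year year of the U-shape minimum, default 1998.
#' @param noise_sigma per country-year multiplicative log-normal noise
#'   standard deviation (on the log scale), >= 0, default 0.
#' @return list of class `trend_spec`.
#' @export
trend_spec <- function(shape = c("exponential-decline", "u-shape", "flat"),
                       start, rate = 0.0322, drop_frac = 0.15,
                       end_ratio = 0.9751, turning_year = 1998L,
                       noise_sigma = 0) {
  shape <- match.arg(shape)
  stopifnot(start > 0, noise_sigma >= 0, rate < 1, drop_frac < 1,
            drop_frac >= 0, end_ratio > 0)
  structure(list(shape = shape, start = start, rate = rate,
                 drop_frac = drop_frac, end_ratio = end_ratio,
                 turning_year = as.integer(turning_year),
                 noise_sigma = noise_sigma),
            class = "trend_spec")
}

## Class-mean rate for each year under a trend spec; always > 0.
.trend_values <- function(spec, years) {
  t0 <- years[1]; t1 <- years[length(years)]
  v <- switch(spec$shape,
    "flat" = rep(spec$start, length(years)),
    "exponential-decline" = spec$start * (1 - spec$rate)^(years - t0),
    "u-shape" = {
      tm <- spec$turning_year
      stopifnot(tm > t0, tm < t1)
      vmin <- spec$start * (1 - spec$drop_frac)
      vend <- spec$start * spec$end_ratio
      down <- spec$start * (vmin / spec$start)^((years - t0) / (tm - t0))
      up <- vmin * (vend / vmin)^((years - tm) / (t1 - tm))
      ifelse(years <= tm, down, up)
    })
  stopifnot(all(v > 0))
  v
}

#' Specify the synthetic country population structure
#'
#' Controls the synthetic world the burden-table generator emulates: 31
#' low-income and 58 high-income countries by default (the study's group
#' sizes), a multiplicative country-level spread, a planted sex gap with a
#' stated fraction of countries where the female rate exceeds the male rate,
#' a bimodal age profile peaking in the under-5 groups and the elderly, and
#' monotone increasing SDI trajectories per class.
#'
#' @param n_low,n_high country counts per income class (defaults 31, 58).
#' @param country_sigma log-scale SD of the country-level multiplicative
#'   spread of baseline rates, default 0.5 (0 gives identical countries).
#' @param sex_gap half-width of the multiplicative sex gap: the dominant sex
#'   gets `(1 + sex_gap)`, the other `(1 - sex_gap)` times the country
#'   rate. Default 0.1.
#' @param female_excess_low,female_excess_high fraction of countries per
#'   class planted with female > male rates; defaults 0.645 and 0.5.
#' @param age_weights named nonnegative weights over age-group labels for
#'   the count (metric "Number") records; the default is bimodal with peaks
#'   at "28-364 days"/"1 to 4" and the 70+ groups.
#' @param count_scale converts a rate to a synthetic count for the Number
#'   records, default 1e4.
#' @param sdi_low,sdi_high length-2 `(first, last)` SDI values per class;
#'   trajectories are linear and nondecreasing in `[0, 1]`.
#' @return list of class `population_spec`.
#' @export
population_spec <- function(n_low = 31L, n_high = 58L, country_sigma = 0.5,
                            sex_gap = 0.1, female_excess_low = 0.645,
                            female_excess_high = 0.5,
                            age_weights = NULL, count_scale = 1e4,
                            sdi_low = c(0.20, 0.40),
                            sdi_high = c(0.70, 0.85)) {
  if (is.null(age_weights)) {
    age_weights <- c("28-364 days" = 0.28, "1 to 4" = 0.26, "5 to 9" = 0.04,
                     "10 to 14" = 0.02, "20 to 24" = 0.05,
                     "30 to 34" = 0.03, "60 to 64" = 0.07,
                     "70 to 74" = 0.11, "75 to 79" = 0.09,
                     "80 to 84" = 0.05)
  }
  stopifnot(n_low >= 1L, n_high >= 1L, country_sigma >= 0,
            sex_gap >= 0, sex_gap < 1,
            female_excess_low >= 0, female_excess_low <= 1,
            female_excess_high >= 0, female_excess_high <= 1,
            all(age_weights >= 0), !is.null(names(age_weights)),
            count_scale > 0,
            all(c(sdi_low, sdi_high) >= 0), all(c(sdi_low, sdi_high) <= 1),
            diff(sdi_low) >= 0, diff(sdi_high) >= 0)
  structure(list(n_low = as.integer(n_low), n_high = as.integer(n_high),
                 country_sigma = country_sigma, sex_gap = sex_gap,
                 female_excess = c(low = female_excess_low,
                                   high = female_excess_high),
                 age_weights = age_weights, count_scale = count_scale,
                 sdi = list(low = sdi_low, high = sdi_high)),
            class = "population_spec")
}

.synth_country_names <- function(pop) {
  if (pop$n_low == 31L && pop$n_high == 58L) {
    groups <- load_income_groups()
    list(low = income_members(groups, "low"),
         high = income_members(groups, "high"), groups = groups)
  } else {
    low <- sprintf("Low Country %02d", seq_len(pop$n_low))
    high <- sprintf("High Country %02d", seq_len(pop$n_high))
    groups <- load_income_groups(data.frame(
      location = c(low, high),
      income_class = rep(c("low", "high"), c(pop$n_low, pop$n_high))))
    list(low = low, high = high, groups = groups)
  }
}

#' Generate a synthetic burden table with a ground-truth ledger
#'
#' Builds a burden table in the results-table dialect that emulates the
#' structure of the real study data: one age-standardized Rate record per
#' (country, year, sex in Male/Female/Both) where "Both" is the average of
#' the two sex rates, plus Number records over the age-profile groups; 95%
#' UI fields are a fixed +/-15% band around the value (plumbing for
#' invariant checks only, carrying no statistical meaning). Alongside the
#' records a ledger of exact ground truth is returned: per-country realized
#' rates, per class-year-sex sums, realized sex-dominance fractions, the
#' planted dominance pattern, class SDI trajectories and the (SDI, summed
#' rate) pairs per class.
#'
#' @param pop a [population_spec()].
#' @param trends named list with elements `low` and `high`, each a
#'   [trend_spec()].
#' @param years integer year span, default `1990:2017`.
#' @param seed integer RNG seed.
#' @return list: `records` (burden data.frame), `ledger` (list described
#'   above), `income_groups` (the matching classification table).
#' @export
gen_burden_table <- function(pop, trends, years = 1990:2017, seed = 1L) {
  stopifnot(inherits(pop, "population_spec"),
            all(c("low", "high") %in% names(trends)))
  years <- as.integer(years)
  set.seed(as.integer(seed))
  nm <- .synth_country_names(pop)
  n_years <- length(years)

  recs <- list(); ledger_rates <- list()
  planted <- list(); sums <- list(); sdi_series <- list()
  for (cls in c("low", "high")) {
    countries <- nm[[cls]]
    nc <- length(countries)
    tr <- trends[[cls]]
    v <- .trend_values(tr, years)
    w <- exp(stats::rnorm(nc, 0, pop$country_sigma))
    n_fem <- round(pop$female_excess[[cls]] * nc)
    fem_excess <- rep(FALSE, nc)
    if (n_fem > 0) fem_excess[sample.int(nc, n_fem)] <- TRUE
    planted[[cls]] <- stats::setNames(fem_excess, countries)

    noise <- if (tr$noise_sigma > 0) {
      matrix(exp(stats::rnorm(nc * n_years, 0, tr$noise_sigma)), nc, n_years)
    } else matrix(1, nc, n_years)
    base <- (w %o% v) * noise                 # country x year realized rate
    fmul <- ifelse(fem_excess, 1 + pop$sex_gap, 1 - pop$sex_gap)
    mmul <- ifelse(fem_excess, 1 - pop$sex_gap, 1 + pop$sex_gap)
    female <- base * fmul
    male <- base * mmul
    both <- (female + male) / 2               # equals base

    cy <- expand.grid(ci = seq_len(nc), yi = seq_len(n_years))
    rate_rows <- function(mat, sex) {
      data.frame(measure = "DALYs", location = countries[cy$ci], sex = sex,
                 age = "Age-standardized", cause = "Diarrheal diseases",
                 metric = "Rate", year = years[cy$yi],
                 val = mat[cbind(cy$ci, cy$yi)], stringsAsFactors = FALSE)
    }
    cls_recs <- rbind(rate_rows(both, "Both"), rate_rows(female, "Female"),
                      rate_rows(male, "Male"))

    ages <- names(pop$age_weights)
    ag <- expand.grid(ci = seq_len(nc), yi = seq_len(n_years),
                      ai = seq_along(ages))
    num_recs <- data.frame(measure = "DALYs", location = countries[ag$ci],
                           sex = "Both", age = ages[ag$ai],
                           cause = "Diarrheal diseases", metric = "Number",
                           year = years[ag$yi],
                           val = both[cbind(ag$ci, ag$yi)] *
                             pop$age_weights[ag$ai] * pop$count_scale,
                           stringsAsFactors = FALSE)
    recs[[cls]] <- rbind(cls_recs, num_recs)

    dimnames(both) <- list(countries, years)
    dimnames(female) <- list(countries, years)
    dimnames(male) <- list(countries, years)
    ledger_rates[[cls]] <- list(both = both, female = female, male = male)
    sums[[cls]] <- data.frame(
      income_class = cls,
      year = rep(years, 3),
      sex = rep(c("Both", "Female", "Male"), each = n_years),
      total = c(colSums(both), colSums(female), colSums(male)))
    sdi_series[[cls]] <- data.frame(
      year = years,
      sdi = seq(pop$sdi[[cls]][1], pop$sdi[[cls]][2],
                length.out = n_years),
      total_rate = colSums(both))
  }

  records <- do.call(rbind, c(recs, make.row.names = FALSE))
  records$upper <- records$val * 1.15
  records$lower <- records$val * 0.85
  records <- records[c("measure", "location", "sex", "age", "cause",
                       "metric", "year", "val", "upper", "lower")]

  dominance <- do.call(rbind, lapply(c("low", "high"), function(cls) {
    lr <- ledger_rates[[cls]]
    data.frame(income_class = cls, year = years,
               female_gt_male = colMeans(lr$female > lr$male),
               male_gt_female = colMeans(lr$male > lr$female))
  }))

  list(records = records,
       ledger = list(years = years, rates = ledger_rates,
                     group_sums = do.call(rbind, sums),
                     dominance = dominance, planted_female_excess = planted,
                     sdi = sdi_series, seed = as.integer(seed)),
       income_groups = nm$groups)
}

## Analytic integral of the squared derivative of a polynomial with
## coefficients cf (cf[1] + cf[2] x + ...) over [a, b].
.poly_volatility <- function(cf, a, b) {
  dcf <- (cf * (seq_along(cf) - 1))[-1]          # derivative coefficients
  if (!length(dcf)) return(0)
  sq <- rep(0, 2 * length(dcf) - 1)              # square by convolution
  for (i in seq_along(dcf)) for (j in seq_along(dcf)) {
    sq[i + j - 1] <- sq[i + j - 1] + dcf[i] * dcf[j]
  }
  k <- seq_along(sq)
  sum(sq * (b^k - a^k) / k)
}

#' Generate an (SDI, DALY-rate) test series with known volatility
#'
#' Draws `y = f_true(x) + Gaussian noise` from one of the shipped smooth
#' families and returns the series together with the closed-form true
#' volatility `integral of {f_true'(x)}^2 dx` over the interval, for use as
#' ground truth in spline tests. Polynomial families integrate the squared
#' derivative exactly; the logistic family uses its closed form
#' `A^2 k [u^2/2 - u^3/3]` between the endpoint sigmoid values.
#'
#' @param family `"linear"`, `"quadratic"`, `"cubic"` or `"logistic"`.
#' @param params named numeric parameters: polynomial coefficients
#'   `a, b, c, d` (constant upward), or `A, k, x0, c0` for the logistic
#'   `c0 + A / (1 + exp(-k (x - x0)))`.
#' @param n number of points, >= 10.
#' @param sigma additive Gaussian noise SD, >= 0.
#' @param seed integer RNG seed.
#' @param interval length-2 domain `[a, b]`, default `c(0, 1)` (the SDI
#'   scale).
#' @param design `"equispaced"` (default) or `"uniform"` random abscissae.
#' @return list: `x`, `y`, `f_true` (vectorised function),
#'   `true_volatility`, plus the generating configuration.
#' @export
gen_sdi_daly_series <- function(family = c("linear", "quadratic", "cubic",
                                           "logistic"),
                                params, n = 28L, sigma = 0, seed = 1L,
                                interval = c(0, 1),
                                design = c("equispaced", "uniform")) {
  family <- match.arg(family)
  design <- match.arg(design)
  stopifnot(n >= 10L, sigma >= 0, interval[1] < interval[2])
  p <- function(name, default = 0) {
    if (name %in% names(params)) params[[name]] else default
  }
  if (family == "logistic") {
    A <- p("A", 1); k <- p("k", 1); x0 <- p("x0", mean(interval))
    c0 <- p("c0", 0)
    f <- function(x) c0 + A / (1 + exp(-k * (x - x0)))
    u <- 1 / (1 + exp(-k * (interval - x0)))
    tv <- A^2 * k * diff(u^2 / 2 - u^3 / 3)
  } else {
    ncf <- c(linear = 2L, quadratic = 3L, cubic = 4L)[[family]]
    cf <- c(p("a"), p("b"), p("c"), p("d"))[seq_len(ncf)]
    f <- function(x) {
      drop(outer(x, seq_along(cf) - 1, `^`) %*% cf)
    }
    tv <- .poly_volatility(cf, interval[1], interval[2])
  }
  set.seed(as.integer(seed))
  x <- if (design == "equispaced") {
    seq(interval[1], interval[2], length.out = n)
  } else sort(stats::runif(n, interval[1], interval[2]))
  y <- f(x) + stats::rnorm(n, 0, sigma)
  list(x = x, y = y, f_true = f, true_volatility = tv, family = family,
       params = params, sigma = sigma, seed = as.integer(seed),
       interval = interval)
}
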