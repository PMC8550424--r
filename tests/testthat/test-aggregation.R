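test_that("percent change and percent higher reproduce printed statistics", {
  # Central African Republic DALY rate, 1990 -> 2017
  expect_equal(format_percent(percent_change(6400.68, 8590.04)), "34.21")
  # low-income group sum, 1990 -> 2017
  expect_equal(format_percent(percent_change(244252.09, 100905.15)), "-58.69")
  # Niger 1990, female vs male
  expect_equal(format_percent(percent_higher(21842.85, 13595.21)), "60.67")
  # Guam 2017, female vs male
  expect_equal(format_percent(percent_higher(487.36, 481.44)), "1.23")
})

test_that("percent operations: identities, equivalence and domain errors", {
  for (x in c(0.3, 1, 57.2, 6400.68)) {
    expect_equal(percent_change(x, x), 0)
    expect_equal(percent_higher(x, x), 0)
  }
  set.seed(42)
  a <- runif(20, 0.1, 1e4); b <- runif(20, 0.1, 1e4)
  expect_equal(percent_change(a, b), percent_higher(b, a))
  expect_error(percent_change(0, 5), "> 0")
  expect_error(percent_change(-1, 5), "> 0")
  expect_error(percent_higher(5, 0), "> 0")
})

test_that("group_ratio identities and reciprocal property", {
  expect_equal(group_ratio(7, 7), 1)
  expect_equal(group_ratio(14, 7), 2)
  set.seed(7)
  a <- runif(10, 1, 1e6); b <- runif(10, 1, 1e6)
  expect_equal(group_ratio(a, b) * group_ratio(b, a), rep(1, 10))
  expect_equal(group_ratio(sum(a), sum(b)), sum(a) / sum(b))
  expect_error(group_ratio(0, 1), "> 0")
  expect_error(group_ratio(1, -2), "> 0")
})

test_that("display rounding sends ties away from zero", {
  expect_equal(round_half_away(0.125, 2), 0.13)
  expect_equal(round_half_away(-0.125, 2), -0.13)
  expect_equal(round_half_away(2.675, 2), 2.68)
  expect_equal(format_percent(-58.685), "-58.69")
})

test_that("group sums add member rates, report absentees, reject duplicates", {
  groups <- load_income_groups(data.frame(
    location = c("A", "B", "C", "X"),
    income_class = c("low", "low", "low", "high")))
  recs <- burden_rows(c("A", "B"), 1990, c(6400.68, 120.5))

  single <- sum_group_rate(burden_rows("A", 1990, 6400.68),
                           groups, "low", 1990)
  expect_equal(single$total, 6400.68)

  gs <- sum_group_rate(recs, groups, "low", 1990)
  expect_equal(gs$total, 6400.68 + 120.5)
  expect_equal(gs$n_contributing, 2L)
  expect_equal(gs$missing, "C")

  dup <- rbind(recs, burden_rows("A", 1990, 1))
  expect_error(sum_group_rate(dup, groups, "low", 1990), "duplicate")
  expect_error(sum_group_rate(burden_rows("A", 1990, 5, metric = "Number"),
                              groups, "low", 1990), "Rate")
})

test_that("synthetic group sums match brute-force addition and partition additivity", {
  sim <- gen_burden_table(population_spec(),
                          list(low = trend_spec("exponential-decline",
                                                start = 7879,
                                                noise_sigma = 0.1),
                               high = trend_spec("exponential-decline",
                                                 start = 120.7,
                                                 noise_sigma = 0.1)),
                          years = 1990:1993, seed = 5)
  slice <- filter_records(sim$records, metric = "Rate",
                          age = "Age-standardized", sex = "Both")
  gs <- sum_group_rate(slice, sim$income_groups, "low", 1991)
  # brute-force oracle: re-add the member rows one by one
  members <- income_members(sim$income_groups, "low")
  manual <- 0
  for (loc in members) {
    manual <- manual + sum(slice$val[slice$location == loc &
                                       slice$year == 1991])
  }
  expect_equal(gs$total, manual)
  expect_length(gs$missing, 0L)

  # additivity under an arbitrary partition of the group
  part <- split(members, rep(1:3, length.out = length(members)))
  parts_total <- sum(vapply(part, function(p) {
    g <- load_income_groups(data.frame(location = p, income_class = "low"))
    sum_group_rate(slice, g, "low", 1991)$total
  }, numeric(1)))
  expect_equal(parts_total, gs$total)
})

test_that("sex dominance counts strict directional inequalities", {
  groups <- load_income_groups(data.frame(location = c("A", "B", "C"),
                                          income_class = "high"))
  recs <- rbind(burden_rows(c("A", "B"), 2017, c(10, 20), sex = "Female"),
                burden_rows(c("A", "B"), 2017, c(20, 10), sex = "Male"))
  sd <- sex_dominance_fraction(recs, groups, "high", 2017, "female>male")
  expect_equal(sd$fraction, 0.5)
  expect_equal(sd$qualifying, "B")
  expect_equal(sd$denominator, 2L)

  # ties count for neither direction
  tied <- rbind(burden_rows("A", 2017, 10, sex = "Female"),
                burden_rows("A", 2017, 10, sex = "Male"))
  expect_equal(sex_dominance_fraction(tied, groups, "high", 2017,
                                      "female>male")$fraction, 0)
  expect_equal(sex_dominance_fraction(tied, groups, "high", 2017,
                                      "male>female")$fraction, 0)

  # a one-sex country is excluded from the denominator and reported
  lop <- rbind(recs, burden_rows("C", 2017, 5, sex = "Female"))
  sd2 <- sex_dominance_fraction(lop, groups, "high", 2017, "female>male")
  expect_equal(sd2$denominator, 2L)
  expect_equal(sd2$excluded, "C")
})

test_that("planted dominance patterns are recovered and directions complement", {
  pop <- population_spec(n_low = 10, n_high = 12, country_sigma = 0.3,
                         female_excess_low = 0.4, female_excess_high = 0.75)
  sim <- gen_burden_table(pop,
                          list(low = trend_spec("flat", start = 1000),
                               high = trend_spec("flat", start = 50)),
                          years = 1990:1991, seed = 9)
  slice <- filter_records(sim$records, metric = "Rate",
                          age = "Age-standardized")
  fgm <- sex_dominance_fraction(slice, sim$income_groups, "low", 1990,
                                "female>male")
  mgf <- sex_dominance_fraction(slice, sim$income_groups, "low", 1990,
                                "male>female")
  expect_equal(fgm$fraction, 0.4)
  expect_setequal(fgm$qualifying,
                  names(which(sim$ledger$planted_female_excess$low)))
  # no ties in the noiseless planted pattern, so the directions partition
  expect_equal(fgm$fraction + mgf$fraction, 1)
  expect_equal(sex_dominance_fraction(slice, sim$income_groups, "high",
                                      1991, "female>male")$fraction, 0.75)
})

test_that("average annual percent change matches pairwise brute force", {
  flat <- annual_series(1990:2017, rep(42, 28))
  expect_equal(average_annual_pct_change(flat), 0)

  geom <- annual_series(1990:2017, 100 * 1.05^(0:27))
  expect_equal(average_annual_pct_change(geom), 5)
  expect_equal(average_annual_pct_change(geom, method = "geometric"), 5)

  set.seed(12)
  vals <- exp(cumsum(rnorm(28, 0, 0.1))) * 500
  ser <- annual_series(1990:2017, vals)
  manual <- 0
  for (t in 1:27) manual <- manual + (vals[t + 1] - vals[t]) / vals[t]
  expect_equal(average_annual_pct_change(ser), 100 * manual / 27)

  expect_error(average_annual_pct_change(annual_series(1990, 5)), "2 points")
  expect_error(average_annual_pct_change(annual_series(1990:1992,
                                                       c(1, 0, 2))), "> 0")
  expect_error(annual_series(c(1990, 1990), c(1, 2)), "strictly increasing")
})
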