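make_problem <- function(n = 28, sigma = 0.1, seed = 8,
                         f = function(x) sin(2 * pi * x)) {
  set.seed(seed)
  x <- sort(runif(n))
  y <- f(x) + rnorm(n, 0, sigma)
  spec <- choose_knots(x)
  list(x = x, y = y, spec = spec,
       design = build_design(x, spec), penalty = penalty_matrix(spec))
}

test_that("lambda = 0 reproduces ordinary least squares on the basis", {
  pr <- make_problem()
  fit <- fit_penalized(pr$design, pr$y, 0, pr$penalty)
  ols <- lm.fit(pr$design$matrix, pr$y)
  expect_equal(unname(fit$coefficients), unname(ols$coefficients),
               tolerance = 1e-8)
  expect_equal(fit$fitted, unname(ols$fitted.values), tolerance = 1e-8)
  expect_equal(fit$df, ncol(pr$design$matrix), tolerance = 1e-8)
})

test_that("constant responses are fitted exactly with zero volatility at any lambda", {
  pr <- make_problem()
  for (lam in c(0, 1, 1e4)) {
    fit <- fit_penalized(pr$design, rep(3.7, length(pr$y)), lam, pr$penalty)
    expect_equal(fit$fitted, rep(3.7, length(pr$y)), tolerance = 1e-9)
    expect_equal(volatility(fit, pr$penalty, "unit-penalty"), 0,
                 tolerance = 1e-12)
    expect_equal(volatility(fit, pr$penalty, "literal-lambda"), 0,
                 tolerance = 1e-12)
    expect_error(bic_of_fit(fit), "zero")
  }
})

test_that("the large-lambda limit collapses to the mean with one degree of freedom", {
  pr <- make_problem(sigma = 0.3, seed = 13)
  fit <- fit_penalized(pr$design, pr$y, 1e8, pr$penalty)
  expect_equal(fit$fitted, rep(mean(pr$y), length(pr$y)),
               tolerance = 1e-3)    # within 0.1% of mean(Y)
  expect_lt(abs(fit$df - 1), 0.01)
})

test_that("BIC-guided selection agrees with an independent per-lambda grid scan", {
  pr <- make_problem(sigma = 0.05, seed = 21,
                     f = function(x) 1 + 2 * x - 3 * x^2 + 1.5 * x^3)
  grid <- default_lambda_grid()
  # independent scan: one closed-form fit per grid value, BIC recomputed
  bics <- vapply(grid, function(l)
    bic_of_fit(fit_penalized(pr$design, pr$y, l, pr$penalty)), numeric(1))
  sel <- select_lambda(pr$design, pr$y, pr$penalty, grid)
  expect_equal(sel$profile$bic, bics, tolerance = 1e-8)
  expect_equal(sel$lambda_star, max(grid[bics == min(bics)]))
  # the BIC minimum is interior to the grid for this noisy cubic signal
  expect_gt(sel$lambda_star, min(grid))
  expect_lt(sel$lambda_star, max(grid))
  # the returned fit is the closed-form fit at lambda*
  direct <- fit_penalized(pr$design, pr$y, sel$lambda_star, pr$penalty)
  expect_equal(sel$fit$coefficients, direct$coefficients)
})

test_that("degrees of freedom fall and RSS rises along the penalty grid", {
  pr <- make_problem(sigma = 0.2, seed = 34)
  prof <- select_lambda(pr$design, pr$y, pr$penalty,
                        default_lambda_grid())$profile
  expect_equal(nrow(prof), 61L)
  expect_true(all(diff(prof$df) <= 1e-10))
  expect_true(all(diff(prof$rss) >= -1e-10))
  expect_true(all(prof$df >= 1 - 1e-8 & prof$df <= ncol(pr$design$matrix)))

  # singleton grid and exact-tie rule
  expect_equal(select_lambda(pr$design, pr$y, pr$penalty, 0.5)$lambda_star,
               0.5)
  expect_equal(select_lambda(pr$design, pr$y, pr$penalty,
                             c(0.5, 0.5))$lambda_star, 0.5)
})

test_that("noiseless linear data give volatility b^2 L", {
  s <- gen_sdi_daly_series("linear", list(a = 4, b = -3), n = 28,
                           sigma = 0, seed = 2, interval = c(0.2, 0.9))
  spec <- choose_knots(s$x)
  design <- build_design(s$x, spec)
  penalty <- penalty_matrix(spec)
  fit <- fit_penalized(design, s$y, 1e-8, penalty)
  L <- diff(range(s$x))
  expect_equal(volatility(fit, penalty), 9 * L, tolerance = 1e-3)
  expect_equal(s$true_volatility, 9 * 0.7)
})

test_that("noiseless cubic data are interpolated and volatility matches the closed form", {
  s <- gen_sdi_daly_series("cubic", list(a = 1, b = 2, c = -3, d = 1.5),
                           n = 28, sigma = 0, seed = 3)
  spec <- choose_knots(s$x)
  design <- build_design(s$x, spec)
  penalty <- penalty_matrix(spec)
  fit <- fit_penalized(design, s$y, 0, penalty)
  expect_equal(fit$fitted, s$y, tolerance = 1e-8)
  expect_equal(volatility(fit, penalty), s$true_volatility,
               tolerance = 1e-6)
})

test_that("unit-penalty volatility equals direct integration of the squared derivative", {
  pr <- make_problem(sigma = 0.15, seed = 55)
  sel <- select_lambda(pr$design, pr$y, pr$penalty)
  vol <- volatility(sel$fit, pr$penalty)
  # direct route: evaluate f-hat' from the coefficients and integrate
  spec <- pr$spec
  deriv_sq <- function(x) {
    D <- dalyvol:::.basis_eval(spec, x, deriv = 1L)
    Dr <- cbind(0, D[, -1, drop = FALSE])   # intercept has zero derivative
    drop(Dr %*% sel$fit$coefficients)^2
  }
  breaks <- unique(c(spec$boundary[1], spec$interior, spec$boundary[2]))
  direct <- 0
  for (i in seq_len(length(breaks) - 1)) {
    direct <- direct + integrate(deriv_sq, breaks[i], breaks[i + 1],
                                 rel.tol = 1e-10)$value
  }
  expect_equal(vol, direct, tolerance = 1e-6)
  # literal-lambda convention scales by the fitted penalty value
  expect_equal(volatility(sel$fit, pr$penalty, "literal-lambda"),
               sel$lambda_star * vol, tolerance = 1e-12)
})

test_that("both identifiability parameterisations give the same curve and volatility", {
  pr <- make_problem(sigma = 0.1, seed = 89)
  pen_a <- pr$penalty
  des_b <- build_design(pr$x, pr$spec, identifiability = "keep-all")
  pen_b <- penalty_matrix(pr$spec, identifiability = "keep-all")
  for (lam in c(1e-4, 0.1, 10)) {
    fa <- fit_penalized(pr$design, pr$y, lam, pen_a)
    fb <- fit_penalized(des_b, pr$y, lam, pen_b)
    expect_equal(fa$fitted, fb$fitted, tolerance = 1e-7)
    expect_equal(fa$df, fb$df, tolerance = 1e-7)
    expect_equal(volatility(fa, pen_a), volatility(fb, pen_b),
                 tolerance = 1e-6)
  }
})

test_that("degenerate abscissae are reported as a singular system", {
  x <- c(rep(0.1, 10), rep(0.2, 10), rep(0.3, 8))
  spec <- suppressWarnings(choose_knots(c(x, seq(0.4, 0.9, length.out = 5)),
                                        interior = 3))
  design <- suppressWarnings(build_design(x, spec))
  penalty <- penalty_matrix(spec)
  expect_error(fit_penalized(design, rnorm(28), 0, penalty),
               "singular|degenerate")
})
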