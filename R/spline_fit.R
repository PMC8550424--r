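#' Default smoothing-parameter grid
#'
#' 61 logarithmically spaced values from 1e-6 to 1e6, spanning effective
#' degrees of freedom from essentially the unpenalized fit down to the
#' intercept-only limit for data on the SDI scale.
#'
#' @return numeric vector, increasing.
#' @export
default_lambda_grid <- function() 10^seq(-6, 6, length.out = 61)

#' Fit the penalized B-spline regression at a fixed penalty
#'
#' Solves the ridge-type normal equations
#' `(X'X + lambda * P) gamma = X'Y`, the closed form of the penalized
#' least-squares problem with first-derivative roughness penalty. Records
#' the fitted values, residual sum of squares, effective degrees of freedom
#' `df(lambda) = tr(S_lambda)` (trace of the smoother matrix
#' `X (X'X + lambda P)^{-1} X'`), and the BIC.
#'
#' @param design a `spline_design` from [build_design()].
#' @param y response vector (DALY rate per 100,000), length `nrow(design)`.
#' @param lambda nonnegative penalty parameter.
#' @param penalty a `penalty_spec` from [penalty_matrix()] with the same
#'   basis spec and identifiability mode as `design`.
#' @return object of class `penalized_fit`: `coefficients`, `lambda`,
#'   `fitted`, `residuals`, `rss`, `df`, `bic` (`NA` when `rss` is zero),
#'   `m`, plus the `design` and `penalty` used.
#' @export
fit_penalized <- function(design, y, lambda, penalty) {
  stopifnot(inherits(design, "spline_design"),
            inherits(penalty, "penalty_spec"),
            lambda >= 0, is.finite(lambda))
  if (!identical(design$identifiability, penalty$identifiability)) {
    stop("design and penalty use different identifiability modes")
  }
  X <- design$matrix
  m <- nrow(X)
  if (length(y) != m) stop("length(y) must equal nrow(design)")
  XtX <- crossprod(X)
  A <- XtX + lambda * penalty$P
  Ainv_XtX_Xty <- tryCatch(solve(A, cbind(XtX, crossprod(X, y))),
                           error = function(e)
                             stop("singular penalized system; x values are ",
                                  "degenerate for this basis", call. = FALSE))
  p <- ncol(X)
  gamma <- drop(Ainv_XtX_Xty[, p + 1L])
  df <- sum(diag(Ainv_XtX_Xty[, seq_len(p), drop = FALSE]))
  fitted <- drop(X %*% gamma)
  resid <- y - fitted
  rss <- sum(resid^2)
  ## an RSS at rounding-error level is an interpolating fit; BIC undefined
  zero_rss <- rss <= 1e-16 * max(sum(y^2), .Machine$double.xmin)
  bic <- if (zero_rss) NA_real_ else m * log(rss / m) + df * log(m)
  structure(list(coefficients = gamma, lambda = lambda, fitted = fitted,
                 residuals = resid, rss = rss, df = df, bic = bic, m = m,
                 design = design, penalty = penalty),
            class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf("Penalized B-spline fit: m = %d, lambda = %.4g\n", x$m,
              x$lambda))
  cat(sprintf("  df = %.3f, RSS = %.6g, BIC = %.4f\n", x$df, x$rss, x$bic))
  invisible(x)
}

#' BIC of a penalized fit
#'
#' The Gaussian profile form `m * log(RSS/m) + df(lambda) * log(m)` with the
#' smoother-matrix trace as effective model dimension. Undefined (an error)
#' when the fit interpolates (`RSS = 0`).
#'
#' @param fit a `penalized_fit`.
#' @return the BIC value.
#' @export
bic_of_fit <- function(fit) {
  stopifnot(inherits(fit, "penalized_fit"))
  if (is.na(fit$bic)) {
    stop("BIC undefined: residual sum of squares is zero (interpolating fit)")
  }
  fit$m * log(fit$rss / fit$m) + fit$df * log(fit$m)
}

## Fast profile of df/RSS/BIC over a lambda grid via one generalized
## eigendecomposition: with X'X = R'R and M = R^{-T} P R^{-1} = U diag(s) U',
## df(l) = sum 1/(1+l*s) and the coefficient path is diagonal in the U basis.
.lambda_profile <- function(X, y, P, grid) {
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e)
    stop("design matrix is rank deficient; x values are degenerate for ",
         "this basis", call. = FALSE))
  p <- ncol(X)
  Rinv <- backsolve(R, diag(p))
  M <- crossprod(Rinv, P %*% Rinv)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  s <- pmax(eg$values, 0)
  z <- drop(crossprod(eg$vectors, backsolve(R, crossprod(X, y),
                                            transpose = TRUE)))
  yty <- sum(y^2)
  m <- nrow(X)
  df <- rss <- numeric(length(grid))
  for (i in seq_along(grid)) {
    shrink <- 1 / (1 + grid[i] * s)
    cc <- shrink * z
    df[i] <- sum(shrink)
    rss[i] <- max(yty - 2 * sum(cc * z) + sum(cc^2), 0)
  }
  zero <- rss <= 1e-16 * max(yty, .Machine$double.xmin)
  bic <- ifelse(zero, Inf, m * log(rss / m) + df * log(m))
  list(lambda = grid, df = df, rss = rss, bic = bic)
}

#' Select the smoothing parameter by BIC over a grid
#'
#' Profiles BIC over the supplied grid and returns the minimizing
#' `lambda_star`, with ties broken toward the larger value (more
#' smoothing), together with the fit at `lambda_star` and the full
#' `(lambda, df, RSS, BIC)` profile.
#'
#' @inheritParams fit_penalized
#' @param grid positive penalty values, default [default_lambda_grid()].
#' @return list of class `lambda_selection`: `lambda_star`, `fit` (the
#'   `penalized_fit` at `lambda_star`), `profile` (data.frame over the
#'   grid).
#' @export
select_lambda <- function(design, y, penalty,
                          grid = default_lambda_grid()) {
  stopifnot(length(grid) >= 1L, all(grid > 0))
  grid <- sort(grid)
  prof <- .lambda_profile(design$matrix, y, penalty$P, grid)
  if (all(!is.finite(prof$bic))) {
    stop("BIC undefined on the whole grid: residual sum of squares is zero")
  }
  lambda_star <- max(grid[prof$bic == min(prof$bic)])
  structure(list(lambda_star = lambda_star,
                 fit = fit_penalized(design, y, lambda_star, penalty),
                 profile = data.frame(lambda = prof$lambda, df = prof$df,
                                      rss = prof$rss, bic = prof$bic)),
            class = "lambda_selection")
}

#' @export
print.lambda_selection <- function(x, ...) {
  cat(sprintf("BIC-selected penalty: lambda* = %.4g (df = %.3f, BIC = %.4f)\n",
              x$lambda_star, x$fit$df, x$fit$bic))
  invisible(x)
}

#' Volatility of the fitted regression function
#'
#' The quadratic form of the fitted spline coefficients in the
#' first-derivative penalty. Under the default `"unit-penalty"` convention
#' this is `gamma' P gamma`, which equals the integrated squared derivative
#' `integral of {f_hat'(x)}^2 dx` over the boundary interval exactly. The
#' `"literal-lambda"` convention returns `gamma' (lambda * P) gamma =
#' lambda * gamma' P gamma`, the quadratic form in the lambda-scaled
#' penalty as fitted.
#'
#' @param fit a `penalized_fit`.
#' @param penalty a `penalty_spec` sharing the fit's basis spec; defaults to
#'   the penalty stored in the fit.
#' @param convention `"unit-penalty"` (default) or `"literal-lambda"`.
#' @return nonnegative scalar, in squared response units per x unit.
#' @export
volatility <- function(fit, penalty = fit$penalty,
                       convention = c("unit-penalty", "literal-lambda")) {
  convention <- match.arg(convention)
  stopifnot(inherits(fit, "penalized_fit"), inherits(penalty, "penalty_spec"))
  if (!identical(fit$design$identifiability, penalty$identifiability)) {
    stop("fit and penalty use different identifiability modes")
  }
  g <- fit$coefficients
  q <- max(drop(crossprod(g, penalty$P %*% g)), 0)
  if (convention == "literal-lambda") fit$lambda * q else q
}

## One full analysis on a single (x, y) sample: sort, choose knots, build
## design and penalty, select lambda by BIC, return fit plus volatility.
.analyse_xy <- function(x, y, interior, degree, grid, identifiability) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  spec <- suppressWarnings(choose_knots(x, interior = interior,
                                        degree = degree))
  design <- build_design(x, spec, identifiability = identifiability)
  penalty <- penalty_matrix(spec, identifiability = identifiability)
  sel <- select_lambda(design, y, penalty, grid = grid)
  list(spec = spec, design = design, penalty = penalty, sel = sel)
}

#' Penalized-spline volatility analysis of an (x, y) series
#'
#' Convenience wrapper running the full pipeline on one series: sort by
#' `x`, place knots at equally spaced quantiles, build the basis and
#' penalty, select the penalty parameter by BIC, and compute the
#' volatility under both conventions.
#'
#' @param x predictor (e.g. average SDI), numeric.
#' @param y response (e.g. DALY rate per 100,000), same length.
#' @param interior,degree basis configuration, defaults 3 and 3.
#' @param grid penalty grid, default [default_lambda_grid()].
#' @param identifiability see [build_design()].
#' @return list: `fit` (`penalized_fit` at the selected penalty),
#'   `lambda_star`, `profile`, `volatility_unit`, `volatility_literal`.
#' @export
fit_volatility <- function(x, y, interior = 3L, degree = 3L,
                           grid = default_lambda_grid(),
                           identifiability = "drop-first") {
  res <- .analyse_xy(x, y, interior, degree, grid, identifiability)
  fit <- res$sel$fit
  list(fit = fit, lambda_star = res$sel$lambda_star,
       profile = res$sel$profile,
       volatility_unit = volatility(fit, res$penalty, "unit-penalty"),
       volatility_literal = volatility(fit, res$penalty, "literal-lambda"))
}

#' Bootstrap confidence interval for the volatility functional
#'
#' Percentile bootstrap for `integral of {f'(x)}^2 dx`. The default scheme
#' resamples `(x_i, y_i)` pairs with replacement; each replicate re-chooses
#' knots on the resampled x, re-selects the penalty parameter by BIC and
#' recomputes the volatility. Replicates whose resampled x cannot support
#' the basis (too few distinct values) are redrawn, with the redraw count
#' reported; more than `100 * replicates` redraws is an error. The
#' `"residual"` scheme instead resamples centred residuals around the
#' full-data fitted curve, keeping x fixed. Fully reproducible from `seed`.
#'
#' @inheritParams fit_volatility
#' @param replicates number of bootstrap replicates, default 1000.
#' @param seed integer RNG seed.
#' @param convention volatility convention per replicate, default
#'   `"unit-penalty"`.
#' @param scheme `"pairs"` (default) or `"residual"`.
#' @param level confidence level, default 0.95.
#' @return object of class `volatility_estimate`: `estimate` (full-data
#'   volatility), `convention`, `ci` (`c(lower, upper)` percentile bounds),
#'   `replicates`, `seed`, `scheme`, `redraws`, `lambda_star`,
#'   `boot_values` (replicate volatilities).
#' @export
bootstrap_volatility <- function(x, y, interior = 3L, degree = 3L,
                                 grid = default_lambda_grid(),
                                 replicates = 1000L, seed = 1L,
                                 convention = c("unit-penalty",
                                                "literal-lambda"),
                                 scheme = c("pairs", "residual"),
                                 level = 0.95,
                                 identifiability = "drop-first") {
  convention <- match.arg(convention)
  scheme <- match.arg(scheme)
  stopifnot(replicates >= 1L, length(x) == length(y))
  n <- length(x)
  base <- .analyse_xy(x, y, interior, degree, grid, identifiability)
  est <- volatility(base$sel$fit, base$penalty, convention)
  min_distinct <- degree + interior + 2L

  set.seed(as.integer(seed))
  boot <- numeric(replicates)
  redraws <- 0L
  centred_resid <- base$sel$fit$residuals - mean(base$sel$fit$residuals)
  xs <- base$design$x
  fitted_base <- base$sel$fit$fitted
  for (b in seq_len(replicates)) {
    repeat {
      ok <- TRUE
      if (scheme == "pairs") {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx]; yb <- y[idx]
        if (length(unique(xb)) < min_distinct) ok <- FALSE
      } else {
        xb <- xs
        yb <- fitted_base + sample(centred_resid, n, replace = TRUE)
      }
      if (ok) {
        res <- tryCatch(
          .analyse_xy(xb, yb, interior, degree, grid, identifiability),
          error = function(e) NULL)
        if (!is.null(res)) {
          boot[b] <- volatility(res$sel$fit, res$penalty, convention)
          break
        }
      }
      redraws <- redraws + 1L
      if (redraws > 100L * replicates) {
        stop("bootstrap abandoned: more than ", 100L * replicates,
             " redraws; x cannot support the basis under resampling")
      }
    }
  }
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  structure(list(estimate = est, convention = convention, ci = ci,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), scheme = scheme,
                 redraws = redraws, level = level,
                 lambda_star = base$sel$lambda_star, boot_values = boot),
            class = "volatility_estimate")
}

#' @export
print.volatility_estimate <- function(x, ...) {
  cat(sprintf("Volatility (%s convention): %.6g\n", x$convention,
              x$estimate))
  cat(sprintf("  %d%% percentile bootstrap CI [%0.6g, %0.6g] (B = %d, %s, seed %d",
              round(100 * x$level), x$ci[1], x$ci[2], x$replicates,
              x$scheme, x$seed))
  if (x$redraws > 0) cat(", ", x$redraws, " redraw(s)", sep = "")
  cat(")\n")
  invisible(x)
}
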