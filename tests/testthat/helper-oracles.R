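# Independent oracles used across the spline tests. The B-spline evaluation
# here is a direct Cox-de Boor recurrence, written without reference to the
# package's implementation path (which goes through splines::splineDesign),
# so the two can disagree if either is wrong.

# Full clamped knot vector for a basis spec.
oracle_full_knots <- function(spec) {
  c(rep(spec$boundary[1], spec$degree + 1), spec$interior,
    rep(spec$boundary[2], spec$degree + 1))
}

# B_{j,d}(x) by the Cox-de Boor recurrence, scalar x, 1-based j over the
# full knot vector. The final basis interval is closed on the right.
oracle_bspline <- function(knots, j, d, x) {
  tmax <- knots[length(knots)]
  if (d == 0) {
    inside <- (x >= knots[j] && x < knots[j + 1]) ||
      (x == tmax && knots[j + 1] == tmax && knots[j] < knots[j + 1])
    return(as.numeric(inside))
  }
  left <- 0
  den1 <- knots[j + d] - knots[j]
  if (den1 > 0) {
    left <- (x - knots[j]) / den1 * oracle_bspline(knots, j, d - 1, x)
  }
  right <- 0
  den2 <- knots[j + d + 1] - knots[j + 1]
  if (den2 > 0) {
    right <- (knots[j + d + 1] - x) / den2 *
      oracle_bspline(knots, j + 1, d - 1, x)
  }
  left + right
}

# First derivative via the standard lower-order difference formula.
oracle_bspline_deriv <- function(knots, j, d, x) {
  out <- 0
  den1 <- knots[j + d] - knots[j]
  if (den1 > 0) out <- out + d / den1 * oracle_bspline(knots, j, d - 1, x)
  den2 <- knots[j + d + 1] - knots[j + 1]
  if (den2 > 0) out <- out - d / den2 * oracle_bspline(knots, j + 1, d - 1, x)
  out
}

# Full-basis evaluation matrix (m x J) from the oracle recurrence.
oracle_basis_matrix <- function(spec, x, deriv = FALSE) {
  knots <- oracle_full_knots(spec)
  J <- spec$J
  fun <- if (deriv) oracle_bspline_deriv else oracle_bspline
  vapply(seq_len(J),
         function(j) vapply(x, function(xi) fun(knots, j, spec$degree, xi),
                            numeric(1)),
         numeric(length(x)))
}

# Adaptive-integration entry of the derivative Gram, split at the knots so
# stats::integrate sees smooth pieces.
oracle_penalty_entry <- function(spec, j, jp) {
  knots <- oracle_full_knots(spec)
  breaks <- unique(c(spec$boundary[1], spec$interior, spec$boundary[2]))
  total <- 0
  for (i in seq_len(length(breaks) - 1)) {
    total <- total + stats::integrate(function(x) {
      vapply(x, function(xi)
        oracle_bspline_deriv(knots, j, spec$degree, xi) *
          oracle_bspline_deriv(knots, jp, spec$degree, xi), numeric(1))
    }, breaks[i], breaks[i + 1], rel.tol = 1e-12, abs.tol = 1e-12)$value
  }
  total
}

# Write a small burden CSV from a data.frame of short-named columns.
write_burden_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Minimal valid burden rows for hand-built fixtures.
burden_rows <- function(location, year, val, sex = "Both",
                        age = "Age-standardized", measure = "DALYs",
                        metric = "Rate", cause = "Diarrheal diseases",
                        lower = val * 0.9, upper = val * 1.1) {
  data.frame(measure = measure, location = location, sex = sex, age = age,
             cause = cause, metric = metric, year = year, val = val,
             upper = upper, lower = lower, stringsAsFactors = FALSE)
}
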