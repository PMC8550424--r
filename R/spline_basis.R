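#' Choose a cubic B-spline knot set from the data
#'
#' Interior knots are placed at equally spaced quantiles of `x` — for `k`
#' interior knots, the `1/(k+1), ..., k/(k+1)` quantiles under the linear
#' interpolation convention (`stats::quantile` type 7) — with boundary knots
#' at `min(x)` and `max(x)`. Coincident knots (interior knots that collide
#' with each other or a boundary after quantile placement) are collapsed
#' with a warning.
#'
#' @param x numeric abscissae (e.g. SDI values).
#' @param interior number of interior knots, default 3.
#' @param degree spline degree, default 3 (cubic).
#' @return object of class `spline_basis_spec`: `degree`, `interior`
#'   (ordered interior knots), `boundary` (`c(min, max)`), and `J`, the
#'   number of B-spline basis functions (`interior + degree + 1`).
#' @export
choose_knots <- function(x, interior = 3L, degree = 3L) {
  if (interior < 0L) stop("interior knot count must be >= 0")
  if (degree < 1L) stop("degree must be >= 1")
  xd <- unique(x[is.finite(x)])
  if (length(xd) < degree + interior + 2L) {
    stop("need at least ", degree + interior + 2L,
         " distinct x values for degree ", degree, " with ", interior,
         " interior knots; got ", length(xd))
  }
  boundary <- range(xd)
  knots <- if (interior > 0L) {
    probs <- seq_len(interior) / (interior + 1)
    as.numeric(stats::quantile(x, probs, type = 7, names = FALSE))
  } else numeric(0)
  all_k <- unique(c(boundary[1], knots, boundary[2]))
  kept <- all_k[all_k > boundary[1] & all_k < boundary[2]]
  if (length(kept) < length(knots)) {
    warning("collapsed ", length(knots) - length(kept),
            " coincident interior knot(s)")
  }
  structure(list(degree = as.integer(degree), interior = sort(kept),
                 boundary = boundary,
                 J = length(kept) + as.integer(degree) + 1L),
            class = "spline_basis_spec")
}

#' @export
print.spline_basis_spec <- function(x, ...) {
  cat(sprintf("Cubic-type B-spline basis: degree %d, %d interior knot(s), J = %d\n",
              x$degree, length(x$interior), x$J))
  cat(sprintf("  boundary [%g, %g]; interior: %s\n", x$boundary[1],
              x$boundary[2],
              if (length(x$interior)) paste(signif(x$interior, 6),
                                            collapse = ", ") else "none"))
  invisible(x)
}

## Full clamped (open-uniform) knot vector: boundaries repeated degree+1
## times around the interior knots.
.full_knots <- function(spec) {
  c(rep(spec$boundary[1], spec$degree + 1L), spec$interior,
    rep(spec$boundary[2], spec$degree + 1L))
}

## Evaluate the full clamped basis (or a derivative) at x; m x J matrix.
.basis_eval <- function(spec, x, deriv = 0L) {
  splines::splineDesign(.full_knots(spec), x, ord = spec$degree + 1L,
                        derivs = rep(deriv, length(x)), outer.ok = FALSE)
}

#' Build the regression design matrix for a basis specification
#'
#' Evaluates the clamped B-spline basis at `x` by the standard recurrence
#' and assembles the design. The parameterisation `f(x) = intercept + sum of
#' spline terms` with a full clamped basis is exactly collinear (the basis
#' functions sum to one), so the default `identifiability = "drop-first"`
#' retains the intercept and drops the first spline column. The alternative
#' `"keep-all"` drops the intercept and keeps all `J` spline columns; both
#' span the same function space and give identical fitted curves.
#'
#' @param x numeric abscissae, all within the boundary interval (no
#'   extrapolation).
#' @param spec a `spline_basis_spec` from [choose_knots()].
#' @param identifiability `"drop-first"` (intercept + spline columns 2..J,
#'   default) or `"keep-all"` (all J spline columns, no intercept).
#' @return object of class `spline_design`: `matrix` (m x p design), `x`,
#'   `spec`, `identifiability`.
#' @export
build_design <- function(x, spec,
                         identifiability = c("drop-first", "keep-all")) {
  identifiability <- match.arg(identifiability)
  stopifnot(inherits(spec, "spline_basis_spec"))
  tol <- 1e-8 * diff(spec$boundary)
  if (any(x < spec$boundary[1] - tol | x > spec$boundary[2] + tol)) {
    stop("x outside the boundary interval [", spec$boundary[1], ", ",
         spec$boundary[2], "]; extrapolation is not supported")
  }
  x <- pmin(pmax(x, spec$boundary[1]), spec$boundary[2])
  B <- .basis_eval(spec, x)
  X <- if (identifiability == "drop-first") {
    cbind(`(Intercept)` = 1, B[, -1L, drop = FALSE])
  } else B
  structure(list(matrix = X, x = x, spec = spec,
                 identifiability = identifiability),
            class = "spline_design")
}

#' @export
print.spline_design <- function(x, ...) {
  cat(sprintf("Spline design: %d observations x %d columns (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$identifiability))
  invisible(x)
}

#' First-derivative roughness penalty matrix
#'
#' Builds the unit penalty matrix `P` whose quadratic form in the spline
#' coefficients equals the integrated squared first derivative of the fitted
#' function, `integral of {f'(x)}^2` over the boundary interval. Entries are
#' exact integrals of products of first-derivative B-splines, computed by
#' Gauss-Legendre quadrature on each inter-knot interval (5 nodes, exact for
#' the piecewise polynomial integrand of degree `2*(degree-1)`). Under the
#' `"drop-first"` parameterisation the intercept row and column are
#' identically zero and the spline block is the derivative Gram restricted
#' to the retained basis functions; the scaled penalty used in fitting is
#' `lambda * P`.
#'
#' @param spec a `spline_basis_spec`.
#' @param identifiability as in [build_design()]; must match the design the
#'   penalty is used with.
#' @return object of class `penalty_spec`: `P` (p x p unit penalty aligned
#'   with the design columns), `P_full` (J x J derivative Gram of the full
#'   basis), `spec`, `identifiability`.
#' @export
penalty_matrix <- function(spec,
                           identifiability = c("drop-first", "keep-all")) {
  identifiability <- match.arg(identifiability)
  stopifnot(inherits(spec, "spline_basis_spec"))
  breaks <- unique(c(spec$boundary[1], spec$interior, spec$boundary[2]))
  J <- spec$J
  G <- matrix(0, J, J)
  for (i in seq_len(length(breaks) - 1L)) {
    gl <- pracma::gaussLegendre(5, breaks[i], breaks[i + 1L])
    D <- .basis_eval(spec, gl$x, deriv = 1L)
    G <- G + t(D) %*% (gl$w * D)
  }
  G <- (G + t(G)) / 2
  P <- if (identifiability == "drop-first") {
    out <- matrix(0, J, J)
    out[-1L, -1L] <- G[-1L, -1L, drop = FALSE]
    out
  } else G
  structure(list(P = P, P_full = G, spec = spec,
                 identifiability = identifiability),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat(sprintf("First-derivative penalty: %d x %d (%s parameterisation)\n",
              nrow(x$P), ncol(x$P), x$identifiability))
  invisible(x)
}
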