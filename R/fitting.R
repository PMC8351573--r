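#' Parameter grid for exhaustive search
#'
#' A Cartesian lattice over the two distribution parameters: the shape `k`
#' (or location `mu`) and the scale `b`. Every node of the grid is visited
#' during fitting, which guarantees the global optimum on the lattice —
#' unlike gradient or likelihood methods that can stall in local optima.
#'
#' @param first_param_values Strictly increasing values for `k` or `mu`.
#' @param second_param_values Strictly increasing positive values for `b`.
#' @return An object of class `grid_spec`.
#' @seealso [default_grid()], [reduced_grid()]
#' @export
grid_spec <- function(first_param_values, second_param_values) {
  check_increasing <- function(x, what) {
    if (length(x) == 0 || any(!is.finite(x)) || any(diff(x) <= 0)) {
      stop(sprintf("%s must be a nonempty, finite, strictly increasing vector", what),
           call. = FALSE)
    }
  }
  check_increasing(first_param_values, "first_param_values")
  check_increasing(second_param_values, "second_param_values")
  if (any(second_param_values <= 0)) {
    stop("second_param_values (scale b) must all be positive", call. = FALSE)
  }
  structure(list(first_param_values = first_param_values,
                 second_param_values = second_param_values),
            class = "grid_spec")
}

#' Default and reduced parameter grids
#'
#' `default_grid()` reproduces the full search lattice: 400 values per
#' parameter (160,000 nodes), `k` and `b` from 0.05 to 20.00 in steps of
#' 0.05 for the shape/scale families. The location families need negative
#' locations to be representable (fits to early-childhood incidence peaks
#' push `mu` below zero), so `mu` runs from -20.0 to 19.9 in steps of 0.1.
#'
#' `reduced_grid()` is a coarser 100 x 100 lattice over the same ranges
#' (steps 0.2 for `k`/`b`, 0.4 for `mu`) used to keep simulation-heavy test
#' runs fast; every reduced-grid node is also a node of the default grid.
#'
#' @param spec A [dist_spec()] or family name.
#' @return A [grid_spec()].
#' @export
default_grid <- function(spec) {
  spec <- as_dist_spec(spec)
  b <- seq(0.05, 20, by = 0.05)
  first <- if (is_k_family(spec)) b else seq(-20, 19.9, by = 0.1)
  grid_spec(first, b)
}

#' @rdname default_grid
#' @export
reduced_grid <- function(spec) {
  spec <- as_dist_spec(spec)
  b <- seq(0.2, 20, by = 0.2)
  first <- if (is_k_family(spec)) b else seq(-20, 19.6, by = 0.4)
  grid_spec(first, b)
}

#' Area under the incidence curve
#'
#' Estimated as the plain sum of the observed crude rates over the age bins
#' (no bin-width weighting). Its only role is to set the amplitude search
#' bracket, `[area / 100, area * 100]`, which is far wider than any
#' plausible amplitude, so the crude estimate is sufficient.
#'
#' @param series An [age_incidence_series()] or a numeric vector of rates.
#' @return Positive scalar.
#' @export
area_estimate <- function(series) {
  rates <- if (inherits(series, "age_incidence_series")) series$crude_rate else series
  if (length(rates) == 0) stop("empty incidence series", call. = FALSE)
  a <- sum(rates)
  if (a <= 0) {
    stop("all crude rates are zero; the amplitude bracket would collapse",
         call. = FALSE)
  }
  a
}

GOLDEN_RATIO <- (sqrt(5) - 1) / 2

#' Golden-section search for a unimodal maximum
#'
#' Derivative-free bracketing maximiser. The bracket shrinks by the golden
#' ratio each iteration until its width falls below `tolerance` times the
#' initial width; the midpoint of the final bracket is returned. For a
#' maximiser interior to the bracket the result is within half the final
#' bracket width of the truth; a maximiser outside the bracket yields the
#' nearer boundary.
#'
#' @param objective Unary function, assumed unimodal on `[lower, upper]`.
#' @param lower,upper Bracket endpoints, `lower < upper`.
#' @param tolerance Relative stopping tolerance on the bracket width.
#' @return The approximate argmax (scalar).
#' @export
golden_section_max <- function(objective, lower, upper, tolerance = 1e-8) {
  if (!(is.finite(lower) && is.finite(upper) && lower < upper)) {
    stop("need finite lower < upper", call. = FALSE)
  }
  a <- lower; b <- upper
  width0 <- b - a
  while ((b - a) > tolerance * width0) {
    h <- b - a
    x1 <- b - GOLDEN_RATIO * h
    x2 <- a + GOLDEN_RATIO * h
    f1 <- objective(x1)
    f2 <- objective(x2)
    if (!is.finite(f1)) stop(sprintf("objective is not finite at %g", x1), call. = FALSE)
    if (!is.finite(f2)) stop(sprintf("objective is not finite at %g", x2), call. = FALSE)
    if (f1 > f2) b <- x2 else a <- x1
  }
  (a + b) / 2
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of the observed values. Equals 1 for a perfect fit, 0 for a constant
#' prediction at the observed mean, and can be negative for fits worse than
#' the mean.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("observed and predicted must have equal length >= 2", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("observed values are all identical; R-squared is undefined", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

# Density matrix: one row per grid node (row-major: first parameter slowest),
# one column per age bin.
node_density_matrix <- function(spec, grid, t) {
  n1 <- length(grid$first_param_values)
  n2 <- length(grid$second_param_values)
  p1 <- rep(grid$first_param_values, each = n2)
  p2 <- rep(grid$second_param_values, times = n1)
  m <- length(t)
  vals <- dist_pdf(spec,
                   rep(p1, times = m),
                   rep(p2, times = m),
                   rep(t, each = n1 * n2))
  list(F = matrix(vals, nrow = n1 * n2, ncol = m), p1 = p1, p2 = p2)
}

# Golden-section amplitude search run simultaneously for every grid node.
# F: node x bin density matrix; y: observed rates. The bracket is common to
# all nodes; the bracket *decisions* are per node, tracked with masks.
#
# The objective per node is SS_res(A) = sum((y - A f)^2); comparisons use
# the equivalent form A^2 sum(f^2) - 2 A sum(y f), dropping the A-free
# constant sum(y^2). The ordering is identical, but at nodes where the
# density is vanishingly small at every bin the constant would swamp the
# A-dependent terms in double precision and make the comparisons noise.
golden_amplitudes <- function(F, y, lower, upper, tolerance) {
  n <- nrow(F)
  s2 <- rowSums(F * F)
  sy <- as.vector(F %*% y)
  q <- function(A) (A * s2 - 2 * sy) * A # maximising R^2 == minimising SS_res
  a <- rep(lower, n); b <- rep(upper, n)
  width0 <- upper - lower
  while (max(b - a) > tolerance * width0) {
    h <- b - a
    x1 <- b - GOLDEN_RATIO * h
    x2 <- a + GOLDEN_RATIO * h
    take_left <- q(x1) < q(x2)
    b <- ifelse(take_left, x2, b)
    a <- ifelse(take_left, a, x1)
  }
  (a + b) / 2
}

#' Fit one model family to an incidence series by exhaustive grid search
#'
#' For every node `(k, b)` (or `(mu, b)`) of the grid, the curve amplitude
#' `A` is optimised by golden-section search of R-squared over
#' `[area / 100, area * 100]`, where `area` is [area_estimate()]; the model
#' curve `A * f(t_i)` is evaluated at the observed bin midpoints only and
#' compared with the observed crude rates. The node with the highest
#' R-squared is the global optimum on the lattice (ties resolved by
#' row-major grid order: lowest first parameter, then lowest scale). The
#' full R-squared landscape over the grid is retained for inspection and
#' heatmap export.
#'
#' @param series An [age_incidence_series()].
#' @param family A [dist_spec()] or family name.
#' @param grid A [grid_spec()]; defaults to the full 400 x 400
#'   [default_grid()] for the family.
#' @param amp_tolerance Relative golden-section stopping tolerance for the
#'   amplitude (fraction of the initial bracket width).
#' @return An object of class `grid_fit`: `family`, `best_params` (named),
#'   `amplitude`, `r_squared`, `mass_below_zero` (at the optimum),
#'   `landscape` and `amplitude_landscape` (matrices, first parameter in
#'   rows, scale in columns), `grid`, `bracket` and `cancer_label`.
#' @export
fit_distribution <- function(series, family, grid = NULL, amp_tolerance = 1e-8) {
  spec <- as_dist_spec(family)
  if (!inherits(series, "age_incidence_series")) {
    stop("'series' must be an age_incidence_series", call. = FALSE)
  }
  if (is.null(grid)) grid <- default_grid(spec)
  if (!inherits(grid, "grid_spec")) stop("'grid' must be a grid_spec", call. = FALSE)
  if (is_k_family(spec) && any(grid$first_param_values <= 0)) {
    stop(sprintf("grid contains non-positive shape values for family '%s'",
                 spec$family), call. = FALSE)
  }

  t <- series$midpoint
  y <- series$crude_rate
  area <- area_estimate(series)
  bracket <- c(area / 100, area * 100)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("observed rates are all identical; fit is undefined", call. = FALSE)

  nd <- node_density_matrix(spec, grid, t)
  A <- golden_amplitudes(nd$F, y, bracket[1], bracket[2], amp_tolerance)
  Y <- matrix(y, nrow = nrow(nd$F), ncol = length(y), byrow = TRUE)
  r2 <- 1 - rowSums((nd$F * A - Y)^2) / ss_tot

  best <- which.max(r2) # first max in row-major order = documented tie-break
  n1 <- length(grid$first_param_values)
  n2 <- length(grid$second_param_values)
  dn <- list(format(grid$first_param_values), format(grid$second_param_values))
  best_params <- stats::setNames(c(nd$p1[best], nd$p2[best]), spec$param_names)

  structure(list(
    family = spec,
    best_params = best_params,
    amplitude = A[best],
    r_squared = r2[best],
    mass_below_zero = mass_below_zero(spec, nd$p1[best], nd$p2[best]),
    landscape = matrix(r2, nrow = n1, ncol = n2, byrow = TRUE, dimnames = dn),
    amplitude_landscape = matrix(A, nrow = n1, ncol = n2, byrow = TRUE, dimnames = dn),
    grid = grid,
    bracket = bracket,
    cancer_label = attr(series, "cancer_label") %||% "unknown"
  ), class = "grid_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.grid_fit <- function(x, ...) {
  p <- x$best_params
  cat(sprintf(
    "Grid fit: %s ~ %s\n  %s = %g, %s = %g, A = %.4g\n  R^2 = %.6f, mass below age 0 = %.4g\n",
    x$cancer_label, x$family$family,
    names(p)[1], p[[1]], names(p)[2], p[[2]], x$amplitude,
    x$r_squared, x$mass_below_zero
  ))
  invisible(x)
}

#' Fit and rank several model families on one series
#'
#' Fits each family with [fit_distribution()] and sorts the results by
#' R-squared, best first (ties keep the input family order; the sort is
#' stable). Each fit carries the probability mass its optimum places below
#' age zero; families exceeding `mass_threshold` are flagged
#' non-interpretable — ages cannot be negative — but are still reported.
#'
#' @param series An [age_incidence_series()].
#' @param families Character vector or list of [dist_spec()]s.
#' @param grids Optional named list of [grid_spec()]s keyed by family name;
#'   families absent from the list use their [default_grid()].
#' @param amp_tolerance Passed to [fit_distribution()].
#' @param mass_threshold Flagging threshold on the below-zero mass.
#' @return An object of class `family_comparison`: list with `fits`
#'   (ranked list of `grid_fit`s) and `table` (data frame: family,
#'   r_squared, mass_below_zero, flagged).
#' @export
compare_families <- function(series, families = DIST_FAMILIES, grids = NULL,
                             amp_tolerance = 1e-8, mass_threshold = 0.05) {
  if (length(families) == 0) stop("need at least one family", call. = FALSE)
  specs <- lapply(families, as_dist_spec)
  fits <- lapply(specs, function(spec) {
    g <- if (!is.null(grids) && spec$family %in% names(grids)) grids[[spec$family]] else NULL
    fit_distribution(series, spec, grid = g, amp_tolerance = amp_tolerance)
  })
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  ord <- order(-r2) # radix sort: stable, ties keep input order
  fits <- fits[ord]
  tab <- data.frame(
    family = vapply(fits, function(f) f$family$family, character(1)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    mass_below_zero = vapply(fits, function(f) f$mass_below_zero, numeric(1)),
    stringsAsFactors = FALSE
  )
  tab$flagged <- tab$mass_below_zero > mass_threshold
  structure(list(fits = fits, table = tab, mass_threshold = mass_threshold),
            class = "family_comparison")
}

#' @export
print.family_comparison <- function(x, ...) {
  cat(sprintf("Family comparison: %s\n", x$fits[[1]]$cancer_label))
  tab <- x$table
  tab$r_squared <- sprintf("%.4f", tab$r_squared)
  tab$mass_below_zero <- sprintf("%.4g", tab$mass_below_zero)
  print.data.frame(tab, row.names = FALSE)
  if (any(x$table$flagged)) {
    cat(sprintf("flagged: > %.2g of the density lies at negative ages\n",
                x$mass_threshold))
  }
  invisible(x)
}

#' Export an R-squared landscape as TSV
#'
#' Writes the grid-fit landscape (first parameter in rows, scale in
#' columns, values R-squared) for external heatmap rendering.
#'
#' @param fit A `grid_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_landscape_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "grid_fit"))
  utils::write.table(fit$landscape, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
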