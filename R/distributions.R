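#' @keywords internal
DIST_FAMILIES <- c("erlang_gamma", "weibull", "extreme_value", "logistic", "normal")

#' Model family specification
#'
#' Identifies one of the five model families used to describe age-incidence
#' curves and records its parameterisation. The gamma/Erlang and Weibull
#' families are shape/scale families `(k, b)` supported on non-negative ages;
#' the extreme value (Gumbel, max convention), logistic and normal families
#' are location/scale families `(mu, b)` supported on the whole real line.
#'
#' @param family One of `"erlang_gamma"`, `"weibull"`, `"extreme_value"`,
#'   `"logistic"`, `"normal"` (partial matching allowed).
#' @return An object of class `dist_spec`: a list with `family`,
#'   `param_names` (`c("k","b")` or `c("mu","b")`) and `support_lower_bound`
#'   (`0` for shape/scale families, `-Inf` otherwise).
#' @examples
#' dist_spec("erlang_gamma")
#' dist_spec("normal")$support_lower_bound
#' @export
dist_spec <- function(family) {
  family <- match.arg(family, DIST_FAMILIES)
  k_family <- family %in% c("erlang_gamma", "weibull")
  structure(
    list(
      family = family,
      param_names = if (k_family) c("k", "b") else c("mu", "b"),
      support_lower_bound = if (k_family) 0 else -Inf
    ),
    class = "dist_spec"
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf(
    "<dist_spec> %s  params: (%s, %s)  support: [%s, Inf)\n",
    x$family, x$param_names[1], x$param_names[2],
    format(x$support_lower_bound)
  ))
  invisible(x)
}

is_k_family <- function(spec) identical(spec$support_lower_bound, 0)

as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) x else dist_spec(x)
}

check_params <- function(spec, first, second) {
  if (any(!is.finite(second)) || any(second <= 0)) {
    stop("invalid parameter: scale 'b' must be positive and finite", call. = FALSE)
  }
  if (is_k_family(spec) && (any(!is.finite(first)) || any(first <= 0))) {
    stop(sprintf("invalid parameter: shape 'k' must be positive for family '%s'",
                 spec$family), call. = FALSE)
  }
  if (!is_k_family(spec) && any(!is.finite(first))) {
    stop("invalid parameter: location 'mu' must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Probability density of a model family
#'
#' Closed-form density `f(t)` for age `t` (years). All densities are
#' evaluated in log space and exponentiated, so large shape parameters with
#' small scales do not overflow the gamma function. Arguments are recycled
#' to a common length, so the function can be evaluated over a vector of
#' ages, a vector of parameter points, or both.
#'
#' For the shape/scale families the support is `t >= 0`: negative ages
#' return density 0. At exactly `t = 0` with `k < 1` the density is
#' analytically infinite; rather than returning a non-finite value the
#' function raises a domain error (the fitting layer only ever evaluates at
#' positive bin midpoints, the smallest being 0.5 years).
#'
#' @param spec A [dist_spec()] (or a family name).
#' @param first Shape `k` (erlang_gamma, weibull; must be > 0) or location
#'   `mu` (extreme_value, logistic, normal).
#' @param second Scale `b` in years; must be > 0.
#' @param t Age(s) in years.
#' @return Numeric vector of finite non-negative densities.
#' @examples
#' dist_pdf("erlang_gamma", 2, 1, 1)   # t * exp(-t) at t = 1
#' dist_pdf("normal", 0, 1, 0)         # 1 / sqrt(2 * pi)
#' @export
dist_pdf <- function(spec, first, second, t) {
  spec <- as_dist_spec(spec)
  check_params(spec, first, second)
  n <- max(length(first), length(second), length(t))
  first <- rep_len(first, n)
  second <- rep_len(second, n)
  t <- rep_len(t, n)
  if (any(!is.finite(t))) stop("age 't' must be finite", call. = FALSE)

  out <- numeric(n)
  if (is_k_family(spec)) {
    if (any(t == 0 & first < 1)) {
      stop("density at t = 0 is unbounded for shape k < 1 (domain error)",
           call. = FALSE)
    }
    pos <- t > 0
    k <- first[pos]; b <- second[pos]; tp <- t[pos]
    if (spec$family == "erlang_gamma") {
      # log f = (k-1) log(t/b) - t/b - log b - lgamma(k)
      out[pos] <- exp((k - 1) * (log(tp) - log(b)) - tp / b - log(b) - lgamma(k))
    } else { # weibull
      out[pos] <- exp(log(k) - log(b) + (k - 1) * (log(tp) - log(b)) - (tp / b)^k)
    }
    # t == 0: limit is 1/b when k == 1, 0 when k > 1
    at0 <- t == 0
    out[at0] <- ifelse(first[at0] == 1, 1 / second[at0], 0)
  } else {
    z <- (t - first) / second
    out <- switch(spec$family,
      extreme_value = exp(-z - exp(-z)) / second,
      logistic = {
        az <- abs(z)
        exp(-az) / (second * (1 + exp(-az))^2)
      },
      normal = exp(-0.5 * z^2) / (second * sqrt(2 * pi))
    )
  }
  out
}

#' Probability mass below age zero
#'
#' The cumulative distribution function at `t = 0`, i.e. the fraction of the
#' fitted density lying at negative ages. Shape/scale families are supported
#' on `t >= 0` and return exactly 0; for the location/scale families a large
#' value disqualifies the fit biologically, since ages cannot be negative.
#'
#' @inheritParams dist_pdf
#' @return Numeric in `[0, 1]` (vectorised over parameters).
#' @examples
#' mass_below_zero("erlang_gamma", 2, 3)   # 0
#' mass_below_zero("normal", 0, 1)         # 0.5
#' @export
mass_below_zero <- function(spec, first, second) {
  spec <- as_dist_spec(spec)
  check_params(spec, first, second)
  n <- max(length(first), length(second))
  first <- rep_len(first, n)
  second <- rep_len(second, n)
  if (is_k_family(spec)) return(rep(0, n))
  switch(spec$family,
    extreme_value = exp(-exp(first / second)),
    logistic = 1 / (1 + exp(first / second)),
    normal = stats::pnorm(0, mean = first, sd = second)
  )
}
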