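#' Carcinogenesis parameters from a gamma/Erlang fit
#'
#' Under the Poisson-process model of driver accumulation, the gamma/Erlang
#' shape `k` is read as the average number of driver events required for a
#' detectable cancer, the scale `b` as the average time between successive
#' events (years), the amplitude divided by 1,000 as the maximal
#' populational susceptibility (percent of the population that can develop
#' this cancer), and the product `k * b` as the expected waiting time until
#' the last required event (years).
#'
#' `carcinogenesis_params()` builds the quantity set from raw values;
#' `interpret_fit()` extracts them from a [fit_distribution()] result. Only
#' the gamma/Erlang family carries this interpretation — it is the waiting
#' time for the k-th event of a Poisson process — so other families error.
#'
#' @param driver_events Shape `k` (> 0; non-integer values read as a
#'   population mixture of integer event counts).
#' @param interval_years Scale `b` in years (> 0).
#' @param amplitude Fitted amplitude `A` (cases per 100,000 x years).
#' @param fit A `grid_fit` with family `erlang_gamma`.
#' @return An object of class `carcinogenesis_params`: list with
#'   `driver_events`, `interval_years`, `susceptibility_percent`
#'   (= amplitude/1000) and `waiting_time_years` (= k * b).
#' @examples
#' carcinogenesis_params(8.95, 3.9, 19660)
#' @export
carcinogenesis_params <- function(driver_events, interval_years, amplitude) {
  if (!is.finite(driver_events) || driver_events <= 0) stop("driver_events must be > 0")
  if (!is.finite(interval_years) || interval_years <= 0) stop("interval_years must be > 0")
  if (!is.finite(amplitude) || amplitude < 0) stop("amplitude must be >= 0")
  structure(list(
    driver_events = driver_events,
    interval_years = interval_years,
    susceptibility_percent = amplitude / 1000,
    waiting_time_years = driver_events * interval_years
  ), class = "carcinogenesis_params")
}

#' @rdname carcinogenesis_params
#' @export
interpret_fit <- function(fit) {
  stopifnot(inherits(fit, "grid_fit"))
  if (fit$family$family != "erlang_gamma") {
    stop(sprintf(
      "carcinogenesis interpretation is defined only for the gamma/Erlang family, not '%s'",
      fit$family$family), call. = FALSE)
  }
  carcinogenesis_params(fit$best_params[["k"]], fit$best_params[["b"]], fit$amplitude)
}

#' @export
print.carcinogenesis_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Carcinogenesis parameters (gamma/Erlang reading):\n",
    "  driver events (k):            %g\n",
    "  inter-event interval (b):     %g years\n",
    "  maximal susceptibility (A/1000): %g %%\n",
    "  expected waiting time (k*b):  %g years\n"),
    x$driver_events, x$interval_years, x$susceptibility_percent,
    x$waiting_time_years))
  invisible(x)
}

#' Two-component driver-count mixture arithmetic
#'
#' A population mixing a hereditary form that needs `k_hereditary` somatic
#' driver events (one, for retinoblastoma: the first hit is inherited) with
#' a sporadic form needing `k_sporadic` events (two: both hits somatic) has
#' combined-incidence shape `k = h * k_hereditary + (1 - h) * k_sporadic`,
#' the prevalence-weighted mean of the component event counts.
#'
#' `expected_k_from_mixture()` computes that mean from the hereditary
#' prevalence `h`; `hereditary_fraction_from_k()` inverts it, recovering the
#' hereditary prevalence implied by a fitted fractional shape:
#' `h = (k_sporadic - k_fitted) / (k_sporadic - k_hereditary)`.
#'
#' @param h Hereditary-form prevalence in `[0, 1]`.
#' @param k_fitted Fitted shape, within `[k_hereditary, k_sporadic]`.
#' @param k_hereditary,k_sporadic Component driver-event counts,
#'   `k_hereditary < k_sporadic`.
#' @return `expected_k_from_mixture()`: the mixture shape.
#'   `hereditary_fraction_from_k()`: the hereditary fraction in `[0, 1]`.
#' @examples
#' expected_k_from_mixture(0.45)      # 1.55
#' hereditary_fraction_from_k(1.3)    # 0.70
#' @export
expected_k_from_mixture <- function(h, k_hereditary = 1, k_sporadic = 2) {
  check_mixture_components(k_hereditary, k_sporadic)
  if (any(!is.finite(h)) || any(h < 0) || any(h > 1)) {
    stop("mixture fraction 'h' must lie in [0, 1]", call. = FALSE)
  }
  h * k_hereditary + (1 - h) * k_sporadic
}

#' @rdname expected_k_from_mixture
#' @export
hereditary_fraction_from_k <- function(k_fitted, k_hereditary = 1, k_sporadic = 2) {
  check_mixture_components(k_hereditary, k_sporadic)
  if (any(!is.finite(k_fitted)) || any(k_fitted < k_hereditary) || any(k_fitted > k_sporadic)) {
    stop(sprintf("k_fitted must lie within [%g, %g] for the mixture reading to be valid",
                 k_hereditary, k_sporadic), call. = FALSE)
  }
  (k_sporadic - k_fitted) / (k_sporadic - k_hereditary)
}

check_mixture_components <- function(k_hereditary, k_sporadic) {
  if (!(is.finite(k_hereditary) && is.finite(k_sporadic) &&
        k_hereditary > 0 && k_hereditary < k_sporadic)) {
    stop("need 0 < k_hereditary < k_sporadic", call. = FALSE)
  }
  invisible(TRUE)
}

#' Range of expected waiting times across cancer types
#'
#' Minimum and maximum of the expected waiting time `k * b` over a set of
#' interpreted fits, rounded half-up to whole years (so 0.94 reports as 1
#' and 34.9 as 35).
#'
#' @param params_list List of [carcinogenesis_params()] objects.
#' @return Named numeric `c(min_years, max_years)`.
#' @export
waiting_time_summary <- function(params_list) {
  if (length(params_list) == 0) stop("empty parameter list", call. = FALSE)
  wt <- vapply(params_list, function(p) {
    stopifnot(inherits(p, "carcinogenesis_params"))
    p$waiting_time_years
  }, numeric(1))
  round_half_up <- function(x) floor(x + 0.5)
  c(min_years = round_half_up(min(wt)), max_years = round_half_up(max(wt)))
}
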