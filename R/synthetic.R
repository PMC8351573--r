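#' Standard childhood/young-adulthood age bins
#'
#' The default bin panel: `"< 1 year"`, `"1-4 years"`, then 5-year groups up
#' to `"35-39 years"` (midpoints 0.5, 3, 7.5, ..., 37.5 years), matching the
#' age range over which childhood and young-adulthood incidence peaks occur.
#'
#' @return Character vector of 9 age-group labels.
#' @export
default_age_groups <- function() {
  c("< 1 year", "1-4 years",
    sprintf("%d-%d years", seq(5, 35, by = 5), seq(9, 39, by = 5)))
}

#' Configuration for a synthetic incidence cohort
#'
#' Describes a ground-truth incidence model from which a CDC WONDER-shaped
#' series can be generated: the expected crude rate in each age bin is
#' `A * f(midpoint)` with `f` the chosen family's density. With a per-bin
#' population the observed case count in each bin is Poisson with mean
#' `A * f(midpoint) / 100000 * population` (crude rates are count-derived,
#' so Poisson counts are the natural noise model); without one the rates
#' are exact (noiseless).
#'
#' Defaults reproduce a typical childhood-cancer series: gamma/Erlang with
#' `k = 1.75`, `b = 2.2` years and amplitude 124 (nephroblastoma-scale).
#'
#' @param family Family name or [dist_spec()].
#' @param first Shape `k` or location `mu` of the true density.
#' @param second Scale `b` in years.
#' @param amplitude Curve amplitude `A` (cases per 100,000 x years).
#' @param age_group_labels Bin labels, parseable by
#'   [parse_age_group_label()].
#' @param per_bin_population Positive integer, or `NULL` for noiseless.
#' @param random_seed Integer seed for the Poisson draws.
#' @param cancer_label Label attached to generated series.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(family = "erlang_gamma", first = 1.75, second = 2.2,
                             amplitude = 124,
                             age_group_labels = default_age_groups(),
                             per_bin_population = NULL, random_seed = 1L,
                             cancer_label = NULL) {
  spec <- as_dist_spec(family)
  check_params(spec, first, second)
  if (!is.finite(amplitude) || amplitude <= 0) stop("amplitude must be > 0")
  midpoints <- parse_age_group_label(age_group_labels) # validates labels
  if (any(diff(midpoints) <= 0)) stop("age-group labels must be in increasing age order")
  if (!is.null(per_bin_population) &&
      (!is.finite(per_bin_population) || per_bin_population < 1)) {
    stop("per_bin_population must be a positive count or NULL")
  }
  if (is.null(cancer_label)) {
    cancer_label <- sprintf("synthetic %s (%s=%g, b=%g, A=%g)",
                            spec$family, spec$param_names[1], first, second, amplitude)
  }
  structure(list(family = spec, first = first, second = second,
                 amplitude = amplitude, age_group_labels = age_group_labels,
                 midpoints = midpoints,
                 per_bin_population = per_bin_population,
                 random_seed = as.integer(random_seed),
                 cancer_label = cancer_label),
            class = "synthetic_config")
}

# Run code with a private RNG stream, leaving the caller's .Random.seed alone.
with_private_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Generate a synthetic incidence series with known ground truth
#'
#' Evaluates the true density at the bin midpoints, scales by the
#' amplitude, and (in noisy mode) replaces each expected rate with a
#' Poisson-sampled observed rate: `count ~ Poisson(rate / 100000 *
#' population)`, `observed rate = count / population * 100000`. The same
#' seed always yields the same series.
#'
#' @param config A [synthetic_config()].
#' @return List with `series` (an [age_incidence_series()]) and `truth`
#'   (family, parameters, amplitude, seed, and the noiseless expected
#'   rates).
#' @export
generate_incidence <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  f <- dist_pdf(config$family, config$first, config$second, config$midpoints)
  expected_rate <- config$amplitude * f
  pop <- config$per_bin_population
  if (is.null(pop)) {
    rate <- expected_rate
  } else {
    lambda <- expected_rate / 1e5 * pop
    if (any(!is.finite(lambda))) stop("non-finite expected counts; check parameters")
    counts <- with_private_seed(config$random_seed, stats::rpois(length(lambda), lambda))
    rate <- counts / pop * 1e5
  }
  series <- age_incidence_series(age_group = config$age_group_labels,
                                 crude_rate = rate,
                                 midpoint = config$midpoints,
                                 cancer_label = config$cancer_label,
                                 population = if (is.null(pop)) NULL
                                              else rep(pop, length(rate)))
  list(series = series,
       truth = list(family = config$family$family,
                    first = config$first, second = config$second,
                    amplitude = config$amplitude,
                    per_bin_population = pop,
                    random_seed = config$random_seed,
                    expected_rate = expected_rate))
}

#' @rdname generate_incidence
#' @param configs List of [synthetic_config()]s.
#' @export
generate_panel <- function(configs) {
  lapply(configs, generate_incidence)
}

#' Write a series in the CDC WONDER TSV dialect
#'
#' Emits the two-column tab-separated layout that
#' [read_incidence_table()] reads back (`"Age Groups"`, `"Crude Rate"`),
#' giving a loss-free round trip for fixture generation.
#'
#' @param series An [age_incidence_series()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_incidence_tsv <- function(series, path) {
  stopifnot(inherits(series, "age_incidence_series"))
  df <- data.frame(`Age Groups` = series$age_group,
                   `Crude Rate` = format(series$crude_rate, digits = 15, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published childhood/young-adulthood gamma/Erlang parameter panel
#'
#' The ten cancer types with their fitted gamma/Erlang carcinogenesis
#' parameters: driver-event count `k`, inter-event interval `b` (years) and
#' maximal populational susceptibility `A/1000` (percent; the fitted
#' amplitude is therefore `susceptibility * 1000`). Used as ground-truth
#' input for end-to-end synthetic panels and for the waiting-time summary.
#'
#' @return Data frame with columns `cancer`, `k`, `b`,
#'   `susceptibility_percent`, `amplitude`.
#' @export
childhood_panel <- function() {
  df <- data.frame(
    cancer = c(
      "Ewing tumour and related sarcomas of bone",
      "Extracranial and extragonadal germ cell tumours of childhood",
      "Extracranial and extragonadal germ cell tumours of young adulthood",
      "Hepatoblastoma",
      "Intracranial and intraspinal embryonal tumours",
      "Intracranial and intraspinal germ cell tumours",
      "Malignant gonadal germ cell tumours",
      "Nephroblastoma and other nonepithelial renal tumours",
      "Neuroblastoma and ganglioneuroblastoma",
      "Retinoblastoma"),
    k = c(4.3, 0.4, 6.5, 1.55, 1.0, 5.65, 8.95, 1.75, 1.0, 1.3),
    b = c(4.25, 2.35, 5.3, 1.4, 14.85, 3.05, 3.9, 2.2, 2.5, 1.45),
    susceptibility_percent = c(0.0846, 0.0322, 0.111, 0.0338, 0.179,
                               0.0426, 1.966, 0.124, 0.179, 0.072),
    stringsAsFactors = FALSE
  )
  df$amplitude <- df$susceptibility_percent * 1000
  df
}
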