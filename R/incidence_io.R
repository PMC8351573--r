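#' Midpoint age of a CDC WONDER age-group label
#'
#' Converts labels such as `"15-19 years"` into the middle age of the real
#' age interval they cover. Integer-age labels denote half-open intervals:
#' `"N-M years"` covers `[N, M+1)`, so its midpoint is `(N + M + 1) / 2`
#' (e.g. 17.5 for `"15-19 years"`); `"< N years"` covers `[0, N)` with
#' midpoint `N / 2`. Either a hyphen or an en-dash is accepted and
#' surrounding whitespace is ignored.
#'
#' Open-ended labels (`"85+ years"`) have no defensible midpoint and raise
#' an error; callers typically drop such bins.
#'
#' @param label Character vector of age-group labels.
#' @return Numeric vector of midpoints in years.
#' @examples
#' parse_age_group_label(c("< 1 year", "1-4 years", "15-19 years"))
#' @export
parse_age_group_label <- function(label) {
  vapply(as.character(label), parse_one_label, numeric(1), USE.NAMES = FALSE)
}

parse_one_label <- function(label) {
  x <- trimws(label)
  if (grepl("^<\\s*[0-9]+\\s*years?$", x)) {
    n <- as.numeric(sub("^<\\s*([0-9]+).*$", "\\1", x))
    return(n / 2)
  }
  if (grepl("^[0-9]+\\s*[-–]\\s*[0-9]+\\s*years?$", x)) {
    lo <- as.numeric(sub("^([0-9]+).*$", "\\1", x))
    hi <- as.numeric(sub("^[0-9]+\\s*[-–]\\s*([0-9]+).*$", "\\1", x))
    if (hi < lo) stop(sprintf("age-group label '%s' has upper age below lower", label),
                      call. = FALSE)
    return((lo + hi + 1) / 2)
  }
  if (grepl("^[0-9]+\\s*\\+\\s*years?$", x)) {
    stop(sprintf("open-ended age group '%s' has no midpoint; drop this bin", label),
         call. = FALSE)
  }
  stop(sprintf("cannot parse age-group label '%s'", label), call. = FALSE)
}

#' Construct an age-incidence series
#'
#' One cancer type's observed incidence: ordered age-bin midpoints (years)
#' with crude rates (new cases per 100,000 persons per year).
#'
#' @param age_group Character vector of age-group labels (midpoints are
#'   derived with [parse_age_group_label()]), or `NULL` if `midpoint` is
#'   given directly.
#' @param crude_rate Non-negative crude rates, one per bin.
#' @param cancer_label Name of the cancer type (free text).
#' @param midpoint Optional explicit midpoints in years (overrides
#'   `age_group`-derived values).
#' @param population Optional positive per-bin population counts.
#' @return A data frame of class `age_incidence_series` with columns
#'   `age_group`, `midpoint`, `crude_rate` (and `population` if supplied),
#'   sorted by midpoint, carrying the cancer label as attribute
#'   `cancer_label`.
#' @examples
#' age_incidence_series(c("< 1 year", "1-4 years", "5-9 years"), c(2.1, 1.0, 0.4))
#' @export
age_incidence_series <- function(age_group = NULL, crude_rate, cancer_label = "unknown",
                                 midpoint = NULL, population = NULL) {
  if (is.null(midpoint)) {
    if (is.null(age_group)) stop("either 'age_group' or 'midpoint' is required")
    midpoint <- parse_age_group_label(age_group)
  }
  if (is.null(age_group)) age_group <- sprintf("[midpoint %.1f]", midpoint)
  n <- length(midpoint)
  if (length(crude_rate) != n || length(age_group) != n) {
    stop("age_group, midpoint and crude_rate must have equal lengths")
  }
  if (n < 3) stop("an incidence series needs at least 3 bins to constrain a 3-parameter fit")
  if (any(!is.finite(midpoint)) || any(midpoint <= 0)) {
    stop("all bin midpoints must be finite and > 0")
  }
  if (any(!is.finite(crude_rate)) || any(crude_rate < 0)) {
    stop("crude rates must be finite and >= 0")
  }
  df <- data.frame(age_group = as.character(age_group), midpoint = midpoint,
                   crude_rate = crude_rate, stringsAsFactors = FALSE)
  if (!is.null(population)) {
    if (length(population) != n || any(population <= 0)) {
      stop("population must be positive, one value per bin")
    }
    df$population <- population
  }
  df <- df[order(df$midpoint), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df$midpoint)) stop("bin midpoints must be strictly increasing")
  structure(df, cancer_label = as.character(cancer_label),
            class = c("age_incidence_series", "data.frame"))
}

#' @export
print.age_incidence_series <- function(x, ...) {
  cat(sprintf("Age-incidence series: %s (%d bins, ages %.1f-%.1f years)\n",
              attr(x, "cancer_label"), nrow(x), min(x$midpoint), max(x$midpoint)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a CDC WONDER-style incidence export
#'
#' Parses a tab-separated export with a header row into an
#' [age_incidence_series()]. Rows whose rate cell is not numeric (CDC marks
#' these `"Suppressed"` or `"Unreliable"`, and blank cells occur) are
#' dropped, as are open-ended age bins such as `"85+ years"`; the number of
#' dropped rows is reported with a message. Remaining rows are sorted by bin
#' midpoint regardless of input order.
#'
#' @param source Path to a file, a connection, or a character vector of
#'   lines (text with embedded newlines also works).
#' @param age_col,rate_col Column names in the header (CDC WONDER defaults).
#' @param cancer_label Label attached to the resulting series.
#' @return An [age_incidence_series()].
#' @export
read_incidence_table <- function(source, age_col = "Age Groups",
                                 rate_col = "Crude Rate",
                                 cancer_label = "unknown") {
  if (is.character(source) && length(source) == 1 && grepl("\n", source)) {
    source <- textConnection(source)
    on.exit(close(source), add = TRUE)
  } else if (is.character(source) && length(source) > 1) {
    source <- textConnection(paste(source, collapse = "\n"))
    on.exit(close(source), add = TRUE)
  }
  df <- utils::read.delim(source, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(c(age_col, rate_col), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("input is missing required column(s): %s",
                 paste(sQuote(missing_cols), collapse = ", ")), call. = FALSE)
  }
  labels <- df[[age_col]]
  rates <- suppressWarnings(as.numeric(df[[rate_col]]))
  usable <- is.finite(rates)
  midpoints <- rep(NA_real_, nrow(df))
  for (i in which(usable)) {
    # open-ended bins ("85+ years") are dropped; truly malformed labels error
    midpoints[i] <- tryCatch(parse_one_label(labels[i]), error = function(e) {
      if (grepl("open-ended", conditionMessage(e))) NA_real_ else stop(e)
    })
  }
  usable <- usable & is.finite(midpoints)
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    message(sprintf("read_incidence_table: dropped %d row(s) (suppressed rates or open-ended bins)",
                    n_dropped))
  }
  if (!any(usable)) stop("no usable incidence rows in input", call. = FALSE)
  age_incidence_series(age_group = labels[usable], crude_rate = rates[usable],
                       midpoint = midpoints[usable], cancer_label = cancer_label)
}

#' Tabulate and write a fit report
#'
#' `fit_report_table()` assembles one row per fitted cancer x family:
#' parameter estimates rounded to 2 decimals (as conventionally printed for
#' these fits), amplitude, amplitude/1000, R-squared to 4 decimals, the
#' probability mass below age zero at the optimum and the negative-mass
#' flag. `write_fit_report()` writes it as a tab-separated file with a
#' deterministic column order, sorted by (cancer, family).
#'
#' @param fits A list of [fit_distribution()] results (class `grid_fit`).
#' @param path Output file path.
#' @return `fit_report_table()`: a data frame. `write_fit_report()`: the
#'   path, invisibly.
#' @export
fit_report_table <- function(fits) {
  if (inherits(fits, "grid_fit")) fits <- list(fits)
  if (length(fits) == 0) stop("no fit results to report", call. = FALSE)
  rows <- lapply(fits, function(fit) {
    stopifnot(inherits(fit, "grid_fit"))
    data.frame(
      cancer = fit$cancer_label,
      family = fit$family$family,
      param1_name = fit$family$param_names[1],
      param1 = as.character(round(fit$best_params[[1]], 2)),
      b = as.character(round(fit$best_params[[2]], 2)),
      amplitude = as.character(round(fit$amplitude, 2)),
      amplitude_per_1000 = as.character(signif(fit$amplitude / 1000, 3)),
      r_squared = sprintf("%.4f", fit$r_squared),
      mass_below_zero = sprintf("%.4f", fit$mass_below_zero),
      flagged = fit$mass_below_zero > 0.05,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cancer, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname fit_report_table
#' @export
write_fit_report <- function(fits, path) {
  tab <- fit_report_table(fits)
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) {
    stop(sprintf("failed to write fit report to '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}
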