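# Shared fixtures: synthetic series and small grids used across test files.

make_noiseless_series <- function(family = "erlang_gamma", first = 1.75,
                                  second = 2.2, amplitude = 124,
                                  label = NULL) {
  cfg <- synthetic_config(family = family, first = first, second = second,
                          amplitude = amplitude, cancer_label = label)
  generate_incidence(cfg)$series
}

# A small lattice around given true values, always containing them.
small_grid_around <- function(first, second, step = 0.25, span = 5) {
  grid_spec(first + step * seq(-span, span), second + step * seq(-span, span))
}

# Closed-form least-squares amplitude for fixed density values f at the bins:
# maximising R^2 over A alone minimises sum((y - A f)^2), whose minimiser is
# A* = sum(y f) / sum(f^2). Independent oracle for the golden-section search.
closed_form_amplitude <- function(y, f) sum(y * f) / sum(f * f)

reduced_grids_all <- function() {
  stats::setNames(lapply(erlangfit:::DIST_FAMILIES, reduced_grid),
                  erlangfit:::DIST_FAMILIES)
}

toy_tsv <- function(rows, header = "Age Groups\tCrude Rate") {
  paste(c(header, rows), collapse = "\n")
}
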