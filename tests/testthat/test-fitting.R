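test_that("R-squared follows the coefficient-of-determination convention", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)   # SS_res = 1, SS_tot = 2
  expect_lt(r_squared(y, c(10, 10, 10)), 0)     # worse than the mean
  expect_error(r_squared(y, c(1, 2)), "equal length")
  expect_error(r_squared(c(2, 2, 2), y), "identical")
})

test_that("area estimate is the plain sum of rates and rejects degenerate data", {
  expect_equal(area_estimate(c(1, 2, 3)), 6)
  expect_equal(area_estimate(5), 5)
  expect_error(area_estimate(c(0, 0, 0)), "zero")
  s <- make_noiseless_series()
  expect_equal(area_estimate(s), sum(s$crude_rate))
})

test_that("golden-section search finds interior and boundary maxima", {
  f <- function(a) -(a - 3)^2
  expect_equal(golden_section_max(f, 0, 10, 1e-8), 3, tolerance = 1e-6)
  expect_equal(golden_section_max(f, 5, 10, 1e-8), 5, tolerance = 1e-6)
  expect_equal(golden_section_max(f, -10, 1, 1e-8), 1, tolerance = 1e-6)
  expect_error(suppressWarnings(golden_section_max(function(a) log(a), -1, 1)),
               "not finite")
  expect_error(golden_section_max(f, 2, 2), "lower < upper")
  # deterministic for fixed inputs
  expect_identical(golden_section_max(f, 0, 10), golden_section_max(f, 0, 10))
})

test_that("golden-section amplitudes match the closed-form least-squares oracle", {
  s <- make_noiseless_series(first = 1.75, second = 2.2, amplitude = 124)
  g <- grid_spec(seq(0.5, 5, by = 0.5), seq(0.5, 5, by = 0.5))
  fit <- fit_distribution(s, "erlang_gamma", grid = g)
  y <- s$crude_rate
  for (i in seq_along(g$first_param_values)) {
    for (j in seq_along(g$second_param_values)) {
      f <- dist_pdf("erlang_gamma", g$first_param_values[i], g$second_param_values[j],
                    s$midpoint)
      a_star <- closed_form_amplitude(y, f)
      inside <- a_star > fit$bracket[1] * (1 + 1e-6) && a_star < fit$bracket[2] * (1 - 1e-6)
      if (inside) {
        expect_equal(fit$amplitude_landscape[i, j], a_star, tolerance = 1e-4,
                     label = sprintf("amplitude at node (%g, %g)",
                                     g$first_param_values[i], g$second_param_values[j]))
      }
    }
  }
})

test_that("noiseless on-grid data is recovered at the true node with R^2 = 1", {
  s <- make_noiseless_series(first = 1.75, second = 2.2, amplitude = 124)
  fit <- fit_distribution(s, "erlang_gamma", grid = small_grid_around(1.75, 2.2))
  expect_equal(unname(fit$best_params), c(1.75, 2.2))
  expect_equal(fit$amplitude, 124, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("fit results are internally consistent and deterministic", {
  s <- make_noiseless_series(first = 2, second = 3, amplitude = 179)
  g <- grid_spec(seq(1, 4, by = 0.5), seq(1, 5, by = 0.5))
  fit <- fit_distribution(s, "erlang_gamma", grid = g)
  expect_equal(fit$r_squared, max(fit$landscape))
  expect_true(fit$best_params[["k"]] %in% g$first_param_values)
  expect_true(fit$best_params[["b"]] %in% g$second_param_values)
  expect_gte(fit$amplitude, fit$bracket[1])
  expect_lte(fit$amplitude, fit$bracket[2])
  expect_equal(dim(fit$landscape), c(7, 9))
  fit2 <- fit_distribution(s, "erlang_gamma", grid = g)
  expect_identical(fit$landscape, fit2$landscape)
  expect_identical(fit$best_params, fit2$best_params)
})

test_that("a mismatched family fits strictly worse than the generating family", {
  s <- make_noiseless_series(first = 1.8, second = 2.2, amplitude = 124)
  ge <- reduced_grid("erlang_gamma")
  fit_e <- fit_distribution(s, "erlang_gamma", grid = ge)
  fit_w <- fit_distribution(s, "weibull", grid = ge)
  expect_equal(fit_e$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit_w$r_squared, fit_e$r_squared)
})

test_that("halving the grid step never decreases the best R^2", {
  s <- make_noiseless_series(first = 1.75, second = 2.2, amplitude = 124)
  coarse <- grid_spec(seq(0.4, 6, by = 0.4), seq(0.4, 6, by = 0.4))
  fine <- grid_spec(seq(0.2, 6, by = 0.2), seq(0.2, 6, by = 0.2))  # superset lattice
  r_coarse <- fit_distribution(s, "erlang_gamma", grid = coarse)$r_squared
  r_fine <- fit_distribution(s, "erlang_gamma", grid = fine)$r_squared
  expect_gte(r_fine, r_coarse)
})

test_that("configuration errors are caught before any fitting happens", {
  s <- make_noiseless_series()
  mu_grid <- grid_spec(seq(-2, 2, by = 1), seq(0.5, 2, by = 0.5))
  expect_error(fit_distribution(s, "erlang_gamma", grid = mu_grid), "non-positive shape")
  expect_error(grid_spec(c(2, 1), c(1, 2)), "strictly increasing")
  expect_error(grid_spec(numeric(0), c(1, 2)), "nonempty")
  expect_error(grid_spec(c(1, 2), c(-1, 1)), "positive")
  expect_error(fit_distribution(s, "erlang_gamma", grid = list(1, 2)), "grid_spec")
  flat <- age_incidence_series(c("< 1 year", "1-4 years", "5-9 years"), rep(2, 3))
  expect_error(fit_distribution(flat, "erlang_gamma", grid = small_grid_around(2, 2)),
               "identical")
})

test_that("family comparison ranks by R^2 and flags negative-age mass", {
  s <- make_noiseless_series(first = 2, second = 3, amplitude = 124)
  cmp <- compare_families(s, families = c("erlang_gamma", "normal"),
                          grids = reduced_grids_all())
  expect_s3_class(cmp, "family_comparison")
  expect_equal(cmp$table$family[1], "erlang_gamma")
  expect_true(all(diff(cmp$table$r_squared) <= 0))
  expect_false(cmp$table$flagged[cmp$table$family == "erlang_gamma"])
  single <- compare_families(s, families = "erlang_gamma", grids = reduced_grids_all())
  expect_length(single$fits, 1)
  expect_false(single$table$flagged)
  expect_error(compare_families(s, families = character(0)), "at least one")
})

test_that("landscape TSV export round-trips through read", {
  s <- make_noiseless_series()
  fit <- fit_distribution(s, "erlang_gamma", grid = small_grid_around(1.75, 2.2))
  path <- tempfile(fileext = ".tsv")
  write_landscape_tsv(fit, path)
  back <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(fit$landscape), tolerance = 1e-6)
})
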