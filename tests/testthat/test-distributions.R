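test_that("family specs carry the right parameterisation and support", {
  for (fam in c("erlang_gamma", "weibull")) {
    spec <- dist_spec(fam)
    expect_identical(spec$param_names, c("k", "b"))
    expect_identical(spec$support_lower_bound, 0)
  }
  for (fam in c("extreme_value", "logistic", "normal")) {
    spec <- dist_spec(fam)
    expect_identical(spec$param_names, c("mu", "b"))
    expect_identical(spec$support_lower_bound, -Inf)
  }
  expect_error(dist_spec("cauchy"))
})

test_that("densities match their closed forms at hand-checked points", {
  expect_equal(dist_pdf("erlang_gamma", 1, 2, 0), 0.5)          # exponential f(0) = 1/b
  expect_equal(dist_pdf("erlang_gamma", 2, 1, 1), exp(-1))      # t * exp(-t) at t = 1
  expect_equal(dist_pdf("weibull", 1, 3, 0), 1 / 3)
  expect_equal(dist_pdf("normal", 0, 1, 0), 1 / sqrt(2 * pi))
  expect_equal(dist_pdf("logistic", 5, 2, 5), 1 / 8)            # 1 / (4b) at the mode
})

test_that("densities agree with reference implementations on random draws", {
  set.seed(101)
  t <- c(0.5, 1, 2.5, 7.5, 12.5, 20, 37.5)
  for (i in 1:25) {
    k <- runif(1, 0.3, 15); b <- runif(1, 0.2, 18); mu <- runif(1, -15, 15)
    expect_equal(dist_pdf("erlang_gamma", k, b, t),
                 dgamma(t, shape = k, scale = b), tolerance = 1e-12)
    expect_equal(dist_pdf("weibull", k, b, t),
                 dweibull(t, shape = k, scale = b), tolerance = 1e-12)
    expect_equal(dist_pdf("normal", mu, b, t),
                 dnorm(t, mean = mu, sd = b), tolerance = 1e-12)
    expect_equal(dist_pdf("logistic", mu, b, t),
                 dlogis(t, location = mu, scale = b), tolerance = 1e-12)
    # Gumbel(max) via change of variables: exp(-(T - mu)/b) ~ Exp(1), so
    # f_T(t) = dexp(exp(-z)) * exp(-z) / b with z = (t - mu)/b.
    z <- (t - mu) / b
    expect_equal(dist_pdf("extreme_value", mu, b, t),
                 dexp(exp(-z)) * exp(-z) / b, tolerance = 1e-12)
  }
})

test_that("support edges behave: negative ages, t = 0, unbounded densities", {
  expect_equal(dist_pdf("erlang_gamma", 2, 1, c(-3, -0.1)), c(0, 0))
  expect_equal(dist_pdf("weibull", 0.7, 1, -1), 0)
  expect_equal(dist_pdf("erlang_gamma", 1, 4, 0), 0.25)  # k = 1 limit is 1/b
  expect_equal(dist_pdf("erlang_gamma", 3, 4, 0), 0)     # k > 1 limit is 0
  expect_error(dist_pdf("erlang_gamma", 0.5, 1, 0), "unbounded")
  expect_error(dist_pdf("weibull", 0.5, 1, 0), "unbounded")
  expect_gt(dist_pdf("normal", 0, 1, -1), 0)             # location families span negatives
})

test_that("invalid parameters are rejected", {
  expect_error(dist_pdf("erlang_gamma", 2, 0, 1), "positive")
  expect_error(dist_pdf("erlang_gamma", 2, -1, 1), "positive")
  expect_error(dist_pdf("erlang_gamma", -2, 1, 1), "shape")
  expect_error(dist_pdf("weibull", 0, 1, 1), "shape")
  expect_error(dist_pdf("normal", 0, 0, 1), "positive")
  expect_error(mass_below_zero("logistic", 0, -1), "positive")
})

test_that("every density integrates to 1 over its support", {
  set.seed(202)
  for (fam in c("erlang_gamma", "weibull", "extreme_value", "logistic", "normal")) {
    spec <- dist_spec(fam)
    for (i in 1:5) {
      first <- if (fam %in% c("erlang_gamma", "weibull")) runif(1, 0.4, 12)
               else runif(1, -10, 10)
      second <- runif(1, 0.3, 12)
      lower <- if (is.finite(spec$support_lower_bound)) 0 else -Inf
      total <- integrate(function(tt) dist_pdf(spec, first, second, tt),
                         lower = lower, upper = Inf, rel.tol = 1e-9)$value
      expect_equal(total, 1, tolerance = 1e-6,
                   label = sprintf("integral of %s(%g, %g)", fam, first, second))
    }
  }
})

test_that("shape k = 1 reduces both waiting-time families to the exponential", {
  t <- seq(0, 50, by = 0.25)
  for (b in c(0.3, 1, 2.5, 14)) {
    expo <- exp(-t / b) / b
    expect_equal(dist_pdf("erlang_gamma", 1, b, t), expo, tolerance = 1e-12)
    expect_equal(dist_pdf("weibull", 1, b, t), expo, tolerance = 1e-12)
  }
})

test_that("mass below zero: exact values, zero on t >= 0 support, monotone in mu", {
  expect_equal(mass_below_zero("erlang_gamma", 3.7, 2.1), 0)
  expect_equal(mass_below_zero("weibull", 0.4, 9), 0)
  expect_equal(mass_below_zero("normal", 0, 1), 0.5)
  expect_equal(mass_below_zero("extreme_value", 0, 1), exp(-1))
  expect_equal(mass_below_zero("logistic", 0, 1), 0.5)
  # cross-check against quadrature of the density over the negative axis
  for (fam in c("extreme_value", "logistic", "normal")) {
    q <- integrate(function(tt) dist_pdf(fam, 1.5, 2, tt), -Inf, 0, rel.tol = 1e-10)$value
    expect_equal(mass_below_zero(fam, 1.5, 2), q, tolerance = 1e-8)
  }
  mus <- seq(-10, 10, by = 0.5)
  for (fam in c("extreme_value", "logistic", "normal")) {
    m <- mass_below_zero(fam, mus, 2.5)
    expect_true(all(diff(m) < 0),
                label = sprintf("%s below-zero mass decreasing in mu", fam))
  }
})
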