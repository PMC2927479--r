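test_that("constructor validates and canonicalizes components", {
  m <- mixture_model(c(.5, .5), c(4000, 2000), c(300, 200))
  expect_equal(m$mean, c(2000, 4000))            # ascending-mean order
  expect_equal(m$sd, c(200, 300))                # sds follow their components
  expect_equal(sum(m$weight), 1)

  expect_error(mixture_model(c(.6, .5), c(1, 2), c(1, 1)), "sum to 1")
  expect_error(mixture_model(c(.5, .5), c(1, 2), c(1, 0)), "positive")
  expect_error(mixture_model(c(-0.2, 1.2), c(1, 2), c(1, 1)), "\\(0, 1\\]")
  expect_error(mixture_model(1, NaN, 1), "finite")

  # rounded published weights are accepted only under renormalize
  expect_error(mixture_model(c(.007, .182, .758, .052), c(1, 2, 3, 4), rep(1, 4)))
  m4 <- mixture_model(c(.007, .182, .758, .052), c(1, 2, 3, 4), rep(1, 4),
                      renormalize = TRUE)
  expect_equal(sum(m4$weight), 1, tolerance = 1e-12)
})

test_that("density matches closed forms and direct summation", {
  single <- mixture_model(1, 3000, 400)
  expect_equal(dmix(single, 3000), 1 / (400 * sqrt(2 * pi)), tolerance = 1e-12)

  # four-component design: direct sum of the normal terms
  mc <- design_c_model()
  direct <- sum(mc$weight * dnorm(3170, mc$mean, mc$sd))
  expect_equal(dmix(mc, 3170), direct, tolerance = 1e-12)

  x <- seq(0, 6000, by = 250)
  expect_true(all(dmix(mc, x) >= 0))
  expect_equal(dmix(mc, x, log = TRUE), log(dmix(mc, x)), tolerance = 1e-10)
})

test_that("every catalog density integrates to one", {
  for (d in design_catalog()) {
    total <- stats::integrate(function(x) dmix(d$model, x), -Inf, Inf,
                              rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("log-likelihood matches the naive oracle and is additive", {
  mc <- design_c_model()
  x <- simulate_birthweights(mc, 100, seed = 42)$birthweight
  expect_equal(loglik_mix(mc, x), naive_loglik(mc, x), tolerance = 1e-10)

  expect_equal(loglik_mix(mixture_model(1, 0, 1), 0), -log(sqrt(2 * pi)),
               tolerance = 1e-12)

  # duplicating every observation doubles the log-likelihood exactly
  expect_equal(loglik_mix(mc, c(x, x)), 2 * loglik_mix(mc, x), tolerance = 1e-9)

  expect_error(loglik_mix(mc, numeric(0)), "empty")
})

test_that("log-sum-exp evaluation keeps extreme tails finite", {
  mc <- design_c_model()
  expect_true(is.finite(loglik_mix(mc, c(500, 5500, 10000))))
  expect_true(dmix(mc, 10000, log = TRUE) < -50)
})

test_that("truncated sampling respects the window and the seed", {
  mc <- design_c_model()
  s1 <- simulate_birthweights(mc, 1000, seed = 7)
  expect_equal(nrow(s1), 1000)
  expect_gte(min(s1$birthweight), 500)
  expect_lte(max(s1$birthweight), 5500)

  s2 <- simulate_birthweights(mc, 1000, seed = 7)
  expect_identical(s1, s2)

  s3 <- simulate_birthweights(mc, 1000, seed = 8)
  expect_false(identical(s1, s3))

  # a window the mixture cannot reach
  far <- mixture_model(1, 3000, 10)
  expect_error(simulate_birthweights(far, 10, trunc_window(5000, 5500)),
               "no mass")
})

test_that("truncated sample mean agrees with the quadrature oracle", {
  mc <- design_c_model()
  n <- 50000
  s <- simulate_birthweights(mc, n, seed = 99)$birthweight
  mu_trunc <- truncated_mean(mc)
  se <- sd(s) / sqrt(n)
  expect_lt(abs(mean(s) - mu_trunc), 3 * se)
})

test_that("truncated empirical CDF converges to the analytic truncated CDF", {
  mc <- design_c_model()
  s <- simulate_birthweights(mc, 10000, seed = 123)$birthweight
  grid <- seq(500, 5500, by = 5)
  emp <- stats::ecdf(s)(grid)
  ks <- max(abs(emp - pmix_trunc(mc, grid)))
  expect_lt(ks, 0.02)
})

test_that("finite populations are reproducible and validated", {
  mc <- design_c_model()
  p1 <- simulate_population(mc, 5000, seed = 5)
  p2 <- simulate_population(mc, 5000, seed = 5)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 5000)
  expect_true(all(p1$birthweight >= 500 & p1$birthweight <= 5500))
  expect_error(simulate_population(mc, 0), "at least 1")
})

test_that("models round-trip through the text format", {
  mc <- design_c_model()
  path <- tempfile(fileext = ".txt")
  write_mixture(mc, path)
  back <- read_mixture(path)
  expect_equal(back$weight, mc$weight, tolerance = 1e-12)
  expect_equal(back$mean, mc$mean, tolerance = 1e-12)
  expect_equal(back$sd, mc$sd, tolerance = 1e-12)
})

test_that("window helpers behave", {
  expect_error(trunc_window(5500, 500), "strictly less")
  w <- trunc_window()
  expect_equal(unname(w[["lower"]]), 500)
  mc <- design_c_model()
  expect_equal(pmix_trunc(mc, 500), 0)
  expect_equal(pmix_trunc(mc, 5500), 1)
  expect_equal(dmix_trunc(mc, 400), 0)
})
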