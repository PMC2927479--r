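test_that("criterion arithmetic is exact", {
  expect_equal(aic_mix(0, 1), 4)
  expect_equal(aic_mix(0, 4), 2 * 11)   # m = 4 has 3m - 1 = 11 free parameters
  # equal logliks: one extra component costs exactly 6 AIC units
  expect_equal(aic_mix(-100, 3) - aic_mix(-100, 2), 6)

  expect_equal(bic_mix(-1000, 2, 5000), 2000 + log(5000) * 5, tolerance = 1e-10)
  # analytic crossover: BIC = AIC exactly when log(n) = 2
  expect_equal(bic_mix(-50, 3, exp(2)), aic_mix(-50, 3), tolerance = 1e-10)
  expect_error(bic_mix(0, 1, 1), "at least 2")

  # penalty dominance for n > e^2
  expect_true(bic_mix(-10, 2, 100) > aic_mix(-10, 2))
})

test_that("flexible criterion recovers BIC and AIC in its limits", {
  ll <- -1234.5
  expect_equal(flic_mix(ll, 3, 5000, delta = .8, B = function(...) 1),
               bic_mix(ll, 3, 5000), tolerance = 1e-12)
  expect_equal(flic_mix(ll, 3, 5000, delta = .8, B = function(...) 0),
               aic_mix(ll, 3), tolerance = 1e-12)
  expect_error(flic_mix(ll, 3, 5000, delta = 0), "\\(0, 1\\]")
  expect_error(flic_mix(ll, 3, 5000, delta = 1.2), "\\(0, 1\\]")

  # default weight: AIC-like for small n, BIC-like for large n
  expect_equal(flic_weight(100, .8), 0)
  expect_gt(flic_weight(5000, .8), 0.9)
  expect_lt(flic_weight(200, .95), 0.5)
  expect_true(all(diff(flic_weight(c(100, 500, 2000, 10000, 1e5), .85)) >= 0))
})

test_that("delta statistic follows the variance decomposition", {
  x <- c(2900, 3000, 3100, 3300, 2800, 3250, 3050, 2950, 3150, 3400, 2700, 3010)
  f1 <- fit_mixture(x, 1)
  expect_equal(delta_statistic(list(f1)), 1)   # no between-component variance

  # hand-computed within/total fractions from published design parameters
  a <- design_a_model()
  w_a <- sum(a$weight * a$sd^2)
  mu_bar <- sum(a$weight * a$mean)
  t_a <- w_a + sum(a$weight * (a$mean - mu_bar)^2)
  expected <- mean(c(1, w_a / t_a))
  expect_equal(delta_statistic(list(f1$model, a)), expected, tolerance = 1e-12)

  d <- delta_statistic(design_catalog() |> lapply(function(d) d$model))
  expect_true(d > 0 && d <= 1)

  degenerate <- mixture_model(1, 3000, 1e-12)
  expect_error(suppressWarnings(delta_statistic(list(degenerate))))
})

test_that("order selection picks the argmin with ties to smaller m", {
  fake_fit <- function(m, loglik, n = 5000) {
    structure(list(model = mixture_model(rep(1 / m, m), seq(2500, by = 300, length.out = m),
                                         rep(400, m)),
                   loglik = loglik, m = m, n = n, n_iterations = 1L,
                   converged = TRUE, refinement_gain = 0),
              class = "mixture_fit")
  }
  # logliks crafted so BIC bottoms out at m = 3
  lls <- c(-21000, -20500, -20400, -20395, -20392)
  fits <- Map(fake_fit, 1:5, lls)
  sel <- select_order(fits)
  expect_equal(unname(sel$selected[["BIC"]]), 3)
  expect_equal(unname(sel$selected[["AIC"]]), which.min(aic_mix(lls, 1:5)))

  # exact criterion tie between m = 2 and m = 4 resolves to m = 2
  n <- 5000
  ll2 <- -20500
  ll4 <- ll2 - (aic_mix(ll2, 4) - aic_mix(ll2, 2)) / -2
  fits_tie <- Map(fake_fit, 1:4, c(-30000, ll2, -25000, ll4))
  sel_tie <- select_order(fits_tie, criteria = "AIC")
  expect_equal(aic_mix(fits_tie[[2]]$loglik, 2), aic_mix(fits_tie[[4]]$loglik, 4))
  expect_equal(unname(sel_tie$selected[["AIC"]]), 2)

  expect_error(select_order(list()), "at least one")

  single <- select_order(list(fake_fit(1, -100)))
  expect_true(all(single$selected == 1))
})

test_that("criteria increase in m at fixed loglik and BIC never exceeds AIC order", {
  ll <- -15000
  n <- 20000
  for (crit in list(function(m) aic_mix(ll, m),
                    function(m) bic_mix(ll, m, n),
                    function(m) flic_mix(ll, m, n, delta = .8))) {
    vals <- vapply(1:7, crit, numeric(1))
    expect_true(all(diff(vals) > 0))
  }

  # on fitted data: BIC-selected order <= AIC-selected order (n > e^2)
  x <- simulate_birthweights(design_a_model(), 3000, seed = 21)
  fits <- fit_mixture_orders(x, M = 4, strategy = init_strategy(seed = 3))
  sel <- select_order(fits)
  expect_lte(sel$selected[["BIC"]], sel$selected[["AIC"]])
})

test_that("selection table carries flags and the delta used", {
  x <- simulate_birthweights(design_a_model(), 1500, seed = 5)
  fits <- fit_mixture_orders(x, M = 3, strategy = init_strategy(seed = 6))
  sel <- select_order(fits)
  tab <- tidy(sel)
  expect_named(tab, c("m", "loglik", "n_par", "AIC", "BIC", "FLIC",
                      "selected_AIC", "selected_BIC", "selected_FLIC"))
  expect_equal(sum(tab$selected_BIC), 1)
  expect_equal(tab$m[tab$selected_BIC], unname(sel$selected[["BIC"]]))
  expect_true(sel$delta > 0 && sel$delta <= 1)
})
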