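test_that("meta-samples are without replacement within, overlapping across", {
  pop <- simulate_population(design_c_model(), 2000, seed = 1)
  samples <- draw_meta_samples(pop, n_rep = 25, sample_size = 500, seed = 2)
  expect_equal(nrow(samples), 25 * 500)

  # distinct values within each sample (continuous draws collide only by reuse)
  per_sample_dupes <- tapply(samples$birthweight, samples$sample,
                             function(v) anyDuplicated(v) > 0)
  expect_false(any(per_sample_dupes))

  # the same individual recurs across samples with 25 draws of a quarter each
  expect_gt(anyDuplicated(samples$birthweight), 0)

  # sample_size = population size makes every sample a permutation
  perm <- draw_meta_samples(pop, n_rep = 3, sample_size = 2000, seed = 3)
  for (i in 1:3) {
    expect_equal(sort(perm$birthweight[perm$sample == i]), sort(pop$birthweight))
  }

  expect_error(draw_meta_samples(pop, 2, 2001), "cannot exceed")

  again <- draw_meta_samples(pop, n_rep = 25, sample_size = 500, seed = 2)
  expect_identical(samples, again)
})

test_that("combining estimates gives meta-sample means and SDs", {
  est <- tibble::tibble(sample = 1:2, p_1 = c(1, 3), mu_1 = c(5, 5), sigma_1 = c(2, 4))
  comb <- combine_estimates(est)
  expect_equal(comb$theta_bar, c(2, 5, 3))
  expect_equal(comb$s_theta, c(sqrt(2), 0, sqrt(2)))

  # spreadsheet-style oracle on a 5 x 3 matrix
  m <- matrix(c(1, 4, 2, 8, 5,
                10, 10, 10, 10, 10,
                -1, 0, 1, 2, 3), ncol = 3)
  est5 <- tibble::as_tibble(as.data.frame(m)) |> setNames(c("p_1", "mu_1", "sigma_1"))
  comb5 <- combine_estimates(est5)
  expect_equal(comb5$theta_bar, colMeans(m))
  expect_equal(comb5$s_theta, apply(m, 2, sd))   # n - 1 denominator

  expect_error(combine_estimates(est[1, ]), "least two")
})

test_that("meta-sample fits align components and recover design C", {
  mc <- design_c_model()
  samples <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(sample = i,
                   birthweight = simulate_birthweights(mc, 8000, seed = 30 + i)$birthweight)
  }))
  est <- fit_meta_samples(samples, k = 4, strategy = init_strategy(n_restarts = 4, seed = 9))
  expect_equal(nrow(est), 3)
  expect_named(est, c("sample", paste0("p_", 1:4), paste0("mu_", 1:4), paste0("sigma_", 1:4)))
  # canonical order within each row
  expect_true(all(est$mu_1 < est$mu_2 & est$mu_2 < est$mu_3 & est$mu_3 < est$mu_4))
  # third component sits near its generating mean
  expect_lt(abs(mean(est$mu_3) - 3170), 60)

  # identical samples give identical rows
  same <- dplyr::bind_rows(
    tibble::tibble(sample = 1, birthweight = samples$birthweight[samples$sample == 1]),
    tibble::tibble(sample = 2, birthweight = samples$birthweight[samples$sample == 1]))
  est_same <- fit_meta_samples(same, k = 4, strategy = init_strategy(n_restarts = 2, seed = 4))
  expect_equal(unlist(est_same[1, -1]), unlist(est_same[2, -1]), tolerance = 1e-8)
})

test_that("interval arithmetic and nesting", {
  ci <- ci_unadjusted(2, sqrt(2), 2.5)
  expect_equal(ci$lower, 2 - 2.5 * sqrt(2))
  expect_equal(ci$upper, 2 + 2.5 * sqrt(2))

  degenerate <- ci_unadjusted(5, 0, 3)
  expect_equal(degenerate$lower, 5)
  expect_equal(degenerate$upper, 5)

  # width is linear in C
  w1 <- with(ci_unadjusted(0, 1.3, 1), upper - lower)
  w3 <- with(ci_unadjusted(0, 1.3, 3), upper - lower)
  expect_equal(w3, 3 * w1)

  # zero bias reduces the adjusted interval to the plain one
  expect_equal(ci_bias_adjusted(2, sqrt(2), 0, 2.5), ci)

  # the bias-adjusted interval always contains the unadjusted one
  tb <- c(.758, 3170, 417)
  st <- c(.037, 7, 10)
  bh <- c(.032, 9, 7)
  a <- ci_bias_adjusted(tb, st, bh, 2.5)
  u <- ci_unadjusted(tb, st, 2.5)
  expect_true(all(a$lower <= u$lower & a$upper >= u$upper))
  expect_error(ci_bias_adjusted(0, 1, -0.1, 2), "nonnegative")

  # published-scale consistency probe: p_3 row magnitudes
  p3 <- ci_bias_adjusted(.758, .037, .032, 2.5)
  expect_lt(abs(p3$lower - .681), 0.06)
  expect_lt(abs(p3$upper - .836), 0.06)
})

test_that("overlap correction matches its closed form and limits", {
  expect_identical(overlap_adjusted_c(2.5, 0, 25), 2.5)   # no overlap, exact
  expect_equal(overlap_adjusted_c(1, .05, 25), 1.315, tolerance = 5e-4)
  expect_equal(overlap_adjusted_c(2.5, .05, 25), 2.5 * sqrt(25 * .05 / (1 - .95^25)),
               tolerance = 1e-12)
  # strictly increasing in phi
  expect_gt(overlap_adjusted_c(2.5, .2465, 25), overlap_adjusted_c(2.5, .05, 25))
  phis <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(overlap_adjusted_c(1, phis, 25)) > 0))
  expect_error(overlap_adjusted_c(2.5, 1, 25), "\\[0, 1\\)")
  expect_error(overlap_adjusted_c(2.5, -0.1, 25), "\\[0, 1\\)")
})

test_that("bias estimates are nonnegative and shrink with sample size", {
  single <- mixture_model(1, 3100, 450)
  b_small <- estimate_bias(single, 500, n_bias_sims = 5, seed = 11)
  expect_true(all(b_small$bias_hat >= 0))
  b_big <- estimate_bias(single, 200000, n_bias_sims = 5, seed = 11)
  # k = 1: the mean's drift is ~ sd/sqrt(n), so it collapses at large n
  mu_small <- b_small$bias_hat[b_small$parameter == "mu_1"]
  mu_big <- b_big$bias_hat[b_big$parameter == "mu_1"]
  expect_lt(mu_big, mu_small)
  expect_lt(mu_big, 5)
})

test_that("the full meta pipeline produces a Table-2 style report", {
  mc <- design_c_model()
  samples <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(sample = i,
                   birthweight = simulate_birthweights(mc, 6000, seed = 50 + i)$birthweight)
  }))
  res <- meta_ci(samples, k = 4, c0 = 2.5, seed = 77,
                 strategy = init_strategy(n_restarts = 4, seed = 78))
  expect_s3_class(res, "meta_estimate")
  expect_equal(nrow(res), 12)
  expect_named(res, c("parameter", "theta_bar", "s_theta", "bias_hat", "lower", "upper"))
  expect_true(all(res$bias_hat >= 0))
  expect_true(all(res$lower <= res$theta_bar & res$theta_bar <= res$upper))
  expect_equal(attr(res, "c_mult"), 2.5)
})
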