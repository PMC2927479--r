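#' Draw overlapping meta-samples from a finite population
#'
#' Draws `n_rep` samples of `sample_size` from a finite population. Each
#' sample is drawn *without* replacement within itself, but samples are drawn
#' independently of one another, so an individual can appear in several
#' samples while never appearing twice in the same sample. When the samples
#' constitute a non-negligible fraction of the population, the resulting
#' parameter estimates are positively dependent — the reason for the overlap
#' correction in [overlap_adjusted_c()].
#'
#' @param population A data frame with a `birthweight` column (e.g. from
#'   [simulate_population()]) or a numeric vector.
#' @param n_rep Number of samples to draw.
#' @param sample_size Size of each sample; must not exceed the population
#'   size.
#' @param seed Optional integer seed.
#' @return A tibble with columns `sample` (1..n_rep) and `birthweight`.
#' @export
draw_meta_samples <- function(population, n_rep, sample_size, seed = NULL) {
  x <- pull_birthweights(population)
  n_pop <- length(x)
  if (n_rep < 1L) abort("`n_rep` must be at least 1.")
  if (sample_size > n_pop) {
    abort("`sample_size` cannot exceed the population size (samples are drawn without replacement within themselves).")
  }
  if (!is.null(seed)) set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_rep), function(i) {
    tibble::tibble(sample = i, birthweight = x[sample.int(n_pop, sample_size)])
  }))
}

#' Fit a k-component mixture to each meta-sample
#'
#' Fits each sample independently and extracts the aligned parameter vector
#' `p_1..p_k, mu_1..mu_k, sigma_1..sigma_k`. Components of every fit are in
#' canonical ascending-mean order before extraction, which is what aligns
#' "component j" across samples. Samples whose fit fails are dropped with a
#' warning.
#'
#' @param samples A tibble with columns `sample` and `birthweight` (from
#'   [draw_meta_samples()] or built by stacking independent samples), or a
#'   list of datasets.
#' @param k Number of mixture components to fit.
#' @param strategy An [init_strategy()].
#' @param ... Further arguments to [fit_mixture()].
#' @return A tibble with one row per successfully fitted sample: `sample`
#'   plus the `3k` parameter columns.
#' @export
fit_meta_samples <- function(samples, k, strategy = init_strategy(), ...) {
  if (is.data.frame(samples)) {
    ids <- unique(samples$sample)
    get <- function(i) samples$birthweight[samples$sample == i]
  } else {
    ids <- seq_along(samples)
    get <- function(i) pull_birthweights(samples[[i]])
  }
  rows <- lapply(ids, function(i) {
    fit <- tryCatch(fit_mixture(get(i), k, strategy = strategy, ...),
                    error = function(e) {
                      warn(sprintf("Fit failed for sample %s: %s", i, conditionMessage(e)))
                      NULL
                    })
    if (is.null(fit)) return(NULL)
    tibble::as_tibble(c(list(sample = i), as.list(param_vector(fit$model))))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) abort("Every meta-sample fit failed.")
  out
}

#' Combine parameter estimates across meta-samples
#'
#' Column-wise meta-sample mean (the overall estimate of each parameter) and
#' standard deviation (with `n_rep - 1` in the denominator).
#'
#' @param estimates Tibble of per-sample parameter estimates from
#'   [fit_meta_samples()] (a `sample` column, if present, is ignored).
#' @return A tibble with columns `parameter`, `theta_bar`, `s_theta`.
#' @export
combine_estimates <- function(estimates) {
  est <- dplyr::select(estimates, -dplyr::any_of("sample"))
  if (nrow(est) < 2L) abort("At least two meta-samples are required to combine estimates.")
  tibble::tibble(
    parameter = names(est),
    theta_bar = unname(vapply(est, mean, numeric(1))),
    s_theta = unname(vapply(est, sd, numeric(1)))
  )
}

# Build the overall mixture model implied by a combined-estimate table.
model_from_estimates <- function(combined) {
  k <- nrow(combined) / 3L
  w <- combined$theta_bar[seq_len(k)]
  mixture_model(w / sum(w),
                combined$theta_bar[k + seq_len(k)],
                combined$theta_bar[2 * k + seq_len(k)])
}

#' Simulation-based bias estimate for meta-sample parameter estimates
#'
#' Simulates `n_bias_sims` truncated datasets of size `sample_size` from the
#' overall fitted model, refits a k-component mixture to each, and records the
#' absolute drift of every re-estimated parameter from the generating value.
#' The average absolute drift is the bias estimate: the drift from the fitted
#' model to its own re-estimates is taken to mirror the drift from the true
#' parameters to the original estimates (which includes, for instance, the
#' systematic displacement induced by fitting an untruncated mixture to
#' truncated data). A replicate whose fit fails is redrawn (up to 3 retries).
#'
#' @param overall_model The `mixture_model` built from the overall estimates.
#' @param sample_size Size of each simulated dataset (same as the
#'   meta-samples).
#' @param n_bias_sims Number of simulated datasets (default 5).
#' @param window The [trunc_window()] used by the data pipeline.
#' @param seed Optional integer seed.
#' @param strategy An [init_strategy()].
#' @param ... Further arguments to [fit_mixture()].
#' @return A tibble with columns `parameter` and `bias_hat` (>= 0).
#' @export
estimate_bias <- function(overall_model, sample_size, n_bias_sims = 5L,
                          window = trunc_window(), seed = NULL,
                          strategy = init_strategy(), ...) {
  stopifnot(inherits(overall_model, "mixture_model"))
  k <- n_components(overall_model)
  truth <- param_vector(overall_model)
  if (!is.null(seed)) set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max - 4L, n_bias_sims * 4L)
  drifts <- matrix(NA_real_, n_bias_sims, length(truth))
  for (s in seq_len(n_bias_sims)) {
    fit <- NULL
    for (attempt in 0:3) {
      sseed <- sim_seeds[(s - 1L) * 4L + attempt + 1L]
      dat <- simulate_birthweights(overall_model, sample_size, window = window, seed = sseed)
      fit <- tryCatch(fit_mixture(dat, k, strategy = strategy, ...),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) abort("Bias simulation fit failed after 3 retries.")
    drifts[s, ] <- abs(param_vector(fit$model) - truth)
  }
  tibble::tibble(parameter = names(truth), bias_hat = colMeans(drifts))
}

#' Meta-sample confidence intervals
#'
#' `ci_unadjusted()` is the plain interval
#' \eqn{(\bar\theta - C s_\theta,\; \bar\theta + C s_\theta)};
#' `ci_bias_adjusted()` widens it symmetrically by the bias estimate:
#' \eqn{(\bar\theta - C s_\theta - \hat b,\; \bar\theta + C s_\theta + \hat b)}.
#' The bias-adjusted interval always contains the unadjusted one.
#'
#' @param theta_bar Meta-sample mean(s).
#' @param s_theta Meta-sample standard deviation(s), >= 0.
#' @param bias_hat Bias estimate(s), >= 0.
#' @param c_mult Critical multiplier C > 0.
#' @return A tibble with columns `lower` and `upper`.
#' @export
ci_unadjusted <- function(theta_bar, s_theta, c_mult) {
  if (any(s_theta < 0)) abort("`s_theta` must be nonnegative.")
  if (any(c_mult <= 0)) abort("`c_mult` must be positive.")
  tibble::tibble(lower = theta_bar - c_mult * s_theta,
                 upper = theta_bar + c_mult * s_theta)
}

#' @rdname ci_unadjusted
#' @export
ci_bias_adjusted <- function(theta_bar, s_theta, bias_hat, c_mult) {
  if (any(bias_hat < 0)) abort("`bias_hat` must be nonnegative.")
  ci <- ci_unadjusted(theta_bar, s_theta, c_mult)
  tibble::tibble(lower = ci$lower - bias_hat, upper = ci$upper + bias_hat)
}

#' Overlap-corrected critical multiplier
#'
#' When each of the `n_rep` meta-samples constitutes a fraction `phi` of the
#' underlying population, the samples overlap and their parameter estimates
#' are positively dependent, so the baseline multiplier `C_0` (calibrated for
#' effectively independent samples) under-covers. The correction inflates it
#' by the square root of the redundancy of the meta-sample:
#' \deqn{C_\phi = C_0 \sqrt{\frac{N_{rep}\,\phi}{1 - (1 - \phi)^{N_{rep}}}}.}
#' The denominator is the expected fraction of the population appearing in at
#' least one sample, so the ratio inside the square root is (total draws) /
#' (expected distinct individuals) — the factor by which the effective
#' independent information is smaller than the nominal one. At `phi = 0` the
#' multiplier is exactly `C_0`; it is strictly increasing in `phi`. At
#' `phi = 0.05` and `n_rep = 25` the inflation factor is 1.315.
#'
#' @param c0 Baseline multiplier `C_0` (default 2.5, the empirically
#'   calibrated value for bias-adjusted intervals at ~95% coverage).
#' @param phi Sampling fraction `sample_size / population_size`, in `[0, 1)`;
#'   0 means an effectively infinite population.
#' @param n_rep Number of meta-samples.
#' @return The adjusted multiplier `C_phi >= C_0`.
#' @export
overlap_adjusted_c <- function(c0 = 2.5, phi, n_rep) {
  if (any(phi < 0 | phi >= 1)) abort("`phi` must lie in [0, 1).")
  if (any(n_rep < 2)) abort("`n_rep` must be at least 2.")
  factor <- ifelse(phi == 0, 1, sqrt(n_rep * phi / (1 - (1 - phi)^n_rep)))
  c0 * factor
}

#' Full meta-sample inference pipeline
#'
#' Fits k-component mixtures to a set of same-size samples, combines the
#' estimates, estimates the bias by simulation, and forms bias-adjusted
#' confidence intervals at the (optionally overlap-corrected) critical
#' multiplier. This is the report layout used for a population analysed
#' through repeated samples: one row per mixture parameter.
#'
#' @inheritParams fit_meta_samples
#' @param c0 Baseline critical multiplier.
#' @param phi Sampling fraction for the overlap correction (0 = none).
#' @param n_bias_sims Number of bias-simulation replicates.
#' @param window [trunc_window()] used for the bias simulations.
#' @param seed Optional integer seed for the bias simulations.
#' @param bias_adjust If `FALSE`, skip the bias term (plain intervals).
#' @return A `meta_estimate` tibble: `parameter`, `theta_bar`, `s_theta`,
#'   `bias_hat`, `lower`, `upper`, with the critical multiplier used stored in
#'   the `c_mult` attribute.
#' @export
meta_ci <- function(samples, k, c0 = 2.5, phi = 0, n_bias_sims = 5L,
                    window = trunc_window(), seed = NULL,
                    strategy = init_strategy(), bias_adjust = TRUE, ...) {
  est <- fit_meta_samples(samples, k, strategy = strategy, ...)
  combined <- combine_estimates(est)
  c_mult <- overlap_adjusted_c(c0, phi, n_rep = nrow(est))
  if (bias_adjust) {
    overall <- model_from_estimates(combined)
    sample_size <- if (is.data.frame(samples)) sum(samples$sample == samples$sample[1]) else length(pull_birthweights(samples[[1]]))
    bias <- estimate_bias(overall, sample_size, n_bias_sims = n_bias_sims,
                          window = window, seed = seed, strategy = strategy, ...)
    combined$bias_hat <- bias$bias_hat
    ci <- ci_bias_adjusted(combined$theta_bar, combined$s_theta, combined$bias_hat, c_mult)
  } else {
    combined$bias_hat <- 0
    ci <- ci_unadjusted(combined$theta_bar, combined$s_theta, c_mult)
  }
  out <- dplyr::bind_cols(combined, ci)
  attr(out, "c_mult") <- c_mult
  class(out) <- c("meta_estimate", class(out))
  out
}
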