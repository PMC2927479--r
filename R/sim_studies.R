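#' Order-selection simulation study
#'
#' For each design and sample size, draws `n_replicates` independent
#' (nonoverlapping) truncated samples, fits all orders m = 1..M, selects the
#' order with each criterion, and tallies how often each order is chosen. The
#' tallies answer how reliably each criterion recovers the generating number
#' of components.
#'
#' @param designs A list of `sim_design` objects (default: all of A-E).
#' @param sample_sizes Sizes of the simulated datasets.
#' @param n_replicates Replicate datasets per (design, size) cell.
#' @param M Largest order fitted.
#' @param criteria Criteria to tally.
#' @param strategy An [init_strategy()] for the per-replicate fits (the
#'   strategy's own seed is ignored; per-replicate seeds are derived from
#'   `seed`).
#' @param seed Integer seed for the whole study.
#' @param max_retries Replicates whose fit fails are redrawn at most this many
#'   times.
#' @param B Interpolation weight function for the flexible criterion.
#' @param ... Further arguments to [fit_mixture()] (e.g. `short_iter`).
#' @return A `selection_study` tibble of counts: `design`, `true_k`,
#'   `sample_size`, `criterion`, `m`, `count`; per-replicate verdicts are in
#'   the `verdicts` attribute, the replicate count in the `n_replicates`
#'   attribute.
#' @export
run_selection_study <- function(designs = design_catalog(),
                                sample_sizes = c(5000, 10000, 25000, 50000, 100000),
                                n_replicates = 25L, M = 7L,
                                criteria = c("FLIC", "BIC", "AIC"),
                                strategy = init_strategy(n_restarts = 4L),
                                seed = NULL, max_retries = 2L, B = flic_weight, ...) {
  if (inherits(designs, "sim_design")) designs <- list(designs)
  if (n_replicates < 1L) abort("`n_replicates` must be at least 1.")
  if (any(sample_sizes < 1)) abort("Sample sizes must be positive.")
  if (!is.null(seed)) set.seed(seed)
  n_cells <- length(designs) * length(sample_sizes) * n_replicates
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_cells * (max_retries + 1L)),
                  ncol = 2L)
  cell <- 0L
  verdicts <- list()
  for (d in designs) {
    for (nsize in sample_sizes) {
      for (r in seq_len(n_replicates)) {
        sel <- NULL
        for (attempt in 0:max_retries) {
          cell <- cell + 1L
          dat <- simulate_birthweights(d$model, nsize, window = d$window,
                                       seed = seeds[cell, 1])
          strat <- init_strategy(method = strategy$method,
                                 n_restarts = strategy$n_restarts,
                                 seed = seeds[cell, 2])
          sel <- tryCatch({
            fits <- fit_mixture_orders(dat, M = M, strategy = strat, ...)
            select_order(fits, criteria = criteria, B = B)
          }, error = function(e) {
            warn(sprintf("Replicate failed (design %s, n = %d): %s",
                         d$label, nsize, conditionMessage(e)))
            NULL
          })
          if (!is.null(sel)) break
        }
        if (is.null(sel)) abort("A replicate failed even after redraws.")
        verdicts[[length(verdicts) + 1L]] <- tibble::tibble(
          design = d$label, true_k = d$true_k, sample_size = nsize,
          replicate = r, criterion = names(sel$selected),
          selected = unname(sel$selected))
      }
    }
  }
  verdicts <- dplyr::bind_rows(verdicts)
  counts <- verdicts |>
    dplyr::mutate(m = factor(.data$selected, levels = seq_len(M))) |>
    dplyr::count(.data$design, .data$true_k, .data$sample_size,
                 .data$criterion, .data$m, name = "count", .drop = FALSE) |>
    dplyr::mutate(m = as.integer(as.character(.data$m)))
  structure(counts, verdicts = verdicts, n_replicates = n_replicates,
            class = c("selection_study", class(counts)))
}

#' Confidence-interval coverage study
#'
#' Calibrates the meta-sample confidence intervals on a known truth. Each
#' meta-repetition draws `n_rep` samples of `sample_size` from the design —
#' independently for the infinite-population regime, or without replacement
#' within-sample from a freshly generated finite population for the finite
#' regime — fits `true_k`-component mixtures, combines the estimates,
#' estimates the bias, and forms both unadjusted and bias-adjusted intervals
#' at every multiplier in `c_grid`. Captures of the design's generating
#' parameters are tallied over `n_meta` meta-repetitions (so each cell is out
#' of `n_meta * 3k` intervals). The tabulated multiplier is the raw `C`; the
#' overlap correction is a separate, analytic reconciliation available through
#' [overlap_adjusted_c()].
#'
#' @param design A `sim_design` (the truth).
#' @param c_grid Critical multipliers to evaluate.
#' @param population_size Finite population size, or `NULL`/`Inf` for the
#'   infinite (independent samples) regime.
#' @param n_meta Number of meta-repetitions.
#' @param n_rep Samples per meta-repetition.
#' @param sample_size Size of each sample.
#' @param n_bias_sims Bias-simulation replicates per meta-repetition.
#' @param strategy An [init_strategy()] for all fits.
#' @param seed Integer seed for the whole study.
#' @param ... Further arguments to [fit_mixture()] (e.g. `short_iter`).
#' @return A `coverage_study` tibble: `c_mult`, `interval` (`"bias_adjusted"`
#'   or `"unadjusted"`), `captured`, `total`, `percent`; per-meta detail in
#'   the `per_meta` attribute.
#' @export
run_coverage_study <- function(design, c_grid = seq(2, 5, by = 0.5),
                               population_size = NULL, n_meta = 10L,
                               n_rep = 25L, sample_size = 50000L,
                               n_bias_sims = 5L,
                               strategy = init_strategy(n_restarts = 4L),
                               seed = NULL, ...) {
  stopifnot(inherits(design, "sim_design"))
  finite <- !is.null(population_size) && is.finite(population_size)
  if (finite && population_size < sample_size) {
    abort("`population_size` must be at least `sample_size`.")
  }
  k <- design$true_k
  truth <- param_vector(design$model)
  if (!is.null(seed)) set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 4L * n_meta), ncol = 4L)
  per_meta <- list()
  for (t in seq_len(n_meta)) {
    if (finite) {
      pop <- simulate_population(design$model, population_size,
                                 window = design$window, seed = seeds[t, 1])
      samples <- draw_meta_samples(pop, n_rep, sample_size, seed = seeds[t, 2])
    } else {
      samples <- dplyr::bind_rows(lapply(seq_len(n_rep), function(i) {
        dat <- simulate_birthweights(design$model, sample_size,
                                     window = design$window,
                                     seed = (seeds[t, 1] + i - 1L) %% .Machine$integer.max)
        tibble::tibble(sample = i, birthweight = dat$birthweight)
      }))
    }
    strat <- init_strategy(method = strategy$method,
                           n_restarts = strategy$n_restarts, seed = seeds[t, 3])
    est <- fit_meta_samples(samples, k, strategy = strat, ...)
    combined <- combine_estimates(est)
    overall <- model_from_estimates(combined)
    bias <- estimate_bias(overall, sample_size, n_bias_sims = n_bias_sims,
                          window = design$window, seed = seeds[t, 4],
                          strategy = strat, ...)
    for (cv in c_grid) {
      ci7 <- ci_bias_adjusted(combined$theta_bar, combined$s_theta, bias$bias_hat, cv)
      ci6 <- ci_unadjusted(combined$theta_bar, combined$s_theta, cv)
      cap7 <- truth >= ci7$lower & truth <= ci7$upper
      cap6 <- truth >= ci6$lower & truth <= ci6$upper
      per_meta[[length(per_meta) + 1L]] <- tibble::tibble(
        meta_rep = t, c_mult = cv,
        interval = rep(c("bias_adjusted", "unadjusted"), each = length(truth)),
        parameter = rep(combined$parameter, 2L),
        truth = rep(unname(truth), 2L),
        lower = c(ci7$lower, ci6$lower), upper = c(ci7$upper, ci6$upper),
        captured = unname(c(cap7, cap6)))
    }
  }
  per_meta <- dplyr::bind_rows(per_meta)
  out <- per_meta |>
    dplyr::group_by(.data$c_mult, .data$interval) |>
    dplyr::summarise(captured = sum(.data$captured), total = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(percent = 100 * .data$captured / .data$total)
  structure(out, per_meta = per_meta,
            regime = if (finite) sprintf("finite(%d)", as.integer(population_size)) else "infinite",
            class = c("coverage_study", class(out)))
}
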