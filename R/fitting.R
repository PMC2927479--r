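#' Initialization strategy for mixture fitting
#'
#' Controls how starting values for the EM algorithm are produced. The
#' `"quantile"` method uses a single deterministic start; `"random-restart"`
#' adds `n_restarts` randomized starts (component means drawn from the data)
#' for models with four or more components, plus a k-means start, to guard
#' against local maxima — small far-tail components are easy to miss from a
#' pure quantile start.
#'
#' @param method `"quantile"` or `"random-restart"`.
#' @param n_restarts Number of randomized restarts (used for m >= 4).
#' @param seed Optional integer seed making the restart set reproducible.
#' @return An object of class `init_strategy`.
#' @export
init_strategy <- function(method = c("random-restart", "quantile"),
                          n_restarts = 10L, seed = NULL) {
  method <- match.arg(method)
  if (n_restarts < 1L) abort("`n_restarts` must be at least 1.")
  structure(list(method = method, n_restarts = as.integer(n_restarts), seed = seed),
            class = "init_strategy")
}

#' Initial parameter values for an m-component fit
#'
#' The deterministic (quantile) start: component means at the
#' `(j - 0.5) / m` empirical quantiles, all standard deviations equal to the
#' sample standard deviation divided by `sqrt(m)`, equal weights.
#'
#' @param data Data frame with a `birthweight` column, or numeric vector.
#' @param m Number of components (requires at least `10 * m` observations).
#' @param strategy An [init_strategy()] (only its seed is consulted here).
#' @return A `mixture_model` of starting values.
#' @export
init_params <- function(data, m, strategy = init_strategy()) {
  x <- pull_birthweights(data)
  if (m < 1L) abort("`m` must be at least 1.")
  if (length(x) < 10L * m) {
    abort(sprintf("Need at least %d observations to initialize an %d-component fit.", 10L * m, m))
  }
  quantile_start(x, m)
}

quantile_start <- function(x, m) {
  mu <- as.numeric(quantile(x, (seq_len(m) - 0.5) / m, names = FALSE))
  if (anyDuplicated(mu)) mu <- mu + seq_len(m) * 1e-6 * max(sd(x), 1)
  s <- max(sd(x) / sqrt(m), 1)
  mixture_model(rep(1 / m, m), mu, rep(s, m))
}

kmeans_start <- function(x, m, sd_floor = 1) {
  km <- tryCatch(
    suppressWarnings(
      kmeans(x, centers = as.numeric(quantile(x, (seq_len(m) - 0.5) / m, names = FALSE)),
             iter.max = 50L, algorithm = "Lloyd")),
    error = function(e) NULL)
  if (is.null(km) || any(km$size < 2L)) return(NULL)
  mu <- as.numeric(km$centers)
  s <- vapply(seq_len(m), function(j) sd(x[km$cluster == j]), numeric(1))
  s <- pmax(s, sd_floor)
  w <- km$size / length(x)
  tryCatch(mixture_model(w / sum(w), mu, s), error = function(e) NULL)
}

random_start <- function(x, m) {
  mu <- sort(sample(x, m))
  if (anyDuplicated(mu)) mu <- mu + seq_len(m) * 1e-6 * max(sd(x), 1)
  s <- max(sd(x) / sqrt(m), 1)
  mixture_model(rep(1 / m, m), mu, rep(s, m))
}

# Warm start for m+1 components: split the fitted component carrying the most
# weighted variance into two offset halves. Sequential splitting is a cheap
# way to land the (m+1)-order fit in the basin the m-order fit already found.
split_start <- function(model) {
  j <- which.max(model$weight * model$sd^2)
  w <- append(model$weight[-j], rep(model$weight[j] / 2, 2), after = j - 1)
  mu <- append(model$mean[-j], model$mean[j] + c(-0.6, 0.6) * model$sd[j], after = j - 1)
  s <- append(model$sd[-j], rep(model$sd[j] * 0.75, 2), after = j - 1)
  mixture_model(w / sum(w), mu, pmax(s, 1))
}

# Full set of candidate starting values for one m. Random starts are only
# generated under the random-restart method and only for m >= 4, where the
# likelihood surface is rugged enough to need them.
candidate_inits <- function(x, m, strategy) {
  inits <- list(quantile_start(x, m))
  if (m >= 2L) {
    ks <- kmeans_start(x, m)
    if (!is.null(ks)) inits <- c(inits, list(ks))
  }
  if (strategy$method == "random-restart" && m >= 4L) {
    inits <- c(inits, lapply(seq_len(strategy$n_restarts), function(r) random_start(x, m)))
  }
  inits
}

new_mixture_fit <- function(model, loglik, n, em_result, refinement_gain = 0,
                            converged = TRUE, n_starts = 1L) {
  structure(list(model = model, loglik = loglik, m = n_components(model), n = n,
                 n_iterations = em_result$iterations, converged = converged,
                 refinement_gain = refinement_gain, loglik_em = em_result$loglik,
                 loglik_trace = em_result$trace, n_starts = n_starts),
            class = "mixture_fit")
}

#' EM estimation of an m-component normal mixture
#'
#' The classic EM iteration: responsibilities in the E-step, weighted means,
#' standard deviations and weights in the M-step. The log-likelihood is
#' non-decreasing across iterations; iteration stops when the improvement
#' falls below `tol` nats per observation or at `max_iter`. Component SDs are
#' floored at `sd_floor` grams and weights at `w_floor` to keep the likelihood
#' bounded (the unbounded-likelihood degeneracy of normal mixtures).
#'
#' @inheritParams init_params
#' @param init A `mixture_model` of starting values with `m` components.
#' @param tol Convergence tolerance in nats per observation (default 1e-7).
#' @param max_iter Maximum EM iterations (default 2000).
#' @param sd_floor,w_floor Lower bounds on component SDs (grams) and weights.
#' @return A `mixture_fit`: the fitted model (components in ascending-mean
#'   order), `loglik`, iteration count, convergence flag and the per-iteration
#'   log-likelihood trace (`loglik_trace`).
#' @export
em_fit <- function(data, m, init = NULL, tol = 1e-7, max_iter = 2000L,
                   sd_floor = 1, w_floor = 1e-6) {
  x <- pull_birthweights(data)
  if (is.null(init)) init <- init_params(x, m)
  if (n_components(init) != m) abort("`init` must have exactly `m` components.")
  res <- mix_em_cpp(x, init$weight, init$mean, init$sd,
                    tol = tol * length(x), max_iter = max_iter,
                    sd_floor = sd_floor, w_floor = w_floor)
  model <- mixture_model(res$weight / sum(res$weight), res$mean, res$sd)
  new_mixture_fit(model, res$loglik, length(x), res, converged = res$converged)
}

# Unconstrained parameterization for the refinement optimizer:
# weights via softmax with the last logit pinned at 0, SDs via log.
par_pack <- function(model) {
  m <- n_components(model)
  a <- log(model$weight) - log(model$weight[m])
  c(a[-m], model$mean, log(model$sd))
}

par_unpack <- function(par, m, sd_floor = 1) {
  a <- c(par[seq_len(m - 1)], 0)
  a <- a - max(a)
  w <- exp(a) / sum(exp(a))
  mu <- par[m:(2 * m - 1)]
  s <- pmax(exp(par[(2 * m):(3 * m - 1)]), sd_floor)
  list(weight = w, mean = mu, sd = s)
}

#' Direct likelihood refinement of an EM solution
#'
#' Maximizes the log-likelihood over the full `(3m - 1)`-dimensional free
#' parameter space (weights on the simplex via a softmax transform, SDs via a
#' log transform) by a quasi-Newton method (PORT routines via
#' [stats::nlminb()]) with an analytic gradient, started at the EM solution.
#' Quasi-Newton steps converge superlinearly along the likelihood ridges where
#' EM crawls, which is what makes the two-stage scheme worthwhile. Returns
#' whichever of the EM and refined solutions has the higher log-likelihood, so
#' the refined log-likelihood can never fall below the EM one; if the
#' optimizer fails the EM solution is returned with `converged = FALSE`.
#'
#' @inheritParams init_params
#' @param fit A `mixture_fit` from [em_fit()].
#' @param maxit Optimizer iteration cap.
#' @param sd_floor Lower bound on component SDs (grams).
#' @return A `mixture_fit` with `refinement_gain` (nats, >= 0) filled in.
#' @export
refine_fit <- function(data, fit, maxit = 300L, sd_floor = 1) {
  stopifnot(inherits(fit, "mixture_fit"))
  x <- pull_birthweights(data)
  m <- fit$m
  if (m == 1L) {
    fit$refinement_gain <- 0
    return(fit)
  }
  # objective and gradient share one likelihood evaluation per parameter value
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$val)
    p <- par_unpack(par, m, sd_floor)
    val <- mix_loglik_grad_cpp(x, p$weight, p$mean, p$sd)
    # chain rule for the sd floor: gradient is zero where the floor binds
    floored <- exp(par[(2 * m):(3 * m - 1)]) < sd_floor
    val$grad_logsd[floored] <- 0
    cache$par <- par
    cache$val <- val
    val
  }
  opt <- tryCatch(
    stats::nlminb(par_pack(fit$model),
                  objective = function(par) -evaluate(par)$loglik,
                  gradient = function(par) {
                    v <- evaluate(par)
                    -c(v$grad_a, v$grad_mu, v$grad_logsd)
                  },
                  control = list(iter.max = maxit, eval.max = 3L * maxit,
                                 rel.tol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective) || -opt$objective < fit$loglik) {
    fit$converged <- fit$converged && !is.null(opt)
    fit$refinement_gain <- 0
    return(fit)
  }
  p <- par_unpack(opt$par, m, sd_floor)
  model <- mixture_model(p$weight, p$mean, p$sd)
  gain <- -opt$objective - fit$loglik
  out <- fit
  out$model <- model
  out$loglik <- -opt$objective
  out$refinement_gain <- gain
  out
}

#' Maximum-likelihood fit of an m-component normal mixture
#'
#' The package's main fitting routine: EM from a set of candidate starts,
#' followed by direct numerical refinement of the likelihood. Restarts use a
#' short-run phase (each candidate start is run for `short_iter` EM
#' iterations, the best by log-likelihood is continued to full convergence)
#' before refinement — the standard "emEM" economy.
#'
#' @inheritParams em_fit
#' @param strategy An [init_strategy()]. Its seed (if any) is set before the
#'   randomized starts are generated, so fits are reproducible.
#' @param refine If `TRUE` (default), apply [refine_fit()] after EM.
#' @param short_iter EM iteration cap for the short-run restart phase.
#' @param extra_inits Optional list of additional `mixture_model` starting
#'   values with `m` components (e.g. warm starts from a neighboring order).
#' @return A `mixture_fit`.
#' @examples
#' x <- simulate_birthweights(bw_design("A")$model, 2000, seed = 1)
#' fit <- fit_mixture(x, m = 2, strategy = init_strategy(seed = 1))
#' tidy(fit)
#' @export
fit_mixture <- function(data, m, strategy = init_strategy(), tol = 1e-7,
                        max_iter = 2000L, refine = TRUE, short_iter = 100L,
                        sd_floor = 1, w_floor = 1e-6, extra_inits = list()) {
  x <- pull_birthweights(data)
  if (m < 1L) abort("`m` must be at least 1.")
  if (length(x) < 10L * m) {
    abort(sprintf("Need at least %d observations for an %d-component fit.", 10L * m, m))
  }
  if (!is.null(strategy$seed)) set.seed(strategy$seed)
  inits <- c(candidate_inits(x, m, strategy), extra_inits)

  # when a BFGS refinement follows, EM only needs to deliver a good basin:
  # it hands over at 10x the tolerance and the quasi-Newton step (which
  # converges superlinearly where EM crawls along ridges) finishes the job
  em_tol <- if (refine) 10 * tol else tol
  run <- function(init, iters) {
    mix_em_cpp(x, init$weight, init$mean, init$sd, tol = em_tol * length(x),
               max_iter = iters, sd_floor = sd_floor, w_floor = w_floor)
  }
  if (length(inits) > 1L) {
    shorts <- lapply(inits, run, iters = short_iter)
    lls <- vapply(shorts, function(r) r$loglik, numeric(1))
    best <- which.max(lls)  # ties resolve to the first (lowest restart index)
    start <- mixture_model(shorts[[best]]$weight / sum(shorts[[best]]$weight),
                           shorts[[best]]$mean, shorts[[best]]$sd)
  } else {
    start <- inits[[1]]
  }
  res <- run(start, max_iter)
  collapsed <- any(res$sd <= sd_floor & res$weight <= 10 * w_floor)
  if (collapsed) {
    # component collapse: retry remaining candidate starts before giving up
    ok <- FALSE
    for (init in inits) {
      res2 <- run(init, max_iter)
      if (!any(res2$sd <= sd_floor & res2$weight <= 10 * w_floor)) {
        res <- res2
        ok <- TRUE
        break
      }
    }
    if (!ok) abort(sprintf("All starts collapsed a component for m = %d.", m))
  }
  model <- mixture_model(res$weight / sum(res$weight), res$mean, res$sd)
  fit <- new_mixture_fit(model, res$loglik, length(x), res,
                         converged = res$converged, n_starts = length(inits))
  if (refine) fit <- refine_fit(x, fit, sd_floor = sd_floor)
  fit
}

#' Fit all candidate orders m = 1..M
#'
#' One maximized fit per candidate order, as required by the order-selection
#' criteria. `M = 7` is the working cap: more components than that would
#' impede downstream inference.
#'
#' @inheritParams fit_mixture
#' @param M Largest number of components to fit.
#' @return A `mixture_fit_set`: a list of `mixture_fit` objects ordered by m.
#' @export
fit_mixture_orders <- function(data, M = 7L, strategy = init_strategy(), ...) {
  x <- pull_birthweights(data)
  if (M < 1L) abort("`M` must be at least 1.")
  fits <- vector("list", M)
  for (m in seq_len(M)) {
    warm <- if (m >= 2L) list(split_start(fits[[m - 1L]]$model)) else list()
    fits[[m]] <- fit_mixture(x, m, strategy = strategy, extra_inits = warm, ...)
  }
  structure(list(fits = fits, n = length(x), M = as.integer(M)),
            class = "mixture_fit_set")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%d-component normal mixture fit (n = %d)\n", x$m, x$n))
  cat(sprintf("  log-likelihood %.4f after %d EM iterations (+%.2e from refinement)\n",
              x$loglik, x$n_iterations, x$refinement_gain))
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_mixture Component-level tibble for a fit (one row per
#'   component: `component`, `weight`, `mean`, `sd`).
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @export
tidy.mixture_fit <- function(x, ...) tidy(x$model)

#' @describeIn fit_mixture One-row fit summary: `m`, `n`, `loglik`,
#'   `n_iterations`, `converged`, `refinement_gain`.
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(m = x$m, n = x$n, loglik = x$loglik,
                 n_iterations = x$n_iterations, converged = x$converged,
                 refinement_gain = x$refinement_gain)
}

#' @export
print.mixture_fit_set <- function(x, ...) {
  cat(sprintf("Normal mixture fits for m = 1..%d (n = %d)\n", x$M, x$n))
  print(glance(x))
  invisible(x)
}

#' @describeIn fit_mixture_orders One row of fit summary per order m.
#' @param x A `mixture_fit_set`.
#' @param ... Unused.
#' @export
glance.mixture_fit_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fits, glance))
}

# Extract the aligned parameter vector (p_1..p_k, mu_1..mu_k, sigma_1..sigma_k)
# of a fitted model; components are already in ascending-mean order.
param_vector <- function(model) {
  k <- n_components(model)
  setNames(c(model$weight, model$mean, model$sd), param_names(k))
}

param_names <- function(k) {
  c(paste0("p_", seq_len(k)), paste0("mu_", seq_len(k)), paste0("sigma_", seq_len(k)))
}
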