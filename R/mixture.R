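#' Construct a finite normal mixture model
#'
#' A finite normal mixture with `k` components has density
#' \deqn{g(x) = \sum_{j=1}^{k} p_j f(x; \mu_j, \sigma_j),}
#' where `f` is the normal density, the mixing proportions `p_j` are positive
#' and sum to one, and each component has its own mean and standard deviation.
#' Components are stored in canonical order of ascending mean, which is the
#' label-alignment convention used everywhere else in the package (fits from
#' different samples can then be aggregated parameter by parameter).
#'
#' @param weight Numeric vector of mixing proportions, each in (0, 1].
#' @param mean Numeric vector of component means (grams, for birthweights).
#' @param sd Numeric vector of component standard deviations (grams, > 0).
#' @param renormalize If `TRUE`, allow weights whose sum differs from 1 by up
#'   to 2e-3 (e.g. parameters transcribed from a rounded table) and rescale
#'   them to sum to exactly 1. If `FALSE` (default) the weights must sum to 1
#'   within 1e-10.
#'
#' @return An object of class `mixture_model`: a list with elements `weight`,
#'   `mean` and `sd`, sorted by ascending mean.
#' @examples
#' m <- mixture_model(weight = c(.12, .88), mean = c(2601, 3186), sd = c(947, 457))
#' dmix(m, 3000)
#' @export
mixture_model <- function(weight, mean, sd, renormalize = FALSE) {
  k <- length(weight)
  if (k < 1L || length(mean) != k || length(sd) != k) {
    abort("`weight`, `mean` and `sd` must have equal length >= 1.")
  }
  if (!all(is.finite(weight)) || !all(is.finite(mean)) || !all(is.finite(sd))) {
    abort("Mixture parameters must all be finite.")
  }
  if (any(sd <= 0)) abort("Component standard deviations must be strictly positive.")
  if (any(weight <= 0) || any(weight > 1)) abort("Component weights must lie in (0, 1].")
  s <- sum(weight)
  if (renormalize) {
    if (abs(s - 1) > 2e-3) abort("Weights must sum to 1 within rounding error (2e-3) to be renormalized.")
    weight <- weight / s
  } else if (abs(s - 1) > 1e-10) {
    abort("Component weights must sum to 1 (within 1e-10); use `renormalize = TRUE` for rounded tables.")
  }
  ord <- order(mean)
  structure(list(weight = weight[ord], mean = mean[ord], sd = sd[ord]),
            class = "mixture_model")
}

#' Number of mixture components
#' @param model A `mixture_model`.
#' @return Integer component count `k`.
#' @export
n_components <- function(model) {
  stopifnot(inherits(model, "mixture_model"))
  length(model$weight)
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("Finite normal mixture, %d component(s)\n", n_components(x)))
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn mixture_model Tidy the components into a tibble with one row
#'   per component (`component`, `weight`, `mean`, `sd`).
#' @param x A `mixture_model`.
#' @param ... Unused.
#' @export
tidy.mixture_model <- function(x, ...) {
  tibble::tibble(component = seq_along(x$weight),
                 weight = x$weight, mean = x$mean, sd = x$sd)
}

#' Mixture density, distribution function and log-likelihood
#'
#' `dmix()` evaluates the mixture density, `pmix()` the distribution function,
#' and `loglik_mix()` the log-likelihood of a dataset. Densities are computed
#' in log space (log-sum-exp) so extreme points never underflow to zero and
#' log-likelihoods stay finite.
#'
#' @param model A `mixture_model`.
#' @param x,q Numeric vector of evaluation points (grams).
#' @param log If `TRUE`, `dmix()` returns log densities.
#' @return `dmix()`/`pmix()`: numeric vector; `loglik_mix()`: a single number
#'   in nats.
#' @examples
#' m <- mixture_model(1, 3000, 400)
#' dmix(m, 3000)  # 1 / (400 * sqrt(2 * pi))
#' @export
dmix <- function(model, x, log = FALSE) {
  stopifnot(inherits(model, "mixture_model"))
  if (!all(is.finite(x))) abort("`x` must be finite.")
  ld <- mix_logdensity_cpp(as.numeric(x), model$weight, model$mean, model$sd)
  if (log) ld else exp(ld)
}

#' @rdname dmix
#' @export
pmix <- function(model, q) {
  stopifnot(inherits(model, "mixture_model"))
  out <- numeric(length(q))
  for (j in seq_along(model$weight)) {
    out <- out + model$weight[j] * pnorm(q, model$mean[j], model$sd[j])
  }
  out
}

#' @rdname dmix
#' @export
loglik_mix <- function(model, x) {
  stopifnot(inherits(model, "mixture_model"))
  x <- pull_birthweights(x)
  if (length(x) < 1L) abort("Cannot evaluate a log-likelihood on an empty dataset.")
  if (!all(is.finite(x))) abort("All data values must be finite.")
  mix_loglik_cpp(as.numeric(x), model$weight, model$mean, model$sd)
}

#' Truncation window
#'
#' The gram range to which both real and simulated birthweights are
#' restricted. Bounds are inclusive; values recorded in integer grams at 500
#' or 5500 are retained.
#'
#' @param lower,upper Window bounds in grams, `lower < upper`.
#' @return An object of class `trunc_window`.
#' @export
trunc_window <- function(lower = 500, upper = 5500) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    abort("`lower` must be strictly less than `upper`.")
  }
  structure(c(lower = lower, upper = upper), class = "trunc_window")
}

#' Probability mass a mixture assigns to a window
#' @param model A `mixture_model`.
#' @param window A [trunc_window()].
#' @return Probability in `[0, 1]`.
#' @export
window_mass <- function(model, window = trunc_window()) {
  pmix(model, window[["upper"]]) - pmix(model, window[["lower"]])
}

#' Truncated mixture density and distribution function
#'
#' The law of a mixture draw conditioned on falling inside the truncation
#' window: density rescaled by the window mass inside the window, zero
#' outside.
#'
#' @inheritParams dmix
#' @param window A [trunc_window()].
#' @return Numeric vector.
#' @export
dmix_trunc <- function(model, x, window = trunc_window()) {
  mass <- window_mass(model, window)
  inside <- x >= window[["lower"]] & x <= window[["upper"]]
  out <- numeric(length(x))
  out[inside] <- dmix(model, x[inside]) / mass
  out
}

#' @rdname dmix_trunc
#' @export
pmix_trunc <- function(model, q, window = trunc_window()) {
  mass <- window_mass(model, window)
  lo <- pmix(model, window[["lower"]])
  p <- (pmix(model, pmin(pmax(q, window[["lower"]]), window[["upper"]])) - lo) / mass
  pmin(pmax(p, 0), 1)
}

#' Simulate truncated birthweights from a mixture
#'
#' Draws are made by rejection: a component is selected with probability equal
#' to its weight, a normal deviate is drawn, and values outside the window are
#' discarded and redrawn until exactly `n` remain. This is the generating
#' mechanism used for all simulation designs.
#'
#' @param model A `mixture_model`.
#' @param n Number of values to return.
#' @param window A [trunc_window()]; defaults to \[500, 5500\] grams.
#' @param seed Optional integer seed; the same seed reproduces the sample
#'   bit for bit.
#' @return A tibble with one column, `birthweight` (grams).
#' @export
simulate_birthweights <- function(model, n, window = trunc_window(), seed = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  if (n < 1L) abort("`n` must be at least 1.")
  mass <- window_mass(model, window)
  if (mass < 1e-12) {
    abort("The mixture assigns (numerically) no mass to the truncation window; rejection sampling would not terminate.")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- n_components(model)
  out <- numeric(0)
  while (length(out) < n) {
    need <- n - length(out)
    batch <- ceiling(need / max(mass, 0.05)) + 16L
    comp <- sample.int(k, batch, replace = TRUE, prob = model$weight)
    v <- rnorm(batch, model$mean[comp], model$sd[comp])
    out <- c(out, v[v >= window[["lower"]] & v <= window[["upper"]]])
  }
  tibble::tibble(birthweight = out[seq_len(n)])
}

#' Generate a finite truncated population
#'
#' A fixed finite population of truncated draws from the mixture, intended to
#' be resampled into overlapping meta-samples by [draw_meta_samples()].
#'
#' @inheritParams simulate_birthweights
#' @param size Population size (number of individuals).
#' @return A tibble with columns `id` and `birthweight`.
#' @export
simulate_population <- function(model, size, window = trunc_window(), seed = NULL) {
  if (size < 1L) abort("`size` must be at least 1.")
  dat <- simulate_birthweights(model, size, window = window, seed = seed)
  tibble::tibble(id = seq_len(size), birthweight = dat$birthweight)
}

#' Write or read a mixture model as plain text
#'
#' A small key-value format (`type`, `k`, then one `weight mean sd` row per
#' component at full precision) so fitted models can be stored and reloaded,
#' e.g. by the command-line interface.
#'
#' @param model A `mixture_model`.
#' @param path File path.
#' @return `write_mixture()` returns `path` invisibly; `read_mixture()`
#'   returns a `mixture_model`.
#' @export
write_mixture <- function(model, path) {
  stopifnot(inherits(model, "mixture_model"))
  lines <- c("type: normal_mixture",
             sprintf("k: %d", n_components(model)),
             "weight mean sd",
             sprintf("%s %s %s",
                     format(model$weight, digits = 17, scientific = FALSE, trim = TRUE),
                     format(model$mean, digits = 17, scientific = FALSE, trim = TRUE),
                     format(model$sd, digits = 17, scientific = FALSE, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mixture
#' @export
read_mixture <- function(path) {
  lines <- readLines(path)
  type <- sub("^type: *", "", lines[1])
  if (type != "normal_mixture") abort(sprintf("Unsupported model type '%s'.", type))
  k <- as.integer(sub("^k: *", "", lines[2]))
  rows <- read.table(text = lines[seq(4, 3 + k)], col.names = c("weight", "mean", "sd"))
  mixture_model(rows$weight, rows$mean, rows$sd, renormalize = TRUE)
}

# Accept either a bare numeric vector or a data frame with a birthweight
# column; all user-facing fitting functions funnel through here.
pull_birthweights <- function(data, col = "birthweight") {
  if (is.numeric(data)) return(as.numeric(data))
  if (is.data.frame(data)) {
    if (!col %in% names(data)) {
      abort(sprintf("Column '%s' not found in `data`.", col))
    }
    return(as.numeric(data[[col]]))
  }
  abort("`data` must be a data frame with a birthweight column or a numeric vector.")
}
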