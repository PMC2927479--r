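#' Simulation designs A-E
#'
#' The five generating mixtures used by the package's simulation studies.
#' They are the fitted 2- through 6-component birthweight models for white
#' singletons born to heavily smoking mothers, combined over 25 samples of
#' size 50,000, and serve as known truths: data are drawn from them truncated
#' to \[500, 5500\] grams. Published weights are rounded to three decimals and
#' may sum to 0.999-1.001; they are renormalized on entry.
#'
#' @param label One of `"A"` to `"E"`.
#' @return `bw_design()`: a `sim_design` (list with `label`, `model`,
#'   `true_k`, `window`); `design_catalog()`: a named list of all five.
#' @examples
#' bw_design("C")$model
#' @export
design_catalog <- function() {
  specs <- list(
    A = list(w = c(.120, .880),
             mu = c(2601, 3186),
             sd = c(947, 457)),
    B = list(w = c(.041, .871, .088),
             mu = c(1673, 3162, 3537),
             sd = c(617, 455, 575)),
    C = list(w = c(.007, .182, .758, .052),
             mu = c(832, 2772, 3170, 3804),
             sd = c(210, 740, 417, 413)),
    D = list(w = c(.007, .086, .678, .214, .014),
             mu = c(803, 2323, 3114, 3441, 4142),
             sd = c(193, 631, 419, 441, 428)),
    E = list(w = c(.006, .032, .268, .586, .099, .010),
             mu = c(752, 1737, 2829, 3215, 3762, 4337),
             sd = c(160, 471, 442, 373, 353, 387))
  )
  out <- lapply(names(specs), function(lab) {
    s <- specs[[lab]]
    structure(list(label = lab,
                   model = mixture_model(s$w, s$mu, s$sd, renormalize = TRUE),
                   true_k = length(s$w),
                   window = trunc_window()),
              class = "sim_design")
  })
  names(out) <- names(specs)
  out
}

#' @rdname design_catalog
#' @export
bw_design <- function(label) {
  cat_ <- design_catalog()
  if (!label %in% names(cat_)) abort("`label` must be one of A, B, C, D, E.")
  cat_[[label]]
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("Simulation design %s: %d-component truncated normal mixture on [%g, %g] g\n",
              x$label, x$true_k, x$window[["lower"]], x$window[["upper"]]))
  print(tidy(x$model))
  invisible(x)
}
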