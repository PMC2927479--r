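# Shared fixtures, built in code.

design_c_model <- function() bw_design("C")$model
design_a_model <- function() bw_design("A")$model

# Naive per-point mixture log-likelihood: direct dnorm sums, no log-sum-exp.
# Independent of the package's compiled evaluation path.
naive_loglik <- function(model, x) {
  sum(log(vapply(x, function(xi) {
    sum(model$weight * dnorm(xi, model$mean, model$sd))
  }, numeric(1))))
}

# Truncated first moment by numeric quadrature.
truncated_mean <- function(model, window = trunc_window()) {
  mass <- window_mass(model, window)
  stats::integrate(function(x) x * dmix(model, x) / mass,
                   window[["lower"]], window[["upper"]],
                   rel.tol = 1e-10)$value
}

# Six-record eligibility worked example: only (3000, 30) and (5500, 40)
# survive the known-age >= 22 weeks and 500 <= birthweight <= 5500 rules.
eligibility_records <- function() {
  tibble::tibble(
    birthweight = c(450, 500, 3000, 5500, 5600, 3200),
    gestational_age = c(25, 21, 30, 40, 30, NA)
  )
}

write_birth_csv <- function(records, path = tempfile(fileext = ".csv")) {
  write.csv(records, path, row.names = FALSE, na = "")
  path
}
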