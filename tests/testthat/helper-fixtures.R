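# Shared fixtures: small grids, quiet phenotypes, independent oracles.

small_grid <- function() {
  build_stimulus_grid(frequencies = c(2, 4, 8), contrasts = c(10, 50, 99),
                      seed = 7)
}

# A phenotype with configurable determinism knobs; noiseless by default.
test_phenotype <- function(label = "test",
                           gain_by_age = c(`1` = 1, `7` = 2),
                           noise_sd = 0, f1_leak_fraction = 0.2,
                           harmonic_rolloff = 0.3, ...) {
  genotype_phenotype(label, gain_by_age = gain_by_age, noise_sd = noise_sd,
                     f1_leak_fraction = f1_leak_fraction,
                     harmonic_rolloff = harmonic_rolloff, ...)
}

# Independent DFT oracle: direct quadrature projection of a series onto
# a complex exponential at one frequency, peak-amplitude convention.
dft_oracle <- function(x, sample_rate, frequency) {
  x <- x - mean(x)
  n <- length(x)
  t <- (seq_len(n) - 1) / sample_rate
  2 * sum(x * exp(-2i * pi * frequency * t)) / n
}

# i.i.d. Gaussian profiles with uninformative labels (structureless data).
null_profiles <- function(n_per_class, k_classes, d = 64) {
  list(x = matrix(stats::rnorm(n_per_class * k_classes * d),
                  n_per_class * k_classes, d),
       y = rep(sprintf("class%02d", seq_len(k_classes)), each = n_per_class))
}

# Brute-force Gaussian discriminant oracle, sharing no code with
# fit_lda/predict: plain loops and solve().
lda_oracle_predict <- function(x_train, y_train, x_new, lambda,
                               priors = NULL) {
  y_train <- factor(y_train)
  labs <- levels(y_train)
  d <- ncol(x_train)
  k <- length(labs)
  if (is.null(priors)) priors <- rep(1 / k, k)
  mu <- lapply(labs, function(l) colMeans(x_train[y_train == l, , drop = FALSE]))
  s <- matrix(0, d, d)
  for (i in seq_len(nrow(x_train))) {
    z <- x_train[i, ] - mu[[as.integer(y_train[i])]]
    s <- s + outer(z, z)
  }
  s <- s / (nrow(x_train) - k)
  s_reg <- (1 - lambda) * s + lambda * mean(diag(s)) * diag(d)
  s_inv <- solve(s_reg)
  apply(x_new, 1L, function(xi) {
    delta <- vapply(seq_len(k), function(j) {
      as.numeric(xi %*% s_inv %*% mu[[j]] -
                   0.5 * mu[[j]] %*% s_inv %*% mu[[j]] + log(priors[j]))
    }, 0)
    labs[which.max(delta)]
  })
}
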