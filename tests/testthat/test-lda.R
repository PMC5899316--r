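test_that("predictions match a brute-force Gaussian discriminant oracle", {
  set.seed(10)
  for (rep in 1:25) {
    d <- sample(2:6, 1)
    k <- sample(2:4, 1)
    n_per <- sample(4:8, 1)
    x <- matrix(stats::rnorm(k * n_per * d), k * n_per, d)
    y <- rep(letters[1:k], each = n_per)
    lambda <- stats::runif(1, 0.05, 1)
    fit <- fit_lda(x, y, shrinkage = lambda)
    x_new <- matrix(stats::rnorm(8 * d), 8, d)
    expect_identical(predict(fit, x_new),
                     lda_oracle_predict(x, y, x_new, lambda))
  }
})

test_that("two spherical classes split along the perpendicular bisector", {
  set.seed(11)
  mu_a <- c(2, 0, 0)
  mu_b <- c(-2, 0, 0)
  x <- rbind(sweep(matrix(stats::rnorm(60), 20, 3), 2, mu_a, `+`),
             sweep(matrix(stats::rnorm(60), 20, 3), 2, mu_b, `+`))
  y <- rep(c("a", "b"), each = 20)
  fit <- fit_lda(x, y, shrinkage = 1)  # spherical covariance model
  # closed-form rule from the fitted means: sign of (x - midpoint).(mu_a - mu_b)
  mid <- colMeans(fit$means)
  dir <- fit$means["a", ] - fit$means["b", ]
  x_new <- matrix(stats::rnorm(300), 100, 3)
  closed_form <- ifelse((x_new - matrix(mid, 100, 3, byrow = TRUE)) %*% dir > 0,
                        "a", "b")
  expect_identical(predict(fit, x_new), as.character(closed_form))
})

test_that("identical class means leave the decision to the priors", {
  x <- rbind(diag(3), diag(3))  # class means coincide exactly
  y <- rep(c("a", "b"), each = 3)
  fit <- fit_lda(x, y, shrinkage = 0.5, priors = c(0.9, 0.1))
  expect_true(all(predict(fit, matrix(stats::rnorm(30), 10, 3)) == "a"))
  # equal priors with exactly tied discriminants: lowest class index wins
  fit_tie <- fit_lda(x, y, shrinkage = 0.5)
  expect_identical(predict(fit_tie, matrix(0, 1, 3)), "a")
})

test_that("singular pooled covariance demands positive shrinkage", {
  set.seed(12)
  x <- matrix(stats::rnorm(10 * 64), 10, 64)  # d >> N - K
  y <- rep(c("a", "b"), each = 5)
  expect_error(fit_lda(x, y, shrinkage = 0), "singular")
  expect_s3_class(fit_lda(x, y, shrinkage = "auto"), "ssvep_lda")
  expect_gt(fit_lda(x, y, shrinkage = "auto")$lambda, 0)
})

test_that("as shrinkage approaches 1 the rule becomes nearest mean", {
  set.seed(13)
  x <- matrix(stats::rnorm(30 * 4), 30, 4)
  x[1:10, 1] <- x[1:10, 1] + 3
  x[11:20, 2] <- x[11:20, 2] + 3
  y <- rep(c("a", "b", "c"), each = 10)
  fit <- fit_lda(x, y, shrinkage = 1)
  x_new <- matrix(stats::rnorm(80), 20, 4)
  nearest <- apply(x_new, 1, function(xi) {
    c("a", "b", "c")[which.min(colSums((t(fit$means) - xi)^2))]
  })
  expect_identical(predict(fit, x_new), nearest)
})

test_that("leave-one-out equals manual enumeration on a six-sample set", {
  x <- matrix(c(0, 0, 1, 0, 0, 1,
                4, 4, 5, 4, 4, 5), 6, 2, byrow = FALSE)
  y <- rep(c("a", "b"), each = 3)
  acc <- loo_accuracy(x, y, shrinkage = 0.5)
  manual <- vapply(1:6, function(i) {
    pred <- lda_oracle_predict(x[-i, , drop = FALSE], y[-i],
                               x[i, , drop = FALSE], 0.5)
    pred == y[i]
  }, TRUE)
  expect_equal(as.numeric(acc), mean(manual))
  expect_equal(attr(acc, "predictions") == attr(acc, "truth"), manual)
  expect_error(loo_accuracy(x[c(1, 4:6), ], y[c(1, 4:6)]), ">= 2 samples")
})

test_that("well-separated classes are classified perfectly by every scheme", {
  set.seed(14)
  x <- rbind(matrix(stats::rnorm(40, 0, 0.1), 10, 4),
             matrix(stats::rnorm(40, 10, 0.1), 10, 4))
  y <- rep(c("a", "b"), each = 10)
  expect_equal(as.numeric(loo_accuracy(x, y)), 1)
  mc <- monte_carlo_accuracy(x, y, iterations = 50, seed = 3)
  expect_true(all(mc$accuracies == 1))
  conf <- nway_confusion(x, y, scheme = "loo")
  expect_equal(conf$normalized, diag(2), ignore_attr = TRUE)
  pw <- pairwise_bootstrap(x, y, "a", "b", iterations = 100, seed = 4)
  expect_equal(pw$mean_accuracy, 1)
  expect_true(pw$significant)
})

test_that("label-shuffled data classify at chance for K = 2, 5 classes", {
  set.seed(15)
  for (k in c(2L, 5L)) {
    dat <- null_profiles(10L, k, d = 16)
    mc <- monte_carlo_accuracy(dat$x, dat$y, iterations = 150, seed = k)
    n_pred <- 150 * k * 2  # 2 holdout flies per class per iteration
    tol <- 3 * sqrt((1 / k) * (1 - 1 / k) / n_pred) +
      0.03  # dataset-level variability around the chance rate
    expect_lt(abs(mc$mean_accuracy - 1 / k), tol)
  }
})

test_that("Monte Carlo accuracy is reproducible from its seed", {
  set.seed(16)
  dat <- null_profiles(6L, 3L, d = 5)
  a <- monte_carlo_accuracy(dat$x, dat$y, iterations = 40, seed = 77)
  b <- monte_carlo_accuracy(dat$x, dat$y, iterations = 40, seed = 77)
  c <- monte_carlo_accuracy(dat$x, dat$y, iterations = 40, seed = 78)
  expect_identical(a$accuracies, b$accuracies)
  expect_false(identical(a$accuracies, c$accuracies))
  # stratified split refuses to empty a training class
  expect_error(monte_carlo_accuracy(dat$x[c(1:3, 7:12, 13:18), ],
                                    dat$y[c(1:3, 7:12, 13:18)],
                                    iterations = 5, holdout_fraction = 0.5),
               "training samples")
})

test_that("confusion matrix rows are normalized per-class rates", {
  set.seed(17)
  dat <- null_profiles(8L, 3L, d = 6)
  for (scheme in c("loo", "mc")) {
    conf <- nway_confusion(dat$x, dat$y, scheme = scheme, iterations = 30,
                           seed = 5)
    expect_equal(rowSums(conf$counts), unname(conf$per_class_n),
                 ignore_attr = TRUE)
    expect_equal(unname(rowSums(conf$normalized)), rep(1, 3))
    expect_equal(conf$accuracy,
                 sum(diag(conf$counts)) / sum(conf$counts))
  }
})

test_that("pairwise bootstrap distinguishes separated but not identical classes", {
  set.seed(18)
  x_null <- matrix(stats::rnorm(24 * 6), 24, 6)
  y <- rep(c("a", "b"), each = 12)
  pw_null <- pairwise_bootstrap(x_null, y, "a", "b", iterations = 200,
                                seed = 6)
  expect_lt(abs(pw_null$mean_accuracy - 0.5), 0.15)
  expect_false(pw_null$significant)
  expect_equal(length(pw_null$accuracies), 200L)
  expect_true(all(pw_null$accuracies >= 0 & pw_null$accuracies <= 1))
  # the literal published wording flags the opposite tail
  pw_strict <- pairwise_bootstrap(x_null, y, "a", "b", iterations = 200,
                                  seed = 6, criterion = "paper-wording")
  expect_identical(pw_strict$accuracies, pw_null$accuracies)
  expect_equal(pw_strict$fraction_chance_side,
               mean(pw_strict$accuracies >= 0.5))
})

test_that("accuracy grows with between-class gain separation", {
  set.seed(19)
  grid <- small_grid()
  acc <- vapply(c(1.0, 1.5, 2.0), function(gain) {
    design <- cohort_design(
      genotypes = list(
        ctrl = test_phenotype("ctrl", gain_by_age = c(`1` = 1), noise_sd = 30),
        mut = test_phenotype("mut", gain_by_age = c(`1` = gain), noise_sd = 30)),
      ages = 1, flies_per_cell = 6, repeats_per_condition = 2,
      seed = 100 + round(10 * gain))
    profiles <- build_profiles(simulate_cohort(design, grid,
                                               materialize = FALSE))
    as.numeric(loo_accuracy(profile_matrix(profiles), profiles$genotype))
  }, 0)
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[3], acc[1])
})
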