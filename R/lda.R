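# Linear discriminant classification of response profiles.
#
# Gaussian classifier with class means and a shared pooled within-class
# covariance. With 64 features and ~10 flies per class the pooled
# covariance is singular, so the covariance is regularized toward a
# scaled identity: S_lambda = (1 - lambda) S + lambda (tr(S)/d) I.
# lambda = "auto" uses Ledoit-Wolf analytic shrinkage computed on the
# pooled within-class residuals.

ledoit_wolf_lambda <- function(z, s) {
  n <- nrow(z)
  d <- ncol(z)
  m <- mean(diag(s))
  d2 <- sum((s - diag(m, d))^2)
  if (d2 <= .Machine$double.eps) return(0)
  # sum_i ||z_i z_i' - S||_F^2 = sum_i (z_i'z_i)^2 - 2 sum_i z_i'S z_i + n ||S||^2
  q <- rowSums(z^2)
  cross <- rowSums((z %*% s) * z)
  b2 <- (sum(q^2) - 2 * sum(cross) + n * sum(s^2)) / n^2
  min(1, max(0, b2 / d2))
}

#' Fit a regularized linear discriminant model
#'
#' Estimates class means and the pooled within-class covariance
#' \eqn{S}, regularized as
#' \eqn{S_\lambda = (1-\lambda) S + \lambda \,(\mathrm{tr}(S)/d)\, I}.
#' Prediction maximizes the linear discriminant
#' \eqn{\delta_k(x) = x^\top S_\lambda^{-1}\mu_k -
#'   \tfrac12 \mu_k^\top S_\lambda^{-1}\mu_k + \log\pi_k},
#' with ties broken toward the lowest class index.
#'
#' @param x Numeric matrix, samples x features (e.g. flies x 64
#'   conditions).
#' @param y Class labels (coerced to factor); >= 2 classes with >= 2
#'   samples each.
#' @param shrinkage `"auto"` (Ledoit-Wolf analytic shrinkage) or a fixed
#'   value in \[0, 1\]. `0` requires a nonsingular pooled covariance.
#' @param priors Class prior probabilities (default uniform, matching a
#'   balanced design); recycled into the discriminant's log-prior term.
#' @return An object of class `ssvep_lda`: `labels`, `means` (classes x
#'   features), `cov` (regularized), `lambda`, `priors`, plus
#'   factorizations used by `predict()`.
#' @export
fit_lda <- function(x, y, shrinkage = "auto", priors = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  y <- droplevels(y)
  if (nrow(x) != length(y)) stopf("`x` and `y` lengths differ")
  counts <- table(y)
  if (length(counts) < 2L) stopf("need >= 2 classes, got %d", length(counts))
  if (any(counts < 2L)) {
    stopf("every class needs >= 2 samples (smallest has %d)", min(counts))
  }
  d <- ncol(x)
  k <- length(counts)
  n <- nrow(x)
  means <- t(vapply(levels(y), function(l) colMeans(x[y == l, , drop = FALSE]),
                    numeric(d)))
  z <- x - means[as.integer(y), , drop = FALSE]
  s <- crossprod(z) / (n - k)
  lambda <- if (identical(shrinkage, "auto")) {
    ledoit_wolf_lambda(z, crossprod(z) / n)
  } else {
    lam <- as.numeric(shrinkage)
    if (is.na(lam) || lam < 0 || lam > 1) stopf("`shrinkage` must be \"auto\" or in [0, 1]")
    lam
  }
  m_diag <- mean(diag(s))
  if (m_diag <= .Machine$double.eps) {
    # no within-class variance at all (e.g. a bootstrap resample of
    # duplicated flies): the discriminant degenerates to nearest mean,
    # for which any spherical covariance is equivalent
    s_reg <- diag(d)
    lambda <- 1
  } else {
    s_reg <- (1 - lambda) * s + lambda * m_diag * diag(d)
  }
  ch <- tryCatch(chol(s_reg), error = function(e) NULL)
  if (is.null(ch)) {
    stopf(paste("regularized pooled covariance is singular (lambda = %g,",
                "%d features, %d samples - %d classes); use shrinkage = \"auto\"",
                "or a positive lambda"), lambda, d, n, k)
  }
  if (is.null(priors)) priors <- rep(1 / k, k)
  priors <- priors / sum(priors)
  if (length(priors) != k || any(priors < 0)) {
    stopf("`priors` must be %d non-negative values", k)
  }
  # W: d x k matrix of S^-1 mu_k; const_k = -1/2 mu_k' S^-1 mu_k + log pi_k
  w <- backsolve(ch, forwardsolve(t(ch), t(means)))
  const <- -0.5 * colSums(t(means) * w) + log(priors)
  structure(
    list(labels = levels(y), means = means, cov = s_reg, lambda = lambda,
         priors = priors, w = w, const = const, n_per_class = as.integer(counts)),
    class = "ssvep_lda"
  )
}

#' Predict class labels (or discriminant scores) from an LDA model
#'
#' @param object An `ssvep_lda` model.
#' @param newdata Numeric matrix (samples x features) or single sample
#'   vector.
#' @param type `"class"` for labels, `"scores"` for the discriminant
#'   matrix.
#' @param ... Unused.
#' @return Character vector of labels, or a samples x classes score
#'   matrix.
#' @export
predict.ssvep_lda <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (ncol(x) != nrow(object$w)) {
    stopf("newdata has %d features; model expects %d", ncol(x), nrow(object$w))
  }
  scores <- sweep(x %*% object$w, 2L, object$const, `+`)
  colnames(scores) <- object$labels
  if (type == "scores") return(scores)
  # ties.method = "first": deterministic, lowest class index wins
  object$labels[max.col(scores, ties.method = "first")]
}

#' @export
print.ssvep_lda <- function(x, ...) {
  cat(sprintf("<ssvep_lda> %d classes, %d features, shrinkage lambda = %.4f\n",
              length(x$labels), nrow(x$w), x$lambda))
  invisible(x)
}

#' Leave-one-out classification accuracy
#'
#' Each sample is predicted by a model trained on the remaining N - 1;
#' the fraction of correct predictions is the generalized LOO accuracy.
#' Deterministic given the data.
#'
#' @inheritParams fit_lda
#' @return Accuracy fraction in \[0, 1\], with attributes `predictions`
#'   and `truth` for confusion-matrix accumulation.
#' @export
loo_accuracy <- function(x, y, shrinkage = "auto") {
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  if (any(table(y) < 2L)) {
    stopf("leave-one-out needs >= 2 samples per class so no fold empties a class")
  }
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- fit_lda(x[-i, , drop = FALSE], y[-i], shrinkage = shrinkage)
    pred[i] <- predict(fit, x[i, ])
  }
  acc <- mean(pred == as.character(y))
  attr(acc, "predictions") <- pred
  attr(acc, "truth") <- as.character(y)
  acc
}

stratified_split <- function(y, holdout_fraction) {
  test <- integer(0)
  for (l in levels(y)) {
    idx <- which(y == l)
    n_test <- max(1L, round(length(idx) * holdout_fraction))
    if (length(idx) - n_test < 2L) {
      stopf("class '%s' (n = %d) leaves < 2 training samples at holdout fraction %g",
            l, length(idx), holdout_fraction)
    }
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

#' Monte Carlo resampling classification accuracy
#'
#' Repeatedly splits the data into stratified train/holdout sets
#' (default 80/20), fits the discriminant on the training part, and
#' scores the holdout. Reproducible from `seed`.
#'
#' @inheritParams fit_lda
#' @param iterations Number of random splits.
#' @param holdout_fraction Fraction of each class held out per split.
#' @param seed Integer seed.
#' @return An object of class `ssvep_mc`: `accuracies` (per iteration),
#'   `mean_accuracy`, the confusion `counts` accumulated over all
#'   holdout predictions, and the settings used.
#' @export
monte_carlo_accuracy <- function(x, y, iterations = 1000,
                                 holdout_fraction = 0.2,
                                 shrinkage = "auto", seed = 1L) {
  stopifnot(is_count(iterations), holdout_fraction > 0, holdout_fraction < 1)
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  labs <- levels(y)
  counts <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  acc <- numeric(iterations)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      test <- stratified_split(y, holdout_fraction)
      fit <- fit_lda(x[-test, , drop = FALSE], y[-test], shrinkage = shrinkage)
      pred <- predict(fit, x[test, , drop = FALSE])
      truth <- as.character(y[test])
      acc[it] <- mean(pred == truth)
      for (j in seq_along(test)) {
        counts[truth[j], pred[j]] <- counts[truth[j], pred[j]] + 1L
      }
    }
  })
  structure(
    list(accuracies = acc, mean_accuracy = mean(acc), counts = counts,
         iterations = iterations, holdout_fraction = holdout_fraction,
         shrinkage = shrinkage, seed = as.integer(seed)),
    class = "ssvep_mc"
  )
}

#' N-way confusion matrix under leave-one-out or Monte Carlo schemes
#'
#' Accumulates (true, predicted) pairs across LOO folds or Monte Carlo
#' holdouts and normalizes each row by its prediction count, so the
#' diagonal holds per-class N-way accuracies and rows sum to 1.
#'
#' @inheritParams monte_carlo_accuracy
#' @param scheme `"loo"` or `"mc"`.
#' @return An object of class `ssvep_confusion`: integer `counts`,
#'   `normalized` rates, `per_class_n`, and `accuracy` (overall fraction
#'   correct).
#' @export
nway_confusion <- function(x, y, scheme = c("loo", "mc"), iterations = 1000,
                           holdout_fraction = 0.2, shrinkage = "auto",
                           seed = 1L) {
  scheme <- match.arg(scheme)
  y <- droplevels(factor(y))
  labs <- levels(y)
  if (scheme == "loo") {
    acc <- loo_accuracy(x, y, shrinkage = shrinkage)
    counts <- table(factor(attr(acc, "truth"), labs),
                    factor(attr(acc, "predictions"), labs))
    counts <- unclass(as.matrix(counts))
  } else {
    mc <- monte_carlo_accuracy(x, y, iterations = iterations,
                               holdout_fraction = holdout_fraction,
                               shrinkage = shrinkage, seed = seed)
    counts <- mc$counts
  }
  per_class_n <- rowSums(counts)
  normalized <- counts / ifelse(per_class_n > 0, per_class_n, 1)
  structure(
    list(counts = counts, normalized = normalized,
         per_class_n = per_class_n,
         accuracy = sum(diag(counts)) / sum(counts),
         scheme = scheme),
    class = "ssvep_confusion"
  )
}

#' Bootstrap pairwise (two-way) classification with significance rule
#'
#' Restricts the data to two classes and, for each of `iterations`
#' bootstrap draws, resamples flies with replacement within each class,
#' fits the discriminant on the resample, and scores the out-of-bag
#' flies. Classification is flagged significantly above chance when
#' fewer than 5% (`alpha`) of the iteration accuracies lie at or below
#' 0.5 (`criterion = "below-chance"`, the default). The published
#' wording of the rule counts accuracies at or *above* 0.5 instead;
#' `criterion = "paper-wording"` applies that literal reading.
#'
#' @inheritParams fit_lda
#' @param class_a,class_b The two class labels to compare.
#' @param iterations Bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @param criterion Significance rule; see Details.
#' @param alpha Criterion level (default 0.05).
#' @return An object of class `ssvep_pairwise`: `accuracies` (length
#'   `iterations`), `mean_accuracy`, `fraction_chance_side`,
#'   `significant`, `redraws` (iterations redrawn for an empty
#'   out-of-bag set), and settings.
#' @export
pairwise_bootstrap <- function(x, y, class_a, class_b, iterations = 1000,
                               shrinkage = "auto", seed = 1L,
                               criterion = c("below-chance", "paper-wording"),
                               alpha = 0.05) {
  criterion <- match.arg(criterion)
  stopifnot(is_count(iterations))
  x <- as.matrix(x)
  y <- as.character(y)
  keep <- y %in% c(class_a, class_b)
  if (sum(y == class_a) < 2L || sum(y == class_b) < 2L) {
    stopf("both classes need >= 2 samples ('%s': %d, '%s': %d)",
          class_a, sum(y == class_a), class_b, sum(y == class_b))
  }
  x <- x[keep, , drop = FALSE]
  y <- factor(y[keep], levels = c(class_a, class_b))
  idx_a <- which(y == class_a)
  idx_b <- which(y == class_b)
  acc <- numeric(iterations)
  redraws <- 0L
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      repeat {
        boot <- c(sample(idx_a, length(idx_a), replace = TRUE),
                  sample(idx_b, length(idx_b), replace = TRUE))
        oob <- setdiff(seq_along(y), unique(boot))
        if (length(oob) > 0L) break
        redraws <- redraws + 1L
      }
      fit <- fit_lda(x[boot, , drop = FALSE], y[boot], shrinkage = shrinkage)
      pred <- predict(fit, x[oob, , drop = FALSE])
      acc[it] <- mean(pred == as.character(y[oob]))
    }
  })
  frac <- if (criterion == "below-chance") mean(acc <= 0.5) else mean(acc >= 0.5)
  structure(
    list(class_a = class_a, class_b = class_b,
         accuracies = acc, mean_accuracy = mean(acc),
         fraction_chance_side = frac,
         significant = frac < alpha,
         criterion = criterion, alpha = alpha,
         iterations = iterations, shrinkage = shrinkage,
         seed = as.integer(seed), redraws = redraws),
    class = "ssvep_pairwise"
  )
}

#' @export
print.ssvep_pairwise <- function(x, ...) {
  cat(sprintf("<ssvep_pairwise> %s vs %s: mean accuracy %.3f over %d bootstraps; %ssignificant (%.1f%% on chance side)\n",
              x$class_a, x$class_b, x$mean_accuracy, x$iterations,
              if (x$significant) "" else "not ", 100 * x$fraction_chance_side))
  invisible(x)
}
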