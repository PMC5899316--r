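# Population statistics: PCA of the profile matrix, factorial ANOVA on
# the first principal-component score, and Sidak-corrected simple
# effects.

#' Principal components of a response-profile matrix
#'
#' Eigendecomposition of the covariance of column-mean-centered (not
#' variance-scaled) data: profile entries share one unit (microvolts), so
#' correlation-matrix scaling would distort the relative weight of high-
#' and low-amplitude conditions. The whole dataset to be compared must be
#' passed in a single call so every fly's score is scaled by the same
#' eigenvectors. Loading signs follow a deterministic convention: the
#' largest-magnitude element of each loading vector is positive.
#'
#' @param x Numeric matrix (flies x conditions) or an `ssvep_profiles`
#'   table.
#' @return An object of class `ssvep_pca`: `loadings` (conditions x
#'   components, orthonormal columns), `variance_fraction`, `scores`
#'   (flies x components), and `center`.
#' @export
pca_fit <- function(x) {
  if (inherits(x, "ssvep_profiles")) x <- profile_matrix(x)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("PCA needs at least 2 rows, got %d", nrow(x))
  if (anyNA(x)) stopf("PCA input contains missing values")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  loadings <- fit$rotation
  scores <- fit$x
  for (j in seq_len(ncol(loadings))) {
    imax <- which.max(abs(loadings[, j]))
    if (loadings[imax, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(loadings = loadings,
         variance_fraction = fit$sdev^2 / sum(fit$sdev^2),
         scores = scores,
         center = fit$center),
    class = "ssvep_pca"
  )
}

#' @export
print.ssvep_pca <- function(x, ...) {
  cat(sprintf("<ssvep_pca> %d components; PC1 explains %.1f%% of variance\n",
              ncol(x$loadings), 100 * x$variance_fraction[1L]))
  invisible(x)
}

check_balanced <- function(...) {
  counts <- table(...)
  if (any(counts == 0L)) stopf("design has empty cells; only fully crossed designs are supported")
  if (any(counts < 2L)) stopf("each design cell needs >= 2 observations")
  if (length(unique(c(counts))) != 1L) {
    stopf("design is unbalanced (cell sizes %s); only balanced designs are supported",
          paste(sort(unique(c(counts))), collapse = ", "))
  }
  invisible(counts)
}

anova_table_from_aov <- function(fit, effects) {
  tab <- summary(fit)[[1L]]
  rn <- trimws(rownames(tab))
  total_ss <- sum(tab[, "Sum Sq"])
  out <- data.frame(
    effect = c(effects, "residual"),
    df = tab[match(c(effects, "Residuals"), rn), "Df"],
    sum_sq = tab[match(c(effects, "Residuals"), rn), "Sum Sq"],
    f = c(tab[match(effects, rn), "F value"], NA_real_),
    p = c(tab[match(effects, rn), "Pr(>F)"], NA_real_),
    eta_sq = c(tab[match(effects, rn), "Sum Sq"] / total_ss, NA_real_),
    row.names = NULL
  )
  structure(out, class = c("ssvep_anova", "data.frame"))
}

#' Two-way between-groups ANOVA with interaction
#'
#' Fixed-effects factorial ANOVA (e.g. 5 genotypes x 5 ages on the first
#' PC score). For the balanced default design (10 flies per cell) the
#' degrees of freedom are (4, 225) for each main effect and (16, 225) for
#' the interaction. Unbalanced or incomplete designs are rejected rather
#' than approximated.
#'
#' @param score Numeric response (one value per fly, e.g. PC1 score).
#' @param factor_a,factor_b Grouping factors (coerced with `factor()`).
#' @return An `ssvep_anova` data frame with one row per effect
#'   (`factor_a`, `factor_b`, `factor_a:factor_b`, `residual`) holding
#'   sum of squares, df, F, p, and eta squared.
#' @export
two_way_anova <- function(score, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  stopifnot(length(score) == length(a), length(score) == length(b))
  check_balanced(a, b)
  d <- data.frame(score = score, a = a, b = b)
  fit <- stats::aov(score ~ a * b, data = d)
  tab <- anova_table_from_aov(fit, c("a", "b", "a:b"))
  tab$effect <- c("factor_a", "factor_b", "factor_a:factor_b", "residual")
  tab
}

#' One-way between-groups ANOVA
#'
#' @inheritParams two_way_anova
#' @param group Grouping factor.
#' @return An `ssvep_anova` data frame with rows `group` and `residual`,
#'   including eta squared for the group effect.
#' @export
one_way_anova <- function(score, group) {
  g <- factor(group)
  stopifnot(length(score) == length(g))
  if (nlevels(g) < 2L) stopf("need at least 2 groups")
  if (any(table(g) < 2L)) stopf("each group needs >= 2 observations")
  d <- data.frame(score = score, g = g)
  fit <- stats::aov(score ~ g, data = d)
  tab <- anova_table_from_aov(fit, "g")
  tab$effect <- c("group", "residual")
  tab
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for a family of `m` comparisons. Always at
#' least the raw p, with equality only at p = 0 or m = 1.
#'
#' @param p Raw p values in \[0, 1\].
#' @param m Family size (number of comparisons), >= 1.
#' @return Adjusted p values.
#' @examples
#' sidak_adjust(0.05, 10)  # 0.4013
#' @export
sidak_adjust <- function(p, m) {
  if (!is_count(m)) stopf("`m` must be a positive integer")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p values must lie in [0, 1]")
  if (m == 1L) return(p)  # exact identity, no floating-point round trip
  pmin(1, 1 - (1 - p)^m)
}

#' Sidak-corrected simple effects from a two-factor design
#'
#' Within each stratum (level) of the stratifying factor, compares every
#' pair of levels of the other factor by a t test on cell means, using
#' the pooled residual mean square of the full factorial model as the
#' error term (the behaviour of standard statistical packages'
#' simple-effects output). Each stratum forms its own Sidak family:
#' `m = choose(groups, 2)` comparisons.
#'
#' @inheritParams two_way_anova
#' @param stratify_on `"A"` to compare levels of factor B within each
#'   level of A, or `"B"` for the converse.
#' @param alpha Significance level for the `significant` flag.
#' @return An `ssvep_simple_effects` data frame with columns `stratum`,
#'   `group_a`, `group_b`, `mean_diff`, `p_raw`, `p_sidak`,
#'   `significant`.
#' @export
simple_effects_sidak <- function(score, factor_a, factor_b,
                                 stratify_on = c("A", "B"), alpha = 0.05) {
  stratify_on <- match.arg(stratify_on)
  a <- factor(factor_a)
  b <- factor(factor_b)
  check_balanced(a, b)
  d <- data.frame(score = score, a = a, b = b)
  fit <- stats::aov(score ~ a * b, data = d)
  tab <- summary(fit)[[1L]]
  mse <- tab["Residuals", "Mean Sq"]
  df_res <- tab["Residuals", "Df"]
  strat <- if (stratify_on == "A") a else b
  comp <- if (stratify_on == "A") b else a
  rows <- list()
  for (s in levels(strat)) {
    in_s <- strat == s
    lv <- levels(droplevels(comp[in_s]))
    if (length(lv) < 2L) {
      warnf("stratum '%s' has fewer than 2 groups; skipped", s)
      next
    }
    m <- choose(length(lv), 2L)
    pairs <- utils::combn(lv, 2L)
    for (j in seq_len(ncol(pairs))) {
      ga <- pairs[1L, j]; gb <- pairs[2L, j]
      xa <- score[in_s & comp == ga]
      xb <- score[in_s & comp == gb]
      diff <- mean(xa) - mean(xb)
      se <- sqrt(mse * (1 / length(xa) + 1 / length(xb)))
      p_raw <- 2 * stats::pt(-abs(diff / se), df_res)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, group_a = ga, group_b = gb, mean_diff = diff,
        p_raw = p_raw, p_sidak = sidak_adjust(p_raw, m),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_sidak < alpha
  structure(out, class = c("ssvep_simple_effects", "data.frame"),
            mse = mse, df_residual = df_res)
}
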