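# End-to-end pipeline: simulate -> extract profiles -> population stats
# -> classification, with a manifest for reproducibility.

#' Build a pipeline run configuration
#'
#' A plain serializable list capturing everything a run depends on, so
#' re-running an identical configuration reproduces byte-identical
#' tabular outputs.
#'
#' @param frequencies,contrasts Stimulus grid values.
#' @param ages Cohort ages in days.
#' @param flies_per_cell,repeats_per_condition Cohort shape.
#' @param stress Logical photic-stress flag.
#' @param discard Onset seconds discarded before each spectrum.
#' @param shrinkage LDA shrinkage (`"auto"` or value in \[0, 1\]).
#' @param mc_iterations,holdout_fraction Monte Carlo settings.
#' @param pairwise_iterations Bootstrap iterations per genotype pair.
#' @param classify_age Age (days) at which the classification suite runs
#'   (`NULL` to skip classification).
#' @param alpha Significance level.
#' @param seed Root seed for all stochastic stages.
#' @return A list of class `ssvep_config`.
#' @export
run_config <- function(frequencies = default_frequencies(),
                       contrasts = default_contrasts(),
                       ages = c(1, 7, 14, 21, 28),
                       flies_per_cell = 10,
                       repeats_per_condition = 3,
                       stress = FALSE,
                       discard = 1,
                       shrinkage = "auto",
                       mc_iterations = 200,
                       holdout_fraction = 0.2,
                       pairwise_iterations = 1000,
                       classify_age = ages[[1L]],
                       alpha = 0.05,
                       seed = 1L) {
  structure(
    list(frequencies = frequencies, contrasts = contrasts, ages = ages,
         flies_per_cell = flies_per_cell,
         repeats_per_condition = repeats_per_condition, stress = stress,
         discard = discard, shrinkage = shrinkage,
         mc_iterations = mc_iterations,
         holdout_fraction = holdout_fraction,
         pairwise_iterations = pairwise_iterations,
         classify_age = classify_age, alpha = alpha, seed = seed,
         schema = "flyssvep-config-v1"),
    class = "ssvep_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' @param config An [run_config()] object.
#' @param path YAML file path.
#' @return `save_config`: `path` invisibly; `load_config`: the config.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "flyssvep-config-v1")) {
    stopf("'%s' is not a flyssvep-config-v1 file", path)
  }
  do.call(run_config, raw[setdiff(names(raw), "schema")])
}

write_table_csv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> extract -> stats -> classify, writing
#' `profiles.csv`, `pca.csv`, `anova.csv`, `simple_effects.csv`,
#' `classification.json`, and `manifest.json` into `out_dir`. Stages
#' whose preconditions the design cannot meet (e.g. a single-genotype
#' design has no factorial ANOVA or classifier) are skipped and recorded
#' as such in the manifest.
#'
#' @param config An [run_config()] object.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory artifacts (`profiles`,
#'   `pca`, `anova`, `simple_effects`, `classification`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "ssvep_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- pipeline_stage("grid", build_stimulus_grid(
    config$frequencies, config$contrasts, seed = config$seed))
  design <- pipeline_stage("design", cohort_design(
    ages = config$ages, flies_per_cell = config$flies_per_cell,
    repeats_per_condition = config$repeats_per_condition,
    stress = config$stress, seed = config$seed))
  cohort <- pipeline_stage("simulate", simulate_cohort(design, grid,
                                                       materialize = FALSE))
  profiles <- pipeline_stage("extract", build_profiles(cohort,
                                                       discard = config$discard))
  write_profiles(profiles, file.path(out_dir, "profiles.csv"))

  skipped <- character(0)
  pca <- anova_tab <- se_tab <- NULL
  if (nrow(profiles) >= 2L) {
    pca <- pipeline_stage("pca", pca_fit(profiles))
    pca_df <- data.frame(condition = rownames(pca$loadings),
                         pc1_loading = pca$loadings[, 1L])
    write_table_csv(pca_df, file.path(out_dir, "pca.csv"))
  } else skipped <- c(skipped, "pca")

  n_geno <- length(unique(profiles$genotype))
  n_ages <- length(unique(profiles$age_days))
  if (!is.null(pca) && n_geno >= 2L && n_ages >= 2L) {
    score <- pca$scores[, 1L]
    anova_tab <- pipeline_stage("anova", two_way_anova(
      score, profiles$genotype, profiles$age_days))
    se_tab <- pipeline_stage("simple_effects", simple_effects_sidak(
      score, factor(profiles$age_days), factor(profiles$genotype),
      stratify_on = "A", alpha = config$alpha))
    write_table_csv(anova_tab, file.path(out_dir, "anova.csv"))
    write_table_csv(se_tab, file.path(out_dir, "simple_effects.csv"))
  } else if (!is.null(pca) && n_geno >= 2L) {
    anova_tab <- pipeline_stage("anova", one_way_anova(
      pca$scores[, 1L], profiles$genotype))
    write_table_csv(anova_tab, file.path(out_dir, "anova.csv"))
    skipped <- c(skipped, "simple_effects")
  } else skipped <- c(skipped, "anova", "simple_effects")

  classification <- NULL
  if (!is.null(config$classify_age) && n_geno >= 2L) {
    at_age <- profiles[profiles$age_days == config$classify_age, ]
    if (nrow(at_age) && all(table(at_age$genotype) >= 3L)) {
      xm <- profile_matrix(at_age)
      yv <- at_age$genotype
      classification <- pipeline_stage("classify", {
        loo <- loo_accuracy(xm, yv, shrinkage = config$shrinkage)
        mc <- monte_carlo_accuracy(xm, yv, iterations = config$mc_iterations,
                                   holdout_fraction = config$holdout_fraction,
                                   shrinkage = config$shrinkage,
                                   seed = config$seed)
        conf <- nway_confusion(xm, yv, scheme = "loo",
                               shrinkage = config$shrinkage)
        genos <- sort(unique(yv))
        pairs <- utils::combn(genos, 2L)
        pw <- lapply(seq_len(ncol(pairs)), function(j) {
          r <- pairwise_bootstrap(xm, yv, pairs[1L, j], pairs[2L, j],
                                  iterations = config$pairwise_iterations,
                                  shrinkage = config$shrinkage,
                                  seed = config$seed + j)
          list(class_a = r$class_a, class_b = r$class_b,
               mean_accuracy = r$mean_accuracy,
               significant = r$significant)
        })
        list(age_days = config$classify_age,
             loo_accuracy = as.numeric(loo),
             mc_mean_accuracy = mc$mean_accuracy,
             confusion_normalized = conf$normalized,
             pairwise = pw,
             shrinkage = config$shrinkage,
             seed = config$seed)
      })
      jsonlite::write_json(
        classification, file.path(out_dir, "classification.json"),
        auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    } else skipped <- c(skipped, "classify")
  } else skipped <- c(skipped, "classify")

  manifest <- list(
    schema = "flyssvep-manifest-v1",
    package_version = as.character(utils::packageVersion("flyssvep")),
    config = unclass(config),
    n_flies = nrow(profiles),
    n_conditions = nrow(grid$conditions),
    n_trials = nrow(profiles) * nrow(grid$conditions) *
      config$repeats_per_condition,
    skipped_stages = as.list(skipped),
    artifacts = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(profiles = profiles, pca = pca, anova = anova_tab,
                 simple_effects = se_tab, classification = classification,
                 manifest = manifest))
}

#' Mean response-amplitude heat maps by group
#'
#' One frequency x contrast heat map of mean second-harmonic amplitude
#' per group, on a shared colour scale so groups are visually
#' comparable.
#'
#' @param profiles An `ssvep_profiles` table.
#' @param group_by Grouping column (default `"genotype"`).
#' @param out_dir Optional directory; if given, one PNG per group is
#'   written.
#' @return Named list of ggplot objects (one per non-empty group).
#' @export
render_heatmap <- function(profiles, group_by = "genotype", out_dir = NULL) {
  stopifnot(group_by %in% names(profiles))
  grid <- attr(profiles, "grid")
  if (is.null(grid)) stopf("profiles carry no grid attribute")
  amp <- profile_matrix(profiles)
  groups <- unique(as.character(profiles[[group_by]]))
  means <- lapply(groups, function(g) {
    rows <- profiles[[group_by]] == g
    if (!any(rows)) return(NULL)
    colMeans(amp[rows, , drop = FALSE])
  })
  names(means) <- groups
  keep <- !vapply(means, is.null, TRUE)
  if (any(!keep)) warnf("empty group(s) skipped: %s",
                        paste(groups[!keep], collapse = ", "))
  means <- means[keep]
  lims <- range(unlist(means))
  plots <- lapply(names(means), function(g) {
    df <- cbind(grid$conditions, amplitude = means[[g]])
    ggplot2::ggplot(df, ggplot2::aes(
      x = factor(.data$contrast_pct),
      y = factor(.data$frequency_hz),
      fill = .data$amplitude)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(limits = lims, name = "2f amplitude\n(µV)") +
      ggplot2::labs(title = g, x = "Michelson contrast (%)",
                    y = "Temporal frequency (Hz)") +
      ggplot2::theme_minimal()
  })
  names(plots) <- names(means)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in names(plots)) {
      ggplot2::ggsave(file.path(out_dir, sprintf("heatmap_%s.png", gsub("[^A-Za-z0-9_-]", "_", g))),
                      plots[[g]], width = 5, height = 4, dpi = 150)
    }
  }
  plots
}

#' @importFrom ggplot2 .data
NULL
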