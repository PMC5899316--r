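# Synthetic ERG trial and cohort generation.
#
# A trial is a stimulus-locked voltage time series: a dominant second
# harmonic at 2f (two contrast reversals per stimulus cycle), attenuated
# higher even harmonics, a small F1 leak at the input frequency, and
# additive phase-random noise. Harmonic phases depend only on the
# stimulus phase, so repeats of a condition are coherent while noise is
# not -- the property coherent averaging exploits.

#' Simulate one stimulus-locked ERG trial
#'
#' @param condition Single-row data frame or list with `frequency_hz` and
#'   `contrast_pct`.
#' @param phenotype A [genotype_phenotype()].
#' @param age_days Age in days (a key of the phenotype's `gain_by_age`).
#' @param stress Logical; photic-stress condition?
#' @param seed Integer seed driving the noise realization only; the
#'   deterministic harmonic content is seed-independent.
#' @param sample_rate Sampling rate in Hz. Must exceed twice the highest
#'   generated harmonic.
#' @param duration Trial duration in seconds (default 11 s: a 1 s onset
#'   window to discard plus a 10 s analysis window).
#' @param stimulus_phase Stimulus phase in radians at trial onset; shared
#'   across repeats of a condition.
#' @param n_even_harmonics Number of even harmonics generated (2f, 4f, ...).
#' @param fly_gain Extra multiplicative gain (per-fly variability).
#' @return An object of class `ssvep_trial`: `samples` (numeric vector),
#'   `sample_rate`, `duration`, `condition`, `stimulus_phase`, `seed`, and
#'   the noiseless second-harmonic `amplitude`.
#' @examples
#' ph <- default_phenotypes()$control
#' tr <- simulate_trial(list(frequency_hz = 8, contrast_pct = 99), ph,
#'                      age_days = 1, seed = 42)
#' length(tr$samples)  # 720 Hz x 11 s
#' @export
simulate_trial <- function(condition, phenotype, age_days, stress = FALSE,
                           seed = 1L, sample_rate = 720, duration = 11,
                           stimulus_phase = 0, n_even_harmonics = 4,
                           fly_gain = 1) {
  stopifnot(is_count(n_even_harmonics), sample_rate > 0, duration > 0)
  f <- condition$frequency_hz
  harmonics <- 2 * f * seq_len(n_even_harmonics)
  nyquist <- sample_rate / 2
  if (max(harmonics) >= nyquist) {
    stopf("harmonic %g Hz violates the Nyquist limit %g Hz at sample rate %g Hz",
          min(harmonics[harmonics >= nyquist]), nyquist, sample_rate)
  }
  amp <- contrast_response_gain(condition, phenotype, age_days, stress) * fly_gain
  n <- round(sample_rate * duration)
  t <- (seq_len(n) - 1) / sample_rate
  samples <- phenotype$f1_leak_fraction * amp *
    sin(2 * pi * f * t + stimulus_phase)
  for (h in seq_len(n_even_harmonics)) {
    samples <- samples + amp * phenotype$harmonic_rolloff^(h - 1) *
      sin(2 * pi * harmonics[h] * t + stimulus_phase)
  }
  if (phenotype$noise_sd > 0) {
    samples <- samples + with_seed(seed, stats::rnorm(n, 0, phenotype$noise_sd))
  }
  structure(
    list(samples = samples,
         sample_rate = sample_rate,
         duration = duration,
         condition = list(frequency_hz = f, contrast_pct = condition$contrast_pct),
         stimulus_phase = stimulus_phase,
         seed = as.integer(seed),
         amplitude = amp),
    class = "ssvep_trial"
  )
}

#' Describe a simulated cohort design
#'
#' The default design mirrors the full study: 5 genotypes x 5 ages
#' (1, 7, 14, 21, 28 days) x 10 flies per cell (N = 250), with 3 repeats
#' of every grid condition per fly. The photic-stress design is a
#' single-age (7 day) design with the `stress` flag set.
#'
#' @param genotypes Named list of [genotype_phenotype()] objects.
#' @param ages Ages in days.
#' @param flies_per_cell Flies per genotype-by-age cell (>= 1).
#' @param repeats_per_condition Presentations of each condition per fly.
#' @param stress Logical; photic-stress rearing condition.
#' @param seed Root seed; all per-fly streams derive from it.
#' @param fly_gain_sd Log-scale SD of the lognormal per-fly gain jitter.
#' @return An object of class `ssvep_design`.
#' @export
cohort_design <- function(genotypes = default_phenotypes(),
                          ages = c(1, 7, 14, 21, 28),
                          flies_per_cell = 10,
                          repeats_per_condition = 3,
                          stress = FALSE,
                          seed = 1L,
                          fly_gain_sd = 0.25) {
  if (!length(genotypes) || !all(vapply(genotypes, inherits, TRUE, "ssvep_phenotype"))) {
    stopf("`genotypes` must be a non-empty list of phenotype objects")
  }
  if (is.null(names(genotypes))) {
    names(genotypes) <- vapply(genotypes, `[[`, "", "label")
  }
  if (!length(ages) || anyDuplicated(ages)) stopf("`ages` must be distinct and non-empty")
  if (!is_count(flies_per_cell)) stopf("`flies_per_cell` must be a positive integer")
  if (!is_count(repeats_per_condition)) stopf("`repeats_per_condition` must be a positive integer")
  if (fly_gain_sd < 0) stopf("`fly_gain_sd` must be >= 0")
  structure(
    list(genotypes = genotypes, ages = as.numeric(ages),
         flies_per_cell = as.integer(flies_per_cell),
         repeats_per_condition = as.integer(repeats_per_condition),
         stress = isTRUE(stress), seed = as.integer(seed),
         fly_gain_sd = fly_gain_sd),
    class = "ssvep_design"
  )
}

#' Photic-stress variant of the default design
#'
#' @inheritParams cohort_design
#' @param stress Logical; set `FALSE` for the matched unstressed cohort.
#' @export
stress_design <- function(genotypes = default_phenotypes(),
                          flies_per_cell = 10, stress = TRUE, seed = 1L, ...) {
  cohort_design(genotypes = genotypes, ages = 7,
                flies_per_cell = flies_per_cell, stress = stress,
                seed = seed, ...)
}

# Per-fly derived quantities. Every random quantity a fly owns (gain
# jitter, per-condition stimulus phases, per-trial noise seeds) comes from
# its own stream, so a fly is reproducible in isolation.
fly_draws <- function(fly_seed, n_conditions, repeats, fly_gain_sd) {
  with_seed(fly_seed, {
    gain <- stats::rlnorm(1, 0, fly_gain_sd)
    phases <- stats::runif(n_conditions, 0, 2 * pi)
    trial_seeds <- sample.int(.Machine$integer.max - 1L,
                              n_conditions * repeats)
    list(gain = gain, phases = phases,
         trial_seeds = matrix(trial_seeds, nrow = n_conditions))
  })
}

#' Simulate a cohort of flies over a stimulus grid
#'
#' Produces one fly record per (genotype, age, replicate) cell, each with
#' `repeats_per_condition` trials per grid condition. Per-fly lognormal
#' gain jitter creates between-fly variance. Fully reproducible from
#' `design$seed`; each fly additionally carries its own derived seed so
#' its raw trials can be regenerated in isolation.
#'
#' For large designs the raw sample arrays are not retained in memory
#' (`materialize = FALSE`); [fly_trials()] regenerates them on demand,
#' which is how [build_profiles()] consumes a cohort.
#'
#' @param design A [cohort_design()].
#' @param grid A [build_stimulus_grid()] object.
#' @param materialize Logical; keep raw trial objects in the cohort?
#'   Default: yes for designs up to 2000 trials.
#' @return An object of class `ssvep_cohort`: the `design`, `grid`, a
#'   `flies` data frame (fly_id, genotype, age_days, stress, fly_seed,
#'   fly_gain), and `trials` (a list of per-fly trial lists, or NULL).
#' @export
simulate_cohort <- function(design, grid, materialize = NULL) {
  stopifnot(inherits(design, "ssvep_design"), inherits(grid, "ssvep_grid"))
  n_cond <- nrow(grid$conditions)
  if (n_cond == 0L) stopf("`grid` has no conditions")
  cells <- expand.grid(replicate = seq_len(design$flies_per_cell),
                       age_days = design$ages,
                       genotype = names(design$genotypes),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_fly <- nrow(cells)
  fly_seeds <- derive_seeds(design$seed, n_fly)
  flies <- data.frame(
    fly_id = sprintf("%s_age%02d_fly%02d", cells$genotype,
                     as.integer(cells$age_days), cells$replicate),
    genotype = cells$genotype,
    age_days = cells$age_days,
    stress = design$stress,
    fly_seed = fly_seeds,
    fly_gain = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_fly)) {
    flies$fly_gain[i] <- fly_draws(fly_seeds[i], n_cond,
                                   design$repeats_per_condition,
                                   design$fly_gain_sd)$gain
  }
  n_trials <- n_fly * n_cond * design$repeats_per_condition
  if (is.null(materialize)) materialize <- n_trials <= 2000L
  cohort <- structure(
    list(design = design, grid = grid, flies = flies, trials = NULL),
    class = "ssvep_cohort"
  )
  if (materialize) {
    cohort$trials <- lapply(seq_len(n_fly), function(i) fly_trials(cohort, i))
  }
  cohort
}

#' Regenerate (or retrieve) the raw trials of one fly in a cohort
#'
#' @param cohort An [simulate_cohort()] object.
#' @param fly Fly index or `fly_id` string.
#' @return A list with one element per grid condition (canonical order),
#'   each a list of `repeats_per_condition` `ssvep_trial` objects.
#' @export
fly_trials <- function(cohort, fly) {
  stopifnot(inherits(cohort, "ssvep_cohort"))
  i <- if (is.character(fly)) match(fly, cohort$flies$fly_id) else as.integer(fly)
  if (is.na(i) || i < 1L || i > nrow(cohort$flies)) stopf("unknown fly: %s", format(fly))
  if (!is.null(cohort$trials)) return(cohort$trials[[i]])
  design <- cohort$design
  grid <- cohort$grid
  row <- cohort$flies[i, ]
  phenotype <- design$genotypes[[row$genotype]]
  draws <- fly_draws(row$fly_seed, nrow(grid$conditions),
                     design$repeats_per_condition, design$fly_gain_sd)
  lapply(seq_len(nrow(grid$conditions)), function(k) {
    cond <- grid$conditions[k, ]
    lapply(seq_len(design$repeats_per_condition), function(r) {
      tr <- simulate_trial(cond, phenotype, row$age_days, row$stress,
                           seed = draws$trial_seeds[k, r],
                           stimulus_phase = draws$phases[k],
                           fly_gain = draws$gain)
      tr$fly_id <- row$fly_id
      tr$trial_index <- r
      tr
    })
  })
}

#' @export
print.ssvep_cohort <- function(x, ...) {
  cat(sprintf("<ssvep_cohort> %d flies (%d genotypes x %d ages x %d), %d conditions x %d repeats%s\n",
              nrow(x$flies), length(x$design$genotypes), length(x$design$ages),
              x$design$flies_per_cell, nrow(x$grid$conditions),
              x$design$repeats_per_condition,
              if (x$design$stress) ", photic stress" else ""))
  invisible(x)
}
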