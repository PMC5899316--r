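# Genotype phenotypes: parametric response surfaces for the simulator.
#
# Each phenotype is a Naka-Rushton contrast saturation crossed with a
# log-Gaussian temporal-frequency tuning curve, scaled by an age-specific
# gain. The functional form is a modelling choice; the parameter values
# encode the cohort structure of the study design (day-1 gain elevation in
# the early-onset mutants, the control day-1 to day-7 amplitude increase,
# and strong attenuation of the disease genotypes under photic stress).

#' Construct a genotype phenotype for the ERG simulator
#'
#' @param label Genotype label (single string).
#' @param gain_by_age Named numeric vector mapping age in days (names) to a
#'   dimensionless multiplicative response gain.
#' @param c50 Semi-saturation Michelson contrast in percent, in (0, 100).
#' @param crf_exponent Naka-Rushton exponent (dimensionless, > 0).
#' @param tuning_peak_hz Peak of the temporal-frequency tuning curve in Hz,
#'   within \[1, 36\].
#' @param tuning_bandwidth_oct Tuning bandwidth (log-Gaussian sigma) in
#'   octaves.
#' @param f1_leak_fraction Fraction of the second-harmonic amplitude leaking
#'   into the stimulus fundamental F1 (residual photoreceptor asymmetry),
#'   in \[0, 1).
#' @param harmonic_rolloff Per-step attenuation of successive even
#'   harmonics (4f, 6f, ... scaled by powers of this factor), >= 0.
#' @param stress_attenuation Multiplicative amplitude factor applied under
#'   the photic-stress condition, >= 0.
#' @param noise_sd Additive white-noise standard deviation per sample, in
#'   the same (nominally microvolt) units as the signal.
#' @param amplitude_scale Overall response scale in microvolts: the
#'   amplitude of a unit-gain response at full contrast and peak tuning.
#' @return An object of class `ssvep_phenotype`.
#' @seealso [default_phenotypes()], [contrast_response_gain()]
#' @export
genotype_phenotype <- function(label,
                               gain_by_age,
                               c50 = 25,
                               crf_exponent = 2,
                               tuning_peak_hz = 7,
                               tuning_bandwidth_oct = 1.5,
                               f1_leak_fraction = 0.2,
                               harmonic_rolloff = 0.3,
                               stress_attenuation = 1,
                               noise_sd = 45,
                               amplitude_scale = 30) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stopf("`label` must be a single non-empty string")
  }
  if (is.null(names(gain_by_age)) || anyNA(suppressWarnings(as.numeric(names(gain_by_age))))) {
    stopf("`gain_by_age` must be a numeric vector named by age in days")
  }
  if (any(gain_by_age < 0)) stopf("age gains must be >= 0")
  if (!(c50 > 0 && c50 < 100)) stopf("`c50` must lie in (0, 100), got %g", c50)
  if (crf_exponent <= 0) stopf("`crf_exponent` must be positive")
  if (tuning_peak_hz < 1 || tuning_peak_hz > 36) {
    stopf("`tuning_peak_hz` must lie in [1, 36], got %g", tuning_peak_hz)
  }
  if (tuning_bandwidth_oct <= 0) stopf("`tuning_bandwidth_oct` must be positive")
  if (f1_leak_fraction < 0 || f1_leak_fraction >= 1) {
    stopf("`f1_leak_fraction` must lie in [0, 1)")
  }
  if (harmonic_rolloff < 0) stopf("`harmonic_rolloff` must be >= 0")
  if (stress_attenuation < 0) stopf("`stress_attenuation` must be >= 0")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (amplitude_scale <= 0) stopf("`amplitude_scale` must be positive")
  structure(
    list(label = label,
         gain_by_age = gain_by_age,
         c50 = c50,
         crf_exponent = crf_exponent,
         tuning_peak_hz = tuning_peak_hz,
         tuning_bandwidth_oct = tuning_bandwidth_oct,
         f1_leak_fraction = f1_leak_fraction,
         harmonic_rolloff = harmonic_rolloff,
         stress_attenuation = stress_attenuation,
         noise_sd = noise_sd,
         amplitude_scale = amplitude_scale),
    class = "ssvep_phenotype"
  )
}

#' Default genotype phenotypes of the simulated cohort
#'
#' Five phenotypes mirroring the study design: a wild-type control
#' (`control`, the white-eyed reference strain role), three early-onset
#' Parkinson's disease loss-of-function models (`EOPD-A`, `EOPD-B`,
#' `EOPD-C`, filling the DJ-1alpha, DJ-1beta, and PINK1 roles), and a
#' kinase knockout (`kinase-null`, the dLRRK role) without day-1 gain
#' elevation.
#'
#' The age-gain trajectories encode: a twofold day-1 amplitude elevation
#' of all three EOPD phenotypes over control; a control amplitude increase
#' from day 1 to day 7 (visual maturation); and broadly comparable
#' amplitudes across genotypes at later ages with subtle per-genotype
#' differences in contrast saturation and temporal tuning that support
#' multivariate classification. Under photic stress the disease
#' phenotypes attenuate to 0.35-0.45 of their unstressed amplitude
#' (at least a 50% reduction); the control is unaffected.
#'
#' @return Named list of [genotype_phenotype()] objects.
#' @export
default_phenotypes <- function() {
  list(
    control = genotype_phenotype(
      "control",
      gain_by_age = c(`1` = 1.0, `7` = 2.0, `14` = 2.0, `21` = 2.1, `28` = 2.0),
      c50 = 25, tuning_peak_hz = 7.0, tuning_bandwidth_oct = 1.5,
      stress_attenuation = 1.0),
    `EOPD-A` = genotype_phenotype(
      "EOPD-A",
      gain_by_age = c(`1` = 2.0, `7` = 2.0, `14` = 1.7, `21` = 1.8, `28` = 1.6),
      c50 = 22, tuning_peak_hz = 6.5, tuning_bandwidth_oct = 1.4,
      stress_attenuation = 0.40),
    `EOPD-B` = genotype_phenotype(
      "EOPD-B",
      gain_by_age = c(`1` = 2.0, `7` = 1.9, `14` = 2.4, `21` = 2.4, `28` = 2.3),
      c50 = 28, tuning_peak_hz = 7.5, tuning_bandwidth_oct = 1.6,
      stress_attenuation = 0.35),
    `EOPD-C` = genotype_phenotype(
      "EOPD-C",
      gain_by_age = c(`1` = 2.0, `7` = 2.2, `14` = 1.9, `21` = 1.8, `28` = 2.1),
      c50 = 25, tuning_peak_hz = 8.0, tuning_bandwidth_oct = 1.5,
      stress_attenuation = 0.40),
    `kinase-null` = genotype_phenotype(
      "kinase-null",
      gain_by_age = c(`1` = 1.0, `7` = 1.7, `14` = 1.7, `21` = 1.8, `28` = 1.8),
      c50 = 26, tuning_peak_hz = 7.2, tuning_bandwidth_oct = 1.5,
      stress_attenuation = 0.45)
  )
}

phenotype_age_gain <- function(phenotype, age_days) {
  key <- as.character(age_days)
  if (!key %in% names(phenotype$gain_by_age)) {
    stopf("age %s days has no defined gain for phenotype '%s' (defined ages: %s); age interpolation is not performed",
          format(age_days), phenotype$label,
          paste(names(phenotype$gain_by_age), collapse = ", "))
  }
  unname(phenotype$gain_by_age[[key]])
}

#' Noise-free response amplitude for one stimulus condition
#'
#' The deterministic second-harmonic amplitude a phenotype produces for a
#' given condition: a Naka-Rushton contrast term
#' \eqn{c^n / (c^n + c_{50}^n)} times a log-Gaussian temporal-frequency
#' tuning term \eqn{\exp(-\log_2(f/f_{peak})^2 / (2\sigma^2))}, scaled by
#' the phenotype's age gain, overall amplitude scale, and (under photic
#' stress) its stress attenuation.
#'
#' The amplitude is strictly increasing in contrast at fixed frequency,
#' equals half its saturated value at `c = c50`, and over the default grid
#' attains its maximum at the highest contrast and the frequency bin
#' nearest the tuning peak.
#'
#' @param condition A single-row data frame or list with `frequency_hz`
#'   and `contrast_pct`, or a row index of `grid`.
#' @param phenotype A [genotype_phenotype()].
#' @param age_days Age in days; must be a key of the phenotype's
#'   `gain_by_age` (no interpolation).
#' @param stress Logical; apply the photic-stress attenuation?
#' @return Amplitude in microvolts (scalar, vectorized over conditions).
#' @export
contrast_response_gain <- function(condition, phenotype, age_days,
                                   stress = FALSE) {
  stopifnot(inherits(phenotype, "ssvep_phenotype"))
  f <- condition$frequency_hz
  c_pct <- condition$contrast_pct
  if (any(f <= 0) || any(c_pct < 0) || any(c_pct > 100)) {
    stopf("invalid stimulus condition: f = %s Hz, c = %s%%",
          paste(f, collapse = ","), paste(c_pct, collapse = ","))
  }
  gain <- phenotype_age_gain(phenotype, age_days)
  n <- phenotype$crf_exponent
  crf <- c_pct^n / (c_pct^n + phenotype$c50^n)
  tuning <- exp(-log2(f / phenotype$tuning_peak_hz)^2 /
                  (2 * phenotype$tuning_bandwidth_oct^2))
  att <- if (isTRUE(stress)) phenotype$stress_attenuation else 1
  phenotype$amplitude_scale * gain * crf * tuning * att
}

#' Noise-free response surface of a phenotype over a stimulus grid
#'
#' @param grid A [build_stimulus_grid()] object.
#' @inheritParams contrast_response_gain
#' @return Numeric vector of amplitudes in canonical grid order.
#' @export
response_surface <- function(grid, phenotype, age_days, stress = FALSE) {
  contrast_response_gain(grid$conditions, phenotype, age_days, stress)
}
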