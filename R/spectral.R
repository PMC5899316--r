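# Frequency-domain analysis: discrete Fourier transform of trials,
# coherent (complex) averaging across repeats, and second-harmonic
# amplitude extraction.
#
# Amplitude convention: a pure sinusoid of peak amplitude A, at a
# frequency that is an exact bin of the analysis window, yields a
# coefficient of modulus A at its bin. The analysis window is rectangular
# (no taper): every stimulus frequency and its harmonics are designed to
# fall exactly on bins, so leakage is zero and a taper would only bias
# amplitudes. The mean (DC) is removed before transforming.

#' Discrete Fourier spectrum of one trial
#'
#' Discards the leading `discard` seconds (onset transients), removes the
#' mean, and transforms the remaining window. Bin spacing is
#' `1 / window_length` (0.1 Hz for the default 10 s window).
#'
#' @param trial An `ssvep_trial` (any object with `samples`,
#'   `sample_rate`, `duration`).
#' @param discard Seconds to discard at trial onset (default 1).
#' @return An object of class `ssvep_spectrum`: `frequencies` (Hz, all
#'   positive bins up to Nyquist), complex `coefficients` in the peak
#'   amplitude convention, `window_length` (s), `sample_rate`, and
#'   `n_trials_averaged` (1).
#' @examples
#' t <- (0:7199) / 720
#' tr <- list(samples = 3 * sin(2 * pi * 16 * t), sample_rate = 720,
#'            duration = 10)
#' sp <- trial_spectrum(tr, discard = 0)
#' Mod(sp$coefficients[sp$frequencies == 16])  # 3
#' @export
trial_spectrum <- function(trial, discard = 1) {
  fs <- trial$sample_rate
  n_total <- length(trial$samples)
  if (discard < 0 || discard >= trial$duration) {
    stopf("`discard` (%g s) must lie in [0, duration = %g s)", discard, trial$duration)
  }
  n_discard <- discard * fs
  if (abs(n_discard - round(n_discard)) > 1e-9) {
    stopf("discard window (%g s) is not an integer number of samples at %g Hz",
          discard, fs)
  }
  n_discard <- round(n_discard)
  x <- trial$samples[(n_discard + 1L):n_total]
  n <- length(x)
  window_length <- n / fs
  coef <- stats::fft(x - mean(x))
  n_pos <- floor(n / 2)
  k <- seq_len(n_pos)
  structure(
    list(frequencies = k / window_length,
         coefficients = 2 * coef[k + 1L] / n,
         window_length = window_length,
         sample_rate = fs,
         n_trials_averaged = 1L),
    class = "ssvep_spectrum"
  )
}

same_spectral_grid <- function(a, b) {
  isTRUE(all.equal(a$window_length, b$window_length)) &&
    length(a$frequencies) == length(b$frequencies) &&
    isTRUE(all.equal(a$frequencies, b$frequencies))
}

#' Coherently average spectra across repeats
#'
#' Element-wise mean of complex coefficients. Because the evoked response
#' is phase-locked to the stimulus, its coefficients add constructively,
#' while phase-random noise performs a 2-D random walk and its averaged
#' amplitude shrinks as \eqn{1/\sqrt{K}}.
#'
#' @param spectra Non-empty list of `ssvep_spectrum` objects sharing one
#'   frequency grid.
#' @return An `ssvep_spectrum` with `n_trials_averaged` equal to the total
#'   number of trials represented.
#' @export
coherent_average <- function(spectra) {
  if (!length(spectra)) stopf("`spectra` must be non-empty")
  ref <- spectra[[1L]]
  for (s in spectra[-1L]) {
    if (!same_spectral_grid(ref, s)) {
      stopf("spectra have mismatched frequency grids (window %g vs %g s, %d vs %d bins)",
            ref$window_length, s$window_length,
            length(ref$frequencies), length(s$frequencies))
    }
  }
  acc <- Reduce(`+`, lapply(spectra, `[[`, "coefficients"))
  out <- ref
  out$coefficients <- acc / length(spectra)
  out$n_trials_averaged <- sum(vapply(spectra, `[[`, 1L, "n_trials_averaged"))
  out
}

# Bin index of a frequency, erroring if off-grid or beyond Nyquist.
spectrum_bin <- function(spectrum, frequency) {
  k <- frequency * spectrum$window_length
  if (abs(k - round(k)) > 1e-6) {
    stopf("%g Hz does not fall on the %g Hz bin grid of a %g s window",
          frequency, 1 / spectrum$window_length, spectrum$window_length)
  }
  k <- round(k)
  if (k < 1L || k > length(spectrum$frequencies)) {
    stopf("%g Hz is outside the analyzed band (0, %g] Hz", frequency,
          max(spectrum$frequencies))
  }
  k
}

#' Second-harmonic (2f) amplitude of a spectrum
#'
#' The response to a contrast-reversing grating concentrates at even
#' multiples of the input frequency (two reversals per cycle), dominated
#' by 2f; analysis reads the coefficient modulus at exactly twice the
#' input frequency.
#'
#' @param spectrum An `ssvep_spectrum`.
#' @param input_frequency Stimulus input frequency f in Hz; `2 * f` must
#'   fall on the bin grid and below Nyquist.
#' @return Amplitude (coefficient modulus) at 2f.
#' @export
second_harmonic_amplitude <- function(spectrum, input_frequency) {
  Mod(spectrum$coefficients[spectrum_bin(spectrum, 2 * input_frequency)])
}

#' Amplitude at an arbitrary on-grid frequency
#'
#' @inheritParams second_harmonic_amplitude
#' @param frequency Frequency in Hz.
#' @export
amplitude_at <- function(spectrum, frequency) {
  Mod(spectrum$coefficients[spectrum_bin(spectrum, frequency)])
}

#' Build per-fly response profiles from a cohort
#'
#' For each fly and grid condition: coherently average the condition's
#' repeat spectra, then extract the second-harmonic amplitude. The
#' resulting profile vector follows the canonical grid order
#' (frequency-major, ascending contrast).
#'
#' @param cohort An [simulate_cohort()] cohort.
#' @param discard Onset seconds discarded before each transform.
#' @return An object of class `ssvep_profiles`: a data frame with columns
#'   `fly_id`, `genotype`, `age_days`, `stress`, then one `amp_f<F>_c<C>`
#'   column per condition; the grid is attached as attribute `grid`.
#' @export
build_profiles <- function(cohort, discard = 1) {
  stopifnot(inherits(cohort, "ssvep_cohort"))
  grid <- cohort$grid
  n_cond <- nrow(grid$conditions)
  labels <- condition_labels(grid)
  n_fly <- nrow(cohort$flies)
  amps <- matrix(NA_real_, n_fly, n_cond, dimnames = list(NULL, labels))
  for (i in seq_len(n_fly)) {
    trials <- fly_trials(cohort, i)
    if (length(trials) != n_cond || any(!vapply(trials, length, 1L))) {
      stopf("fly %s is missing trials for one or more conditions",
            cohort$flies$fly_id[i])
    }
    for (k in seq_len(n_cond)) {
      avg <- coherent_average(lapply(trials[[k]], trial_spectrum, discard = discard))
      amps[i, k] <- second_harmonic_amplitude(avg, grid$conditions$frequency_hz[k])
    }
  }
  out <- cbind(cohort$flies[, c("fly_id", "genotype", "age_days", "stress")],
               as.data.frame(amps, check.names = FALSE))
  rownames(out) <- NULL
  structure(out, grid = grid, class = c("ssvep_profiles", "data.frame"))
}

#' Extract the amplitude matrix from a profile table
#'
#' @param profiles An `ssvep_profiles` table (or any data frame with
#'   `amp_*` columns).
#' @return Numeric matrix, flies x conditions, in canonical grid order.
#' @export
profile_matrix <- function(profiles) {
  cols <- grep("^amp_f", names(profiles), value = TRUE)
  if (!length(cols)) stopf("no amplitude (amp_f*_c*) columns found")
  as.matrix(as.data.frame(profiles)[, cols, drop = FALSE])
}

PROFILE_SCHEMA <- "flyssvep-profiles-v1"

#' Write a profile table to CSV
#'
#' Plain CSV with a one-line schema header comment, fixed column order,
#' and repr-stable full-precision numbers, so identical profiles yield
#' byte-identical files.
#'
#' @param profiles An `ssvep_profiles` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", PROFILE_SCHEMA), con)
  df <- as.data.frame(profiles)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "age_days"
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profile table written by [write_profiles()]
#'
#' @param path CSV path.
#' @return An `ssvep_profiles` data frame. The attached grid is
#'   reconstructed from the column labels (canonical order assumed).
#' @export
read_profiles <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl(PROFILE_SCHEMA, header, fixed = TRUE)) {
    stopf("'%s' does not carry the %s schema header", path, PROFILE_SCHEMA)
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  cols <- grep("^amp_f", names(df), value = TRUE)
  cond <- parse_condition_labels(cols)
  grid <- build_stimulus_grid(sort(unique(cond$frequency_hz)),
                              sort(unique(cond$contrast_pct)))
  want <- condition_labels(grid)
  if (!identical(sort(want), sort(cols))) {
    stopf("profile columns do not form a complete frequency x contrast grid")
  }
  out <- cbind(df[, c("fly_id", "genotype", "age_days", "stress")],
               df[, want, drop = FALSE])
  out$stress <- as.logical(out$stress)
  structure(out, grid = grid, class = c("ssvep_profiles", "data.frame"))
}
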