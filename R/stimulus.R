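# Stimulus grid: the temporal-frequency x Michelson-contrast sweep.

#' Default temporal frequencies of the stimulus sweep (Hz)
#'
#' Eight temporal frequencies of the contrast-reversing grating.
#'
#' @return Numeric vector of frequencies in Hz.
#' @export
default_frequencies <- function() c(1, 2, 4, 6, 8, 12, 18, 36)

#' Default Michelson contrast levels of the stimulus sweep (percent)
#'
#' Eight contrast levels. The published protocol lists seven values
#' (1, 4, 8, 16, 32, 64, 99) for an eight-level sweep; a 2% level is
#' inserted between 1% and 4% to complete the approximately geometric
#' series. Override via [build_stimulus_grid()] if another completion is
#' preferred.
#'
#' @return Numeric vector of contrasts in percent.
#' @export
default_contrasts <- function() c(1, 2, 4, 8, 16, 32, 64, 99)

validate_condition_values <- function(frequencies, contrasts) {
  if (length(frequencies) == 0L) stopf("`frequencies` must be non-empty")
  if (length(contrasts) == 0L) stopf("`contrasts` must be non-empty")
  if (anyNA(frequencies) || anyNA(contrasts)) {
    stopf("stimulus values must not contain NA")
  }
  if (any(frequencies <= 0)) {
    stopf("temporal frequencies must be positive, got %s",
          paste(frequencies[frequencies <= 0], collapse = ", "))
  }
  if (any(contrasts <= 0 | contrasts > 100)) {
    stopf("Michelson contrasts must lie in (0, 100], got %s",
          paste(contrasts[contrasts <= 0 | contrasts > 100], collapse = ", "))
  }
  if (anyDuplicated(frequencies)) stopf("duplicate temporal frequencies")
  if (anyDuplicated(contrasts)) stopf("duplicate contrast levels")
  invisible(TRUE)
}

#' Build a temporal-contrast stimulus grid
#'
#' Forms the Cartesian product of temporal frequencies and Michelson
#' contrasts, in canonical order (frequency-major, ascending contrast
#' within each frequency), together with a seeded random presentation
#' order. The default arguments give the 8 x 8 = 64-condition sweep.
#'
#' @param frequencies Temporal frequencies in Hz (positive, distinct).
#' @param contrasts Michelson contrasts in percent, in (0, 100], distinct.
#' @param seed Integer seed for the random presentation order.
#' @return An object of class `ssvep_grid`: a list with `conditions`
#'   (data frame of `frequency_hz`, `contrast_pct` in canonical order),
#'   `presentation_order` (permutation of condition indices),
#'   `frequencies`, and `contrasts`.
#' @examples
#' grid <- build_stimulus_grid()
#' nrow(grid$conditions)  # 64
#' @export
build_stimulus_grid <- function(frequencies = default_frequencies(),
                                contrasts = default_contrasts(),
                                seed = 1L) {
  frequencies <- sort(as.numeric(frequencies))
  contrasts <- sort(as.numeric(contrasts))
  validate_condition_values(frequencies, contrasts)
  conditions <- expand.grid(contrast_pct = contrasts,
                            frequency_hz = frequencies,
                            KEEP.OUT.ATTRS = FALSE)[, c(2L, 1L)]
  rownames(conditions) <- NULL
  order <- with_seed(seed, sample.int(nrow(conditions)))
  structure(
    list(conditions = conditions,
         presentation_order = order,
         frequencies = frequencies,
         contrasts = contrasts),
    class = "ssvep_grid"
  )
}

#' @export
print.ssvep_grid <- function(x, ...) {
  cat(sprintf("<ssvep_grid> %d conditions: %d frequencies x %d contrasts\n",
              nrow(x$conditions), length(x$frequencies), length(x$contrasts)))
  cat("  frequencies (Hz):", paste(x$frequencies, collapse = ", "), "\n")
  cat("  contrasts (%):  ", paste(x$contrasts, collapse = ", "), "\n")
  invisible(x)
}

# Stable per-condition column labels for the profile table schema,
# e.g. "amp_f8_c99"; fractional values keep their decimal point.
condition_labels <- function(grid) {
  fmt <- function(v) {
    s <- format(v, trim = TRUE, scientific = FALSE)
    frac <- grepl(".", s, fixed = TRUE)
    s[frac] <- sub("\\.$", "", sub("0+$", "", s[frac]))
    s
  }
  sprintf("amp_f%s_c%s",
          fmt(grid$conditions$frequency_hz),
          fmt(grid$conditions$contrast_pct))
}

# Invert a profile column label back to its (frequency, contrast) pair.
parse_condition_labels <- function(labels) {
  m <- regmatches(labels, regexec("^amp_f([0-9.]+)_c([0-9.]+)$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stopf("malformed condition label(s): %s",
                      paste(labels[bad], collapse = ", "))
  data.frame(frequency_hz = as.numeric(vapply(m, `[`, "", 2L)),
             contrast_pct = as.numeric(vapply(m, `[`, "", 3L)))
}

# Index of one (f, c) condition within the canonical grid order.
condition_index <- function(grid, frequency_hz, contrast_pct) {
  i <- which(abs(grid$conditions$frequency_hz - frequency_hz) < 1e-9 &
               abs(grid$conditions$contrast_pct - contrast_pct) < 1e-9)
  if (length(i) != 1L) {
    stopf("condition (%g Hz, %g%%) not present in grid", frequency_hz, contrast_pct)
  }
  i
}
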