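test_that("a single-bin sinusoid is recovered at peak amplitude", {
  fs <- 720
  t <- (0:7199) / fs
  tr <- list(samples = 3 * sin(2 * pi * 16 * t), sample_rate = fs,
             duration = 10)
  sp <- trial_spectrum(tr, discard = 0)
  expect_equal(amplitude_at(sp, 16), 3, tolerance = 1e-9)
  others <- Mod(sp$coefficients[abs(sp$frequencies - 16) > 1e-9])
  expect_lt(max(others), 1e-9)
  # zero signal gives all-zero coefficients
  sp0 <- trial_spectrum(list(samples = numeric(7200), sample_rate = fs,
                             duration = 10), discard = 0)
  expect_equal(max(Mod(sp0$coefficients)), 0)
})

test_that("spectra match an independent quadrature oracle on noisy trials", {
  ph <- test_phenotype(noise_sd = 5)
  tr <- simulate_trial(list(frequency_hz = 8, contrast_pct = 60), ph, 1,
                       seed = 21, stimulus_phase = 1.1)
  sp <- trial_spectrum(tr, discard = 1)
  kept <- tr$samples[721:7920]
  for (f in c(0.3, 8, 16, 24, 32, 100.5)) {
    expect_equal(sp$coefficients[flyssvep:::spectrum_bin(sp, f)],
                 dft_oracle(kept, 720, f), tolerance = 1e-9)
  }
})

test_that("discard handling and off-bin frequencies error cleanly", {
  ph <- test_phenotype()
  tr <- simulate_trial(list(frequency_hz = 8, contrast_pct = 50), ph, 1,
                       seed = 1)
  expect_error(trial_spectrum(tr, discard = 11), "duration")
  sp <- trial_spectrum(tr, discard = 1)
  expect_equal(sp$window_length, 10)
  expect_equal(sp$frequencies[1L] * sp$window_length, 1)  # 0.1 Hz bins
  expect_error(amplitude_at(sp, 16.05), "bin grid")
  expect_error(amplitude_at(sp, 1000), "outside the analyzed band")
})

test_that("coherent averaging is the element-wise complex mean", {
  fs <- 100
  t <- (0:99) / fs
  mk <- function(phase) trial_spectrum(
    list(samples = sin(2 * pi * 10 * t + phase), sample_rate = fs,
         duration = 1), discard = 0)
  s <- mk(0.4)
  # identical spectra average to themselves
  avg <- coherent_average(list(s, s, s))
  expect_equal(avg$coefficients, s$coefficients)
  expect_equal(avg$n_trials_averaged, 3L)
  # equal magnitude, opposite phase cancels to zero
  opp <- coherent_average(list(mk(0), mk(pi)))
  expect_lt(max(Mod(opp$coefficients)), 1e-12)
  # mismatched grids are rejected
  long <- trial_spectrum(list(samples = numeric(200), sample_rate = fs,
                              duration = 2), discard = 0)
  expect_error(coherent_average(list(s, long)), "mismatched")
})

test_that("averaged random-phase amplitude matches the 2-D random-walk oracle", {
  # K unit-amplitude random-phase coefficients average to an expected
  # modulus of sqrt(pi/4)/sqrt(K); Monte Carlo oracle over 10,000 draws.
  set.seed(404)
  k <- 100
  reps <- 10000
  phases <- matrix(stats::runif(reps * k, 0, 2 * pi), reps, k)
  mc <- mean(Mod(rowMeans(exp(1i * phases))))
  expect_equal(mc, sqrt(pi / 4) / sqrt(k), tolerance = 0.02)
})

test_that("second-harmonic extraction reads the 2f bin exactly", {
  fs <- 720
  t <- (0:7199) / fs
  tr <- list(samples = 5 * sin(2 * pi * 16 * t + 0.3), sample_rate = fs,
             duration = 10)
  sp <- trial_spectrum(tr, discard = 0)
  # an 8 Hz stimulus (16 reversals/s) is analyzed at the 16 Hz bin
  expect_equal(second_harmonic_amplitude(sp, 8), 5, tolerance = 1e-9)
  # round trip through the simulator recovers the generator amplitude
  ph <- test_phenotype()
  sim <- simulate_trial(list(frequency_hz = 12, contrast_pct = 75), ph, 7,
                        seed = 2, stimulus_phase = 2.2)
  got <- second_harmonic_amplitude(trial_spectrum(sim, discard = 1), 12)
  expect_equal(got, sim$amplitude, tolerance = 1e-9)
})

test_that("noiseless profiles equal the closed-form response surface", {
  grid <- small_grid()
  ph <- test_phenotype()
  design <- cohort_design(genotypes = list(test = ph), ages = 1,
                          flies_per_cell = 2, repeats_per_condition = 2,
                          seed = 9, fly_gain_sd = 0)
  profiles <- build_profiles(simulate_cohort(design, grid))
  expect_equal(nrow(profiles), 2L)
  surface <- response_surface(grid, ph, 1)
  for (i in 1:2) {
    expect_equal(unname(profile_matrix(profiles)[i, ]), surface,
                 tolerance = 1e-9)
  }
})

test_that("profiles are linear in the trial amplitudes", {
  grid <- small_grid()
  design <- cohort_design(
    genotypes = list(a = test_phenotype("a", amplitude_scale = 10),
                     b = test_phenotype("b", amplitude_scale = 30)),
    ages = 1, flies_per_cell = 1, repeats_per_condition = 2, seed = 4,
    fly_gain_sd = 0)
  pm <- profile_matrix(build_profiles(simulate_cohort(design, grid)))
  expect_equal(unname(pm[2, ]), unname(3 * pm[1, ]), tolerance = 1e-9)
})

test_that("noisy profile bias shrinks as repeats grow", {
  # weak-signal condition (2% contrast): the amplitude estimate is
  # noise-inflated for single trials; coherent averaging removes it
  grid <- build_stimulus_grid(8, 2)
  amps <- vapply(c(1L, 16L), function(reps) {
    design <- cohort_design(
      genotypes = list(a = test_phenotype("a", noise_sd = 40)),
      ages = 1, flies_per_cell = 8, repeats_per_condition = reps,
      seed = 31, fly_gain_sd = 0)
    mean(profile_matrix(build_profiles(simulate_cohort(design, grid))))
  }, 0)
  truth <- response_surface(grid, test_phenotype("a"), 1)
  # averaging more repeats pulls the noise-inflated amplitude toward truth
  expect_lt(abs(amps[2] - truth), abs(amps[1] - truth))
})

test_that("profile tables round-trip through the CSV schema", {
  grid <- small_grid()
  design <- cohort_design(
    genotypes = list(a = test_phenotype("a", noise_sd = 3)),
    ages = 1, flies_per_cell = 2, repeats_per_condition = 2, seed = 12)
  profiles <- build_profiles(simulate_cohort(design, grid))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(profiles, path)
  back <- read_profiles(path)
  expect_equal(profile_matrix(back), profile_matrix(profiles),
               tolerance = 1e-12)
  expect_equal(back$fly_id, profiles$fly_id)
  expect_equal(attr(back, "grid")$conditions, grid$conditions)
  expect_error(read_profiles(withr::local_tempfile(lines = "x,y")), "schema")
})
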