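test_that("identical spec and seed give bit-identical records", {
  spec <- sim_spec(n_subjects = 1, duration_per_subject = 20, seed = 42)
  tr <- depth_trajectory(20, seed = 42)
  r1 <- simulate_clean_eeg(spec, tr)
  r2 <- simulate_clean_eeg(spec, tr)
  expect_identical(r1$data, r2$data)
  d1 <- generate_dataset(sim_spec(n_subjects = 2, duration_per_subject = 15,
                                  seed = 5))
  d2 <- generate_dataset(sim_spec(n_subjects = 2, duration_per_subject = 15,
                                  seed = 5))
  expect_identical(d1[[2]]$record$data, d2[[2]]$record$data)
})

test_that("constant single-band weights concentrate power in that band", {
  spec <- sim_spec(n_subjects = 1, duration_per_subject = 20,
                   band_weight_fn = function(d)
                     matrix(rep(c(0, 0, 1, 0, 0), each = length(d)),
                            ncol = 5),
                   background_fraction = 0.05, subject_gain_sd = 0,
                   seed = 3)
  tr <- depth_trajectory(20, seed = 3)
  rec <- simulate_clean_eeg(spec, tr)
  psd <- multitaper_psd(rec$data[1, 1:712], spec$fs)
  expect_gte(band_powers(psd)$relative[["alpha"]], 0.9)
})

test_that("all-zero weights with the background disabled give silence", {
  spec <- sim_spec(n_subjects = 1, duration_per_subject = 10,
                   band_weight_fn = function(d) matrix(0, length(d), 5),
                   background_fraction = 0, seed = 2)
  tr <- depth_trajectory(10, seed = 2)
  rec <- suppressWarnings(simulate_clean_eeg(spec, tr))
  expect_true(all(rec$data == 0))
})

test_that("non-finite band weights are rejected with a diagnostic", {
  spec <- sim_spec(n_subjects = 1, duration_per_subject = 10, seed = 2)
  spec$band_weight_fn <- function(d) matrix(NaN, length(d), 5)
  tr <- depth_trajectory(10, seed = 2)
  expect_error(simulate_clean_eeg(spec, tr), "non-finite")
})

test_that("blink train honours rate, amplitude and spectral content", {
  spec <- sim_spec(n_subjects = 1, duration_per_subject = 60,
                   artifact_rate = 0, seed = 4)
  expect_true(all(simulate_eoa_train(spec, 30) == 0))

  spec5 <- sim_spec(artifact_rate = 12, artifact_amplitude_ratio = 5,
                    seed = 8)
  clean_rms <- 15
  tr <- simulate_eoa_train(spec5, 120, clean_rms = clean_rms)
  peak <- max(abs(tr[1, ]))
  expect_lt(abs(peak - 5 * clean_rms) / (5 * clean_rms), 0.2)
  # identical polarity across channels
  expect_true(all(sign(tr[2, tr[1, ] > 1]) >= 0))

  # pulse energy: >= 80% below 5 Hz
  spec1 <- sim_spec(artifact_rate = 6, seed = 11)
  p <- simulate_eoa_train(spec1, 60, clean_rms = 15)
  expect_gt(sum(p[1, ]^2), 0)
  n <- length(p[1, ])
  sp <- Mod(fft(p[1, ]))^2
  freq <- (seq_len(n) - 1) * spec1$fs / n
  low <- sum(sp[freq < 5 | freq > spec1$fs - 5])
  expect_gte(low / sum(sp), 0.8)
})

test_that("contamination is additive and exactly disabled at zero amplitudes", {
  spec0 <- sim_spec(n_subjects = 1, duration_per_subject = 10,
                    artifact_rate = 0, line_noise_amplitude = 0,
                    drift_amplitude = 0, seed = 6)
  tr <- depth_trajectory(10, seed = 6)
  clean <- simulate_clean_eeg(spec0, tr)
  out0 <- contaminate(clean, spec0)
  expect_identical(out0$data, clean$data)

  spec1 <- sim_spec(n_subjects = 1, duration_per_subject = 10, seed = 6)
  out1 <- contaminate(clean, spec1)
  comps <- attr(out1, "components")
  expect_lt(max(abs(out1$data - clean$data - comps$eoa - comps$line -
                      comps$drift)), 1e-10)
  expect_identical(attr(out1, "clean")$data, clean$data)

  # line noise produces a 50 Hz spectral peak absent from the clean record
  psd_c <- multitaper_psd(clean$data[1, ], spec1$fs)
  psd_d <- multitaper_psd(out1$data[1, ], spec1$fs)
  at50 <- which.min(abs(psd_c$freq - 50))
  near <- abs(psd_c$freq - 50) < 2 & abs(psd_c$freq - 50) > 0.75
  expect_gt(psd_d$power[at50] / median(psd_d$power[near]), 3)
  expect_lt(psd_c$power[at50] / median(psd_c$power[near]), 3)
})

test_that("generated datasets have the expected label structure", {
  ds <- generate_dataset(sim_spec(n_subjects = 5,
                                  duration_per_subject = 60, seed = 9))
  expect_length(unique(vapply(ds, `[[`, character(1), "subject_id")), 5)

  # state frequencies: awake most common, deep anesthesia least
  big <- generate_dataset(sim_spec(n_subjects = 3,
                                   duration_per_subject = 300, seed = 10))
  samples <- prepare_samples(big, bandpass = FALSE)
  tab <- table(psi_to_state(samples$psi))
  expect_true(tab[["AW"]] > tab[["LA"]])
  expect_true(tab[["AW"]] > tab[["NA"]])
  expect_true(tab[["LA"]] > tab[["DA"]])
  expect_true(tab[["NA"]] > tab[["DA"]])
})

test_that("maximum depth maps to deep-anesthesia PSI", {
  tr <- depth_trajectory(20, depth_fn = function(t) rep(1, length(t)))
  expect_true(all(tr$psi <= 25))
  expect_true(all(tr$psi >= 0))
})

test_that("trajectory PSI stays in range and decreases with depth", {
  tr <- depth_trajectory(120, seed = 13)
  expect_true(all(tr$psi >= 0 & tr$psi <= 100))
  ord <- order(tr$depth)
  expect_true(all(diff(tr$psi[ord]) <= 0))
})
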