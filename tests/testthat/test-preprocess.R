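make_record <- function(n, fs = 178.2, seed = 1) {
  set.seed(seed)
  eeg_record(matrix(rnorm(4 * n), 4), fs)
}

test_that("segmentation produces the documented window counts", {
  rec <- make_record(10692)             # 60 s at 178.2 Hz
  segs <- segment_record(rec)
  expect_length(segs, 29)
  expect_true(all(vapply(segs, function(s) ncol(s$data), integer(1)) == 712))

  one <- segment_record(make_record(712))
  expect_length(one, 1)

  expect_error(segment_record(make_record(700)), "at least 712")
})

test_that("segment start times follow the 50% hop", {
  segs <- segment_record(make_record(2136))
  starts <- vapply(segs, `[[`, numeric(1), "start_time")
  expect_equal(starts, c(0, 356, 712, 1068, 1424) / 178.2)
})

test_that("FIR bandpass has the specified passband and stopband behaviour", {
  fs <- 178.2
  n <- 712
  t <- (seq_len(n) - 1) / fs
  tone <- function(f) eeg_segment(matrix(rep(sin(2 * pi * f * t), each = 4),
                                         4, byrow = FALSE), fs)
  # 10 Hz passes within 10% (compare RMS over the central region)
  mid <- 100:600
  y10 <- bandpass_fir(tone(10))
  expect_lt(abs(sd(y10$data[1, mid]) / sd(sin(2 * pi * 10 * t)[mid]) - 1),
            0.1)
  # DC is annihilated
  dc <- eeg_segment(matrix(1, 4, n), fs)
  expect_lt(max(abs(bandpass_fir(dc)$data)), 0.05)
  # 60 Hz attenuated at least 10x
  y60 <- bandpass_fir(tone(60))
  expect_lt(sd(y60$data[1, mid]), sd(sin(2 * pi * 60 * t)) / 10)
})

test_that("bandpass rejects too-low sampling rates", {
  seg <- eeg_segment(matrix(rnorm(4 * 712), 4), fs = 90)
  expect_error(bandpass_fir(seg), "too low")
})

test_that("component classification follows the entropy threshold", {
  set.seed(40)
  t <- seq(0, 1, length.out = 300)
  pulse <- exp(-((t - 0.5) / 0.05)^2)        # smooth blink-like component
  noise <- rnorm(300)
  ics <- rbind(pulse, noise)
  mask <- classify_ics(ics, sampen_threshold = 0.5)
  expect_true(mask[1])
  expect_false(mask[2])
  expect_true(all(!classify_ics(ics, sampen_threshold = 0)))
  expect_true(all(classify_ics(ics, sampen_threshold = 1e6)))
})

test_that("the removal chain is the identity when nothing is flagged", {
  pair <- blink_pair()
  seg <- bandpass_fir(segment_record(pair$contaminated)[[3]])
  cfg <- cleaning_config(sampen_threshold = 0, ceemdan_ensemble_size = 20)
  out <- remove_eoa(seg, cfg)
  expect_lt(max(abs(out$data - seg$data)),
            1e-5 * sqrt(mean(seg$data^2)))
})

test_that("cleaning reduces the distance to the clean truth on blink segments", {
  pair <- blink_pair()
  segs_d <- segment_record(pair$contaminated)
  segs_c <- segment_record(attr(pair$contaminated, "clean"))
  cfg <- cleaning_config(ceemdan_ensemble_size = 30)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  before <- numeric(0); after <- numeric(0)
  for (i in seq_along(segs_d)) {
    sd_f <- bandpass_fir(segs_d[[i]])
    sc_f <- bandpass_fir(segs_c[[i]])
    b <- rmse(sd_f$data, sc_f$data)
    if (b < 10) next                       # skip blink-free windows
    out <- suppressWarnings(remove_eoa(sd_f, cfg))
    before <- c(before, b)
    after <- c(after, rmse(out$data, sc_f$data))
    if (length(before) >= 5) break
  }
  expect_gte(length(before), 3)
  expect_lt(mean(after), mean(before))          # blinks shrink on average
  expect_lt(max(after / before), 1.25)          # no window badly degraded
})

test_that("artifact-free segments survive cleaning nearly unchanged", {
  pair <- blink_pair()
  seg <- bandpass_fir(segment_record(pair$clean)[[2]])
  out <- remove_eoa(seg, cleaning_config(ceemdan_ensemble_size = 30))
  expect_gt(cor(as.vector(out$data), as.vector(seg$data)), 0.95)
})

test_that("prepared samples flatten to 2848 columns with in-range labels", {
  ds <- generate_dataset(sim_spec(n_subjects = 2,
                                  duration_per_subject = 20, seed = 3))
  samples <- prepare_samples(ds)
  expect_equal(ncol(samples$x), 2848)
  expect_equal(samples$window, 712)
  expect_true(all(samples$psi >= 0 & samples$psi <= 100))
  expect_setequal(unique(samples$subject), c("S01", "S02"))
  # flattening is channel-major: first 712 columns are channel L1
  m <- sample_matrix(samples, 1)
  expect_equal(m[1, ], samples$x[1, 1:712])
  expect_equal(m[4, ], samples$x[1, 2137:2848])
})
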