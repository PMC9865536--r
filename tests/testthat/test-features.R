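fs <- 178.2
t712 <- (0:711) / fs

test_that("multitaper spectrum locates a pure tone and integrates variance", {
  x <- sin(2 * pi * 10 * t712)
  psd <- multitaper_psd(x, fs)
  expect_lt(abs(psd$freq[which.max(psd$power)] - 10), 0.5)

  expect_true(all(multitaper_psd(numeric(712), fs)$power == 0))

  set.seed(50)
  wn <- rnorm(712)
  psd_w <- multitaper_psd(wn, fs)
  df <- psd_w$freq[2] - psd_w$freq[1]
  expect_lt(abs(sum(psd_w$power) * df / var(wn) - 1), 0.15)

  expect_error(multitaper_psd(rnorm(32), fs), "too short")
})

test_that("band powers integrate correctly and normalise to one", {
  psd <- multitaper_psd(sin(2 * pi * 10 * t712), fs)
  bp <- band_powers(psd)
  expect_gte(bp$relative[["alpha"]], 0.9)
  expect_equal(sum(bp$relative), 1, tolerance = 1e-9)
  expect_equal(sum(bp$absolute), bp$total, tolerance = 1e-9)

  # flat density: band share proportional to bandwidth
  grid <- seq(0, fs / 2, by = 0.1)
  flat <- list(freq = grid, power = as.numeric(grid >= 1 & grid < 51))
  bf <- band_powers(flat)
  expect_lt(abs(bf$relative[["delta"]] / (3 / 50) - 1), 0.1)
  expect_lt(abs(bf$relative[["gamma"]] / (20 / 50) - 1), 0.1)

  expect_error(band_powers(list(freq = grid, power = numeric(length(grid)))),
               "zero total")
  expect_error(band_powers(list(freq = seq(0, 40, 0.1),
                                power = rep(1, 401))), "cover")
})

test_that("spectral edge frequency matches the cumulative-power oracle", {
  grid <- seq(0, fs / 2, by = 0.05)
  flat <- list(freq = grid, power = as.numeric(grid >= 1 & grid <= 51))
  expect_lt(abs(sef95(flat) - 48.5), 0.2)

  lowpass <- list(freq = grid, power = as.numeric(grid >= 1 & grid < 4))
  expect_lte(sef95(lowpass), 4)

  psd <- multitaper_psd(sin(2 * pi * 10 * t712), fs)
  expect_lt(abs(sef95(psd) - 10), 1)

  expect_error(sef95(list(freq = grid, power = numeric(length(grid)))),
               "zero power")
})

test_that("sample entropy matches the brute-force template count", {
  x <- rep(c(1, 2), 5)
  expect_equal(sample_entropy(x), sampen_bruteforce(x))
  set.seed(51)
  for (i in 1:10) {
    y <- rnorm(sample(50:300, 1))
    expect_equal(sample_entropy(y), sampen_bruteforce(y))
  }
})

test_that("sample entropy behaves at the boundary cases", {
  expect_equal(sample_entropy(rep(2, 50)), 0)
  set.seed(52)
  expect_gt(sample_entropy(rnorm(712)),
            sample_entropy(sin(2 * pi * 10 * t712)))
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "too short")
})

test_that("the 14-feature vector has the documented layout and symmetries", {
  set.seed(53)
  seg <- eeg_segment(matrix(rnorm(4 * 712), 4), fs)
  f <- extract_features(seg)
  expect_length(f, 14)
  expect_named(f, feature_names())
  expect_equal(sum(f[4:8]), 1, tolerance = 1e-9)
  expect_true(all(f[9:10] >= 1 & f[9:10] <= 51))
  expect_true(all(f[11:14] >= 0))

  # zeroed left channels: no left-hemisphere power
  dat <- matrix(rnorm(4 * 712), 4); dat[1:2, ] <- 0
  fz <- extract_features(dat, fs = fs)
  expect_equal(fz[["total_power_left"]], 0, tolerance = 1e-12)

  # identical inputs on all channels give symmetric edge frequencies
  s <- sin(2 * pi * 10 * t712)
  fsym <- extract_features(matrix(rep(s, each = 4), 4, byrow = FALSE),
                           fs = fs)
  expect_equal(fsym[["sef95_left"]], fsym[["sef95_right"]])
})

test_that("scaling a sample rescales powers but not shape features", {
  set.seed(54)
  dat <- matrix(rnorm(4 * 712), 4)
  f1 <- extract_features(dat, fs = fs)
  f3 <- extract_features(3 * dat, fs = fs)
  expect_equal(f3[1:3], 9 * f1[1:3], tolerance = 1e-8)
  expect_equal(f3[4:14], f1[4:14], tolerance = 1e-8)
})
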