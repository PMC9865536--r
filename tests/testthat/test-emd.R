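zero_crossing_rate <- function(x) mean(diff(sign(x)) != 0)

test_that("ensemble decomposition is complete to numerical precision", {
  set.seed(20)
  t <- seq(0, 1, length.out = 300)
  for (sig in list(sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 40 * t),
                   rnorm(300),
                   cumsum(rnorm(300)) / 10)) {
    dec <- ceemdan(sig, ensemble_size = 20, rng_seed = 1)
    recon <- if (nrow(dec$imfs) > 0) colSums(dec$imfs) + dec$residue
             else dec$residue
    expect_lt(max(abs(recon - sig)), 1e-6 * max(sd(sig), 1e-12))
  }
})

test_that("modes are ordered fast to slow on a two-tone signal", {
  t <- seq(0, 2, length.out = 400)
  sig <- sin(2 * pi * 5 * t) + sin(2 * pi * 40 * t)
  dec <- ceemdan(sig, ensemble_size = 20, rng_seed = 2)
  expect_gte(nrow(dec$imfs), 2)
  zc <- apply(dec$imfs, 1, zero_crossing_rate)
  expect_gt(zc[1], zc[nrow(dec$imfs)])
})

test_that("constant input yields no oscillatory modes", {
  dec <- ceemdan(rep(3.5, 64), ensemble_size = 10, rng_seed = 3)
  expect_equal(nrow(dec$imfs), 0)
  expect_equal(dec$residue, rep(3.5, 64))
})

test_that("decomposition is deterministic given the seed", {
  set.seed(21)
  x <- rnorm(200)
  d1 <- ceemdan(x, ensemble_size = 15, rng_seed = 9)
  d2 <- ceemdan(x, ensemble_size = 15, rng_seed = 9)
  expect_identical(d1, d2)
})

test_that("too-short and non-finite inputs are rejected", {
  expect_error(ceemdan(rnorm(8)), "too short")
  expect_error(emd(c(1, NA, 3)), "non-finite")
})
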