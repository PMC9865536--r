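test_that("soft thresholding implements the three-branch shrinkage exactly", {
  expect_equal(soft_threshold(0.5, 0.2), 0.3)
  expect_equal(soft_threshold(0.1, 0.2), 0)
  expect_equal(soft_threshold(-0.5, 0.2), -0.3)
  expect_equal(soft_threshold(-0.2, 0.2), 0)
  x <- rnorm(20)
  expect_equal(soft_threshold(x, 0), x)
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("soft thresholding is non-expansive with an exact dead zone", {
  set.seed(60)
  x1 <- rnorm(200); x2 <- rnorm(200)
  for (tau in c(0.1, 0.5, 2)) {
    y1 <- soft_threshold(x1, tau); y2 <- soft_threshold(x2, tau)
    expect_true(all(abs(y1 - y2) <= abs(x1 - x2) + 1e-12))
    expect_true(all(y1[abs(x1) <= tau] == 0))
    expect_true(all(sign(y1[abs(x1) > tau]) == sign(x1[abs(x1) > tau])))
  }
})

test_that("channel thresholds satisfy tau = sigmoid(z) * mean|x| bounds", {
  set.seed(61)
  x <- array(rnorm(64 * 8 * 6), dim = c(64, 8, 6))
  # default (zero-weight) module: z = 0, alpha = 1/2, tau = x_avg / 2
  th <- channel_thresholds(x)
  expect_equal(th$alpha, matrix(0.5, 8, 6), ignore_attr = TRUE)
  expect_equal(th$tau, th$x_avg / 2, tolerance = 1e-12)

  # zeros in, zero thresholds out
  th0 <- channel_thresholds(array(0, dim = c(16, 4, 2)))
  expect_true(all(th0$tau == 0))

  # random modules keep 0 <= tau <= x_avg
  for (i in 1:5) {
    pars <- anescore:::init_thr_module(8L)
    th <- channel_thresholds(x, pars, train = TRUE)
    expect_true(all(th$tau >= 0))
    expect_true(all(th$tau <= th$x_avg + 1e-12))
    expect_true(all(th$alpha > 0 & th$alpha < 1))
  }
})

test_that("residual units preserve shape and respond to ablation", {
  set.seed(62)
  blk_id <- anescore:::init_block(8L, 8L, 3L, 1L, "identity")
  x <- array(rnorm(40 * 8 * 3), dim = c(40, 8, 3))
  out <- rsbu_forward(x, blk_id)
  expect_equal(dim(out$y), dim(x))

  # zeroed branch weights: identity variant returns its input untouched
  blk0 <- blk_id
  blk0$conv1$w[] <- 0; blk0$conv1$b[] <- 0
  blk0$conv2$w[] <- 0; blk0$conv2$b[] <- 0
  out0 <- rsbu_forward(x, blk0)
  expect_equal(out0$y, x, tolerance = 1e-12)

  # ablated vs full differ whenever branch values fall below the threshold
  outf <- rsbu_forward(x, blk_id, ablate = FALSE)
  outa <- rsbu_forward(x, blk_id, ablate = TRUE)
  expect_false(isTRUE(all.equal(outf$y, outa$y)))

  # convolutional variant halves the width
  blk_c <- anescore:::init_block(8L, 16L, 3L, 2L, "conv")
  outc <- rsbu_forward(x, blk_c)
  expect_equal(dim(outc$y), c(20, 16, 3))

  expect_error(rsbu_forward(array(rnorm(40 * 3 * 2), dim = c(40, 3, 2)),
                            blk_id), "channels")
})

test_that("the 1x1 head is a pure channel contraction", {
  r <- array(1, dim = c(89, 16, 2))
  y <- conv1x1_head(r, rep(1, 16), 0)
  expect_equal(dim(y), c(89, 1, 2))
  expect_true(all(abs(y - 16) < 1e-12))
  expect_true(all(conv1x1_head(r, rep(0, 16), 0) == 0))
  expect_error(conv1x1_head(array(0, dim = c(10, 8, 1)), rep(1, 16)),
               "channels")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(63)
  cfg <- drsn_config(stages = c(4L, 16L), batch_size = 3L, seed = 3L)
  net <- anescore:::init_net(cfg)
  x <- array(rnorm(24 * 4 * 3), dim = c(24, 4, 3))
  y <- c(30, 60, 85)
  fwd <- anescore:::net_forward(net, x, train = TRUE)
  gp <- 2 * (fwd$p - y) / 3
  grads <- anescore:::net_backward(fwd$net, fwd$cache, gp)
  gf <- anescore:::flatten_blocks(grads)
  pf <- anescore:::flatten_blocks(net)
  loss_fn <- function(nn) {
    f <- anescore:::net_forward(nn, x, train = TRUE, keep_cache = FALSE)
    mean((f$p - y)^2)
  }
  eps <- 1e-5
  for (key in sample(names(gf), 12)) {
    i <- sample(length(gf[[key]]), 1)
    for (s in c(1, -1)) {
      p2 <- pf; p2[[key]][i] <- p2[[key]][i] + s * eps
      assign(if (s == 1) "lp" else "lm",
             loss_fn(anescore:::assign_tree(net, p2)))
    }
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - gf[[key]][i]) /
                max(1e-4, abs(num) + abs(gf[[key]][i])), 5e-3)
  }
})

test_that("predictions are strictly inside (0, 100) and follow the logistic map", {
  set.seed(64)
  cfg <- drsn_config(stages = c(4L, 16L), max_epochs = 1L, seed = 5L)
  x <- matrix(rnorm(8 * 2848), 8)
  fit <- drsn_fit(x, runif(8, 0, 100), cfg)
  p <- predict(fit, x)
  expect_true(all(p > 0 & p < 100))

  # zeroed head: v = 0 hence p = 50; bias ln 3 gives p = 75
  fit0 <- fit
  fit0$net$head$w[] <- 0; fit0$net$head$b <- 0
  pr <- predict_psi(fit0, matrix(rnorm(4 * 712), 4))
  expect_equal(pr$v, 0, tolerance = 1e-12)
  expect_equal(pr$p, 50, tolerance = 1e-12)
  fit0$net$head$b <- log(3)
  pr3 <- predict_psi(fit0, matrix(rnorm(4 * 712), 4))
  expect_equal(pr3$p, 75, tolerance = 1e-9)
})

test_that("the learning-rate schedule drops 10% every 20 epochs", {
  cfg <- drsn_config()
  expect_equal(lr_at_epoch(1, cfg), 0.005)
  expect_equal(lr_at_epoch(19, cfg), 0.005)
  expect_equal(lr_at_epoch(20, cfg), 0.0045)
  expect_equal(lr_at_epoch(40, cfg), 0.00405)
})

test_that("a small network overfits a constant label", {
  set.seed(65)
  x <- matrix(rnorm(64 * 2848), 64)
  fit <- drsn_fit(x, rep(50, 64), drsn_config(max_epochs = 40L, seed = 1L))
  expect_lt(tail(fit$loss_history, 1), 1)
  expect_true(all(is.finite(fit$loss_history)))
  expect_lte(tail(fit$loss_history, 1), fit$loss_history[1])
})

test_that("the 1x1 head has far fewer parameters than a dense readout", {
  cfg <- drsn_config(max_epochs = 1L)
  net <- anescore:::init_net(cfg)
  head_params <- length(net$head$w) + length(net$head$b)
  w_final <- 712 / 2^length(cfg$stages)
  dense_params <- ceiling(w_final) * 16 + 1
  expect_lt(head_params, dense_params)
})

test_that("configs are validated with the offending fields named", {
  expect_error(drsn_config(lr = 0), "lr")
  expect_error(drsn_config(stages = c(8L, 8L)), "16 channels")
  expect_error(drsn_fit(matrix(rnorm(2848), 1), 101), "\\[0, 100\\]")
  expect_error(drsn_fit(matrix(0, 0, 2848), numeric(0)), "empty|one label")
})
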