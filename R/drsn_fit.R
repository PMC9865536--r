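## Training front-end for the residual shrinkage regressor.

samples_to_array <- function(x, width = NULL, channels = 4L) {
  x <- as.matrix(x)
  if (is.null(width)) width <- ncol(x) %/% channels
  stop_if(ncol(x) != width * channels,
          "each row must flatten ", channels, " channels x ", width,
          " samples (", width * channels, " values), got ", ncol(x))
  array(t(x), dim = c(width, channels, nrow(x)))
}

#' Fit the deep residual shrinkage PSI regressor
#'
#' Trains the channel-wise residual shrinkage network on standardized EEG
#' windows (see [standardize()]) with Adam on the mean squared error of the
#' predicted PSI, batch size 64, initial learning rate 0.005 decaying by 10%
#' every 20 epochs, and L2 weight decay.
#'
#' @param x `N x 2848` matrix of flattened standardized 4 x 712 windows (one
#'   channel after another), or a `(712, 4, N)` array.
#' @param psi numeric PSI labels in \[0, 100\].
#' @param config a [drsn_config()].
#' @param ablate_soft_threshold build the ablated variant whose residual
#'   branches pass unshrunk (no threshold module).
#' @param verbose print the loss every few epochs.
#' @return an object of class `"drsn"` with the trained parameters, the
#'   per-epoch `loss_history`, the config, and the fitted training
#'   predictions.
#' @seealso [predict.drsn()], [run_experiment()]
#' @export
drsn_fit <- function(x, psi, config = drsn_config(),
                     ablate_soft_threshold = FALSE, verbose = FALSE) {
  if (is.matrix(x) || is.data.frame(x)) x <- samples_to_array(x, channels = config$in_channels)
  stop_if(length(dim(x)) != 3L, "x must be a matrix or a (W, C, N) array")
  N <- dim(x)[3]
  stop_if(N < 1L, "empty training set")
  stop_if(length(psi) != N, "psi must have one label per sample")
  stop_if(any(psi < 0 | psi > 100), "PSI labels must lie in [0, 100]")

  net <- with_seed(config$seed, init_net(config))
  opt <- list(m = list(), v = list(), t = 0)

  val_idx <- integer(0)
  if (config$val_fraction > 0 && N >= 10) {
    val_idx <- with_seed(child_seed(config$seed, 7L),
                         sample(N, max(1L, round(config$val_fraction * N))))
  }
  tr_idx <- setdiff(seq_len(N), val_idx)
  best <- list(loss = Inf, net = NULL, epoch = 0L)
  wait <- 0L
  loss_history <- numeric(0)

  for (epoch in seq_len(config$max_epochs)) {
    lr <- lr_at_epoch(epoch, config)
    ord <- with_seed(child_seed(config$seed, 1000L + epoch),
                     sample(tr_idx))
    epoch_loss <- 0; nb <- 0L
    for (b0 in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      xb <- x[, , idx, drop = FALSE]
      yb <- psi[idx]
      fwd <- net_forward(net, xb, train = TRUE,
                         ablate = ablate_soft_threshold)
      net <- fwd$net
      err <- fwd$p - yb
      loss <- mean(err^2)
      gp <- 2 * err / length(err)
      grads <- net_backward(net, fwd$cache, gp)
      st <- adam_step(net, grads, opt, lr, config$weight_decay,
                      clip_norm = config$clip_norm)
      net <- st$net; opt <- st$opt
      epoch_loss <- epoch_loss + loss; nb <- nb + 1L
    }
    loss_history <- c(loss_history, epoch_loss / nb)
    if (verbose && (epoch %% 10L == 0L || epoch == 1L))
      message(sprintf("epoch %3d  lr %.5f  train MSE %.2f", epoch, lr,
                      epoch_loss / nb))
    if (length(val_idx) > 0) {
      vp <- net_predict(net, x[, , val_idx, drop = FALSE],
                        ablate = ablate_soft_threshold)
      vloss <- mean((vp - psi[val_idx])^2)
      if (vloss < best$loss - 1e-8) {
        best <- list(loss = vloss, net = net, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }
  if (!is.null(best$net)) net <- best$net

  fitted_p <- net_predict(net, x, ablate = ablate_soft_threshold)
  structure(list(net = net, config = config,
                 ablated = ablate_soft_threshold,
                 loss_history = loss_history,
                 fitted = fitted_p, psi = psi,
                 n_train = length(tr_idx),
                 stopped_epoch = length(loss_history)),
            class = "drsn")
}

## Adam with per-key first/second moments; decoupled from BN running stats
adam_step <- function(net, grads, opt, lr, weight_decay, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip_norm = Inf) {
  pf <- flatten_blocks(net)
  gf <- flatten_blocks(grads)
  if (is.finite(clip_norm)) {
    gnorm <- sqrt(sum(vapply(gf, function(g) sum(g^2), numeric(1))))
    if (gnorm > clip_norm)
      gf <- lapply(gf, function(g) g * (clip_norm / gnorm))
  }
  opt$t <- opt$t + 1
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (key in names(gf)) {
    g <- gf[[key]]
    if (weight_decay > 0 && decay_key(key)) g <- g + weight_decay * pf[[key]]
    m <- opt$m[[key]]; v <- opt$v[[key]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    opt$m[[key]] <- m; opt$v[[key]] <- v
    pf[[key]] <- pf[[key]] - lr * (m / corr1) / (sqrt(v / corr2) + eps)
  }
  list(net = assign_tree(net, pf), opt = opt)
}

net_predict <- function(net, x, ablate = FALSE, chunk = 256L) {
  N <- dim(x)[3]
  p <- numeric(N)
  for (b0 in seq(1L, N, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, N)
    fwd <- net_forward(net, x[, , idx, drop = FALSE], train = FALSE,
                       ablate = ablate, keep_cache = FALSE)
    p[idx] <- fwd$p
  }
  p
}

#' Predict PSI for new standardized samples
#'
#' @param object a fitted `"drsn"` model.
#' @param newdata `N x 2848` matrix (standardized with the training-set
#'   statistics) or `(712, 4, N)` array.
#' @param ... unused.
#' @return numeric PSI predictions, strictly inside (0, 100).
#' @export
predict.drsn <- function(object, newdata, ...) {
  if (is.matrix(newdata) || is.data.frame(newdata))
    newdata <- samples_to_array(newdata, channels = object$config$in_channels)
  stop_if(length(dim(newdata)) != 3L ||
            dim(newdata)[2] != object$config$in_channels,
          "newdata must be an N x (C*W) matrix or (W, C, N) array with ",
          object$config$in_channels, " channels")
  net_predict(object$net, newdata, ablate = object$ablated)
}

#' Predict PSI for one sample, exposing the pre-activation value
#'
#' @param model a fitted `"drsn"`.
#' @param sample a 4 x 712 matrix (standardized) or flat length-2848 vector.
#' @return list with `v` (pre-activation) and `p = 100 / (1 + exp(-v))`.
#' @export
predict_psi <- function(model, sample) {
  stopifnot(inherits(model, "drsn"))
  if (is.null(dim(sample))) sample <- matrix(sample, nrow = 1)
  if (nrow(sample) == 4L) sample <- matrix(as.vector(t(sample)), nrow = 1)
  x <- samples_to_array(sample, channels = model$config$in_channels)
  fwd <- net_forward(model$net, x, train = FALSE, ablate = model$ablated,
                     keep_cache = FALSE)
  list(v = fwd$v, p = fwd$p)
}

#' @export
print.drsn <- function(x, ...) {
  cat(sprintf("Deep residual shrinkage PSI regressor%s\n",
              if (x$ablated) " (soft thresholding ablated)" else ""))
  cat(sprintf("  stages: %s channels, kernel %d, %d parameters\n",
              paste(x$config$stages, collapse = "-"), x$config$kernel_size,
              n_params(x)))
  cat(sprintf("  trained %d epochs on %d samples; final train MSE %.2f\n",
              x$stopped_epoch, x$n_train, tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
summary.drsn <- function(object, ...) {
  print(object)
  res <- object$psi - object$fitted
  cat(sprintf("  training residuals: RMSE %.2f, MAE %.2f\n",
              sqrt(mean(res^2)), mean(abs(res))))
  invisible(object)
}

#' @export
residuals.drsn <- function(object, ...) object$psi - object$fitted

#' @export
fitted.drsn <- function(object, ...) object$fitted

#' @export
plot.drsn <- function(x, ...) {
  plot(seq_along(x$loss_history), x$loss_history, type = "l",
       xlab = "epoch", ylab = "training MSE",
       main = "Residual shrinkage network training loss", ...)
  invisible(x)
}

#' Number of trainable parameters
#' @param model a fitted `"drsn"` or a raw network list.
#' @return integer count.
#' @export
n_params <- function(model) {
  net <- if (inherits(model, "drsn")) model$net else model
  sum(vapply(flatten_blocks(net), length, integer(1)))
}

#' Learning rate at a given epoch under the decay schedule
#'
#' The rate drops by the decay factor every `lr_decay_every` epochs:
#' `lr * decay^floor(epoch / every)`, so epoch 20 runs at `0.005 * 0.9`
#' and epoch 40 at `0.005 * 0.81` under the defaults.
#'
#' @param epoch 1-based epoch number.
#' @param config a [drsn_config()].
#' @return the learning rate used during that epoch.
#' @export
lr_at_epoch <- function(epoch, config = drsn_config()) {
  config$lr * config$lr_decay^(epoch %/% config$lr_decay_every)
}
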