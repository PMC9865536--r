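## 1-D deep residual shrinkage network with channel-wise thresholds.
##
## Architecture: the 4 EEG channels enter as the channel dimension of a
## 1 x 712 feature map.  Four stages (output channels 8, 8, 16, 16) each
## open with a convolutional residual shrinkage unit (stride 2) followed by
## an identity unit; kernel size 3; pre-activation layout (BN -> ELU ->
## conv).  Each unit's residual branch is soft-thresholded with per-channel
## thresholds tau_c = sigmoid(z_c) * mean(|branch|), learned by a small
## two-layer fully connected module (with BN + ReLU) on the pooled absolute
## feature map, so 0 <= tau_c <= mean(|branch|) by construction.  A final
## BN + ELU feeds a 1x1 convolution (16 -> 1 channels), global average
## pooling yields a scalar v, and the prediction is p = 100 / (1 + e^-v),
## strictly inside (0, 100).
##
## Forward and backward passes are written out explicitly; the 1-D
## convolutions run in compiled code.  Optimisation is Adam on the MSE of
## the predicted PSI, with the learning rate decaying by 10% every 20
## epochs and L2 weight decay on convolution / fully connected weights.

#' Model configuration for the residual shrinkage regressor
#'
#' @param stages output channels of each stage (the last must be 16, the
#'   width of the final representation).
#' @param kernel_size convolution kernel length.
#' @param in_channels input channels (4 EEG channels).
#' @param batch_size minibatch size.
#' @param blocks_per_stage residual units per stage (the first is always
#'   the stride-2 convolutional unit; the rest are identity units).
#' @param lr initial Adam learning rate.
#' @param lr_decay,lr_decay_every multiplicative decay (0.9 = minus 10%)
#'   applied every `lr_decay_every` epochs.
#' @param max_epochs training epoch cap.
#' @param weight_decay L2 penalty on convolution and fully connected
#'   weights.
#' @param val_fraction fraction of the training set held out for early
#'   stopping (0 disables early stopping).
#' @param patience epochs without validation improvement before stopping.
#' @param clip_norm global gradient-norm ceiling per step (Inf disables);
#'   tames the occasional large minibatch gradient.
#' @param seed seed for initialisation and batch shuffling.
#' @return object of class `"drsn_config"`.
#' @export
drsn_config <- function(stages = c(8L, 8L, 16L, 16L), kernel_size = 3L,
                        in_channels = 4L, batch_size = 64L,
                        blocks_per_stage = 2L, lr = 0.005,
                        lr_decay = 0.9, lr_decay_every = 20L,
                        max_epochs = 256L, weight_decay = 1e-4,
                        val_fraction = 0, patience = 15L, clip_norm = 5,
                        seed = 1L) {
  cfg <- structure(list(stages = as.integer(stages),
                        kernel_size = as.integer(kernel_size),
                        in_channels = as.integer(in_channels),
                        batch_size = as.integer(batch_size),
                        blocks_per_stage = as.integer(blocks_per_stage),
                        lr = lr,
                        lr_decay = lr_decay,
                        lr_decay_every = as.integer(lr_decay_every),
                        max_epochs = as.integer(max_epochs),
                        weight_decay = weight_decay,
                        val_fraction = val_fraction,
                        patience = as.integer(patience),
                        clip_norm = clip_norm,
                        seed = as.integer(seed)),
                   class = "drsn_config")
  bad <- character(0)
  if (cfg$lr <= 0) bad <- c(bad, "lr")
  if (length(cfg$stages) < 1 || any(cfg$stages < 1)) bad <- c(bad, "stages")
  if (cfg$stages[length(cfg$stages)] != 16L) bad <- c(bad, "stages (final representation must have 16 channels)")
  if (cfg$batch_size < 1) bad <- c(bad, "batch_size")
  stop_if(length(bad) > 0, "invalid drsn_config field(s): ",
          paste(bad, collapse = ", "))
  cfg
}

## ---- elementary layers ----------------------------------------------------

elu_fwd <- function(x) elu_c(x)

#' Channel-wise soft thresholding
#'
#' `y = x - tau` for `x > tau`, `0` for `|x| <= tau`, `x + tau` for
#' `x < -tau`, applied elementwise with one threshold per channel (and per
#' sample).  The shrinkage operator of the residual branch.
#'
#' @param x feature map: a `(W, C, N)` array, a `W x C` matrix, or a vector
#'   (single channel).
#' @param tau nonnegative threshold(s): scalar, length-`C` vector, or
#'   `C x N` matrix matching `x`.
#' @return shrunk feature map, same shape as `x`.
#' @export
soft_threshold <- function(x, tau) {
  stop_if(any(tau < 0), "thresholds must be nonnegative")
  d <- dim(x)
  if (is.null(d)) {                      # vector, scalar tau
    stop_if(length(tau) != 1L, "vector input needs a scalar tau")
    tcol <- tau
  } else if (length(d) == 2L) {          # W x C, tau per channel
    stop_if(!length(tau) %in% c(1L, d[2]), "tau must have one value per channel")
    tcol <- rep(tau, length.out = d[2])[rep(seq_len(d[2]), each = d[1])]
  } else {                               # (W, C, N), tau C x N
    tau <- if (length(tau) == 1L) matrix(tau, d[2], d[3]) else as.matrix(tau)
    stop_if(nrow(tau) != d[2] || ncol(tau) != d[3],
            "tau must be a C x N matrix")
    tcol <- rep(as.vector(tau), each = d[1])
  }
  y <- sign(x) * pmax(abs(x) - tcol, 0)
  if (!is.null(d)) dim(y) <- d
  y
}

## spatial batch norm over (W, N) per channel; x is (W, C, N)
bn_sp_fwd <- function(x, gamma, beta, run, train, momentum = 0.9,
                      eps = 1e-5) {
  d <- dim(x)
  if (train) {
    mom <- ch_moments(x)
    mu <- mom[, 1]
    v <- pmax(mom[, 2] - mu^2, 0)
    run$mean <- momentum * run$mean + (1 - momentum) * mu
    run$var <- momentum * run$var + (1 - momentum) * v
  } else {
    mu <- run$mean; v <- run$var
  }
  ivar <- 1 / sqrt(v + eps)
  aff <- bn_affine(x, mu, ivar, gamma, beta)
  list(y = aff$y,
       cache = list(xhat = aff$xhat, ivar = ivar, gamma = gamma, dims = d),
       run = run)
}

bn_sp_bwd <- function(cache, gy) {
  d <- cache$dims; W <- d[1]; C <- d[2]; N <- d[3]
  m <- W * N
  s <- ch_sums2(gy, cache$xhat)
  gbeta <- s[, 1]
  ggamma <- s[, 2]
  gx <- bn_bwd_elem(gy, cache$xhat, cache$gamma * cache$ivar,
                    gbeta / m, ggamma / m)
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

## dense batch norm over rows; x is N x C
bn_fc_fwd <- function(x, gamma, beta, run, train, momentum = 0.9,
                      eps = 1e-5) {
  if (train) {
    mu <- colMeans(x)
    v <- pmax(colMeans(x * x) - mu^2, 0)
    run$mean <- momentum * run$mean + (1 - momentum) * mu
    run$var <- momentum * run$var + (1 - momentum) * v
  } else {
    mu <- run$mean; v <- run$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(x, 2, mu) * rep(ivar, each = nrow(x))
  y <- sweep(xhat * rep(gamma, each = nrow(x)), 2, beta, `+`)
  list(y = y, cache = list(xhat = xhat, ivar = ivar, gamma = gamma,
                           n = nrow(x)),
       run = run)
}

bn_fc_bwd <- function(cache, gy) {
  n <- cache$n
  gbeta <- colSums(gy)
  ggamma <- colSums(gy * cache$xhat)
  coef <- rep(cache$gamma * cache$ivar, each = n)
  gx <- coef * (gy - rep(gbeta / n, each = n) -
                  cache$xhat * rep(ggamma / n, each = n))
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

## ---- threshold module -----------------------------------------------------

#' Channel-wise thresholds from a feature map
#'
#' Implements the threshold sub-module of a residual shrinkage unit:
#' `x_avg` is the per-channel mean of `|x|` (absolute value taken so the
#' thresholds stay positive for signed feature maps); a two-layer fully
#' connected network (BN + ReLU between the layers) produces `z_c`; the
#' scaling is `alpha_c = sigmoid(z_c)` and the threshold
#' `tau_c = alpha_c * x_avg`, hence `0 <= tau_c <= x_avg`.
#'
#' @param x feature map, `(W, C, N)` array (or `W x C` matrix for one
#'   sample).
#' @param params module parameters (`W1`, `b1`, `bn` gamma/beta + running
#'   stats, `W2`, `b2`); see [drsn_fit()].  Defaults to an identity-style
#'   module (`z = 0`), giving `tau = x_avg / 2`.
#' @param train use batch statistics in the module's BN layer.
#' @return list with `tau` (`C x N`), `alpha`, `x_avg`, `z`, and a cache
#'   for backpropagation.
#' @export
channel_thresholds <- function(x, params = NULL, train = FALSE) {
  if (is.matrix(x)) dim(x) <- c(nrow(x), ncol(x), 1L)
  d <- dim(x); W <- d[1]; C <- d[2]; N <- d[3]
  stop_if(!all(is.finite(x)), "feature map contains non-finite values")
  if (is.null(params)) params <- init_thr_module(C, zero = TRUE)
  U <- t(gap_abs_c(x))                                              # N x C
  z1 <- U %*% params$W1 + rep(params$b1, each = N)
  bn <- bn_fc_fwd(z1, params$bn$gamma, params$bn$beta, params$bn$run, train)
  r <- pmax(bn$y, 0)
  z2 <- r %*% params$W2 + rep(params$b2, each = N)
  alpha <- 1 / (1 + exp(-z2))
  tau <- t(alpha * U)                                               # C x N
  list(tau = tau, alpha = t(alpha), x_avg = t(U), z = t(z2),
       cache = list(U = U, z1 = z1, bn = bn$cache, r = r, alpha = alpha,
                    params = params),
       run = bn$run)
}

thr_module_bwd <- function(cache, gtau) {
  ## gtau arrives as C x N; internal orientation is N x C
  gt <- t(gtau)
  U <- cache$U; alpha <- cache$alpha; p <- cache$params
  n <- nrow(U)
  galpha <- gt * U
  gU <- gt * alpha
  gz2 <- galpha * alpha * (1 - alpha)
  gW2 <- crossprod(cache$r, gz2)
  gb2 <- colSums(gz2)
  gr <- tcrossprod(gz2, p$W2)
  gbn_y <- gr * (cache$r > 0)
  bnb <- bn_fc_bwd(cache$bn, gbn_y)
  gz1 <- bnb$gx
  gW1 <- crossprod(U, gz1)
  gb1 <- colSums(gz1)
  gU <- gU + tcrossprod(gz1, p$W1)
  list(gU = gU, grads = list(W1 = gW1, b1 = gb1,
                             bn = list(gamma = bnb$ggamma, beta = bnb$gbeta),
                             W2 = gW2, b2 = gb2))
}

## ---- parameter initialisation ---------------------------------------------

init_bn <- function(C) list(gamma = rep(1, C), beta = rep(0, C),
                            run = list(mean = rep(0, C), var = rep(1, C)))

init_conv <- function(K, Cin, Cout) {
  w <- array(rnorm(K * Cin * Cout, 0, sqrt(2 / (K * Cin))),
             dim = c(K, Cin, Cout))
  list(w = w, b = rep(0, Cout))
}

init_thr_module <- function(C, zero = FALSE) {
  s <- if (zero) 0 else sqrt(1 / C)
  list(W1 = matrix(rnorm(C * C, 0, s), C, C), b1 = rep(0, C),
       bn = init_bn(C),
       W2 = matrix(rnorm(C * C, 0, s), C, C), b2 = rep(0, C))
}

init_block <- function(Cin, Cout, K, stride, variant) {
  b <- list(variant = variant, stride = stride,
            bn1 = init_bn(Cin), conv1 = init_conv(K, Cin, Cout),
            bn2 = init_bn(Cout), conv2 = init_conv(K, Cout, Cout),
            thr = init_thr_module(Cout))
  if (variant == "conv") {
    b$convs <- init_conv(1L, Cin, Cout)
    b$bns <- init_bn(Cout)
  }
  b
}

init_net <- function(cfg) {
  blocks <- list()
  Cin <- cfg$in_channels
  bps <- if (is.null(cfg$blocks_per_stage)) 2L else cfg$blocks_per_stage
  for (s in seq_along(cfg$stages)) {
    Cout <- cfg$stages[s]
    blocks[[length(blocks) + 1L]] <-
      init_block(Cin, Cout, cfg$kernel_size, 2L, "conv")
    if (bps > 1L)
      for (j in seq_len(bps - 1L))
        blocks[[length(blocks) + 1L]] <-
          init_block(Cout, Cout, cfg$kernel_size, 1L, "identity")
    Cin <- Cout
  }
  list(blocks = blocks, bn_head = init_bn(Cin),
       head = init_conv(1L, Cin, 1L))
}

## ---- forward / backward ---------------------------------------------------

#' Forward pass through one residual shrinkage unit
#'
#' Pre-activation block: BN-ELU-conv, BN-ELU-conv, channel-wise soft
#' thresholding of the branch, plus the (identity or convolutional)
#' shortcut.
#'
#' @param x `(W, C, N)` input array.
#' @param params block parameter list (see [drsn_fit()] internals).
#' @param train training mode (batch statistics in BN layers).
#' @param ablate skip the threshold module (branch passes unshrunk).
#' @return list with `y`, updated `params` (running BN stats) and `cache`.
#' @export
rsbu_forward <- function(x, params, train = FALSE, ablate = FALSE) {
  K <- dim(params$conv1$w)[1]
  stop_if(dim(x)[2] != dim(params$conv1$w)[2],
          "input has ", dim(x)[2], " channels but conv1 expects ",
          dim(params$conv1$w)[2])
  pad <- (K - 1L) %/% 2L
  bn1 <- bn_sp_fwd(x, params$bn1$gamma, params$bn1$beta, params$bn1$run, train)
  params$bn1$run <- bn1$run
  a1 <- elu_fwd(bn1$y)
  h1 <- conv1d_fwd(a1, params$conv1$w, params$conv1$b, params$stride, pad)
  bn2 <- bn_sp_fwd(h1, params$bn2$gamma, params$bn2$beta, params$bn2$run, train)
  params$bn2$run <- bn2$run
  a2 <- elu_fwd(bn2$y)
  h2 <- conv1d_fwd(a2, params$conv2$w, params$conv2$b, 1L, pad)
  if (ablate) {
    branch <- h2
    thr <- NULL
  } else {
    thr <- channel_thresholds(h2, params$thr, train)
    params$thr$bn$run <- thr$run
    branch <- soft_thr_c(h2, thr$tau)
  }
  if (params$variant == "identity") {
    shortcut <- x
    scache <- NULL
  } else {
    hs <- conv1d_fwd(a1, params$convs$w, params$convs$b, params$stride, 0L)
    bns <- bn_sp_fwd(hs, params$bns$gamma, params$bns$beta, params$bns$run,
                     train)
    params$bns$run <- bns$run
    shortcut <- bns$y
    scache <- list(a1 = a1, bns = bns$cache)
  }
  y <- shortcut + branch
  list(y = y, params = params,
       cache = list(x = x, bn1 = bn1$cache, a1 = a1, h1 = h1,
                    bn2 = bn2$cache, a2 = a2, h2 = h2, thr = thr,
                    scache = scache, pad = pad, ablate = ablate))
}

rsbu_backward <- function(params, cache, gy) {
  pad <- cache$pad
  g <- list()
  ## branch: soft threshold
  if (cache$ablate) {
    gh2 <- gy
    g$thr <- NULL
  } else {
    ## two passes: first the threshold-module gradient needs gtau, which
    ## depends only on the shrinkage mask; then the pooled-|x| side path
    ## (gU) is folded into gh2 by the fused backward kernel
    st0 <- soft_thr_bwd_c(cache$h2, cache$thr$tau, gy,
                          matrix(0, dim(cache$h2)[2], dim(cache$h2)[3]))
    tb <- thr_module_bwd(cache$thr$cache, st0$gtau)
    g$thr <- tb$grads
    st <- soft_thr_bwd_c(cache$h2, cache$thr$tau, gy, t(tb$gU))
    gh2 <- st$gx
  }
  cb2 <- conv1d_bwd(cache$a2, params$conv2$w, gh2, 1L, pad)
  g$conv2 <- list(w = cb2$gw, b = cb2$gb)
  ga2 <- cb2$gx
  gbn2y <- elu_bwd_c(ga2, cache$a2)
  b2 <- bn_sp_bwd(cache$bn2, gbn2y)
  g$bn2 <- list(gamma = b2$ggamma, beta = b2$gbeta)
  gh1 <- b2$gx
  cb1 <- conv1d_bwd(cache$a1, params$conv1$w, gh1, params$stride, pad)
  g$conv1 <- list(w = cb1$gw, b = cb1$gb)
  ga1 <- cb1$gx
  ## shortcut
  if (params$variant == "identity") {
    gx_short <- gy
  } else {
    bs <- bn_sp_bwd(cache$scache$bns, gy)
    g$bns <- list(gamma = bs$ggamma, beta = bs$gbeta)
    cbs <- conv1d_bwd(cache$scache$a1, params$convs$w, bs$gx,
                      params$stride, 0L)
    g$convs <- list(w = cbs$gw, b = cbs$gb)
    ga1 <- ga1 + cbs$gx
    gx_short <- NULL
  }
  gbn1y <- elu_bwd_c(ga1, cache$a1)
  b1 <- bn_sp_bwd(cache$bn1, gbn1y)
  g$bn1 <- list(gamma = b1$ggamma, beta = b1$gbeta)
  gx <- b1$gx
  if (!is.null(gx_short)) gx <- gx + gx_short
  list(gx = gx, grads = g)
}


#' 1x1 convolution head
#'
#' Reduces a `(W, 16, N)` representation to `(W, 1, N)` without changing the
#' width; far fewer parameters (16 + 1) than a dense layer on the flattened
#' map (`16 W + 1`).
#'
#' @param r `(W, C, N)` array with `C = 16` channels (or `W x 16` matrix).
#' @param w length-16 kernel; `b` scalar bias.
#' @param b bias.
#' @return `(W, 1, N)` array.
#' @export
conv1x1_head <- function(r, w, b = 0) {
  if (is.matrix(r)) dim(r) <- c(nrow(r), ncol(r), 1L)
  stop_if(dim(r)[2] != length(w),
          "representation has ", dim(r)[2], " channels but kernel expects ",
          length(w))
  wa <- array(w, dim = c(1L, length(w), 1L))
  conv1d_fwd(r, wa, b, 1L, 0L)
}

net_forward <- function(net, x, train = FALSE, ablate = FALSE,
                        keep_cache = TRUE) {
  caches <- list()
  h <- x
  for (i in seq_along(net$blocks)) {
    out <- rsbu_forward(h, net$blocks[[i]], train, ablate)
    net$blocks[[i]] <- out$params
    if (keep_cache) caches[[i]] <- out$cache
    h <- out$y
  }
  bnh <- bn_sp_fwd(h, net$bn_head$gamma, net$bn_head$beta, net$bn_head$run,
                   train)
  net$bn_head$run <- bnh$run
  ah <- elu_fwd(bnh$y)
  y1 <- conv1d_fwd(ah, net$head$w, net$head$b, 1L, 0L)
  W <- dim(y1)[1]; N <- dim(y1)[3]
  v <- .colMeans(matrix(y1, nrow = W), W, N)
  p <- 100 / (1 + exp(-v))
  list(net = net, p = p, v = v,
       cache = if (keep_cache) list(blocks = caches, h = h, bnh = bnh$cache,
                                    ah = ah, y1 = y1, W = W, N = N) else NULL)
}

net_backward <- function(net, cache, gp) {
  W <- cache$W; N <- cache$N
  p <- 100 / (1 + exp(-(.colMeans(matrix(cache$y1, nrow = W), W, N))))
  gv <- gp * p * (100 - p) / 100
  gy1 <- array(rep(gv, each = W) / W, dim = dim(cache$y1))
  chb <- conv1d_bwd(cache$ah, net$head$w, gy1, 1L, 0L)
  grads <- list(head = list(w = chb$gw, b = chb$gb))
  gah <- chb$gx
  gbnh <- elu_bwd_c(gah, cache$ah)
  bh <- bn_sp_bwd(cache$bnh, gbnh)
  grads$bn_head <- list(gamma = bh$ggamma, beta = bh$gbeta)
  gh <- bh$gx
  gblocks <- vector("list", length(net$blocks))
  for (i in rev(seq_along(net$blocks))) {
    bb <- rsbu_backward(net$blocks[[i]], cache$blocks[[i]], gh)
    gblocks[[i]] <- bb$grads
    gh <- bb$gx
  }
  grads$blocks <- gblocks
  grads
}

## ---- parameter tree utilities ---------------------------------------------

flatten_tree <- function(x, path = "") {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (nm %in% c("variant", "stride", "run")) next
    key <- paste0(path, "/", nm)
    if (is.list(v)) out <- c(out, flatten_tree(v, key))
    else if (is.numeric(v)) out[[key]] <- v
  }
  out
}

flatten_blocks <- function(net_or_grads) {
  out <- list()
  for (i in seq_along(net_or_grads$blocks))
    out <- c(out, flatten_tree(net_or_grads$blocks[[i]], sprintf("b%02d", i)))
  for (nm in setdiff(names(net_or_grads), "blocks"))
    out <- c(out, flatten_tree(net_or_grads[nm], ""))
  out
}

assign_tree <- function(net, flat) {
  set_path <- function(obj, parts, value) {
    if (length(parts) == 1L) { obj[[parts]] <- value; return(obj) }
    obj[[parts[1]]] <- set_path(obj[[parts[1]]], parts[-1], value)
    obj
  }
  for (key in names(flat)) {
    parts <- strsplit(sub("^/", "", key), "/")[[1]]
    if (grepl("^b[0-9]+$", parts[1])) {
      i <- as.integer(sub("b", "", parts[1]))
      net$blocks[[i]] <- set_path(net$blocks[[i]], parts[-1], flat[[key]])
    } else {
      net <- set_path(net, parts, flat[[key]])
    }
  }
  net
}

## keys subject to L2 weight decay: convolution and FC weights only
decay_key <- function(key) grepl("/(w|W1|W2)$", key)
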