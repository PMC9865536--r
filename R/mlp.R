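## Small fully connected regressor (used for the 14-64-16-1 ANN baseline).
## ReLU hidden activations, linear output, Adam with the same protocol as
## the deep model (batch 64, lr 0.005 decaying 10% every 20 epochs, L2).

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(i) {
      list(W = matrix(rnorm(sizes[i] * sizes[i + 1], 0,
                            sqrt(2 / sizes[i])), sizes[i], sizes[i + 1]),
           b = rep(0, sizes[i + 1]))
    })
  })
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  h <- X
  for (i in seq_along(layers)) {
    h <- h %*% layers[[i]]$W + rep(layers[[i]]$b, each = nrow(h))
    if (i < length(layers)) h <- pmax(h, 0)
    acts[[i + 1L]] <- h
  }
  list(out = h, acts = acts)
}

mlp_fit <- function(X, y, hidden = c(64L, 16L), batch_size = 64L,
                    lr = 0.005, lr_decay = 0.9, lr_decay_every = 20L,
                    epochs = 120L, weight_decay = 1e-4, seed = 1L) {
  X <- as.matrix(X); N <- nrow(X)
  sizes <- c(ncol(X), hidden, 1L)
  layers <- mlp_init(sizes, seed)
  mstate <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  vstate <- mstate
  t <- 0
  for (epoch in seq_len(epochs)) {
    lrate <- lr * lr_decay^(epoch %/% lr_decay_every)
    ord <- with_seed(child_seed(seed, 2000L + epoch), sample(N))
    for (b0 in seq(1L, N, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, N)]
      fw <- mlp_forward(layers, X[idx, , drop = FALSE])
      err <- fw$out[, 1] - y[idx]
      g <- matrix(2 * err / length(err), ncol = 1)
      t <- t + 1
      for (i in rev(seq_along(layers))) {
        a <- fw$acts[[i]]
        gW <- crossprod(a, g) + weight_decay * layers[[i]]$W
        gb <- colSums(g)
        if (i > 1L) g <- tcrossprod(g, layers[[i]]$W) * (fw$acts[[i]] > 0)
        for (nm in c("W", "b")) {
          gr <- if (nm == "W") gW else gb
          mstate[[i]][[nm]] <- 0.9 * mstate[[i]][[nm]] + 0.1 * gr
          vstate[[i]][[nm]] <- 0.999 * vstate[[i]][[nm]] + 0.001 * gr^2
          layers[[i]][[nm]] <- layers[[i]][[nm]] - lrate *
            (mstate[[i]][[nm]] / (1 - 0.9^t)) /
            (sqrt(vstate[[i]][[nm]] / (1 - 0.999^t)) + 1e-8)
        }
      }
    }
  }
  structure(list(layers = layers, sizes = sizes), class = "anescore_mlp")
}

mlp_predict <- function(model, X) {
  mlp_forward(model$layers, as.matrix(X))$out[, 1]
}
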