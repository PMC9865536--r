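## Fixed-point (FastICA-style) independent component analysis.
##
## Used to separate ocular-artifact sources from EEG sources within the IMF
## stack of each wavelet coefficient.  Symmetric decorrelation with the
## log-cosh contrast; whitening by eigendecomposition with a relative rank
## cutoff (IMF stacks are often nearly rank-deficient).

#' Independent component analysis of a signal stack
#'
#' Decomposes `n_sig` mixed signals (rows) into independent components such
#' that `X ~= mixing %*% S + rowmeans`.  With fewer than 2 rows the input is
#' passed through unchanged.
#'
#' @param X numeric matrix, one mixed signal per row.
#' @param max_iter maximum fixed-point iterations.
#' @param tol convergence tolerance on the unmixing update.
#' @param rng_seed seed for the random orthogonal initialisation.
#' @return list of class `"ica_decomposition"` with `S` (components x n),
#'   `mixing` (n_sig x n_comp), `rowmeans`, and `converged`.  If the
#'   iteration fails to converge a warning is raised and an identity
#'   fall-back (components = centered inputs) is returned.
#' @export
ica_decompose <- function(X, max_iter = 200L, tol = 1e-4, rng_seed = 1L) {
  X <- as.matrix(X)
  p <- nrow(X); n <- ncol(X)
  mu <- rowMeans(X)
  if (p < 2L) {
    return(structure(list(S = X - mu, mixing = diag(1, p), rowmeans = mu,
                          converged = TRUE),
                     class = "ica_decomposition"))
  }
  Xc <- X - mu
  CV <- (Xc %*% t(Xc)) / n
  eg <- eigen(CV, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10 & eg$values > 0
  if (!any(keep)) {
    return(structure(list(S = Xc, mixing = diag(1, p), rowmeans = mu,
                          converged = TRUE),
                     class = "ica_decomposition"))
  }
  E <- eg$vectors[, keep, drop = FALSE]
  D <- eg$values[keep]
  K <- diag(1 / sqrt(D), length(D)) %*% t(E)      # whitening, k x p
  Z <- K %*% Xc                                    # whitened, k x n
  k <- nrow(Z)
  W <- with_seed(rng_seed, {
    M <- matrix(rnorm(k * k), k, k)
    qr.Q(qr(M))
  })
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- 1 - G^2
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(gprime), k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("ICA did not converge in ", max_iter,
            " iterations; treating inputs as already-separated components")
    return(structure(list(S = Xc, mixing = diag(1, p), rowmeans = mu,
                          converged = FALSE),
                     class = "ica_decomposition"))
  }
  S <- W %*% Z
  ## mixing such that Xc ~= mixing %*% S (pseudo-inverse of the unmixing map)
  mixing <- E %*% diag(sqrt(D), length(D)) %*% t(W)
  structure(list(S = S, mixing = mixing, rowmeans = mu, converged = TRUE),
            class = "ica_decomposition")
}

#' Reconstruct a signal stack from independent components
#'
#' @param dec an `"ica_decomposition"` from [ica_decompose()].
#' @param keep_mask logical vector, one entry per component; components with
#'   `FALSE` are zeroed before mixing back (artifact rejection).  Defaults to
#'   keeping everything, which reproduces the input to numerical precision
#'   (up to any rank truncation in whitening).
#' @return matrix of the same shape as the original input.
#' @export
ica_reconstruct <- function(dec, keep_mask = NULL) {
  stopifnot(inherits(dec, "ica_decomposition"))
  S <- dec$S
  if (is.null(keep_mask)) keep_mask <- rep(TRUE, nrow(S))
  stop_if(length(keep_mask) != nrow(S),
          "keep_mask length ", length(keep_mask), " != number of components ",
          nrow(S))
  Sk <- S * as.numeric(keep_mask)
  dec$mixing %*% Sk + dec$rowmeans
}
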