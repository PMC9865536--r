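## Multilevel discrete wavelet transform (periodized, orthogonal).
##
## The EOA-removal chain decomposes each EEG channel into wavelet
## sub-bands before the ensemble empirical-mode decomposition stage.
## Periodization keeps the transform orthogonal and exactly invertible;
## odd-length inputs are extended by one repeated sample per level and the
## original length is restored on reconstruction, so the round trip is exact.

## Orthonormal scaling (lowpass) decomposition filters.
.wt_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db4 = c(-0.010597401784997278, 0.032883011666982945,
          0.030841381835986965, -0.18703481171888114,
          -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523)
)

wt_filter_pair <- function(wavelet) {
  lo <- .wt_filters[[wavelet]]
  stop_if(is.null(lo), "unknown wavelet '", wavelet, "'")
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  list(lo = lo, hi = hi)
}

## one periodized analysis step on an even-length signal
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  half <- n / 2L
  a <- numeric(half)
  d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(lo)) {
    idx <- (base + (k - 1L)) %% n + 1L
    a <- a + lo[k] * x[idx]
    d <- d + hi[k] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, lo, hi) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(lo)) {
    idx <- (base + (k - 1L)) %% n + 1L
    x[idx] <- x[idx] + lo[k] * a + hi[k] * d
  }
  x
}

#' Multilevel wavelet decomposition
#'
#' Decomposes a signal into detail coefficients `d1..dL` (fine to coarse) and
#' the final approximation `aL` using a periodized orthogonal wavelet.
#' [wt_reconstruct()] inverts the transform exactly.
#'
#' @param x numeric signal (finite values).
#' @param wavelet one of `"db4"` (default), `"db2"`, `"haar"`.
#' @param levels number of decomposition levels.
#' @return an object of class `"wt_decomposition"`: a list with `coeffs`
#'   (named list `d1`, ..., `dL`, `aL`), the wavelet name and the per-level
#'   input lengths needed for exact reconstruction.
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 1, length.out = 256))
#' w <- wt_decompose(x, levels = 3)
#' max(abs(wt_reconstruct(w) - x)) < 1e-10
#' @export
wt_decompose <- function(x, wavelet = "db4", levels = 4L) {
  stop_if(!all(is.finite(x)), "signal contains non-finite values")
  flt <- wt_filter_pair(wavelet)
  maxlev <- floor(log2(max(length(x), 1) / length(flt$lo))) + 1
  stop_if(levels > maxlev,
          "requested ", levels, " levels but signal of length ", length(x),
          " supports at most ", maxlev)
  coeffs <- list()
  lens <- integer(levels)
  cur <- x
  for (lev in seq_len(levels)) {
    lens[lev] <- length(cur)
    if (length(cur) %% 2L == 1L) cur <- c(cur, cur[length(cur)])
    st <- dwt_step(cur, flt$lo, flt$hi)
    coeffs[[paste0("d", lev)]] <- st$d
    cur <- st$a
  }
  coeffs[[paste0("a", levels)]] <- cur
  structure(list(coeffs = coeffs, wavelet = wavelet, levels = levels,
                 lens = lens),
            class = "wt_decomposition")
}

#' Invert a multilevel wavelet decomposition
#'
#' @param w a `"wt_decomposition"` from [wt_decompose()], possibly with
#'   modified coefficients.
#' @return the reconstructed signal, same length as the original input.
#' @export
wt_reconstruct <- function(w) {
  stopifnot(inherits(w, "wt_decomposition"))
  flt <- wt_filter_pair(w$wavelet)
  cur <- w$coeffs[[paste0("a", w$levels)]]
  for (lev in rev(seq_len(w$levels))) {
    cur <- idwt_step(cur, w$coeffs[[paste0("d", lev)]], flt$lo, flt$hi)
    cur <- cur[seq_len(w$lens[lev])]
  }
  cur
}
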