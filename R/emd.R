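## Ensemble empirical-mode decomposition with adaptive noise.
##
## The sifting core (extrema detection, cubic-spline envelopes) is compiled
## code; this file orchestrates the complete-ensemble scheme: at each stage
## the k-th mode is the ensemble average of first modes extracted from the
## current residue perturbed by the k-th mode of the noise realisations,
## which makes the decomposition complete by construction
## (sum of modes + residue == input exactly).

#' Empirical-mode decomposition
#'
#' Plain EMD of a signal into intrinsic mode functions (IMFs), ordered from
#' fastest to slowest oscillation, plus a monotone residue.
#'
#' @param x numeric signal.
#' @param max_imfs maximum number of modes to extract.
#' @param max_sift maximum sifting iterations per mode.
#' @param sd_thresh sifting stop threshold on the relative envelope-mean
#'   energy.
#' @return list with `imfs` (matrix, one row per mode; zero rows for a
#'   constant/monotone input) and `residue`.
#' @export
emd <- function(x, max_imfs = 8L, max_sift = 30L, sd_thresh = 0.05) {
  stop_if(!all(is.finite(x)), "signal contains non-finite values")
  emd_c(as.numeric(x), as.integer(max_imfs), as.integer(max_sift), sd_thresh)
}

#' Complete ensemble empirical-mode decomposition with adaptive noise
#'
#' Decomposes a signal into IMFs using an ensemble of white-noise
#' realisations whose own modes are injected stage by stage, then removed by
#' averaging.  Completeness is exact: `colSums(imfs) + residue == x`.
#'
#' @param x numeric signal, length >= 16.
#' @param ensemble_size number of noise realisations.
#' @param noise_std noise standard deviation as a fraction of `sd(x)`.
#' @param max_imfs maximum number of modes.
#' @param rng_seed integer seed making the decomposition deterministic.
#' @param max_sift,sd_thresh sifting controls passed to the EMD core.
#' @return list with `imfs` (n_modes x n matrix) and `residue`; a constant
#'   input yields zero modes and `residue == x`.
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 1, length.out = 128)) +
#'   0.5 * sin(2 * pi * 40 * seq(0, 1, length.out = 128))
#' dec <- ceemdan(x, ensemble_size = 20, rng_seed = 1)
#' max(abs(colSums(dec$imfs) + dec$residue - x)) < 1e-8
#' @export
ceemdan <- function(x, ensemble_size = 50L, noise_std = 0.2, max_imfs = 8L,
                    rng_seed = 1L, max_sift = 30L, sd_thresh = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  stop_if(n < 16L, "signal too short for ensemble decomposition (length ",
          n, " < 16)")
  stop_if(!all(is.finite(x)), "signal contains non-finite values")
  sx <- sd(x)
  if (!is.finite(sx) || sx == 0) {
    return(list(imfs = matrix(numeric(0), nrow = 0, ncol = n), residue = x))
  }
  with_seed(rng_seed, {
    noise <- matrix(rnorm(ensemble_size * n), nrow = ensemble_size)
    ## modes of each noise realisation, computed once
    noise_modes <- lapply(seq_len(ensemble_size), function(i)
      emd_c(noise[i, ], as.integer(max_imfs), as.integer(max_sift), sd_thresh)$imfs)
    imfs <- matrix(0, nrow = 0, ncol = n)
    resid <- x
    for (k in seq_len(max_imfs)) {
      sr <- sd(resid)
      if (!is.finite(sr) || sr == 0) break
      ## stop when the residue no longer oscillates
      if (nrow(emd_c(resid, 1L, as.integer(max_sift), sd_thresh)$imfs) == 0) break
      acc <- numeric(n)
      for (i in seq_len(ensemble_size)) {
        nm <- noise_modes[[i]]
        pert <- if (nrow(nm) >= k) {
          sn <- sd(nm[k, ])
          if (sn > 0) noise_std * sr * nm[k, ] / sn else numeric(n)
        } else numeric(n)
        acc <- acc + emd_first_imf(resid + pert, as.integer(max_sift), sd_thresh)
      }
      mode_k <- acc / ensemble_size
      if (sd(mode_k) < 1e-12 * sx) break
      imfs <- rbind(imfs, mode_k)
      resid <- resid - mode_k
    }
    rownames(imfs) <- NULL
    list(imfs = imfs, residue = resid)
  })
}
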