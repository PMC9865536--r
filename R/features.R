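## Spectral and entropy features for the conventional baselines: multitaper
## power spectral density, absolute/relative band powers over the canonical
## EEG bands (delta 1-4, theta 4-8, alpha 8-14, beta 14-31, gamma 31-51 Hz),
## the 95% spectral edge frequency per hemisphere, and per-channel sample
## entropy -- 14 features per 4 x 712 sample.

## Discrete prolate spheroidal (Slepian) tapers via the symmetric
## tridiagonal formulation; cached per (n, nw, k).
dpss_tapers <- function(n, nw = 2.5, k = 4L) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  cache_get(key, function() {
    W <- nw / n
    i <- seq_len(n) - 1
    diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
    off_v <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
    M <- diag(diag_v)
    M[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off_v
    M[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off_v
    eg <- eigen(M, symmetric = TRUE)
    H <- eg$vectors[, seq_len(k), drop = FALSE]
    ## normalise and fix sign (positive mean for symmetric tapers)
    for (j in seq_len(k)) {
      H[, j] <- H[, j] / sqrt(sum(H[, j]^2))
      if (sum(H[, j]) < 0) H[, j] <- -H[, j]
    }
    H
  })
}

#' Multitaper power spectral density
#'
#' Averages periodograms over discrete prolate spheroidal (Slepian) tapers.
#' The one-sided density integrates (rectangle rule, `df = fs/n`) to the
#' signal variance.
#'
#' @param x numeric signal, length >= 64.
#' @param fs sampling rate, Hz.
#' @param nw time-bandwidth product.
#' @param k number of tapers (defaults to `2*nw - 1` rounded).
#' @return list with `freq` (0 to fs/2) and `power` (density, unit^2/Hz).
#' @export
multitaper_psd <- function(x, fs, nw = 2.5, k = NULL) {
  n <- length(x)
  stop_if(n < 64L, "signal too short for spectral estimation (length ",
          n, " < 64)")
  stop_if(!all(is.finite(x)), "signal contains non-finite values")
  if (is.null(k)) k <- max(1L, as.integer(round(2 * nw - 1)))
  H <- dpss_tapers(n, nw, k)
  nh <- n %/% 2L
  acc <- numeric(nh + 1L)
  for (j in seq_len(k)) {
    X <- fft(H[, j] * x)
    acc <- acc + Mod(X[seq_len(nh + 1L)])^2
  }
  S <- acc / (k * fs)                   # two-sided density on [0, fs/2]
  S[2:(nh + (n %% 2L))] <- 2 * S[2:(nh + (n %% 2L))]  # fold negative freqs
  list(freq = (0:nh) * fs / n, power = S)
}

.band_names <- c("delta", "theta", "alpha", "beta", "gamma")

#' Absolute and relative EEG band powers
#'
#' Integrates a PSD over delta \[1,4), theta \[4,8), alpha \[8,14),
#' beta \[14,31) and gamma \[31,51) Hz.  The five bands partition 1-51 Hz,
#' so the relative powers sum to one exactly.
#'
#' @param psd list with `freq` and `power` (from [multitaper_psd()]).
#' @return list with `absolute` and `relative`, both named 5-vectors, and
#'   `total` (1-51 Hz power).
#' @export
band_powers <- function(psd) {
  stop_if(max(psd$freq) < 51, "PSD must cover 1-51 Hz (max freq ",
          round(max(psd$freq), 2), ")")
  df <- psd$freq[2] - psd$freq[1]
  absolute <- vapply(seq_len(5), function(b) {
    idx <- psd$freq >= .band_edges[b, 1] & psd$freq < .band_edges[b, 2]
    sum(psd$power[idx]) * df
  }, numeric(1))
  names(absolute) <- .band_names
  total <- sum(absolute)
  stop_if(total <= 0, "zero total band power; relative powers undefined")
  list(absolute = absolute, relative = absolute / total, total = total)
}

#' 95% spectral edge frequency
#'
#' The smallest grid frequency below which 95% of the 1-51 Hz power lies.
#'
#' @param psd list with `freq` and `power`.
#' @return frequency in Hz.
#' @export
sef95 <- function(psd) {
  idx <- which(psd$freq >= 1 & psd$freq <= 51)
  p <- psd$power[idx]
  tot <- sum(p)
  stop_if(tot <= 0, "zero power in 1-51 Hz; spectral edge undefined")
  cum <- cumsum(p)
  psd$freq[idx[which(cum >= 0.95 * tot)[1]]]
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A/B)` where `B` counts pairs of length-`m` templates
#' within Chebyshev distance `r` (self-matches excluded) and `A` the same
#' for length `m+1`.  Returns `0` for a constant signal and `Inf` when no
#' `(m+1)`-length matches exist.
#'
#' @param x numeric series, length > m + 1.
#' @param m template length.
#' @param r_factor tolerance as a multiple of `sd(x)`.
#' @return nonnegative entropy (possibly `Inf`).
#' @export
sample_entropy <- function(x, m = 2L, r_factor = 0.2) {
  x <- as.numeric(x)
  stop_if(length(x) <= m + 1L, "series too short for m = ", m)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  cnt <- sampen_counts(x, as.integer(m), r_factor * s)
  if (cnt[2] == 0 || cnt[1] == 0) return(Inf)
  -log(cnt[1] / cnt[2])
}

#' Extract the 14-feature vector from a sample
#'
#' Order: total power (all four frontopolar channels), total power left
#' hemisphere (L1, L2), total power right hemisphere (R1, R2); relative
#' delta/theta/alpha/beta/gamma power of the all-channel average PSD; SEF95
#' of the left- and right-hemisphere average PSDs; sample entropy of each
#' channel (L1, L2, R1, R2).
#'
#' @param sample an [eeg_segment()], or a 4 x n matrix (then `fs` required).
#' @param fs sampling rate when `sample` is a bare matrix.
#' @param sampen_m,sampen_r_factor sample-entropy parameters.
#' @return named numeric vector of length 14.
#' @export
extract_features <- function(sample, fs = NULL, sampen_m = 2L,
                             sampen_r_factor = 0.2) {
  if (inherits(sample, "eeg_segment")) {
    data <- sample$data; fs <- sample$fs
  } else {
    data <- as.matrix(sample)
    stop_if(is.null(fs), "fs must be given for a bare matrix")
  }
  stop_if(nrow(data) != 4L, "expected 4 channels")
  psds <- lapply(1:4, function(ch) multitaper_psd(data[ch, ], fs))
  freq <- psds[[1]]$freq
  pow <- vapply(psds, `[[`, numeric(length(freq)), "power")
  df <- freq[2] - freq[1]
  in_band <- freq >= 1 & freq < 51
  ch_total <- colSums(pow[in_band, , drop = FALSE]) * df
  avg_all <- list(freq = freq, power = rowMeans(pow))
  avg_left <- list(freq = freq, power = rowMeans(pow[, 1:2, drop = FALSE]))
  avg_right <- list(freq = freq, power = rowMeans(pow[, 3:4, drop = FALSE]))
  rel <- band_powers(avg_all)$relative
  se <- vapply(1:4, function(ch)
    sample_entropy(data[ch, ], sampen_m, sampen_r_factor), numeric(1))
  ## a silent hemisphere has no defined spectral edge; use the lower band
  ## edge so the degenerate case stays representable in a feature table
  sef_safe <- function(psd) if (sum(psd$power) > 0) sef95(psd) else 1
  out <- c(sum(ch_total), sum(ch_total[1:2]), sum(ch_total[3:4]),
           rel, sef_safe(avg_left), sef_safe(avg_right), se)
  names(out) <- feature_names()
  out
}

#' The fixed 14-feature order
#' @return character vector of length 14.
#' @export
feature_names <- function() {
  c("total_power_frontopolar", "total_power_left", "total_power_right",
    paste0("rel_power_", .band_names), "sef95_left", "sef95_right",
    paste0("sampen_", .eeg_channels))
}

#' Feature table for a whole sample set
#'
#' @param samples a `"doa_samples"` object from [prepare_samples()].
#' @return N x 14 matrix with columns [feature_names()].
#' @export
features_table <- function(samples) {
  stopifnot(inherits(samples, "doa_samples"))
  t(vapply(seq_len(nrow(samples$x)), function(i)
    extract_features(sample_matrix(samples, i), fs = samples$fs),
    numeric(14)))
}
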