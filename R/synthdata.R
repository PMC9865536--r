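## Synthetic multi-subject EEG with known depth -> spectrum -> PSI structure.
##
## The clinical recordings this pipeline targets are not public, so the
## generator defines the ground truth instead: a latent depth d(t) in [0,1]
## drives the delta/theta/alpha/beta/gamma band mixture of every channel,
## and the ground-truth PSI is defined as round(100 * (1 - d)).  Depth in
## means: more delta, less beta/gamma, plus an alpha bump at moderate depth
## (the frontal alpha seen under sedation), so spectral content suffices to
## recover PSI.  Ocular (blink) artifacts, 50 Hz line noise, baseline drift
## and per-subject amplitude gain provide the nuisance structure.

#' Default depth-to-band-weight mapping
#'
#' Maps latent anesthetic depth `d` in \[0,1\] to nonnegative relative weights
#' of the five EEG bands (delta, theta, alpha, beta, gamma).  Awake (`d = 0`)
#' is beta/gamma-rich; deep (`d = 1`) is delta-dominant; alpha power peaks at
#' moderate depth.
#'
#' @param d numeric vector of depths in \[0,1\].
#' @return a `length(d) x 5` matrix with columns `delta`, `theta`, `alpha`,
#'   `beta`, `gamma`.
#' @export
default_band_weights <- function(d) {
  w <- cbind(
    delta = 0.15 + 2.6 * d^2,
    theta = 0.15 + 0.5 * d,
    alpha = 0.25 + 1.1 * exp(-(d - 0.55)^2 / (2 * 0.12^2)),
    beta  = 0.08 + 0.9 * (1 - d)^2,
    gamma = 0.03 + 0.45 * (1 - d)^3
  )
  w
}

#' Simulation specification for synthetic EEG
#'
#' @param n_subjects number of subjects.
#' @param duration_per_subject recording length per subject, seconds.
#' @param fs sampling rate in Hz.
#' @param band_weight_fn function mapping depth in \[0,1\] to a 5-column
#'   matrix of nonnegative band weights (see [default_band_weights()]).
#' @param artifact_rate blink rate, events per minute.
#' @param artifact_amplitude_ratio blink peak amplitude as a multiple of the
#'   clean-EEG RMS.
#' @param line_noise_amplitude 50 Hz line-noise amplitude, microvolts.
#' @param drift_amplitude RMS of the sub-0.5 Hz baseline drift, microvolts.
#' @param subject_gain_sd log-scale SD of the per-subject lognormal gain.
#' @param base_rms_uV nominal clean-EEG RMS before the subject gain.
#' @param background_fraction fraction of clean-signal power given to the
#'   1/f broadband background (0 disables it).
#' @param seed integer seed; everything derived from a spec is deterministic
#'   given this value.
#' @return an object of class `"sim_spec"`.
#' @export
sim_spec <- function(n_subjects = 10L, duration_per_subject = 420,
                     fs = 178.2, band_weight_fn = default_band_weights,
                     artifact_rate = 6, artifact_amplitude_ratio = 5,
                     line_noise_amplitude = 5, drift_amplitude = 10,
                     subject_gain_sd = 0.3, base_rms_uV = 15,
                     background_fraction = 0.05, seed = 1L) {
  spec <- structure(list(
    n_subjects = as.integer(n_subjects),
    duration_per_subject = duration_per_subject, fs = fs,
    band_weight_fn = band_weight_fn, artifact_rate = artifact_rate,
    artifact_amplitude_ratio = artifact_amplitude_ratio,
    line_noise_amplitude = line_noise_amplitude,
    drift_amplitude = drift_amplitude, subject_gain_sd = subject_gain_sd,
    base_rms_uV = base_rms_uV, background_fraction = background_fraction,
    seed = as.integer(seed)), class = "sim_spec")
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  stop_if(spec$n_subjects < 1L, "n_subjects must be >= 1")
  stop_if(!is.finite(spec$fs) || spec$fs <= 0, "fs must be positive")
  stop_if(spec$artifact_rate < 0, "artifact_rate must be >= 0")
  stop_if(spec$duration_per_subject <= 0, "duration_per_subject must be > 0")
  w <- spec$band_weight_fn(seq(0, 1, by = 0.05))
  stop_if(!all(is.finite(w)), "band_weight_fn produced non-finite weights")
  stop_if(any(w < 0), "band_weight_fn produced negative weights")
  invisible(spec)
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Synthetic EEG simulation spec\n")
  cat(sprintf("  %d subject(s), %.0f s each at %.1f Hz\n", x$n_subjects,
              x$duration_per_subject, x$fs))
  cat(sprintf("  blinks: %.1f/min at %.1fx RMS; line 50 Hz %.1f uV; drift %.1f uV\n",
              x$artifact_rate, x$artifact_amplitude_ratio,
              x$line_noise_amplitude, x$drift_amplitude))
  cat(sprintf("  subject gain sd %.2f (lognormal), base RMS %.1f uV, seed %d\n",
              x$subject_gain_sd, x$base_rms_uV, x$seed))
  invisible(x)
}

.eeg_channels <- c("L1", "L2", "R1", "R2")

#' Construct an EEG record
#'
#' @param data channels x samples matrix, microvolts.
#' @param fs sampling rate, Hz.
#' @param channel_names ordered channel labels.
#' @param subject_id identifier.
#' @return object of class `"eeg_record"`.
#' @export
eeg_record <- function(data, fs, channel_names = .eeg_channels,
                       subject_id = "S01") {
  data <- as.matrix(data)
  stop_if(nrow(data) != 4L, "an EEG record must have exactly 4 channels")
  stop_if(!all(is.finite(data)), "EEG record contains non-finite values")
  stop_if(!is.finite(fs) || fs <= 0, "fs must be positive")
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 subject_id = subject_id), class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("EEG record %s: 4 x %d samples (%.1f s at %.1f Hz)\n",
              x$subject_id, ncol(x$data), ncol(x$data) / x$fs, x$fs))
  invisible(x)
}

#' Depth-of-anesthesia trajectory
#'
#' Generates a piecewise-smooth latent depth trajectory following an
#' awake -> induction -> maintenance (with a brief deep excursion) ->
#' emergence -> awake course, with subject-specific smooth jitter.  Ground
#' truth PSI is `round(100 * (1 - d))` clipped to \[0, 100\], so awake time
#' dominates and deep anesthesia is the rarest state.
#'
#' @param duration length in seconds.
#' @param dt grid step of the trajectory, seconds.
#' @param seed integer seed.
#' @param depth_fn optional function of time (seconds) returning depth in
#'   \[0,1\]; overrides the built-in surgical profile (useful for constant-
#'   depth test data).
#' @return object of class `"depth_trajectory"` with `times`, `depth`, `psi`.
#' @export
depth_trajectory <- function(duration, dt = 0.25, seed = 1L,
                             depth_fn = NULL) {
  times <- seq(0, duration, by = dt)
  if (!is.null(depth_fn)) {
    depth <- pmin(pmax(depth_fn(times), 0), 1)
  } else {
    nodes_t <- c(0, 0.20, 0.26, 0.34, 0.38, 0.43, 0.47, 0.60,
                 0.66, 0.74, 0.80, 1.00)
    nodes_d <- c(0.05, 0.07, 0.60, 0.62, 0.80, 0.82, 0.62, 0.60,
                 0.40, 0.38, 0.10, 0.05)
    depth <- with_seed(seed, {
      jt <- c(0, pmin(pmax(nodes_t[2:11] + rnorm(10, 0, 0.01), 0.01), 0.99), 1)
      jt <- sort(jt)
      base <- approx(jt * duration, nodes_d, xout = times, rule = 2)$y
      ## smooth subject-specific wander (moving average of white noise)
      wn <- rnorm(length(times), 0, 1)
      ## ~30 s smoothing window, capped for short recordings
      k <- min(max(3L, as.integer(round(30 / dt))),
               max(3L, length(times) %/% 3L))
      wander <- stats::filter(wn, rep(1 / k, k), sides = 2, circular = TRUE)
      wander <- as.numeric(wander) / max(sd(as.numeric(wander)), 1e-12) * 0.04
      pmin(pmax(base + wander, 0.02), 0.95)
    })
  }
  psi <- pmin(pmax(round(100 * (1 - depth)), 0), 100)
  structure(list(times = times, depth = depth, psi = psi),
            class = "depth_trajectory")
}

#' Interpolate trajectory depth / PSI at arbitrary times
#' @param trajectory a `"depth_trajectory"`.
#' @param t times in seconds.
#' @return list with `depth` and `psi` at `t` (PSI rounded to integers).
#' @export
trajectory_at <- function(trajectory, t) {
  d <- approx(trajectory$times, trajectory$depth, xout = t, rule = 2)$y
  list(depth = d, psi = pmin(pmax(round(100 * (1 - d)), 0), 100))
}

## band-limited unit-variance Gaussian noise via brick-wall FFT masking
bandlimited_noise <- function(n, fs, f_lo, f_hi, shape = NULL) {
  wn <- rnorm(n)
  sp <- fft(wn)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)  # two-sided
  mask <- freq >= f_lo & freq <= f_hi
  if (!is.null(shape)) {
    g <- numeric(n); g[mask] <- shape(freq[mask]); sp <- sp * g
  } else sp[!mask] <- 0
  out <- Re(fft(sp, inverse = TRUE)) / n
  s <- sd(out)
  if (s > 0) out / s else out
}

.band_edges <- cbind(lo = c(1, 4, 8, 14, 31), hi = c(4, 8, 14, 31, 51))

#' Simulate clean (artifact-free) EEG for one subject
#'
#' Each channel is a sum of five band-limited Gaussian processes whose
#' instantaneous power follows `spec$band_weight_fn(d(t))` (normalised to
#' unit total), plus an optional 1/f broadband background, scaled to
#' `spec$base_rms_uV` times a lognormal per-subject gain.
#'
#' @param spec a [sim_spec()].
#' @param trajectory a [depth_trajectory()] covering the requested duration.
#' @param subject_id identifier stored in the record.
#' @param seed seed (defaults to `spec$seed`); identical spec + seed gives a
#'   bit-identical record.
#' @return an [eeg_record()].
#' @export
simulate_clean_eeg <- function(spec, trajectory, subject_id = "S01",
                               seed = spec$seed) {
  validate_sim_spec(spec)
  duration <- max(trajectory$times)
  stop_if(duration + 1e-9 < spec$duration_per_subject,
          "trajectory covers ", duration, " s < duration_per_subject = ",
          spec$duration_per_subject, " s")
  n <- floor(spec$duration_per_subject * spec$fs)
  tt <- (seq_len(n) - 1) / spec$fs
  d <- trajectory_at(trajectory, tt)$depth
  w <- spec$band_weight_fn(d)
  stop_if(!all(is.finite(w)), "band_weight_fn produced non-finite weights")
  stop_if(any(w < 0), "band_weight_fn produced negative weights")
  tot <- rowSums(w)
  wn <- w / ifelse(tot > 0, tot, 1)  # normalised; zero rows stay zero
  wn[tot == 0, ] <- 0
  fb <- spec$background_fraction
  with_seed(seed, {
    gain <- rlnorm(1, 0, spec$subject_gain_sd)
    data <- matrix(0, 4, n)
    for (ch in 1:4) {
      sig <- numeric(n)
      for (b in 1:5) {
        e <- bandlimited_noise(n, spec$fs, .band_edges[b, 1], .band_edges[b, 2])
        sig <- sig + sqrt(wn[, b]) * e
      }
      if (fb > 0) {
        bg <- bandlimited_noise(n, spec$fs, 1, 51, shape = function(f) 1 / sqrt(f))
        sig <- sqrt(1 - fb) * sig + sqrt(fb) * bg * (tot > 0)
      }
      data[ch, ] <- sig * spec$base_rms_uV * gain
    }
    eeg_record(data, spec$fs, subject_id = subject_id)
  })
}

#' Simulate a blink (ocular-artifact) trace
#'
#' Blink events occur at Poisson times with rate `spec$artifact_rate` per
#' minute; each is a smooth biphasic squared-cosine pulse of 300-500 ms with
#' identical polarity across the four frontal channels and peak amplitude
#' `spec$artifact_amplitude_ratio * clean_rms`.  Spectral content is
#' concentrated below 5 Hz.
#'
#' @param spec a [sim_spec()].
#' @param duration trace length, seconds.
#' @param clean_rms reference clean-EEG RMS in microvolts.
#' @param seed seed (defaults to `spec$seed`).
#' @return a 4 x n matrix (microvolts); all zeros when `artifact_rate = 0`.
#' @export
simulate_eoa_train <- function(spec, duration, clean_rms = spec$base_rms_uV,
                               seed = spec$seed) {
  stop_if(duration <= 0, "duration must be > 0")
  n <- floor(duration * spec$fs)
  out <- matrix(0, 4, n)
  if (spec$artifact_rate <= 0) return(out)
  ## frontopolar channels see slightly larger blink deflections
  ch_gain <- c(1, 0.8, 1, 0.8)
  with_seed(seed, {
    n_ev <- rpois(1, spec$artifact_rate / 60 * duration)
    if (n_ev > 0) {
      t0 <- sort(runif(n_ev, 0, duration))
      width <- runif(n_ev, 0.3, 0.5)
      amp <- spec$artifact_amplitude_ratio * clean_rms * runif(n_ev, 0.9, 1.1)
      tt <- (seq_len(n) - 1) / spec$fs
      pulse <- numeric(n)
      for (ev in seq_len(n_ev)) {
        u <- (tt - t0[ev]) / width[ev]
        main <- ifelse(abs(u) < 0.5, cos(pi * u)^2, 0)
        v <- (tt - t0[ev] - 0.65 * width[ev]) / (0.6 * width[ev])
        rebound <- ifelse(abs(v) < 0.5, cos(pi * v)^2, 0)
        pulse <- pulse + amp[ev] * (main - 0.3 * rebound)
      }
      for (ch in 1:4) out[ch, ] <- ch_gain[ch] * pulse
    }
    out
  })
}

#' Contaminate a clean EEG record
#'
#' Adds the blink-artifact trace, 50 Hz sinusoidal line noise and slow
#' (< 0.5 Hz) baseline drift.  The clean record and each injected component
#' are attached as attributes for paired clean-vs-contaminated comparisons.
#'
#' @param clean an [eeg_record()].
#' @param spec a [sim_spec()].
#' @param seed seed (defaults to `spec$seed`).
#' @return a contaminated [eeg_record()] with attributes `clean` (the input
#'   record) and `components` (list of the injected 4 x n matrices).
#' @export
contaminate <- function(clean, spec, seed = spec$seed) {
  stopifnot(inherits(clean, "eeg_record"))
  n <- ncol(clean$data)
  duration <- n / clean$fs
  clean_rms <- sqrt(mean(clean$data^2))
  if (!is.finite(clean_rms) || clean_rms == 0) clean_rms <- spec$base_rms_uV
  eoa <- simulate_eoa_train(spec, duration, clean_rms,
                            seed = child_seed(seed, 101L))
  eoa <- eoa[, seq_len(n), drop = FALSE]
  tt <- (seq_len(n) - 1) / clean$fs
  line <- matrix(0, 4, n)
  drift <- matrix(0, 4, n)
  with_seed(child_seed(seed, 202L), {
    if (spec$line_noise_amplitude > 0) {
      phases <- runif(4, 0, 2 * pi)
      for (ch in 1:4)
        line[ch, ] <- spec$line_noise_amplitude * sin(2 * pi * 50 * tt + phases[ch])
    }
    if (spec$drift_amplitude > 0) {
      for (ch in 1:4)
        drift[ch, ] <- spec$drift_amplitude *
          bandlimited_noise(n, clean$fs, 0.01, 0.4)
    }
  })
  out <- eeg_record(clean$data + eoa + line + drift, clean$fs,
                    clean$channel_names, clean$subject_id)
  attr(out, "clean") <- clean
  attr(out, "components") <- list(eoa = eoa, line = line, drift = drift)
  out
}

#' Generate a complete multi-subject dataset
#'
#' Every subject gets its own depth trajectory (awake -> deep -> awake with
#' smooth jitter), clean EEG, and contamination.  Deterministic given
#' `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @return object of class `"doa_dataset"`: a list of per-subject entries,
#'   each with `record` (contaminated [eeg_record()], clean attached as an
#'   attribute), `trajectory` and `subject_id`.
#' @export
generate_dataset <- function(spec) {
  validate_sim_spec(spec)
  subjects <- lapply(seq_len(spec$n_subjects), function(s) {
    sid <- sprintf("S%02d", s)
    sd_seed <- child_seed(spec$seed, s)
    traj <- depth_trajectory(spec$duration_per_subject, seed = sd_seed)
    clean <- simulate_clean_eeg(spec, traj, subject_id = sid,
                                seed = child_seed(sd_seed, 1L))
    rec <- contaminate(clean, spec, seed = child_seed(sd_seed, 2L))
    list(record = rec, trajectory = traj, subject_id = sid)
  })
  structure(subjects, class = "doa_dataset", spec = spec)
}

#' @export
print.doa_dataset <- function(x, ...) {
  cat(sprintf("Synthetic DoA dataset: %d subject(s)\n", length(x)))
  for (s in x)
    cat(sprintf("  %s: %.0f s at %.1f Hz\n", s$subject_id,
                ncol(s$record$data) / s$record$fs, s$record$fs))
  invisible(x)
}
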