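# Shared fixtures: small synthetic records built once per test run.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

# a 90 s single-subject record with strong blinks and a paired clean truth
blink_pair <- function() {
  fixture("blink_pair", function() {
    spec <- sim_spec(n_subjects = 1, duration_per_subject = 90,
                     artifact_rate = 10, artifact_amplitude_ratio = 5,
                     line_noise_amplitude = 0, drift_amplitude = 0,
                     seed = 7)
    tr <- depth_trajectory(90, seed = 7)
    clean <- simulate_clean_eeg(spec, tr)
    contaminated <- contaminate(clean, spec)
    list(spec = spec, trajectory = tr, clean = clean,
         contaminated = contaminated)
  })
}

# brute-force O(n^2) sample entropy, independent of the compiled kernel
sampen_bruteforce <- function(x, m = 2L, r_factor = 0.2) {
  n <- length(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  r <- r_factor * s
  A <- 0L; B <- 0L
  nt <- n - m
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      dm <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (dm < r) {
        B <- B + 1L
        if (max(dm, abs(x[i + m] - x[j + m])) < r) A <- A + 1L
      }
    }
  }
  if (B == 0L || A == 0L) return(Inf)
  -log(A / B)
}

# brute-force one-vs-rest confusion tallies from state labels
metrics_bruteforce <- function(pred_state, true_state) {
  states <- c("AW", "LA", "NA", "DA")
  n <- length(pred_state)
  res <- list()
  for (st in states) {
    tp <- sum(pred_state == st & true_state == st)
    fp <- sum(pred_state == st & true_state != st)
    fn <- sum(pred_state != st & true_state == st)
    tn <- n - tp - fp - fn
    se <- if (tp + fn == 0) 0 else tp / (tp + fn)
    pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
    f1 <- if (se + pr == 0) 0 else 2 * se * pr / (se + pr)
    res[[st]] <- c(acc = (tp + tn) / n, se = se, pr = pr, f1 = f1)
  }
  res
}
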