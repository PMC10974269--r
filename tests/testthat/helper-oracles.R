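# Independent oracles and small builders shared across the suite.

# Direct O(N^2) DFT by summation -- independent of stats::fft.
brute_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))
  }, complex(1))
}

# Literal diagonal cross-bispectrum from time samples, via brute_dft.
brute_bispec <- function(xa, xb, n_bins, conj_from = "b", eps = 1e-12) {
  Xa <- brute_dft(xa)
  Xb <- brute_dft(xb)
  Xc <- if (conj_from == "b") Xb else Xa
  vapply(0:(n_bins - 1), function(i) {
    log(max(Mod(Xa[i + 1] * Xb[i + 1] * Conj(Xc[2 * i + 1])), eps))
  }, numeric(1))
}

# Closed-form analog Butterworth magnitude responses (design order n).
butter_bp_mag <- function(f, f1, f2, n) {
  1 / sqrt(1 + ((f^2 - f1 * f2) / (f * (f2 - f1)))^(2 * n))
}
butter_bs_mag <- function(f, f1, f2, n) {
  1 / sqrt(1 + ((f * (f2 - f1)) / (f^2 - f1 * f2))^(2 * n))
}

# Steady-state amplitude of a filtered unit sine (skip the first half
# of the window to let transients die).
post_transient_amp <- function(y) max(abs(y[(length(y) %/% 2):length(y)]))

sine_window <- function(f, fs = 250, seconds = 4, amp = 1, phase = 0) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * f * t + phase)
}

# A sample_window with named channels from a list of numeric vectors.
window_from <- function(channels, subject_id = "s", window_index = 0L) {
  m <- do.call(cbind, channels)
  colnames(m) <- names(channels)
  sample_window(subject_id, window_index, m)
}

random_window <- function(n = 1000, chans = eeg_channels(),
                          subject_id = "s", window_index = 0L) {
  m <- matrix(rnorm(n * length(chans)), nrow = n,
              dimnames = list(NULL, chans))
  sample_window(subject_id, window_index, m)
}

# Detrend every channel of a window (no filtering).
preprocess_detrend_only <- function(w) {
  w$samples <- apply(w$samples, 2, detrend_linear)
  w
}

# In-memory stream source over a long sample matrix.
matrix_source <- function(subject_id, samples, n_per_window,
                          has_window = NULL) {
  n_win <- nrow(samples) %/% n_per_window
  stream_source(
    subject_id, n_win,
    get_window = function(l) {
      rows <- (l * n_per_window + 1):((l + 1) * n_per_window)
      sample_window(subject_id, l, samples[rows, , drop = FALSE])
    },
    has_window = has_window
  )
}

# One dyad's collaboration/competition session pair: coupling kappa only
# in the collaboration task. Returns the two band summaries.
simulate_dyad_pair <- function(seed, task_seconds = 600, kappa = 25,
                               calibration_seconds = 60, f0 = 35) {
  cfg <- session_config(calibration_seconds = calibration_seconds,
                        reference_mode = "referenced-2ch")
  dur <- 4 + calibration_seconds + task_seconds
  run_one <- function(task_kappa, sub_seed) {
    spec <- synthetic_spec(
      duration = dur, f0 = f0,
      segments = data.frame(
        label = c("baseline", "task"),
        start = c(0, 4 + calibration_seconds),
        end = c(4 + calibration_seconds, dur),
        kappa = c(0, task_kappa)))
    g <- generate_dyad(spec, sub_seed)
    sa <- matrix_source("a", g$subject_a, 1000)
    sb <- matrix_source("b", g$subject_b, 1000)
    run_session(sa, sb, cfg)$band_summary
  }
  list(collab = run_one(kappa, seed),
       compete = run_one(0, seed + 500000L))
}
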