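#' Specification of a synthetic two-subject EEG session
#'
#' Describes the pseudo-EEG each channel is built from: one band-limited
#' oscillator per EEG band (independent random phases per subject and
#' channel), 1/f (pink) background noise, 60 Hz line contamination, and a
#' slow linear drift. Cross-subject coupling is injected per segment as a
#' shared oscillator at `f0` plus a phase-locked harmonic at `2 f0` (half
#' amplitude) added to both subjects' C3 and C4 — energy at a frequency
#' and its double is exactly what a diagonal bispectrum estimator rewards,
#' so the coupling amplitude `kappa` is a controllable ground truth.
#'
#' Default amplitudes are in the range typical of dry-electrode scalp EEG:
#' stronger slow rhythms (20 uV delta) tapering to weak gamma (5 uV), 10 uV
#' pink background, 5 uV line noise and 0.5 uV/s drift.
#'
#' @param duration Total length in seconds.
#' @param sampling_rate Hz.
#' @param osc_amp Named oscillator amplitudes per band (uV).
#' @param osc_freq Named oscillator frequencies per band (Hz), one
#'   representative tone inside each band.
#' @param pink_amp Pink-noise RMS amplitude (uV).
#' @param line_amp 60 Hz line amplitude (uV).
#' @param drift_slope Linear drift slope (uV/s).
#' @param f0 Shared-oscillator frequency (Hz); `2*f0` must stay below
#'   Nyquist. The default 35 Hz sits in the gamma band with its harmonic
#'   at 70 Hz, clear of the 58-62 Hz notch.
#' @param segments data.frame with columns `label`, `start`, `end`
#'   (seconds), `kappa` (coupling amplitude, uV); must tile
#'   `[0, duration]`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration,
                           sampling_rate = 250,
                           osc_amp = c(Delta = 20, Theta = 10, Alpha = 15,
                                       Beta = 8, Gamma = 5),
                           osc_freq = c(Delta = 2, Theta = 6, Alpha = 10,
                                        Beta = 20, Gamma = 40),
                           pink_amp = 10,
                           line_amp = 5,
                           drift_slope = 0.5,
                           f0 = 35,
                           segments = data.frame(label = "baseline",
                                                 start = 0, end = duration,
                                                 kappa = 0)) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("invalid spec: duration must be positive", call. = FALSE)
  }
  if (!identical(sort(names(osc_amp)), sort(names(osc_freq)))) {
    stop("invalid spec: osc_amp and osc_freq must share names", call. = FALSE)
  }
  if (any(c(osc_amp, pink_amp, line_amp) < 0)) {
    stop("invalid spec: amplitudes must be >= 0", call. = FALSE)
  }
  if (2 * f0 >= sampling_rate / 2) {
    stop("invalid spec: f0 and 2*f0 must be below the Nyquist frequency",
         call. = FALSE)
  }
  if (!is.data.frame(segments) ||
      !all(c("label", "start", "end", "kappa") %in% names(segments))) {
    stop("invalid spec: segments needs columns label, start, end, kappa",
         call. = FALSE)
  }
  segments <- segments[order(segments$start), , drop = FALSE]
  ok <- nrow(segments) >= 1L &&
    isTRUE(all.equal(segments$start[1L], 0)) &&
    isTRUE(all.equal(segments$end[nrow(segments)], duration)) &&
    (nrow(segments) == 1L ||
       isTRUE(all.equal(segments$start[-1L],
                        segments$end[-nrow(segments)])))
  if (!ok) {
    stop("invalid spec: segments must tile [0, duration] contiguously",
         call. = FALSE)
  }
  if (any(segments$kappa < 0)) {
    stop("invalid spec: kappa must be >= 0", call. = FALSE)
  }
  structure(
    list(duration = duration, sampling_rate = sampling_rate,
         osc_amp = osc_amp, osc_freq = osc_freq, pink_amp = pink_amp,
         line_amp = line_amp, drift_slope = drift_slope, f0 = f0,
         segments = segments),
    class = "synthetic_spec"
  )
}

#' Pink (1/f) noise by spectral shaping of seeded white noise
#'
#' White Gaussian noise is transformed, its spectrum scaled by
#' `1/sqrt(f)` (symmetrically, DC zeroed), inverted, and rescaled to the
#' requested RMS amplitude. Fully reproducible under the caller's RNG
#' state.
#'
#' @param n Number of samples.
#' @param amp Target RMS amplitude (standard deviation).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, amp = 1) {
  if (n < 2L || amp == 0) return(numeric(n))
  w <- stats::rnorm(n)
  k <- seq_len(n - 1L)
  scale <- c(0, 1 / sqrt(pmin(k, n - k)))
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  x / stats::sd(x) * amp
}

synth_subject <- function(spec, t, channels, coupling) {
  n <- length(t)
  out <- matrix(0, nrow = n, ncol = length(channels),
                dimnames = list(NULL, channels))
  for (ch in channels) {
    sig <- numeric(n)
    for (b in names(spec$osc_amp)) {
      phi <- stats::runif(1, 0, 2 * pi)
      sig <- sig + spec$osc_amp[[b]] *
        cos(2 * pi * spec$osc_freq[[b]] * t + phi)
    }
    sig <- sig + pink_noise(n, spec$pink_amp)
    sig <- sig + spec$line_amp * cos(2 * pi * 60 * t + stats::runif(1, 0, 2 * pi))
    sig <- sig + spec$drift_slope * t
    if (ch %in% c("C3", "C4")) sig <- sig + coupling
    out[, ch] <- sig
  }
  out
}

#' Generate a synthetic dyad recording
#'
#' Produces the two subjects' raw 4-channel recordings for one session,
#' reproducibly from `seed`. During segments with `kappa > 0` both
#' subjects' C3 and C4 receive the shared component
#' `kappa * (cos(2 pi f0 t + phi) + 0.5 cos(2 pi 2 f0 t + 2 phi))` with a
#' per-segment random phase `phi` common to the dyad.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; identical seeds give identical recordings.
#' @param out_dir Optional directory; when given, writes
#'   `subject_a.csv` / `subject_b.csv` in the raw recording schema
#'   (`time_s, A1, A2, C3, C4`).
#' @return Invisibly, a list with `time` (seconds), `subject_a`,
#'   `subject_b` (sample matrices), and — when `out_dir` is given —
#'   `paths`.
#' @export
generate_dyad <- function(spec, seed, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed))
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1L) / fs

  coupling <- numeric(n)
  for (i in seq_len(nrow(spec$segments))) {
    seg <- spec$segments[i, ]
    phi <- stats::runif(1, 0, 2 * pi)  # drawn per segment, shared by the dyad
    if (seg$kappa > 0) {
      idx <- which(t >= seg$start & t < seg$end)
      coupling[idx] <- coupling[idx] + seg$kappa *
        (cos(2 * pi * spec$f0 * t[idx] + phi) +
           0.5 * cos(2 * pi * 2 * spec$f0 * t[idx] + 2 * phi))
    }
  }

  channels <- eeg_channels()
  sa <- synth_subject(spec, t, channels, coupling)
  sb <- synth_subject(spec, t, channels, coupling)

  out <- list(time = t, subject_a = sa, subject_b = sb)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, c("subject_a.csv", "subject_b.csv"))
    write_recording(t, sa, paths[1L])
    write_recording(t, sb, paths[2L])
    out$paths <- paths
  }
  invisible(out)
}

write_recording <- function(t, samples, path) {
  dt <- data.table::data.table(time_s = t)
  for (ch in colnames(samples)) dt[[ch]] <- samples[, ch]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Ready-made synthetic sessions for testing and demos
#'
#' `tiny`: one 90 s recording pair — a 64 s uncoupled lead-in (the
#' discarded startup window plus a 60 s calibration) followed by 26 s of
#' coupled "task" activity; 22 complete 4 s windows end-to-end. `standard`:
#' two recording pairs mimicking a full protocol — each 904 s (startup
#' window + 5 min calibration + 10 min task, 150 task windows), with the
#' coupling present only in the collaboration-labelled task.
#'
#' @param preset `"tiny"` or `"standard"`.
#' @param seed Integer seed.
#' @param dir Directory to write recordings into.
#' @param kappa Coupling amplitude during coupled segments (uV).
#' @return A list: `config` (a [session_config()]) plus, for `tiny`,
#'   `subject_a`/`subject_b` paths; for `standard`, `collab` and
#'   `compete` path pairs.
#' @export
make_fixture_session <- function(preset = c("tiny", "standard"), seed, dir,
                                 kappa = 25) {
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (preset == "tiny") {
    spec <- synthetic_spec(
      duration = 90,
      segments = data.frame(label = c("baseline", "task"),
                            start = c(0, 64), end = c(64, 90),
                            kappa = c(0, kappa)))
    g <- generate_dyad(spec, seed, out_dir = dir)
    cfg <- session_config(calibration_seconds = 60,
                          reference_mode = "referenced-2ch", seed = seed)
    list(config = cfg, subject_a = g$paths[1L], subject_b = g$paths[2L])
  } else {
    mk <- function(task_kappa, sub_seed, sub_dir) {
      spec <- synthetic_spec(
        duration = 904,
        segments = data.frame(label = c("baseline", "task"),
                              start = c(0, 304), end = c(304, 904),
                              kappa = c(0, task_kappa)))
      generate_dyad(spec, sub_seed, out_dir = sub_dir)$paths
    }
    collab <- mk(kappa, seed, file.path(dir, "collab"))
    compete <- mk(0, seed + 1L, file.path(dir, "compete"))
    cfg <- session_config(calibration_seconds = 300,
                          reference_mode = "referenced-2ch", seed = seed)
    list(config = cfg,
         collab = list(subject_a = collab[1L], subject_b = collab[2L]),
         compete = list(subject_a = compete[1L], subject_b = compete[2L]))
  }
}
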