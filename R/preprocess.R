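#' Filter specification for per-window signal conditioning
#'
#' Defaults follow common practice for wearable dry-electrode EEG in the
#' Americas: a fourth-order Butterworth 0.1-100 Hz bandpass plus a 60 Hz
#' notch (realized as a fourth-order Butterworth band-stop over 58-62 Hz).
#' Orders are the Butterworth design parameter handed to [signal::butter()].
#'
#' @param bandpass_low,bandpass_high Bandpass corner frequencies in Hz.
#' @param bandpass_order Butterworth design order of the bandpass.
#' @param notch_low,notch_high Band-stop corner frequencies in Hz.
#' @param notch_order Butterworth design order of the band-stop.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(bandpass_low = 0.1, bandpass_high = 100,
                        bandpass_order = 4,
                        notch_low = 58, notch_high = 62,
                        notch_order = 4) {
  for (o in c(bandpass_order, notch_order)) {
    if (!is.numeric(o) || length(o) != 1L || o <= 0 || o %% 2 != 0) {
      stop("invalid filter: orders must be positive even integers",
           call. = FALSE)
    }
  }
  for (pair in list(c(bandpass_low, bandpass_high), c(notch_low, notch_high))) {
    if (!(pair[1] > 0 && pair[1] < pair[2])) {
      stop("invalid filter: need 0 < low < high for each band", call. = FALSE)
    }
  }
  structure(
    list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
         bandpass_order = as.integer(bandpass_order),
         notch_low = notch_low, notch_high = notch_high,
         notch_order = as.integer(notch_order)),
    class = "filter_spec"
  )
}

#' Remove the least-squares linear trend from a signal
#'
#' Subtracts the best-fitting straight line (intercept + slope), so the
#' output has zero mean and zero linear trend. This is the first
#' conditioning stage: it suppresses electrode drift and slow movement
#' artifacts before any filtering.
#'
#' @param x Numeric vector of samples.
#' @return Numeric vector of the same length.
#' @export
detrend_linear <- function(x) {
  if (length(x) < 2L) {
    stop("too short: detrending needs at least 2 samples", call. = FALSE)
  }
  t <- seq_along(x)
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc * tc)
  x - mean(x) - slope * tc
}

butter_apply <- function(x, low, high, order, fs, type) {
  nyq <- fs / 2
  if (high >= nyq) {
    stop("invalid filter: upper corner ", high,
         " Hz must be below the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  }
  flt <- signal::butter(order, c(low, high) / nyq, type = type)
  as.numeric(signal::filter(flt, x))
}

#' Butterworth bandpass, applied once, forward, from zero state
#'
#' Causal single-pass filtering: each window is filtered independently with
#' zero initial conditions, as a streaming estimator must. Edge transients
#' at the window start are accepted.
#'
#' @param x Numeric vector of samples (one channel, one window).
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @return Filtered numeric vector.
#' @export
bandpass <- function(x, spec = filter_spec(), fs) {
  stopifnot(inherits(spec, "filter_spec"))
  butter_apply(x, spec$bandpass_low, spec$bandpass_high,
               spec$bandpass_order, fs, "pass")
}

#' 60 Hz notch (Butterworth band-stop), applied once, forward
#'
#' @inheritParams bandpass
#' @return Filtered numeric vector.
#' @export
notch <- function(x, spec = filter_spec(), fs) {
  stopifnot(inherits(spec, "filter_spec"))
  butter_apply(x, spec$notch_low, spec$notch_high,
               spec$notch_order, fs, "stop")
}

#' Construct a sample window
#'
#' One window of multichannel samples for one subject, tagged with its
#' ordinal on the shared session clock.
#'
#' @param subject_id Subject identifier.
#' @param window_index 0-based window ordinal.
#' @param samples Numeric matrix, rows = samples, named columns = channels
#'   (microvolts).
#' @param start_time Window start in seconds on the session clock.
#' @return An object of class `sample_window`.
#' @export
sample_window <- function(subject_id, window_index, samples, start_time = NA_real_) {
  if (!is.matrix(samples) || !is.numeric(samples) || is.null(colnames(samples))) {
    stop("invalid window: samples must be a numeric matrix with channel column names",
         call. = FALSE)
  }
  if (window_index < 0) {
    stop("invalid window: window_index must be >= 0", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id,
         window_index = as.integer(window_index),
         start_time = start_time,
         samples = samples),
    class = "sample_window"
  )
}

#' Condition one window: detrend, bandpass, notch
#'
#' Applies the per-channel chain linear detrend -> Butterworth bandpass ->
#' 60 Hz notch, in that order, leaving metadata (subject, index, start
#' time), window length and channel count unchanged.
#'
#' @param window A [sample_window()].
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @return A `sample_window` with conditioned samples.
#' @export
preprocess_window <- function(window, spec = filter_spec(), fs) {
  stopifnot(inherits(window, "sample_window"))
  out <- window$samples
  for (j in seq_len(ncol(out))) {
    out[, j] <- notch(bandpass(detrend_linear(out[, j]), spec, fs), spec, fs)
  }
  window$samples <- out
  window
}

#' Re-reference scalp channels to linked ears
#'
#' Subtracts the average of the two ear-cup electrodes from each scalp
#' channel, sample-wise: C3' = C3 - (A1 + A2)/2, C4' = C4 - (A1 + A2)/2.
#' The ear channels are dropped from the output. Applied after filtering.
#'
#' @param window A [sample_window()] containing channels A1, A2, C3, C4.
#' @return A `sample_window` with channels `C3'` and `C4'`.
#' @export
rereference <- function(window) {
  stopifnot(inherits(window, "sample_window"))
  need <- eeg_channels()
  missing <- setdiff(need, colnames(window$samples))
  if (length(missing) > 0L) {
    stop("missing channel: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  s <- window$samples
  ears <- (s[, "A1"] + s[, "A2"]) / 2
  out <- cbind(s[, "C3"] - ears, s[, "C4"] - ears)
  colnames(out) <- referenced_channels()
  window$samples <- out
  window
}
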