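#' Default EEG channel labels
#'
#' The four dry electrodes of each headset: two ear-cup electrodes (A1, A2)
#' and two top-band electrodes over the central scalp (C3, C4), named after
#' their International 10-20 positions.
#'
#' @return Character vector of channel labels, in canonical order.
#' @export
eeg_channels <- function() c("A1", "A2", "C3", "C4")

#' Linked-ears referenced channel labels
#'
#' Labels of the scalp channels after subtracting the ear-electrode average:
#' C3' = C3 - (A1 + A2)/2 and C4' = C4 - (A1 + A2)/2.
#'
#' @return Character vector `c("C3'", "C4'")`.
#' @export
referenced_channels <- function() c("C3'", "C4'")

#' Build the frequency axis for a windowed DFT
#'
#' Fixes the bookkeeping every later stage relies on: a window of
#' `window_seconds` at `sampling_rate` holds `n_samples` points, its one-sided
#' spectrum has `n_bins = n_samples / 2` bins, bin `k` (0-based) sits at
#' `k / window_seconds` Hz, and the Nyquist frequency is `sampling_rate / 2`.
#' The defaults elsewhere in the package (250 Hz, 4 s) give 1000 samples,
#' 500 bins at 0.25 Hz resolution and a 125 Hz Nyquist.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param window_seconds Window length in seconds.
#' @return An object of class `freq_axis`: a list with `sampling_rate`,
#'   `window_seconds`, `n_samples`, `n_bins`, `resolution` (Hz) and
#'   `nyquist` (Hz).
#' @examples
#' ax <- make_axis(250, 4)
#' ax$n_bins      # 500
#' ax$resolution  # 0.25
#' @export
make_axis <- function(sampling_rate, window_seconds) {
  if (!is.numeric(sampling_rate) || !is.numeric(window_seconds) ||
      length(sampling_rate) != 1L || length(window_seconds) != 1L ||
      !is.finite(sampling_rate) || !is.finite(window_seconds)) {
    stop("invalid window: sampling_rate and window_seconds must be finite scalars",
         call. = FALSE)
  }
  n <- sampling_rate * window_seconds
  if (n <= 0 || abs(n - round(n)) > 1e-9 || round(n) %% 2 != 0) {
    stop("invalid window: sampling_rate * window_seconds must be a positive even integer, got ",
         format(n), call. = FALSE)
  }
  n <- as.integer(round(n))
  structure(
    list(
      sampling_rate = sampling_rate,
      window_seconds = window_seconds,
      n_samples = n,
      n_bins = n %/% 2L,
      resolution = 1 / window_seconds,
      nyquist = sampling_rate / 2
    ),
    class = "freq_axis"
  )
}

#' @export
print.freq_axis <- function(x, ...) {
  cat(sprintf(
    "<freq_axis> %g Hz x %g s: %d samples, %d one-sided bins, %.4g Hz resolution, Nyquist %g Hz\n",
    x$sampling_rate, x$window_seconds, x$n_samples, x$n_bins, x$resolution,
    x$nyquist))
  invisible(x)
}

#' Canonical EEG frequency band table
#'
#' Delta (0.1-4 Hz), Theta (4-7 Hz), Alpha (8-12 Hz), Beta (13-30 Hz),
#' Gamma (30-50 Hz). Band edges are taken literally, including the
#' unassigned gaps at 7-8 Hz and 12-13 Hz; see [band_bin_map()] for how
#' shared edges are resolved.
#'
#' @return A data.frame with columns `name`, `low`, `high` (Hz).
#' @export
default_bands <- function() {
  data.frame(
    name = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
    low  = c(0.1, 4, 8, 13, 30),
    high = c(4, 7, 12, 30, 50),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands) {
  if (!is.data.frame(bands) || nrow(bands) < 1L ||
      !all(c("name", "low", "high") %in% names(bands))) {
    stop("invalid band table: need a data.frame with columns name, low, high",
         call. = FALSE)
  }
  if (anyDuplicated(bands$name)) {
    stop("invalid band table: band names must be unique", call. = FALSE)
  }
  if (any(bands$low >= bands$high)) {
    stop("invalid band table: each band needs low < high", call. = FALSE)
  }
  if (is.unsorted(bands$low, strictly = TRUE)) {
    stop("invalid band table: band lows must be strictly increasing",
         call. = FALSE)
  }
  invisible(bands)
}

#' Enumerate cross-subject channel combinations
#'
#' Every pairing of a subject-1 channel with a subject-2 channel, in
#' row-major order (subject-1 channel varies slowest). Four channels per
#' subject give the full 16-combination set; the two referenced channels
#' give 4.
#'
#' @param channels_a Ordered channel labels for subject 1.
#' @param channels_b Ordered channel labels for subject 2.
#' @return A data.frame with columns `index` (1-based ordinal), `subject_a`,
#'   `subject_b`, and `label` (`"<a>-<b>"`).
#' @examples
#' nrow(enumerate_combinations(eeg_channels(), eeg_channels()))  # 16
#' @export
enumerate_combinations <- function(channels_a, channels_b) {
  for (ch in list(channels_a, channels_b)) {
    if (length(ch) == 0L || anyDuplicated(ch) || any(!nzchar(ch))) {
      stop("invalid channel set: labels must be non-empty and unique",
           call. = FALSE)
    }
  }
  la <- length(channels_a)
  lb <- length(channels_b)
  out <- data.frame(
    index = seq_len(la * lb),
    subject_a = rep(channels_a, each = lb),
    subject_b = rep(channels_b, times = la),
    stringsAsFactors = FALSE
  )
  out$label <- paste0(out$subject_a, "-", out$subject_b)
  out
}

#' Map frequency bins to bands
#'
#' Assigns every one-sided DFT bin whose frequency lies inside a band's
#' closed interval `[low, high]` to that band. A bin sitting exactly on an
#' edge shared by two bands (4 Hz, 30 Hz in the default table) is assigned
#' to the higher band, so band means are reproducible. Bins falling in the
#' printed gaps between bands (7-8 Hz, 12-13 Hz) belong to no band.
#'
#' @param bands Band table as from [default_bands()].
#' @param axis A `freq_axis`.
#' @return Named list (one entry per band) of 0-based bin indices.
#' @export
band_bin_map <- function(bands = default_bands(), axis) {
  validate_bands(bands)
  stopifnot(inherits(axis, "freq_axis"))
  if (any(bands$low < 0) || any(bands$high > axis$nyquist)) {
    stop("out of range: band edges must lie within [0, nyquist]",
         call. = FALSE)
  }
  freqs <- (seq_len(axis$n_bins) - 1L) * axis$resolution
  sets <- lapply(seq_len(nrow(bands)), function(i) {
    which(freqs >= bands$low[i] & freqs <= bands$high[i]) - 1L
  })
  names(sets) <- bands$name
  # shared boundary bin goes to the higher band
  if (length(sets) > 1L) {
    for (i in seq_len(length(sets) - 1L)) {
      higher <- unique(unlist(sets[(i + 1L):length(sets)]))
      sets[[i]] <- setdiff(sets[[i]], higher)
    }
  }
  sets
}

#' Bins covered by a single band
#'
#' @param band Band name present in `bands`, or a single row index.
#' @param axis A `freq_axis`.
#' @param bands Band table used to resolve shared edges.
#' @return Integer vector of 0-based bin indices.
#' @export
band_bins <- function(band, axis, bands = default_bands()) {
  map <- band_bin_map(bands, axis)
  key <- if (is.numeric(band)) names(map)[band] else band
  if (is.na(key) || !key %in% names(map)) {
    stop("out of range: unknown band '", band, "'", call. = FALSE)
  }
  map[[key]]
}
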