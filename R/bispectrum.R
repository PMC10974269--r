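#' Full-length DFT of one preprocessed window
#'
#' Unnormalized forward DFT per channel (via [stats::mvfft()]). The full
#' length-N transform is kept because the diagonal bispectrum needs the
#' sum-frequency bin `2i`, which for `i < N/2` always lies inside the full
#' transform; downstream consumers read the one-sided view of the first
#' `n_bins = N/2` bins.
#'
#' @param window A [sample_window()] of preprocessed samples.
#' @param axis A `freq_axis` whose `n_samples` matches the window length.
#' @return An object of class `spectral_frame`: `subject_id`,
#'   `window_index`, `fft` (complex matrix n_samples x channels),
#'   `n_bins`.
#' @export
spectral_frame <- function(window, axis) {
  stopifnot(inherits(window, "sample_window"), inherits(axis, "freq_axis"))
  if (nrow(window$samples) != axis$n_samples) {
    stop("shape error: window has ", nrow(window$samples),
         " samples, axis expects ", axis$n_samples, call. = FALSE)
  }
  structure(
    list(subject_id = window$subject_id,
         window_index = window$window_index,
         fft = stats::mvfft(window$samples),
         n_bins = axis$n_bins),
    class = "spectral_frame"
  )
}

#' Diagonal cross-bispectrum of one channel pair
#'
#' For each one-sided bin `i` (0-based), computes the log-magnitude
#' diagonal bispectrum
#' `B[i] = log |X_a(f_i) * X_b(f_i) * conj(X_c(2 f_i))|`,
#' where `X_a`, `X_b` are the full-length DFTs of one channel from each
#' subject and the sum-frequency (conjugated) factor `X_c` comes from
#' subject b by default (`conj_from = "b"`), selectable to subject a.
#' The magnitude is clamped at `eps` before the natural log, so all-zero
#' input yields `log(eps)` everywhere.
#'
#' @param xa,xb Complex full-length DFT vectors of the two channels
#'   (same window index).
#' @param n_bins Number of one-sided bins (half the DFT length).
#' @param conj_from `"b"` (default) or `"a"`: which subject supplies the
#'   conjugated sum-frequency factor.
#' @param eps Magnitude floor before the log.
#' @return Numeric vector of `n_bins` log-magnitude values.
#' @export
bispectrum_pair <- function(xa, xb, n_bins, conj_from = c("b", "a"),
                            eps = 1e-12) {
  conj_from <- match.arg(conj_from)
  if (length(xa) != length(xb)) {
    stop("shape error: DFT lengths differ", call. = FALSE)
  }
  if (2L * (n_bins - 1L) + 1L > length(xa)) {
    stop("shape error: full DFT too short for ", n_bins, " one-sided bins",
         call. = FALSE)
  }
  i <- seq_len(n_bins) - 1L
  xc <- if (conj_from == "b") xb else xa
  prod <- xa[i + 1L] * xb[i + 1L] * Conj(xc[2L * i + 1L])
  log(pmax(Mod(prod), eps))
}

#' Raw bispectrum matrix for one window
#'
#' One row per cross-subject channel combination (in the canonical
#' row-major order), one column per one-sided frequency bin. With the
#' default 4x4 channel set at 250 Hz / 4 s this is the 16 x 500 matrix a
#' session produces every window.
#'
#' @param frame_a,frame_b `spectral_frame`s of the two subjects for the
#'   same window index.
#' @param combos Combination table from [enumerate_combinations()].
#' @param axis A `freq_axis`.
#' @param conj_from Passed to [bispectrum_pair()].
#' @return Numeric matrix (combinations x n_bins) with the combination
#'   labels as rownames; attributes `window_index` and `kind = "raw"`.
#' @export
window_matrix <- function(frame_a, frame_b, combos, axis, conj_from = "b") {
  stopifnot(inherits(frame_a, "spectral_frame"),
            inherits(frame_b, "spectral_frame"))
  if (frame_a$window_index != frame_b$window_index) {
    stop("alignment error: window indices differ (",
         frame_a$window_index, " vs ", frame_b$window_index, ")",
         call. = FALSE)
  }
  miss_a <- setdiff(unique(combos$subject_a), colnames(frame_a$fft))
  miss_b <- setdiff(unique(combos$subject_b), colnames(frame_b$fft))
  if (length(miss_a) + length(miss_b) > 0L) {
    stop("missing channel: ", paste(c(miss_a, miss_b), collapse = ", "),
         call. = FALSE)
  }
  out <- matrix(NA_real_, nrow = nrow(combos), ncol = axis$n_bins,
                dimnames = list(combos$label, NULL))
  for (r in seq_len(nrow(combos))) {
    out[r, ] <- bispectrum_pair(frame_a$fft[, combos$subject_a[r]],
                                frame_b$fft[, combos$subject_b[r]],
                                axis$n_bins, conj_from = conj_from)
  }
  attr(out, "window_index") <- frame_a$window_index
  attr(out, "kind") <- "raw"
  out
}

#' Average raw bispectrum matrices into a calibration baseline
#'
#' Element-wise arithmetic mean over the calibration (no-interaction)
#' windows. The baseline is the reference against which every later task
#' window is normalized, so synchrony indices read as above/below the
#' subjects' basal state.
#'
#' @param matrices List of raw bispectrum matrices of identical shape.
#' @return An object of class `calibration_baseline`: `values` (matrix),
#'   `n_windows`.
#' @export
calibration_baseline <- function(matrices) {
  if (length(matrices) < 1L) {
    stop("no calibration: need at least one calibration window", call. = FALSE)
  }
  d <- dim(matrices[[1L]])
  for (m in matrices) {
    if (!identical(dim(m), d)) {
      stop("shape error: calibration matrices differ in shape", call. = FALSE)
    }
  }
  values <- Reduce(`+`, matrices) / length(matrices)
  attr(values, "window_index") <- NULL
  attr(values, "kind") <- NULL
  structure(list(values = values, n_windows = length(matrices)),
            class = "calibration_baseline")
}

#' Normalize a bispectrum matrix against the calibration baseline
#'
#' Bounded relative difference, element-wise:
#' `n = (B - C) / (|B| + |C| + eps)` with `C` the baseline mean. The index
#' is strictly inside (-1, 1), exactly 0 where the window equals the
#' baseline, and carries the sign of `B - C`: positive values mean more
#' synchrony than the no-interaction calibration state.
#'
#' @param matrix Raw bispectrum matrix.
#' @param baseline A [calibration_baseline()].
#' @param eps Denominator guard for the all-zero case.
#' @return Matrix of the same shape, attribute `kind = "normalized"`.
#' @export
normalize_bispectrum <- function(matrix, baseline, eps = 1e-12) {
  stopifnot(inherits(baseline, "calibration_baseline"))
  if (!identical(dim(matrix), dim(baseline$values))) {
    stop("shape error: matrix and baseline shapes differ", call. = FALSE)
  }
  out <- (matrix - baseline$values) /
    (abs(matrix) + abs(baseline$values) + eps)
  attr(out, "window_index") <- attr(matrix, "window_index")
  attr(out, "kind") <- "normalized"
  out
}

#' Average a normalized matrix over EEG frequency bands
#'
#' Mean of the normalized values over each band's bin range, per
#' combination. Bins in the gaps between bands contribute to no band.
#'
#' @param matrix Normalized bispectrum matrix (combinations x n_bins).
#' @param bands Band table as from [default_bands()].
#' @param axis A `freq_axis`.
#' @return Numeric matrix (bands x combinations), dimnames set.
#' @export
band_average <- function(matrix, bands = default_bands(), axis) {
  map <- band_bin_map(bands, axis)
  empty <- names(map)[vapply(map, length, 1L) == 0L]
  if (length(empty) > 0L) {
    stop("empty band: no bins fall inside ", paste(empty, collapse = ", "),
         " at this resolution", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow = length(map), ncol = nrow(matrix),
                dimnames = list(names(map), rownames(matrix)))
  for (b in seq_along(map)) {
    out[b, ] <- rowMeans(matrix[, map[[b]] + 1L, drop = FALSE])
  }
  attr(out, "window_index") <- attr(matrix, "window_index")
  out
}
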