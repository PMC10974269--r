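#' Session configuration
#'
#' Everything a session run depends on: clocking (sampling rate, window
#' length), the calibration duration (the initial no-interaction stretch
#' whose mean bispectrum becomes the normalization baseline; one minute by
#' default), the reference mode (all four raw channels, 16 combinations,
#' or the two linked-ears referenced channels, 4 combinations), the filter
#' chain, the band table, and which subject supplies the conjugated
#' sum-frequency bispectrum factor.
#'
#' @param sampling_rate Hz.
#' @param window_seconds Window length in seconds.
#' @param calibration_seconds Calibration duration; must be a multiple of
#'   `window_seconds`.
#' @param reference_mode `"raw-4ch"` or `"referenced-2ch"`.
#' @param filter A [filter_spec()].
#' @param bands Band table as from [default_bands()].
#' @param channels Raw channel labels expected in recordings.
#' @param conj_from `"b"` or `"a"`; see [bispectrum_pair()].
#' @param seed Optional integer seed recorded with the session (used by
#'   synthetic runs).
#' @param verbose Emit one status line per consumed window.
#' @return An object of class `session_config`.
#' @export
session_config <- function(sampling_rate = 250,
                           window_seconds = 4,
                           calibration_seconds = 60,
                           reference_mode = c("raw-4ch", "referenced-2ch"),
                           filter = filter_spec(),
                           bands = default_bands(),
                           channels = eeg_channels(),
                           conj_from = c("b", "a"),
                           seed = NULL,
                           verbose = FALSE) {
  reference_mode <- match.arg(reference_mode)
  conj_from <- match.arg(conj_from)
  axis <- make_axis(sampling_rate, window_seconds)  # validates the window
  if (calibration_seconds <= 0 ||
      abs(calibration_seconds / window_seconds -
          round(calibration_seconds / window_seconds)) > 1e-9) {
    stop("invalid config: calibration_seconds must be a positive multiple of window_seconds",
         call. = FALSE)
  }
  stopifnot(inherits(filter, "filter_spec"))
  validate_bands(bands)
  if (filter$bandpass_high >= axis$nyquist) {
    stop("invalid config: bandpass upper corner must be below Nyquist",
         call. = FALSE)
  }
  structure(
    list(sampling_rate = sampling_rate,
         window_seconds = window_seconds,
         calibration_seconds = calibration_seconds,
         reference_mode = reference_mode,
         filter = filter,
         bands = bands,
         channels = channels,
         conj_from = conj_from,
         seed = seed,
         verbose = isTRUE(verbose)),
    class = "session_config"
  )
}

#' @rdname session_config
#' @param config A `session_config`.
#' @export
session_axis <- function(config) {
  make_axis(config$sampling_rate, config$window_seconds)
}

#' Read / write a session configuration as YAML
#'
#' Flat keys mirror [session_config()] arguments; `filter` and `bands` are
#' nested maps. Unspecified keys fall back to the defaults.
#'
#' @param path File path.
#' @return `read_session_config()` returns a `session_config`;
#'   `write_session_config()` returns `path` invisibly.
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("sampling_rate", "window_seconds", "calibration_seconds",
              "reference_mode", "conj_from", "seed", "channels")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(args$channels)) args$channels <- unlist(args$channels)
  if (!is.null(y$filter)) {
    args$filter <- do.call(filter_spec, y$filter)
  }
  if (!is.null(y$bands)) {
    b <- do.call(rbind, lapply(y$bands, function(e) {
      data.frame(name = e$name, low = e$low, high = e$high,
                 stringsAsFactors = FALSE)
    }))
    args$bands <- b
  }
  do.call(session_config, args)
}

#' @rdname read_session_config
#' @param config A `session_config`.
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  y <- list(
    sampling_rate = config$sampling_rate,
    window_seconds = config$window_seconds,
    calibration_seconds = config$calibration_seconds,
    reference_mode = config$reference_mode,
    conj_from = config$conj_from,
    channels = as.list(config$channels),
    filter = unclass(config$filter),
    bands = lapply(seq_len(nrow(config$bands)), function(i) {
      list(name = config$bands$name[i], low = config$bands$low[i],
           high = config$bands$high[i])
    })
  )
  if (!is.null(config$seed)) y$seed <- config$seed
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Construct a stream source (adapter seam)
#'
#' A stream source yields consecutive [sample_window()]s aligned to the
#' shared session clock. `has_window(l)` reports whether window `l` is
#' available yet (always true for replay; a live adapter may lag), and
#' `get_window(l)` returns it. The session consumer only pulls a window
#' once both subjects' copies exist.
#'
#' @param subject_id Subject identifier.
#' @param n_windows Number of complete windows this source will produce.
#' @param get_window Function(l) returning the `sample_window` of 0-based
#'   index `l`.
#' @param has_window Function(l) returning TRUE once window `l` is
#'   available; defaults to always available.
#' @return An object of class `stream_source`.
#' @export
stream_source <- function(subject_id, n_windows, get_window,
                          has_window = NULL) {
  if (is.null(has_window)) has_window <- function(l) TRUE
  structure(
    list(subject_id = subject_id,
         n_windows = as.integer(n_windows),
         get_window = get_window,
         has_window = has_window),
    class = "stream_source"
  )
}

#' Replay a raw recording CSV as a stream source
#'
#' Reads a recording in the raw schema (`time_s` plus one column per
#' channel, in microvolts) and yields its complete windows exactly as a
#' live source would. A trailing partial window is dropped with a message
#' reporting the count.
#'
#' @param path CSV path.
#' @param config A [session_config()] (defines window length and expected
#'   channels).
#' @param subject_id Identifier; defaults to the file name without
#'   extension.
#' @return A [stream_source()]; attribute `dropped_samples` carries the
#'   number of trailing samples not forming a complete window.
#' @export
replay_source <- function(path, config, subject_id = NULL) {
  stopifnot(inherits(config, "session_config"))
  if (!file.exists(path)) {
    stop("recording not found: ", path, call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  dt <- data.table::fread(path)
  need <- c("time_s", config$channels)
  missing <- setdiff(need, names(dt))
  if (length(missing) > 0L) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in if (nrow(dt) > 0L) need else character(0)) {
    if (!is.numeric(dt[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt[[col]]))))[1L]
      stop("parse error in ", path, ": non-numeric value in column ", col,
           " at data row ", bad, call. = FALSE)
    }
    if (anyNA(dt[[col]])) {
      stop("parse error in ", path, ": missing value in column ", col,
           " at data row ", which(is.na(dt[[col]]))[1L], call. = FALSE)
    }
  }
  axis <- session_axis(config)
  n_win <- nrow(dt) %/% axis$n_samples
  dropped <- nrow(dt) - n_win * axis$n_samples
  if (dropped > 0L) {
    message("replay_source: dropped trailing partial window (",
            dropped, " samples) from ", basename(path))
  }
  samples <- as.matrix(dt[, config$channels, with = FALSE])
  times <- dt$time_s
  src <- stream_source(
    subject_id = subject_id,
    n_windows = n_win,
    get_window = function(l) {
      rows <- (l * axis$n_samples + 1L):((l + 1L) * axis$n_samples)
      sample_window(subject_id, l, samples[rows, , drop = FALSE],
                    start_time = times[rows[1L]])
    }
  )
  attr(src, "dropped_samples") <- dropped
  src
}

#' Run a complete dyad session
#'
#' Drives both subjects' sources against the shared window clock, exactly
#' as the streaming estimator does: window 0 is discarded (startup
#' overhead), the next `calibration_seconds / window_seconds` windows form
#' the calibration baseline, and every later window is conditioned,
#' optionally re-referenced, turned into a raw bispectrum matrix,
#' normalized against the baseline and band-averaged. A window is only
#' consumed once both subjects' copies are available; sources whose window
#' indices disagree abort with a desync error.
#'
#' @param source_a,source_b [stream_source()]s for the two subjects.
#' @param config A [session_config()].
#' @param max_polls Safety bound on availability polling per window before
#'   declaring a desync.
#' @return An object of class `b2b_session`: counts (`n_windows`,
#'   `n_discarded`, `n_calibration`, `n_task`), the baseline, per-window
#'   raw/normalized matrices, per-window band summaries (long
#'   `data.table`), and the raw/preprocessed signals needed to persist the
#'   session.
#' @export
run_session <- function(source_a, source_b, config, max_polls = 1e6) {
  stopifnot(inherits(source_a, "stream_source"),
            inherits(source_b, "stream_source"),
            inherits(config, "session_config"))
  axis <- session_axis(config)
  n_cal <- as.integer(round(config$calibration_seconds / config$window_seconds))
  n <- min(source_a$n_windows, source_b$n_windows)
  if (n < 1L + n_cal) {
    stop("insufficient calibration: have ", n, " windows, need at least ",
         1L + n_cal, " (1 discarded + ", n_cal, " calibration)",
         call. = FALSE)
  }
  combos <- if (config$reference_mode == "referenced-2ch") {
    enumerate_combinations(referenced_channels(), referenced_channels())
  } else {
    enumerate_combinations(config$channels, config$channels)
  }

  raw_windows <- list(a = vector("list", n), b = vector("list", n))
  pre_windows <- list(a = vector("list", n), b = vector("list", n))
  raw_mats <- list()
  norm_mats <- list()
  cal_mats <- vector("list", n_cal)
  baseline <- NULL
  band_rows <- list()

  for (l in 0:(n - 1L)) {
    polls <- 0L
    while (!(isTRUE(source_a$has_window(l)) &&
             isTRUE(source_b$has_window(l)))) {
      polls <- polls + 1L
      if (polls > max_polls) {
        stop("desync error: window ", l,
             " never became available on both sources", call. = FALSE)
      }
    }
    t0 <- proc.time()[["elapsed"]]
    wa <- source_a$get_window(l)
    wb <- source_b$get_window(l)
    if (wa$window_index != l || wb$window_index != l) {
      stop("desync error: expected window ", l, ", sources delivered ",
           wa$window_index, " (a) and ", wb$window_index, " (b)",
           call. = FALSE)
    }
    raw_windows$a[[l + 1L]] <- wa
    raw_windows$b[[l + 1L]] <- wb
    if (l == 0L) {
      if (config$verbose) {
        message(sprintf("window %4d  discarded  %5.1f ms", l,
                        1000 * (proc.time()[["elapsed"]] - t0)))
      }
      next
    }
    pa <- preprocess_window(wa, config$filter, config$sampling_rate)
    pb <- preprocess_window(wb, config$filter, config$sampling_rate)
    if (config$reference_mode == "referenced-2ch") {
      pa <- rereference(pa)
      pb <- rereference(pb)
    }
    pre_windows$a[[l + 1L]] <- pa
    pre_windows$b[[l + 1L]] <- pb
    fa <- spectral_frame(pa, axis)
    fb <- spectral_frame(pb, axis)
    mat <- window_matrix(fa, fb, combos, axis, conj_from = config$conj_from)
    raw_mats[[as.character(l)]] <- mat
    stage <- if (l <= n_cal) "calibration" else "task"
    if (l <= n_cal) {
      cal_mats[[l]] <- mat
    } else {
      if (is.null(baseline)) baseline <- calibration_baseline(cal_mats)
      nm <- normalize_bispectrum(mat, baseline)
      norm_mats[[as.character(l)]] <- nm
      bs <- band_average(nm, config$bands, axis)
      band_rows[[length(band_rows) + 1L]] <- data.table::data.table(
        window_index = l,
        band = rep(rownames(bs), times = ncol(bs)),
        combination = rep(colnames(bs), each = nrow(bs)),
        value = as.vector(bs)
      )
    }
    if (config$verbose) {
      message(sprintf("window %4d  %-11s %5.1f ms", l, stage,
                      1000 * (proc.time()[["elapsed"]] - t0)))
    }
  }
  if (is.null(baseline)) baseline <- calibration_baseline(cal_mats)
  bands_dt <- if (length(band_rows) > 0L) {
    data.table::rbindlist(band_rows)
  } else {
    data.table::data.table(window_index = integer(), band = character(),
                           combination = character(), value = numeric())
  }
  structure(
    list(config = config,
         axis = axis,
         combinations = combos,
         n_windows = n,
         n_discarded = 1L,
         n_calibration = n_cal,
         n_task = n - 1L - n_cal,
         subject_ids = c(source_a$subject_id, source_b$subject_id),
         baseline = baseline,
         raw_windows = raw_windows,
         pre_windows = pre_windows,
         raw_matrices = raw_mats,
         norm_matrices = norm_mats,
         band_summary = bands_dt),
    class = "b2b_session"
  )
}

#' @export
print.b2b_session <- function(x, ...) {
  cat(sprintf(
    "<b2b_session> %d windows (%d discarded, %d calibration, %d task), %s, %d combinations\n",
    x$n_windows, x$n_discarded, x$n_calibration, x$n_task,
    x$config$reference_mode, nrow(x$combinations)))
  invisible(x)
}

windows_to_dt <- function(windows, fs) {
  parts <- Filter(Negate(is.null), windows)
  data.table::rbindlist(lapply(parts, function(w) {
    n <- nrow(w$samples)
    start <- if (is.finite(w$start_time)) w$start_time else
      w$window_index * n / fs
    dt <- data.table::data.table(time_s = start + (seq_len(n) - 1L) / fs)
    for (ch in colnames(w$samples)) dt[[ch]] <- w$samples[, ch]
    dt
  }))
}

long_bispec_dt <- function(mats, axis) {
  data.table::rbindlist(lapply(names(mats), function(k) {
    m <- mats[[k]]
    data.table::data.table(
      window_index = as.integer(k),
      combination = rep(rownames(m), each = ncol(m)),
      bin_hz = rep((seq_len(ncol(m)) - 1L) * axis$resolution,
                   times = nrow(m)),
      value = as.vector(t(m))
    )
  }))
}

#' Persist a session record to disk
#'
#' Writes the fixed session file set into `out_dir`: per-subject raw and
#' preprocessed signals (`raw_s1.csv`, `raw_s2.csv`, `pre_s1.csv`,
#' `pre_s2.csv`; the `pre` files hold the channels actually fed to the
#' bispectrum, i.e. the referenced channels in referenced mode), the raw
#' and normalized bispectrum matrices in long form (`bispec_raw.csv`,
#' `bispec_norm.csv`: window_index, combination, bin_hz, value), the band
#' summaries (`bands.csv`: window_index, band, combination, value), and a
#' `session.json` with the configuration and window counts. Identical
#' sessions produce byte-identical files.
#'
#' @param record A `b2b_session` from [run_session()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_session_outputs <- function(record, out_dir) {
  stopifnot(inherits(record, "b2b_session"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("I/O error: cannot create output directory ", out_dir,
         call. = FALSE)
  }
  fs <- record$config$sampling_rate
  paths <- c(
    raw_s1 = file.path(out_dir, "raw_s1.csv"),
    raw_s2 = file.path(out_dir, "raw_s2.csv"),
    pre_s1 = file.path(out_dir, "pre_s1.csv"),
    pre_s2 = file.path(out_dir, "pre_s2.csv"),
    bispec_raw = file.path(out_dir, "bispec_raw.csv"),
    bispec_norm = file.path(out_dir, "bispec_norm.csv"),
    bands = file.path(out_dir, "bands.csv"),
    session = file.path(out_dir, "session.json")
  )
  data.table::fwrite(windows_to_dt(record$raw_windows$a, fs), paths["raw_s1"])
  data.table::fwrite(windows_to_dt(record$raw_windows$b, fs), paths["raw_s2"])
  data.table::fwrite(windows_to_dt(record$pre_windows$a, fs), paths["pre_s1"])
  data.table::fwrite(windows_to_dt(record$pre_windows$b, fs), paths["pre_s2"])
  data.table::fwrite(long_bispec_dt(record$raw_matrices, record$axis),
                     paths["bispec_raw"])
  data.table::fwrite(long_bispec_dt(record$norm_matrices, record$axis),
                     paths["bispec_norm"])
  data.table::fwrite(record$band_summary, paths["bands"])
  cfg <- record$config
  meta <- list(
    subjects = record$subject_ids,
    sampling_rate = cfg$sampling_rate,
    window_seconds = cfg$window_seconds,
    calibration_seconds = cfg$calibration_seconds,
    reference_mode = cfg$reference_mode,
    conj_from = cfg$conj_from,
    bands = cfg$bands,
    filter = unclass(cfg$filter),
    n_windows = record$n_windows,
    n_discarded = record$n_discarded,
    n_calibration = record$n_calibration,
    n_task = record$n_task,
    combinations = record$combinations$label
  )
  jsonlite::write_json(meta, paths["session"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Replay two recordings through a full session and persist it
#'
#' Convenience wrapper: [replay_source()] on both recordings,
#' [run_session()], then [write_session_outputs()] when `out_dir` is
#' given.
#'
#' @param config A [session_config()].
#' @param path_a,path_b Raw recording CSVs for subjects 1 and 2.
#' @param out_dir Optional output directory.
#' @return The `b2b_session` record, invisibly.
#' @export
run_session_files <- function(config, path_a, path_b, out_dir = NULL) {
  src_a <- replay_source(path_a, config, subject_id = "s1")
  src_b <- replay_source(path_b, config, subject_id = "s2")
  record <- run_session(src_a, src_b, config)
  if (!is.null(out_dir)) write_session_outputs(record, out_dir)
  invisible(record)
}
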