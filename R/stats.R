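#' One-sided Wilcoxon rank sum (Mann-Whitney) p-value
#'
#' Two-sample, unpaired. `tail = "right"` tests whether `x` is
#' stochastically greater than `y`; `"left"` the reverse. The exact
#' distribution is enumerated when the combined sample size is at most 12
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric value vectors.
#' @param tail `"right"` or `"left"`.
#' @return The p-value.
#' @export
rank_sum_one_sided <- function(x, y, tail = c("right", "left")) {
  tail <- match.arg(tail)
  if (length(x) == 0L || length(y) == 0L) {
    stop("insufficient data: both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  alt <- if (tail == "right") "greater" else "less"
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Bonferroni-corrected per-test significance level
#'
#' @param alpha Family-wise level (e.g. 0.05).
#' @param m Number of tests in the family.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("invalid level: alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || m < 1) {
    stop("invalid count: m must be >= 1", call. = FALSE)
  }
  alpha / m
}

#' Per-window synchrony series for one dyad and task
#'
#' Collects, from a session's band summary, the vector of per-window mean
#' normalized bispectrum values for every (band, combination) cell.
#'
#' @param bands Either a session output directory (containing `bands.csv`)
#'   or a data.frame/data.table with columns `window_index`, `band`,
#'   `combination`, `value`.
#' @param dyad_id Dyad identifier.
#' @param task Task label (e.g. `"collaboration"`, `"competition"`).
#' @return An object of class `task_series`: `dyad_id`, `task`, and
#'   `values`, a named list (`"<band>|<combination>"`) of numeric
#'   vectors.
#' @export
task_series <- function(bands, dyad_id, task) {
  if (is.character(bands) && length(bands) == 1L) {
    path <- file.path(bands, "bands.csv")
    if (!file.exists(path)) {
      stop("no band summary found at ", path, call. = FALSE)
    }
    bands <- data.table::fread(path)
  }
  need <- c("window_index", "band", "combination", "value")
  if (!all(need %in% names(bands))) {
    stop("band summary must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(bands) == 0L) {
    stop("insufficient data: band summary is empty", call. = FALSE)
  }
  key <- paste(bands$band, bands$combination, sep = "|")
  values <- split(bands$value, key)
  # preserve first-appearance order (band-major as written by the session)
  values <- values[unique(key)]
  structure(list(dyad_id = dyad_id, task = task, values = values),
            class = "task_series")
}

#' Dyad x band x combination comparison grid
#'
#' For every dyad and every (band, combination) cell, compares the
#' per-window synchrony values of the first task against the second with
#' right- and left-tailed rank sum tests, and flags cells whose p-value
#' falls below the Bonferroni-corrected threshold `alpha / m`, where `m`
#' is the total number of cells. With 8 dyads, 5 bands and 4 referenced
#' combinations the family holds 160 tests and the threshold is
#' 0.05 / 160 = 3.125e-4.
#'
#' @param series_pairs Named list, one entry per dyad, each a list with
#'   elements `collab` and `compete` (both [task_series()] with matching
#'   cells).
#' @param alpha Family-wise significance level.
#' @return An object of class `comparison_grid`: a data.frame with
#'   columns `dyad`, `band`, `combination`, `p_right`, `p_left`,
#'   `sig_right`, `sig_left`, and attributes `alpha`, `m`, `threshold`,
#'   `frac_sig_right`, `frac_sig_left`.
#' @export
compare_tasks <- function(series_pairs, alpha = 0.05) {
  if (length(series_pairs) == 0L) {
    stop("insufficient data: no dyads supplied", call. = FALSE)
  }
  rows <- list()
  for (d in seq_along(series_pairs)) {
    pair <- series_pairs[[d]]
    if (!all(c("collab", "compete") %in% names(pair))) {
      stop("incomplete dyad: each dyad needs both 'collab' and 'compete' series",
           call. = FALSE)
    }
    ts1 <- pair$collab
    ts2 <- pair$compete
    keys <- names(ts1$values)
    if (!setequal(keys, names(ts2$values))) {
      stop("incomplete dyad: (band, combination) cells differ between tasks for dyad ",
           ts1$dyad_id, call. = FALSE)
    }
    dyad_id <- if (!is.null(names(series_pairs)) &&
                   nzchar(names(series_pairs)[d])) {
      names(series_pairs)[d]
    } else {
      as.character(ts1$dyad_id)
    }
    for (k in keys) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
      x <- ts1$values[[k]]
      y <- ts2$values[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        dyad = dyad_id, band = parts[1L], combination = parts[2L],
        p_right = rank_sum_one_sided(x, y, "right"),
        p_left = rank_sum_one_sided(x, y, "left"),
        stringsAsFactors = FALSE
      )
    }
  }
  grid <- do.call(rbind, rows)
  m <- nrow(grid)
  thr <- bonferroni_threshold(alpha, m)
  grid$sig_right <- grid$p_right < thr
  grid$sig_left <- grid$p_left < thr
  structure(grid,
            class = c("comparison_grid", "data.frame"),
            alpha = alpha, m = m, threshold = thr,
            frac_sig_right = sum(grid$sig_right) / m,
            frac_sig_left = sum(grid$sig_left) / m)
}

#' @export
print.comparison_grid <- function(x, ...) {
  cat(sprintf(
    "<comparison_grid> %d cells (%d dyads), alpha = %g, Bonferroni threshold = %g\n",
    attr(x, "m"), length(unique(x$dyad)), attr(x, "alpha"),
    attr(x, "threshold")))
  cat(sprintf("  significant right-tailed: %d/%d (%.2f%%)\n",
              sum(x$sig_right), attr(x, "m"),
              100 * attr(x, "frac_sig_right")))
  cat(sprintf("  significant left-tailed:  %d/%d (%.2f%%)\n",
              sum(x$sig_left), attr(x, "m"),
              100 * attr(x, "frac_sig_left")))
  NextMethod()
  invisible(x)
}
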