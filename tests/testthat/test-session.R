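test_that("window accounting: discard, calibration, task", {
  # a 10-minute source at 4-s windows: 150 windows produced,
  # 1 discarded + 15 calibration + 134 task
  set.seed(31)
  n <- 150 * 1000
  mk <- function() matrix(rnorm(n * 4), ncol = 4,
                          dimnames = list(NULL, eeg_channels()))
  cfg <- session_config()
  rec <- run_session(matrix_source("a", mk(), 1000),
                     matrix_source("b", mk(), 1000), cfg)
  expect_equal(rec$n_windows, 150L)
  expect_equal(rec$n_discarded, 1L)
  expect_equal(rec$n_calibration, 15L)
  expect_equal(rec$n_task, 134L)
  # task windows strictly ordered, no holes or duplicates
  idx <- sort(unique(rec$band_summary$window_index))
  expect_equal(idx, 16:149)
  expect_equal(rec$baseline$n_windows, 15L)
})

test_that("sessions refuse to run without enough calibration windows", {
  set.seed(32)
  short <- matrix(rnorm(10 * 1000 * 4), ncol = 4,
                  dimnames = list(NULL, eeg_channels()))
  cfg <- session_config()  # needs 1 + 15 windows
  expect_error(run_session(matrix_source("a", short, 1000),
                           matrix_source("b", short, 1000), cfg),
               "insufficient calibration")
})

test_that("a replayed recording reproduces the windows that were written", {
  spec <- synthetic_spec(duration = 24)
  dir <- withr::local_tempdir()
  g <- generate_dyad(spec, seed = 5, out_dir = dir)
  cfg <- session_config(calibration_seconds = 8)
  src <- replay_source(g$paths[1], cfg, subject_id = "a")
  expect_equal(src$n_windows, 6L)
  w2 <- src$get_window(2L)
  expect_equal(w2$window_index, 2L)
  expect_equal(w2$samples[, "C3"], g$subject_a[2001:3000, "C3"],
               tolerance = 1e-9, ignore_attr = TRUE)

  # truncation: final partial window dropped with a message
  dt <- data.table::fread(g$paths[1])
  trunc_path <- file.path(dir, "trunc.csv")
  data.table::fwrite(dt[1:3500, ], trunc_path)
  expect_message(src3 <- replay_source(trunc_path, cfg),
                 "dropped trailing partial window")
  expect_equal(src3$n_windows, 3L)
  expect_equal(attr(src3, "dropped_samples"), 500L)

  # empty recording: zero windows, the session refuses to calibrate
  empty_path <- file.path(dir, "empty.csv")
  data.table::fwrite(dt[0, ], empty_path)
  src0 <- replay_source(empty_path, cfg)
  expect_equal(src0$n_windows, 0L)
  expect_error(run_session(src0, src0, cfg), "insufficient calibration")

  # schema violations are reported with position
  bad_path <- file.path(dir, "bad.csv")
  writeLines(c("time_s,A1,A2,C3", "0,1,2,3"), bad_path)
  expect_error(replay_source(bad_path, cfg), "missing column")
})

test_that("no window is consumed before both subjects' copies exist", {
  set.seed(33)
  n_win <- 18L
  samples <- matrix(rnorm(n_win * 1000 * 4), ncol = 4,
                    dimnames = list(NULL, eeg_channels()))
  log <- new.env()
  log$events <- character(0)
  note <- function(e) log$events <- c(log$events, e)

  slow_source <- function(id, delay) {
    ready_after <- new.env()
    polls <- new.env()
    stream_source(
      id, n_win,
      get_window = function(l) {
        note(paste0("get_", id, "_", l))
        rows <- (l * 1000 + 1):((l + 1) * 1000)
        sample_window(id, l, samples[rows, , drop = FALSE])
      },
      has_window = function(l) {
        key <- as.character(l)
        cnt <- if (is.null(polls[[key]])) 0L else polls[[key]]
        polls[[key]] <- cnt + 1L
        ok <- cnt >= delay
        if (ok && is.null(ready_after[[key]])) {
          ready_after[[key]] <- TRUE
          note(paste0("ready_", id, "_", l))
        }
        ok
      })
  }
  cfg <- session_config(calibration_seconds = 8)
  rec <- run_session(slow_source("a", 0L), slow_source("b", 3L), cfg)
  expect_equal(rec$n_task, n_win - 1L - 2L)
  for (l in 0:(n_win - 1L)) {
    got <- which(log$events == paste0("get_a_", l))
    ra <- which(log$events == paste0("ready_a_", l))
    rb <- which(log$events == paste0("ready_b_", l))
    expect_true(length(got) == 1 && length(ra) == 1 && length(rb) == 1)
    expect_gt(got, max(ra, rb))
  }
})

test_that("index disagreement between sources aborts with a desync error", {
  set.seed(34)
  samples <- matrix(rnorm(20 * 1000 * 4), ncol = 4,
                    dimnames = list(NULL, eeg_channels()))
  good <- matrix_source("a", samples, 1000)
  skewed <- stream_source("b", 20L, function(l) {
    rows <- (l * 1000 + 1):((l + 1) * 1000)
    sample_window("b", l + 1L, samples[rows, , drop = FALSE])  # wrong index
  })
  cfg <- session_config(calibration_seconds = 8)
  expect_error(run_session(good, skewed, cfg), "desync")
})

test_that("session outputs form the fixed file set and are reproducible", {
  dir <- withr::local_tempdir()
  fx <- make_fixture_session("tiny", seed = 21, dir = file.path(dir, "sim"))
  out1 <- file.path(dir, "out1")
  out2 <- file.path(dir, "out2")
  rec <- run_session_files(fx$config, fx$subject_a, fx$subject_b, out1)
  run_session_files(fx$config, fx$subject_a, fx$subject_b, out2)

  want <- c("raw_s1.csv", "raw_s2.csv", "pre_s1.csv", "pre_s2.csv",
            "bispec_raw.csv", "bispec_norm.csv", "bands.csv", "session.json")
  expect_setequal(list.files(out1), want)

  h1 <- tools::md5sum(file.path(out1, want))
  h2 <- tools::md5sum(file.path(out2, want))
  expect_identical(unname(h1), unname(h2))

  # referenced mode: band summary has the 4 referenced combinations
  bands <- data.table::fread(file.path(out1, "bands.csv"))
  expect_setequal(unique(bands$combination),
                  c("C3'-C3'", "C3'-C4'", "C4'-C3'", "C4'-C4'"))
  expect_equal(nrow(bands), rec$n_task * 5 * 4)

  # replaying the written raw CSV reproduces byte-identical downstream files
  out3 <- file.path(dir, "out3")
  run_session_files(fx$config, file.path(out1, "raw_s1.csv"),
                    file.path(out1, "raw_s2.csv"), out3)
  for (f in c("bispec_raw.csv", "bispec_norm.csv", "bands.csv")) {
    expect_identical(unname(tools::md5sum(file.path(out3, f))),
                     unname(tools::md5sum(file.path(out1, f))))
  }
})

test_that("raw-4ch mode yields the 16-combination matrices", {
  set.seed(35)
  samples_a <- matrix(rnorm(18 * 1000 * 4), ncol = 4,
                      dimnames = list(NULL, eeg_channels()))
  samples_b <- matrix(rnorm(18 * 1000 * 4), ncol = 4,
                      dimnames = list(NULL, eeg_channels()))
  cfg <- session_config(calibration_seconds = 8, reference_mode = "raw-4ch")
  rec <- run_session(matrix_source("a", samples_a, 1000),
                     matrix_source("b", samples_b, 1000), cfg)
  expect_identical(dim(rec$raw_matrices[["1"]]), c(16L, 500L))
  expect_equal(length(unique(rec$band_summary$combination)), 16L)
})

test_that("session config survives a YAML round trip", {
  dir <- withr::local_tempdir()
  cfg <- session_config(calibration_seconds = 32,
                        reference_mode = "referenced-2ch",
                        conj_from = "a", seed = 9,
                        filter = filter_spec(notch_low = 48, notch_high = 52))
  path <- file.path(dir, "cfg.yaml")
  write_session_config(cfg, path)
  back <- read_session_config(path)
  expect_equal(back$calibration_seconds, 32)
  expect_equal(back$reference_mode, "referenced-2ch")
  expect_equal(back$conj_from, "a")
  expect_equal(back$filter$notch_low, 48)
  expect_equal(back$bands, cfg$bands)
  expect_error(read_session_config(file.path(dir, "nope.yaml")), "not found")
})
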