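test_that("pair events survive a write/read round trip", {
  p <- synth_params(fps = 30, duration_s = 5)
  ev1 <- simulate_trapped_pair(p, seed = 3, pair_id = "pA", event_id = "e1")
  ev2 <- simulate_natural_pair(synth_params(fps = 25, duration_s = 5),
                               seed = 4, pair_id = "pB", event_id = "e1")
  tracks <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".csv")
  write_pair_events(list(ev1, ev2), tracks, meta)
  back <- read_pair_events(tracks, meta)
  expect_length(back, 2)
  # fps 30 (trapped) and 25 (natural) both accepted and preserved
  expect_equal(back[[1]]$fps, 30)
  expect_equal(back[[2]]$fps, 25)
  for (i in 1:2) {
    orig <- list(ev1, ev2)[[i]]
    expect_equal(back[[i]]$condition, orig$condition)
    expect_equal(back[[i]]$entry_frame, orig$entry_frame)
    expect_equal(back[[i]]$f_escape_frame, orig$f_escape_frame)
    expect_equal(back[[i]]$female$body_length_mm, orig$female$body_length_mm)
    expect_equal(as.data.frame(back[[i]]$female$frames),
                 as.data.frame(orig$female$frames), tolerance = 1e-12)
    expect_equal(as.data.frame(back[[i]]$male$frames),
                 as.data.frame(orig$male$frames), tolerance = 1e-12)
  }
})

test_that("malformed event tables are hard errors", {
  ev <- simulate_natural_pair(synth_params(fps = 25, duration_s = 2), seed = 1)
  tracks <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".csv")
  write_pair_events(list(ev), tracks, meta)

  # track rows without a metadata row
  t2 <- readr::read_csv(tracks, show_col_types = FALSE)
  t2$event_id <- "unknown_event"
  tracks2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(t2, tracks2)
  expect_error(read_pair_events(tracks2, meta), "no metadata row")

  # event with only one sex
  t3 <- readr::read_csv(tracks, show_col_types = FALSE)
  t3 <- t3[t3$sex == "F", ]
  tracks3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(t3, tracks3)
  expect_error(read_pair_events(tracks3, meta), "male track missing")

  # non-monotone frames rejected by the container invariant
  expect_error(
    tracked_individual("x", "F", 8,
                       tibble::tibble(frame = c(0, 2, 1),
                                      x_mm = 0, y_mm = 0)),
    "strictly increasing")
  expect_error(
    tracked_individual("x", "F", 8,
                       tibble::tibble(frame = c(0, 1, 1),
                                      x_mm = 0, y_mm = 0)),
    "duplicated")
})

test_that("posture tables are read in both dialects with likelihood masking", {
  # pose-estimation dialect: three header rows, x/y/likelihood triples
  parts <- c("fHead", "fPro", "fTip", "mHead", "mPro", "mTip")
  lines <- c(
    paste0("scorer,", paste(rep("net", 18), collapse = ",")),
    paste0("bodyparts,", paste(rep(parts, each = 3), collapse = ",")),
    paste0("coords,", paste(rep(c("x", "y", "likelihood"), 6), collapse = ",")),
    paste0("0,", paste(rep(c("1.0", "2.0", "0.95"), 6), collapse = ",")),
    paste0("1,", paste(rep(c("3.0", "4.0", "0.85"), 6), collapse = ","))
  )
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, f)
  long <- read_posture_table(f, p_cutoff = 0.9)
  expect_equal(nrow(long), 12)
  kept <- long[long$frame == 0, ]
  expect_true(all(kept$x_mm == 1.0))          # above cutoff: passthrough
  masked <- long[long$frame == 1, ]
  expect_true(all(is.na(masked$x_mm)))        # 0.85 < 0.9: masked
  expect_true(all(masked$likelihood == 0.85)) # likelihood retained

  # cutoff 0 is a no-op
  long0 <- read_posture_table(f, p_cutoff = 0)
  expect_false(anyNA(long0$x_mm))

  # masking invariant: no retained point below the cutoff
  ok <- !is.na(long$x_mm)
  expect_true(all(long$likelihood[ok] >= 0.9))

  # tidy dialect round trip
  tidy <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(long0, tidy)
  long_tidy <- read_posture_table(tidy, p_cutoff = 0.9)
  expect_equal(long_tidy$x_mm, long$x_mm)

  # unknown body part
  bad <- long0
  bad$bodypart[1] <- "fAntenna"
  badf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, badf)
  expect_error(read_posture_table(badf), "unknown body part")

  # malformed header
  badh <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorer,a,b", "oops,a,b", "coords,x,y"), badh)
  expect_error(read_posture_table(badh), "malformed pose-estimation header")
})

test_that("downsampling keeps every fps/target-th frame and maps metadata", {
  n <- 301
  ev <- make_event(seq_len(n), rep(0, n), seq_len(n), rep(1, n),
                   condition = "trapped", fps = 30,
                   entry_frame = 31L, f_escape_frame = 65L)
  ds <- downsample(ev, 1)
  expect_equal(ds$fps, 1)
  expect_equal(ds$female$frames$frame, 0:10)
  # every 30th source frame kept
  expect_equal(ds$female$frames$x_mm, ev$female$frames$x_mm[seq(1, 301, 30)])
  # entry/escape snap to the next kept frame at or after the original,
  # in renumbered units consistent with the new rate
  expect_equal(ds$entry_frame, 2L)
  expect_equal(ds$f_escape_frame, 3L)

  ev25 <- make_event(1:51, rep(0, 51), 1:51, rep(1, 51), fps = 25)
  ds25 <- downsample(ev25, 1)
  expect_equal(ds25$female$frames$frame, 0:2)
  expect_equal(ds25$female$frames$x_mm, ev25$female$frames$x_mm[c(1, 26, 51)])

  # identity at equal rates, and idempotence after the first pass
  ev1 <- make_event(1:5, rep(0, 5), 1:5, rep(1, 5), fps = 1)
  expect_identical(downsample(ev1, 1), ev1)
  expect_identical(downsample(ds, 1), ds)

  expect_error(downsample(ev25, 10), "not an integer multiple")
})
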