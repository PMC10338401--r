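test_that("match_roi scores a self-match at exactly 1 and noise below threshold", {
  p <- toy_profile("XI")
  spec <- p$indicators[["COAG_R"]]
  frame <- array(0.35, dim = c(p$frame_height, p$frame_width, 3L))
  r <- spec$roi
  frame[(r$y + 1):(r$y + r$h), (r$x + 1):(r$x + r$w), ] <- spec$active_template
  m <- match_roi(frame, spec)
  expect_equal(m$score, 1.0)
  expect_equal(m$state, "active")

  # seeded uniform noise in the ROI: score must fall below 0.95, agreeing
  # with an independently coded correlation
  set.seed(42)
  noise <- array(stats::runif(r$h * r$w * 3), dim = c(r$h, r$w, 3L))
  frame[(r$y + 1):(r$y + r$h), (r$x + 1):(r$x + r$w), ] <- noise
  m2 <- match_roi(frame, spec)
  expect_lt(m2$score, 0.95)
  expect_equal(m2$state, "inactive")
  expect_equal(m2$score, oracle_corr(noise, spec$active_template),
               tolerance = 1e-12)

  # ROI partially outside the frame is a geometry error
  bad <- indicator_spec("CAMERA", roi_spec(0, 0, 30, 20),
                        template_pattern("CAMERA", "active", 30, 20))
  small <- array(0.5, dim = c(10, 10, 3L))
  expect_error(match_roi(small, bad), "exceeds")
})

test_that("flat background never matches a structured template", {
  expect_equal(ncc_score(array(0.5, c(4, 4, 3)), array(0.5, c(4, 4, 3))), 1)
  expect_equal(ncc_score(array(0.5, c(4, 4, 3)), array(0.7, c(4, 4, 3))), 0)
  tmpl <- template_pattern("CLUTCH", "active", 4, 4)
  expect_equal(ncc_score(array(0.5, c(4, 4, 3)), tmpl), 0)
})

test_that("scan_video yields one state per channel per frame and fails fast on mismatch", {
  p <- toy_profile("SI")
  vid <- flat_video(n = 10L, w = 320L, h = 180L)
  states <- scan_video(vid, p)
  expect_setequal(names(states), profile_channels(p))
  expect_true(all(vapply(states, length, integer(1)) == 10L))
  expect_true(all(unlist(states) == "inactive"))

  # wrong resolution: hard error, not silent zero counts
  expect_error(scan_video(flat_video(w = 100L, h = 100L), p), "mismatch")

  # truncated on-disk video errors with the frame index
  dir <- withr::local_tempdir()
  tl <- random_timeline("CAMERA", duration_s = 2, seed = 3)
  generate_console_video(tl, p, out_dir = file.path(dir, "v"))
  vdisk <- read_video(file.path(dir, "v"))
  unlink(file.path(dir, "v", "frame_000020.png"))
  expect_error(scan_video(vdisk, p), "frame index 19")
  expect_error(read_video(file.path(dir, "v")), "truncated")
})

test_that("events_from_states matches the brute-force maximal-run oracle", {
  # the spec'd worked examples
  s <- c("inactive", "active", "active", "inactive", "active")
  ev <- events_from_states(s, fps = 15)
  expect_equal(ev$start_frame, c(1L, 4L))
  expect_equal(ev$end_frame, c(3L, 5L))
  expect_equal(ev$start_s, c(1, 4) / 15)

  expect_equal(nrow(events_from_states(rep("inactive", 6), 15)), 0L)
  one <- events_from_states(rep("active", 3), 15)
  expect_equal(one[, c("start_frame", "end_frame")],
               data.frame(start_frame = 0L, end_frame = 3L))
  merged <- events_from_states(c("active", "inactive", "active"), 15,
                               min_gap_frames = 2)
  expect_equal(merged[, c("start_frame", "end_frame")],
               data.frame(start_frame = 0L, end_frame = 3L))

  # exhaustive: every binary sequence up to length 12, one aggregate check
  mismatches <- 0L
  for (n in 1:12) {
    for (code in 0:(2^n - 1)) {
      act <- bitwAnd(code, 2^(0:(n - 1))) > 0
      got <- events_from_states(act, fps = 15)
      want <- oracle_events(act)
      if (!identical(got$start_frame, want$start_frame) ||
          !identical(got$end_frame, want$end_frame)) {
        mismatches <- mismatches + 1L
      }
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("debounced extraction agrees with the oracle on random sequences", {
  set.seed(7)
  for (i in 1:400) {
    n <- sample(13:60, 1)
    act <- stats::runif(n) < stats::runif(1, 0.2, 0.8)
    md <- sample(1:4, 1); mg <- sample(1:4, 1)
    got <- events_from_states(act, fps = 15, min_duration_frames = md,
                              min_gap_frames = mg)
    want <- oracle_events(act, min_duration = md, min_gap = mg)
    expect_identical(got$start_frame, want$start_frame)
    expect_identical(got$end_frame, want$end_frame)
  }
})

test_that("raising debounce parameters never increases the event count", {
  set.seed(8)
  for (i in 1:100) {
    act <- stats::runif(40) < 0.5
    base <- nrow(events_from_states(act, 15))
    for (md in 2:4) {
      expect_lte(nrow(events_from_states(act, 15, min_duration_frames = md)),
                 nrow(events_from_states(act, 15, min_duration_frames = md - 1)))
    }
    for (mg in 2:4) {
      expect_lte(nrow(events_from_states(act, 15, min_gap_frames = mg)), base)
    }
  }
})

test_that("events_from_states validates its parameters", {
  expect_error(events_from_states(c("active"), fps = 0), "fps")
  expect_error(events_from_states(character(0), fps = 15), "nonempty")
  expect_error(events_from_states(c("active"), 15, min_gap_frames = 0), ">= 1")
})

test_that("detect_events recovers scripted counts and is deterministic on disk", {
  p <- toy_profile("XI")
  tl <- event_timeline(data.frame(
    channel = c("COAG_R", "COAG_R", "COAG_R", "CLUTCH_L", "CAMERA", "CAMERA"),
    start_s = c(0.2, 1.0, 2.0, 0.5, 1.5, 3.0),
    end_s   = c(0.6, 1.4, 2.5, 1.0, 2.0, 3.4)), fps = 15, duration_s = 4)
  gen <- generate_console_video(tl, p)
  log <- detect_events(gen$video, p)
  want <- c(COAG_R = 3L, CLUTCH_L = 1L, CAMERA = 2L)
  expect_equal(log$counts[names(want)], want)
  expect_true(all(log$counts[setdiff(names(log$counts), names(want))] == 0L))
  expect_identical(log$events, gen$truth$events)

  # empty timeline: all counts zero
  empty <- event_timeline(data.frame(channel = character(0),
                                     start_s = numeric(0),
                                     end_s = numeric(0)), 15, 1)
  log0 <- detect_events(generate_console_video(empty, p)$video, p)
  expect_true(all(log0$counts == 0L))

  # two scans of the same file give byte-identical event CSVs
  dir <- withr::local_tempdir()
  write_video(gen$video, file.path(dir, "v"))
  v1 <- read_video(file.path(dir, "v"))
  csv1 <- file.path(dir, "a.csv"); csv2 <- file.path(dir, "b.csv")
  write_event_csv(detect_events(v1, p), csv1)
  write_event_csv(detect_events(read_video(file.path(dir, "v")), p), csv2)
  expect_identical(readBin(csv1, "raw", file.size(csv1)),
                   readBin(csv2, "raw", file.size(csv2)))
})

test_that("hover frames are audited in the state stream but never counted", {
  p <- toy_profile("XI")
  tl <- event_timeline(data.frame(channel = "COAG_L", start_s = 0.2,
                                  end_s = 1.0, state = "hover"),
                       fps = 15, duration_s = 2)
  vid <- generate_console_video(tl, p)$video
  states <- scan_video(vid, p)
  expect_equal(sum(states$COAG_L == "hover"), 12L)  # frames [3, 15)
  expect_equal(sum(states$COAG_L == "active"), 0L)
  log <- detect_events(vid, p)
  expect_equal(unname(log$counts["COAG_L"]), 0L)
})

test_that("Si and Xi renders of one timeline agree after clutch pooling", {
  shared <- c("CUT_L", "CUT_R", "COAG_L", "COAG_R", "THIRD_ARM_SWAP",
              "CAMERA", "CLUTCH")
  for (seed in c(21, 22, 23)) {
    tl <- random_timeline(shared, duration_s = 5, seed = seed)
    counts <- lapply(c("SI", "XI"), function(gen) {
      p <- toy_profile(gen)
      g <- generate_console_video(adapt_timeline(tl, p), p)
      pool_clutch_counts(detect_events(g$video, p)$counts)
    })
    expect_equal(counts[[1]][sort(names(counts[[1]]))],
                 counts[[2]][sort(names(counts[[2]]))])
  }
})
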