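test_that("path_length reproduces closed-form examples", {
  obs <- data.frame(frame_index = 0:1, x = c(0, 3), y = c(0, 4),
                    confidence = 1, valid = TRUE)
  m <- path_length(hand_track("left", "wrist", obs, fps = 15))
  expect_equal(m$path_length_px, 5.0)
  expect_equal(m$n_valid_points, 2L)
  expect_equal(m$n_gaps, 0L)

  square <- data.frame(frame_index = 0:4,
                       x = c(0, 10, 10, 0, 0), y = c(0, 0, 10, 10, 0),
                       confidence = 1, valid = TRUE)
  expect_equal(path_length(hand_track("right", "wrist", square, 15))$path_length_px,
               40.0)

  # degenerate tracks have zero length
  empty <- hand_track("left", "wrist", obs[0, ], fps = 15)
  expect_equal(path_length(empty)$path_length_px, 0)
  single <- hand_track("left", "wrist", obs[1, ], fps = 15)
  expect_equal(path_length(single)$path_length_px, 0)
})

test_that("path_length agrees with a brute-force oracle on seeded walks", {
  set.seed(101)
  for (i in 1:20) {
    n <- 1000L
    xs <- cumsum(stats::rnorm(n)); ys <- cumsum(stats::rnorm(n))
    obs <- data.frame(frame_index = 0:(n - 1L), x = xs, y = ys,
                      confidence = 1, valid = TRUE)
    m <- path_length(hand_track("left", "wrist", obs, 15))
    expect_equal(m$path_length_px, oracle_path_length(xs, ys),
                 tolerance = 1e-9)
  }
})

test_that("path length is translation-invariant, scales linearly, and split <= bridge", {
  set.seed(202)
  fails <- c(translation = 0L, scaling = 0L, split = 0L, additive = 0L)
  for (i in 1:300) {
    tr <- random_track(n = sample(5:60, 1), dropout = stats::runif(1, 0, 0.4))
    b <- path_length(tr, "bridge")$path_length_px
    s <- path_length(tr, "split")$path_length_px
    if (s > b + 1e-12) fails["split"] <- fails["split"] + 1L

    shifted <- tr
    dx <- stats::rnorm(1, sd = 50); dy <- stats::rnorm(1, sd = 50)
    shifted$obs$x <- shifted$obs$x + dx; shifted$obs$y <- shifted$obs$y + dy
    if (abs(path_length(shifted)$path_length_px - b) > 1e-9 * max(1, b)) {
      fails["translation"] <- fails["translation"] + 1L
    }

    k <- stats::runif(1, 0.1, 5)
    scaled <- tr
    scaled$obs$x <- scaled$obs$x * k; scaled$obs$y <- scaled$obs$y * k
    if (abs(path_length(scaled)$path_length_px - k * b) > 1e-9 * max(1, b)) {
      fails["scaling"] <- fails["scaling"] + 1L
    }
  }
  # additivity: concatenating B after A, B starting at A's endpoint
  for (i in 1:50) {
    a <- random_track(n = 20); a$obs$valid <- TRUE
    b <- random_track(n = 20); b$obs$valid <- TRUE
    b$obs$x <- b$obs$x - b$obs$x[1] + a$obs$x[20]
    b$obs$y <- b$obs$y - b$obs$y[1] + a$obs$y[20]
    b$obs$frame_index <- b$obs$frame_index + 20L
    ab <- hand_track("left", "wrist", rbind(a$obs, b$obs[-1, ]), 15)
    la <- path_length(a)$path_length_px
    lb <- path_length(b)$path_length_px
    lab <- path_length(ab)$path_length_px
    if (abs(lab - (la + lb)) > 1e-9 * max(1, lab)) {
      fails["additive"] <- fails["additive"] + 1L
    }
  }
  expect_true(all(fails == 0L), info = paste(names(fails), fails, collapse = ", "))
})

test_that("build_tracks applies confidence and geometry validity and handles gaps", {
  lm <- data.frame(frame_index = c(0, 1, 2, 3, 4),
                   hand = "left", landmark = "wrist",
                   x = c(5, 6, 400, 8, 9), y = c(5, 6, 7, 8, 9),
                   confidence = c(0.9, 0.3, 0.9, 0.9, 0.9))
  tr <- build_tracks(lm, fps = 15, frame_width = 320, frame_height = 180)
  expect_equal(tr$left$obs$valid, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  m <- path_length(tr$left)
  expect_equal(m$n_valid_points, 3L)
  expect_equal(m$n_gaps, 1L)  # 0 -> 3 spans invalid frames
  expect_equal(nrow(tr$right$obs), 0L)
})

test_that("track_hands honors the detector contract, logging failures as gaps", {
  vid <- flat_video(n = 10L)
  fixed <- function(frame, i) {
    data.frame(hand = c("left", "right"), landmark = "wrist",
               x = c(3, 10), y = c(4, 2), confidence = 0.9)
  }
  tracks <- track_hands(vid, fixed)
  expect_equal(nrow(tracks$left$obs), 10L)
  expect_equal(path_length(tracks$left)$n_gaps, 0L)
  expect_equal(path_length(tracks$left)$path_length_px, 0)

  flaky <- function(frame, i) {
    if (i %in% 5:9) stop("model diverged")
    data.frame(hand = "left", landmark = "wrist", x = i, y = 0,
               confidence = 1)
  }
  w <- capture_warnings(tracks2 <- track_hands(vid, flaky))
  expect_length(w, 5L)  # one logged failure per bad frame
  expect_match(w[1], "frame 5")
  expect_equal(nrow(tracks2$left$obs), 5L)
  expect_gte(path_length(tracks2$left)$n_gaps, 0L)
  expect_equal(nrow(tracks2$right$obs), 0L)

  left_only <- function(frame, i) {
    data.frame(hand = "left", landmark = "wrist", x = 1, y = 1,
               confidence = 1)
  }
  expect_equal(nrow(track_hands(vid, left_only)$right$obs), 0L)
})

test_that("landmark CSV round-trips through write/read", {
  dir <- withr::local_tempdir()
  gen <- generate_landmark_stream(n_steps = 50, seed = 5,
                                  out_csv = file.path(dir, "lm.csv"))
  back <- read_landmarks(file.path(dir, "lm.csv"))
  expect_equal(back$x, gen$landmarks$x, tolerance = 1e-12)
  expect_equal(back$hand, gen$landmarks$hand)
  expect_error(read_landmarks(
    write_landmarks(gen$landmarks[, -3], file.path(dir, "bad.csv"))),
    "missing column")
})

test_that("overlay leaves untouched pixels identical and draws the trail", {
  vid <- textured_video(n = 3L)
  # empty tracks: output pixel-identical to input
  out0 <- render_path_overlay(vid, list())
  for (i in 1:3) expect_identical(get_frame(out0, i), get_frame(vid, i))

  obs <- data.frame(frame_index = 0:1, x = c(2, 12), y = c(3, 3),
                    confidence = 1, valid = TRUE)
  tr <- hand_track("right", "wrist", obs, fps = 15)
  out <- render_path_overlay(vid, list(tr))
  last <- get_frame(out, 3)
  # endpoints carry the right-hand color (green)
  expect_equal(last[4, 3, ], c(0, 1, 0))
  expect_equal(last[4, 13, ], c(0, 1, 0))
  # the segment between them is drawn on the row
  expect_true(all(last[4, 3:13, 2] == 1))
  # rows far from the trail are untouched
  expect_identical(last[10:18, , ], get_frame(vid, 3)[10:18, , ])

  # geometry mismatch is an error
  far <- hand_track("left", "wrist",
                    data.frame(frame_index = 0, x = 999, y = 1,
                               confidence = 1, valid = TRUE), 15)
  expect_error(render_path_overlay(vid, list(far)), "outside")
})
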