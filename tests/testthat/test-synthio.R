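test_that("timeline validation enforces span ordering and channel hygiene", {
  expect_error(event_timeline(data.frame(channel = "CAMERA", start_s = 1,
                                         end_s = 0.5), 15, 10),
               "end_s > start_s")
  expect_error(event_timeline(data.frame(channel = "CAMERA", start_s = 1,
                                         end_s = 20), 15, 10), "within")
  expect_error(event_timeline(data.frame(channel = "NOT_A_CHANNEL",
                                         start_s = 0, end_s = 1), 15, 10),
               "unknown channel")
  # same-channel spans closer than a frame would fuse when rendered
  expect_error(event_timeline(data.frame(channel = "CAMERA",
                                         start_s = c(0, 1), end_s = c(1, 2)),
                              15, 10), "overlap or touch")
  # a timeline channel the profile lacks is an error at render time
  tl <- event_timeline(data.frame(channel = "CLUTCH", start_s = 0,
                                  end_s = 1), 15, 2)
  expect_error(generate_console_video(tl, toy_profile("XI")),
               "absent from profile")
})

test_that("scripted spans map to the expected ground-truth frames", {
  tl <- event_timeline(data.frame(channel = "COAG_R", start_s = 1.0,
                                  end_s = 1.4), fps = 15, duration_s = 3)
  truth <- timeline_truth(tl)
  expect_equal(truth$events$start_frame, 15L)
  expect_equal(truth$events$end_frame, 21L)
  expect_equal(unname(truth$counts["COAG_R"]), 1L)

  empty <- event_timeline(data.frame(channel = character(0),
                                     start_s = numeric(0),
                                     end_s = numeric(0)),
                          fps = 15, duration_s = 2)
  t0 <- timeline_truth(empty, channels = c("CAMERA", "CLUTCH"))
  expect_true(all(t0$counts == 0L))
  expect_equal(t0$n_frames, 30L)
})

test_that("renders are seed-deterministic, byte-identical on disk", {
  p <- toy_profile("SI")
  tl <- random_timeline(profile_channels(p), duration_s = 2, seed = 9)
  scene <- synthetic_scene(noise_sd = 0.03, seed = 123)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_console_video(tl, p, scene, out_dir = file.path(d1, "v"))
  generate_console_video(tl, p, scene, out_dir = file.path(d2, "v"))
  f1 <- list.files(file.path(d1, "v"), pattern = "png$", full.names = TRUE)
  f2 <- list.files(file.path(d2, "v"), pattern = "png$", full.names = TRUE)
  expect_equal(length(f1), length(f2))
  same <- mapply(function(a, b) identical(readBin(a, "raw", file.size(a)),
                                          readBin(b, "raw", file.size(b))),
                 f1, f2)
  expect_true(all(same))
  # different seed changes the noise, hence the pixels
  alt <- generate_console_video(tl, p, synthetic_scene(noise_sd = 0.03,
                                                       seed = 124))
  ref <- generate_console_video(tl, p, scene)
  expect_false(identical(get_frame(alt$video, 1), get_frame(ref$video, 1)))
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(1)
  a <- stats::runif(3)
  set.seed(1)
  invisible(generate_console_video(
    random_timeline("CAMERA", duration_s = 1, seed = 2), toy_profile("SI"),
    synthetic_scene(noise_sd = 0.02, seed = 99)))
  b <- stats::runif(3)
  expect_identical(a, b)
})

test_that("event recovery stays exact up to the pinned noise amplitude", {
  # noise_sd = 0.05 is the documented robustness bound for the toy profiles
  p <- toy_profile("XI")
  tl <- random_timeline(profile_channels(p), duration_s = 4, seed = 31)
  clean <- generate_console_video(tl, p)
  noisy <- generate_console_video(tl, p, synthetic_scene(noise_sd = 0.05,
                                                         seed = 7))
  expect_gt(sum(clean$truth$counts), 0)
  expect_identical(detect_events(clean$video, p)$counts, clean$truth$counts)
  expect_identical(detect_events(noisy$video, p)$counts, noisy$truth$counts)
})

test_that("landmark generator's analytic truth matches the analysis module", {
  # two waypoints on a 3-4-5 triangle
  wp <- generate_landmark_stream(waypoints = cbind(c(0, 3), c(0, 4)))
  expect_equal(wp$truth$bridge, 5.0)
  tr <- build_tracks(wp$landmarks, fps = 15)$left
  expect_equal(path_length(tr)$path_length_px, 5.0)

  # seeded 500-step walk, no dropout: bridge length equals generated truth
  gen <- generate_landmark_stream(n_steps = 500, seed = 21)
  tr2 <- build_tracks(gen$landmarks, fps = 15)$left
  expect_equal(path_length(tr2, "bridge")$path_length_px, gen$truth$bridge,
               tolerance = 1e-9)

  # with dropout, truths separate and the module recovers both
  drp <- generate_landmark_stream(n_steps = 400, seed = 22,
                                  dropout_rate = 0.1)
  tr3 <- build_tracks(drp$landmarks, fps = 15)$left
  expect_equal(path_length(tr3, "bridge")$path_length_px, drp$truth$bridge,
               tolerance = 1e-9)
  expect_equal(path_length(tr3, "split")$path_length_px, drp$truth$split,
               tolerance = 1e-9)
  expect_lte(drp$truth$split, drp$truth$bridge)
})

test_that("label-file generator closes the loop with aggregation", {
  # all-zero request: empty event list
  z <- generate_label_file(c("Suction" = 0))
  expect_equal(nrow(z$events), 0L)

  set.seed(99)
  subs <- unlist(default_label_schema(), use.names = FALSE)
  req <- stats::setNames(sample(0:9, length(subs), replace = TRUE), subs)
  dir <- withr::local_tempdir()
  gen <- generate_label_file(req, seed = 4,
                             out_tsv = file.path(dir, "lab.tsv"))
  tab <- aggregate_label_counts(parse_labels(gen$path))
  expect_equal(stats::setNames(tab$count, tab$subcategory)[subs], req)
  expect_equal(tab$category_total, gen$truth$category_total)

  expect_error(generate_label_file(c("Suction" = 1000), duration_s = 1),
               "infeasible packing")
  expect_error(generate_label_file(c("Nonsense" = 1)), "not in schema")
})
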