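#' @title Synthetic console-video simulator
#'
#' @description
#' The simulator renders console videos from scripted event timelines with
#' exact, frame-level ground truth, plus landmark streams and label files
#' with analytically known metrics. It is the test bed for the whole
#' pipeline: every generator returns its paired ground truth, and the
#' corresponding analysis module must recover it exactly on clean output.
#'
#' Real console overlays are proprietary imagery; the simulator instead
#' gives each (channel, state) its own deterministic sinusoid pattern.
#' Distinct patterns use distinct Fourier modes of the ROI grid, so they
#' are mutually near-orthogonal under normalized correlation — an
#' indicator's active template scores ~1 on its own rendering, ~0 on
#' background, hover patterns, and every other channel. The detection
#' templates ARE crops of the rendered active state, so profile and
#' renderer are self-consistent by construction.
#' @name synthio
NULL

# restore the caller's RNG state after seeded generation
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic indicator template pattern
#'
#' Channel- and state-specific sinusoid over the ROI grid: channel `k`
#' (its position in [event_channels()]) uses Fourier mode
#' `(1 + k mod 4, 1 + k mod 3)` for the active state and a shifted mode for
#' hover, with per-color phase offsets. Values stay in `[0.1, 0.9]`, pixel
#' standard deviation ~0.2.
#'
#' @param channel channel id.
#' @param state `"active"` or `"hover"`.
#' @param w,h template extent in pixels.
#' @return `h x w x 3` array in `[0, 1]`.
#' @export
template_pattern <- function(channel, state = c("active", "hover"), w, h) {
  state <- match.arg(state)
  k <- match(channel, event_channels())
  if (is.na(k)) stop("unknown channel: ", channel, call. = FALSE)
  fx <- 1L + k %% 4L
  fy <- 1L + k %% 3L
  if (state == "hover") {
    fx <- fx + 4L
    fy <- fy + 3L
  }
  x <- matrix(rep(0:(w - 1L), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1L), times = w), nrow = h)
  out <- array(0, dim = c(h, w, 3L))
  for (c3 in 1:3) {
    phase <- (c3 - 1) * 2 * pi / 3
    out[, , c3] <- 0.5 + 0.4 * sin(2 * pi * fx * x / w + phase) *
      cos(2 * pi * fy * y / h)
  }
  out
}

#' Bundled toy profiles for the simulator
#'
#' Small-resolution (default 320x180) Si and Xi profiles whose indicator
#' templates come from [template_pattern()]. Indicators sit in a bottom
#' panel strip, one 30x20 ROI per channel; thresholds are the package
#' defaults ([default_threshold()]). These profiles keep the full
#' closed-loop render-and-detect test fast.
#'
#' @param generation `"XI"` or `"SI"`.
#' @param width,height frame resolution in pixels.
#' @param fps default frame rate.
#' @param with_hover include hover templates for the pedal indicators.
#' @return A `system_profile`.
#' @export
toy_profile <- function(generation = c("XI", "SI"), width = 320L,
                        height = 180L, fps = 15, with_hover = TRUE) {
  generation <- match.arg(toupper(generation), c("XI", "SI"))
  chans <- generation_channels(generation)
  w <- 30L; h <- 20L
  y0 <- height - h - 10L
  hover_chans <- c("CUT_L", "CUT_R", "COAG_L", "COAG_R")
  indicators <- lapply(seq_along(chans), function(i) {
    ch <- chans[i]
    x0 <- 5L + (i - 1L) * (w + 5L)
    if (x0 + w > width) stop("frame too narrow for the toy panel", call. = FALSE)
    hover <- if (with_hover && ch %in% hover_chans) {
      template_pattern(ch, "hover", w, h)
    }
    indicator_spec(ch, roi_spec(x0, y0, w, h),
                   active_template = template_pattern(ch, "active", w, h),
                   hover_template = hover)
  })
  system_profile(generation, width, height, indicators, fps_default = fps)
}

#' Scripted event timeline
#'
#' Ground truth driving the simulator: a set of per-channel spans, each
#' `[start_s, end_s)` in a given state. Spans of one channel must not
#' overlap and — so that two scripted presses never fuse into one rendered
#' run — consecutive same-channel spans must be separated by at least one
#' frame.
#'
#' @param spans data.frame with columns `channel`, `start_s`, `end_s` and
#'   optionally `state` (`"active"` default, or `"hover"`).
#' @param fps frames per second.
#' @param duration_s total video duration in seconds.
#' @return An `event_timeline` object.
#' @export
event_timeline <- function(spans, fps, duration_s) {
  stopifnot(is.data.frame(spans), fps > 0, duration_s > 0)
  if (is.null(spans$state)) spans$state <- rep("active", nrow(spans))
  if (nrow(spans)) {
    stopifnot(all(c("channel", "start_s", "end_s") %in% names(spans)))
    if (!all(spans$channel %in% event_channels())) {
      stop("unknown channel in timeline", call. = FALSE)
    }
    if (!all(spans$state %in% c("active", "hover"))) {
      stop("span state must be active or hover", call. = FALSE)
    }
    if (any(spans$end_s <= spans$start_s)) {
      stop("timeline spans must satisfy end_s > start_s", call. = FALSE)
    }
    if (any(spans$start_s < 0) || any(spans$end_s > duration_s + 1e-9)) {
      stop("timeline spans must lie within [0, duration_s]", call. = FALSE)
    }
    for (ch in unique(spans$channel)) {
      sub <- spans[spans$channel == ch, , drop = FALSE]
      sub <- sub[order(sub$start_s), , drop = FALSE]
      if (nrow(sub) > 1L) {
        a <- round_frame(sub$start_s[-1L] * fps)
        b <- round_frame(sub$end_s[-nrow(sub)] * fps)
        if (any(a <= b)) {
          stop("spans for channel ", ch,
               " overlap or touch within one frame", call. = FALSE)
        }
      }
    }
    spans <- spans[order(spans$start_s, spans$channel), , drop = FALSE]
    rownames(spans) <- NULL
  }
  structure(list(spans = spans, fps = as.numeric(fps),
                 duration_s = as.numeric(duration_s)),
            class = "event_timeline")
}

#' Adapt a timeline's clutch channel to a profile's generation
#'
#' A generation-neutral timeline may script `CLUTCH`; on an Xi profile
#' those spans render on `CLUTCH_L`. Conversely `CLUTCH_L`/`CLUTCH_R`
#' spans map onto the conjoined `CLUTCH` of an Si profile.
#'
#' @param timeline an `event_timeline`.
#' @param profile a `system_profile`.
#' @return An `event_timeline` whose channels all exist in the profile.
#' @export
adapt_timeline <- function(timeline, profile) {
  spans <- timeline$spans
  have <- profile_channels(profile)
  if (nrow(spans)) {
    if (!"CLUTCH" %in% have) {
      spans$channel[spans$channel == "CLUTCH"] <- "CLUTCH_L"
    } else {
      spans$channel[spans$channel %in% c("CLUTCH_L", "CLUTCH_R")] <- "CLUTCH"
    }
    missing <- setdiff(unique(spans$channel), have)
    if (length(missing)) {
      stop("timeline channel(s) absent from profile: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  event_timeline(spans, timeline$fps, timeline$duration_s)
}

#' Ground-truth event log of a timeline
#'
#' The log a perfect detector would produce: one event per scripted
#' *active* span, on frames `[round(start_s * fps), round(end_s * fps))`;
#' hover spans contribute nothing.
#'
#' @param timeline an `event_timeline`.
#' @param channels channels to tabulate counts over (e.g.
#'   `profile_channels(profile)`); defaults to the channels present in the
#'   timeline.
#' @param video_id identifier for the log.
#' @return An `event_log`.
#' @export
timeline_truth <- function(timeline, channels = NULL, video_id = "synthetic") {
  spans <- timeline$spans
  act <- spans[spans$state == "active", , drop = FALSE]
  fps <- timeline$fps
  nf <- round_frame(timeline$duration_s * fps)
  if (nrow(act)) {
    events <- data.frame(channel = act$channel,
                         start_frame = round_frame(act$start_s * fps),
                         end_frame = round_frame(act$end_s * fps),
                         stringsAsFactors = FALSE)
    events$start_s <- events$start_frame / fps
    events$duration_s <- (events$end_frame - events$start_frame) / fps
    events <- events[events$end_frame > events$start_frame, , drop = FALSE]
    events <- events[order(events$start_frame, events$channel), , drop = FALSE]
    rownames(events) <- NULL
  } else {
    events <- data.frame(channel = character(0), start_frame = integer(0),
                         end_frame = integer(0), start_s = numeric(0),
                         duration_s = numeric(0))
  }
  if (is.null(channels)) channels <- unique(events$channel)
  counts <- vapply(channels, function(ch) sum(events$channel == ch), integer(1))
  names(counts) <- channels
  event_log(video_id, fps, nf, events, counts)
}

#' Rendering conditions for the simulator
#'
#' @param background_gray flat background intensity in `[0, 1]`.
#' @param noise_sd Gaussian pixel noise standard deviation (0 = clean).
#'   Event recovery is exact up to `noise_sd = 0.05` with the toy
#'   profiles' default thresholds.
#' @param seed RNG seed making renders byte-identical.
#' @return A `synthetic_scene` list.
#' @export
synthetic_scene <- function(background_gray = 0.35, noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0, background_gray >= 0, background_gray <= 1)
  structure(list(background_gray = background_gray, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' Render a console video from a scripted timeline
#'
#' Every frame starts from the flat background; each channel whose
#' timeline state covers the frame gets its active (or hover) template
#' pasted into its ROI; optional Gaussian noise is added last and clamped
#' to `[0, 1]`. Identical seeds give identical pixels.
#'
#' @param timeline an `event_timeline` (channels must exist in the
#'   profile; use [adapt_timeline()] for generation-neutral scripts).
#' @param profile a `system_profile`.
#' @param scene a [synthetic_scene()].
#' @param out_dir optional frame-sequence directory for the rendered
#'   video.
#' @param video_id identifier for the video and its truth log.
#' @return List with `video` (a `frame_video`) and `truth` (the
#'   ground-truth `event_log` over the profile's channels).
#' @export
generate_console_video <- function(timeline, profile,
                                   scene = synthetic_scene(),
                                   out_dir = NULL, video_id = "synthetic") {
  stopifnot(inherits(timeline, "event_timeline"),
            inherits(profile, "system_profile"))
  spans <- timeline$spans
  missing <- setdiff(unique(spans$channel), profile_channels(profile))
  if (length(missing)) {
    stop("timeline channel(s) absent from profile: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fps <- timeline$fps
  nf <- round_frame(timeline$duration_s * fps)
  bg <- array(scene$background_gray,
              dim = c(profile$frame_height, profile$frame_width, 3L))
  # per-span frame ranges, precomputed once
  if (nrow(spans)) {
    spans$f0 <- round_frame(spans$start_s * fps)
    spans$f1 <- round_frame(spans$end_s * fps)
  }
  frames <- with_seed(scene$seed, {
    lapply(seq_len(nf), function(i) {
      f <- bg
      fr <- i - 1L
      if (nrow(spans)) {
        live <- spans[spans$f0 <= fr & fr < spans$f1, , drop = FALSE]
        for (j in seq_len(nrow(live))) {
          ind <- profile$indicators[[live$channel[j]]]
          tmpl <- if (live$state[j] == "active") ind$active_template
                  else ind$hover_template
          if (is.null(tmpl)) next  # hover scripted on an indicator without one
          r <- ind$roi
          f[(r$y + 1L):(r$y + r$h), (r$x + 1L):(r$x + r$w), ] <- tmpl
        }
      }
      if (scene$noise_sd > 0) {
        f <- f + array(stats::rnorm(length(f), sd = scene$noise_sd), dim = dim(f))
        f[f < 0] <- 0; f[f > 1] <- 1
      }
      f
    })
  })
  video <- frame_video(frames, fps = fps, video_id = video_id)
  if (!is.null(out_dir)) write_video(video, out_dir)
  truth <- timeline_truth(timeline, channels = profile_channels(profile),
                          video_id = video_id)
  list(video = video, truth = truth)
}

#' Random scripted timeline
#'
#' Draws, for each requested channel, a random set of active spans (and
#' optional hover lead-ins for pedal channels) aligned to frame
#' boundaries, with at least one clear frame between consecutive spans of
#' a channel. Deterministic for a fixed seed.
#'
#' @param channels channel ids to script.
#' @param duration_s video duration in seconds.
#' @param fps frames per second.
#' @param seed RNG seed.
#' @param max_events_per_channel upper bound on spans per channel.
#' @return An `event_timeline`.
#' @export
random_timeline <- function(channels, duration_s = 8, fps = 15, seed = 1L,
                            max_events_per_channel = 4L) {
  nf <- round_frame(duration_s * fps)
  with_seed(seed, {
    rows <- list()
    for (ch in channels) {
      k <- sample(0:max_events_per_channel, 1L)
      pos <- sample(0:5, 1L)
      for (e in seq_len(k)) {
        len <- sample(2:8, 1L)
        if (pos + len + 2L > nf) break
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, start_s = pos / fps, end_s = (pos + len) / fps,
          state = "active", stringsAsFactors = FALSE)
        pos <- pos + len + sample(2:12, 1L)
      }
    }
    spans <- if (length(rows)) do.call(rbind, rows) else
      data.frame(channel = character(0), start_s = numeric(0),
                 end_s = numeric(0), state = character(0))
    event_timeline(spans, fps, duration_s)
  })
}

#' Generate a landmark stream with known path length
#'
#' Either a fixed waypoint sequence (one observation per frame) or a
#' seeded Gaussian random walk, with an optional dropout fraction whose
#' affected frames get confidence 0 (invalid). The true path lengths under
#' both gap policies are computed at generation time from the surviving
#' points.
#'
#' @param waypoints optional 2-column matrix/data.frame of x, y positions.
#' @param n_steps walk length when no waypoints are given.
#' @param start walk starting position `c(x, y)`.
#' @param step_sd walk step standard deviation in pixels.
#' @param frame_size `c(width, height)` bounds (positions are clamped).
#' @param dropout_rate fraction of observations marked invalid.
#' @param hand,landmark identity of the track.
#' @param fps frames per second.
#' @param seed RNG seed.
#' @param out_csv optional CSV path for the stream.
#' @return List with `landmarks` (data.frame), `truth` (list `bridge`,
#'   `split`: true path lengths in pixels) and `fps`.
#' @export
generate_landmark_stream <- function(waypoints = NULL, n_steps = 500L,
                                     start = c(160, 90), step_sd = 3,
                                     frame_size = c(320, 180),
                                     dropout_rate = 0, hand = "left",
                                     landmark = "wrist", fps = 15,
                                     seed = 1L, out_csv = NULL) {
  pts <- with_seed(seed, {
    if (!is.null(waypoints)) {
      m <- as.matrix(as.data.frame(waypoints))
      colnames(m) <- c("x", "y")
      m
    } else {
      dx <- stats::rnorm(n_steps, sd = step_sd)
      dy <- stats::rnorm(n_steps, sd = step_sd)
      x <- pmin(pmax(start[1] + cumsum(dx), 0), frame_size[1] - 1)
      y <- pmin(pmax(start[2] + cumsum(dy), 0), frame_size[2] - 1)
      cbind(x = c(start[1], x), y = c(start[2], y))
    }
  })
  n <- nrow(pts)
  valid <- rep(TRUE, n)
  if (dropout_rate > 0) {
    valid <- with_seed(seed + 1L, stats::runif(n) >= dropout_rate)
  }
  landmarks <- data.frame(frame_index = 0:(n - 1L), hand = hand,
                          landmark = landmark, x = pts[, "x"], y = pts[, "y"],
                          confidence = ifelse(valid, 1, 0),
                          stringsAsFactors = FALSE)
  v <- pts[valid, , drop = FALSE]
  truth <- if (nrow(v) > 1L) {
    seg <- sqrt(diff(v[, "x"])^2 + diff(v[, "y"])^2)
    adjacent <- diff(which(valid)) == 1L
    list(bridge = sum(seg), split = sum(seg[adjacent]))
  } else {
    list(bridge = 0, split = 0)
  }
  if (!is.null(out_csv)) write_landmarks(landmarks, out_csv)
  list(landmarks = landmarks, truth = truth, fps = fps)
}

#' Generate a label TSV with known aggregate counts
#'
#' Packs the requested number of intervals per subcategory into the
#' duration as non-overlapping slots (subcategory order shuffled by the
#' seed) and emits a well-formed START/STOP TSV whose
#' [aggregate_label_counts()] equals the request exactly.
#'
#' @param counts named integer vector: subcategory -> interval count
#'   (subcategories absent from the names get 0).
#' @param schema a `label_schema`; all names in `counts` must be in it.
#' @param duration_s total annotated duration in seconds.
#' @param seed RNG seed for slot shuffling.
#' @param out_tsv optional TSV output path.
#' @return List with `events` (data.frame), `truth` (a `count_table`) and
#'   `path` (the TSV path or `NULL`).
#' @export
generate_label_file <- function(counts, schema = default_label_schema(),
                                duration_s = 3600, seed = 1L,
                                out_tsv = NULL) {
  subs <- unlist(schema, use.names = FALSE)
  unknown <- setdiff(names(counts), subs)
  if (length(unknown)) {
    stop("count name(s) not in schema: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  total <- sum(counts)
  if (total > 0) {
    slot <- duration_s / total
    if (slot < 0.01) {
      stop("infeasible packing: ", total, " intervals do not fit in ",
           duration_s, " s", call. = FALSE)
    }
    behaviors <- rep(names(counts), counts)
    behaviors <- with_seed(seed, sample(behaviors))
    i <- seq_along(behaviors) - 1L
    starts <- i * slot + 0.05 * slot
    stops <- (i + 1L) * slot - 0.05 * slot
    events <- data.frame(
      time_s = as.vector(rbind(starts, stops)),
      behavior = rep(behaviors, each = 2L),
      status = rep(c("START", "STOP"), times = total),
      stringsAsFactors = FALSE)
  } else {
    events <- data.frame(time_s = numeric(0), behavior = character(0),
                         status = character(0), stringsAsFactors = FALSE)
  }
  path <- NULL
  if (!is.null(out_tsv)) {
    serialize_labels(events, out_tsv)
    path <- out_tsv
  }
  truth_counts <- stats::setNames(integer(length(subs)), subs)
  truth_counts[names(counts)] <- as.integer(counts)
  cat_of <- schema_lookup(schema)
  truth <- data.frame(category = unname(cat_of[subs]), subcategory = subs,
                      count = as.integer(truth_counts),
                      stringsAsFactors = FALSE)
  totals <- tapply(truth$count, truth$category, sum)
  truth$category_total <- as.integer(totals[truth$category])
  class(truth) <- c("count_table", "data.frame")
  list(events = events, truth = truth, path = path)
}
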