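#' @title Console event detection by ROI template matching
#'
#' @description
#' The console overlays indicate every discrete event — a pedal press, a
#' clutch engage, a third-arm swap, camera movement — by lighting a panel
#' or screen-edge lines. Detection scans every frame, crops each
#' indicator's region of interest, and scores it against the indicator's
#' active-state (and optional hover-state) template with the normalized
#' correlation coefficient. A frame is `active` when the active-template
#' score reaches the indicator's threshold; `hover` when only the hover
#' template matches. One *event* is a maximal run of active frames (a
#' rising edge of the active state): the method counts presses, not lit
#' frames. Hover frames are recorded for audit but never counted.
#' @name event_detection
NULL

#' Normalized correlation coefficient between two images
#'
#' Pearson correlation over all pixels (all channels pooled), in `[-1, 1]`;
#' a pixel-identical pair scores exactly 1. Degenerate zero-variance inputs
#' score 1 when pixel-identical and 0 otherwise, so a flat background never
#' spuriously matches a flat template unless it truly equals it.
#'
#' @param a,b numeric arrays of identical dimensions.
#' @return Score in `[-1, 1]`.
#' @export
ncc_score <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  av <- as.numeric(a); bv <- as.numeric(b)
  sa <- stats::sd(av); sb <- stats::sd(bv)
  if (sa == 0 || sb == 0) {
    return(if (isTRUE(all.equal(av, bv, tolerance = 1e-12))) 1 else 0)
  }
  stats::cor(av, bv)
}

crop_roi <- function(frame, roi) {
  d <- dim(frame)
  if (roi$x + roi$w > d[2L] || roi$y + roi$h > d[1L]) {
    stop("ROI (", roi$x, ",", roi$y, ",", roi$w, ",", roi$h,
         ") exceeds the ", d[2L], "x", d[1L], " frame", call. = FALSE)
  }
  frame[(roi$y + 1L):(roi$y + roi$h), (roi$x + 1L):(roi$x + roi$w), ,
        drop = FALSE]
}

#' Match one indicator in one frame
#'
#' @param frame `h x w x 3` array in `[0, 1]`.
#' @param spec an [indicator_spec()].
#' @param frame_index 0-based frame index recorded in the result.
#' @return A list (`match_result`) with `channel`, `frame_index`, `score`
#'   (active-template score), and `state` in `inactive`/`hover`/`active`.
#' @export
match_roi <- function(frame, spec, frame_index = 0L) {
  stopifnot(inherits(spec, "indicator_spec"))
  crop <- crop_roi(frame, spec$roi)
  score <- ncc_score(crop, spec$active_template)
  state <- if (score >= spec$threshold) {
    "active"
  } else if (!is.null(spec$hover_template) &&
             ncc_score(crop, spec$hover_template) >= spec$threshold) {
    "hover"
  } else {
    "inactive"
  }
  structure(list(channel = spec$channel, frame_index = as.integer(frame_index),
                 score = score, state = state),
            class = "match_result")
}

#' Scan every frame of a video against a profile
#'
#' @param video a `frame_video` whose resolution equals the profile's
#'   (checked via [validate_templates()]).
#' @param profile a `system_profile`.
#' @return A named list, one character vector per channel, each of length
#'   `n_frames(video)` with values `inactive`/`hover`/`active`. Determinstic
#'   for fixed input.
#' @export
scan_video <- function(video, profile) {
  stopifnot(inherits(video, "frame_video"), inherits(profile, "system_profile"))
  rep_ <- validate_templates(profile, c(video$width, video$height))
  if (any(rep_$status == "MISMATCH")) {
    stop("profile/video resolution mismatch: ",
         paste(unique(rep_$reason[rep_$status == "MISMATCH"]), collapse = "; "),
         call. = FALSE)
  }
  chans <- profile_channels(profile)
  nf <- n_frames(video)
  states <- lapply(chans, function(ch) character(nf))
  names(states) <- chans
  for (i in seq_len(nf)) {
    frame <- tryCatch(get_frame(video, i), error = function(e) {
      stop("scan failed at frame index ", i - 1L, ": ", conditionMessage(e),
           call. = FALSE)
    })
    for (ch in chans) {
      states[[ch]][i] <- match_roi(frame, profile$indicators[[ch]], i - 1L)$state
    }
  }
  states
}

#' Discretize a per-frame state sequence into counted events
#'
#' One event per maximal run of `active` frames, after (i) merging runs
#' separated by fewer than `min_gap_frames` non-active frames and
#' (ii) dropping merged runs shorter than `min_duration_frames`. The
#' defaults (both 1) perform no debouncing: raw maximal runs. `hover`
#' frames are non-active — they never extend or create an event.
#'
#' @param states character (or logical) vector of per-frame states;
#'   `"active"`/`TRUE` counts as active.
#' @param fps frames per second (> 0).
#' @param min_duration_frames drop merged events shorter than this many
#'   frames.
#' @param min_gap_frames merge events separated by gaps shorter than this
#'   many frames.
#' @return A data.frame with `start_frame`, `end_frame` (half-open,
#'   0-based), `start_s`, `duration_s`.
#' @examples
#' s <- c("inactive", "active", "active", "inactive", "active")
#' events_from_states(s, fps = 15)  # two events: [1,3) and [4,5)
#' @export
events_from_states <- function(states, fps, min_duration_frames = 1L,
                               min_gap_frames = 1L) {
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive", call. = FALSE)
  if (length(states) == 0L) stop("states must be nonempty", call. = FALSE)
  if (min_duration_frames < 1L || min_gap_frames < 1L) {
    stop("debounce parameters must be >= 1 frame", call. = FALSE)
  }
  act <- if (is.logical(states)) states else states == "active"
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based half-open [start, end)
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs whose separating gap is shorter than min_gap_frames
  if (nrow(runs) > 1L && min_gap_frames > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)]
      if (gap < min_gap_frames) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs <- runs[runs$end - runs$start >= min_duration_frames, , drop = FALSE]
  data.frame(start_frame = as.integer(runs$start),
             end_frame = as.integer(runs$end),
             start_s = runs$start / fps,
             duration_s = (runs$end - runs$start) / fps,
             row.names = NULL)
}

#' Detect and count console events in a video
#'
#' Composes [scan_video()] and [events_from_states()] over every channel of
#' the profile and tabulates per-channel totals. Deterministic: repeated
#' runs on the same input give identical logs.
#'
#' @inheritParams scan_video
#' @inheritParams events_from_states
#' @return An `event_log`: list with `video_id`, `fps`, `n_frames`,
#'   `events` (data.frame with a `channel` column) and `counts` (named
#'   integer vector over the profile's channels).
#' @export
detect_events <- function(video, profile, min_duration_frames = 1L,
                          min_gap_frames = 1L) {
  states <- scan_video(video, profile)
  fps <- video$fps
  per_chan <- lapply(names(states), function(ch) {
    ev <- events_from_states(states[[ch]], fps,
                             min_duration_frames = min_duration_frames,
                             min_gap_frames = min_gap_frames)
    if (nrow(ev)) cbind(channel = ch, ev, stringsAsFactors = FALSE) else NULL
  })
  events <- do.call(rbind, per_chan)
  if (is.null(events)) {
    events <- data.frame(channel = character(0), start_frame = integer(0),
                         end_frame = integer(0), start_s = numeric(0),
                         duration_s = numeric(0))
  }
  events <- events[order(events$start_frame, events$channel), , drop = FALSE]
  rownames(events) <- NULL
  counts <- vapply(names(states), function(ch) sum(events$channel == ch),
                   integer(1))
  event_log(video$video_id, fps, n_frames(video), events, counts)
}

#' Construct an event log
#'
#' @param video_id identifier of the source video.
#' @param fps frames per second.
#' @param n_frames total frames scanned.
#' @param events data.frame of event records (`channel`, `start_frame`,
#'   `end_frame`, `start_s`, `duration_s`).
#' @param counts named integer vector of per-channel totals; recomputed
#'   from `events` when omitted.
#' @return An `event_log` object.
#' @export
event_log <- function(video_id, fps, n_frames, events,
                      counts = NULL) {
  if (nrow(events) && any(events$end_frame > n_frames)) {
    stop("event beyond the last frame of the video", call. = FALSE)
  }
  if (is.null(counts)) {
    chans <- unique(events$channel)
    counts <- vapply(chans, function(ch) sum(events$channel == ch), integer(1))
  }
  structure(list(video_id = video_id, fps = fps, n_frames = as.integer(n_frames),
                 events = events, counts = counts),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log '%s'> %d frames @ %g fps, %d event(s)\n",
              x$video_id, x$n_frames, x$fps, nrow(x$events)))
  if (length(x$counts)) {
    cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an event log as CSV (+ optional JSON counts summary)
#'
#' Output is byte-reproducible: two runs on the same recording produce
#' identical files.
#'
#' @param log an `event_log`.
#' @param csv_path output CSV path (columns: video_id, channel,
#'   start_frame, end_frame, start_s, duration_s).
#' @param counts_json_path optional path for a JSON per-channel counts
#'   summary.
#' @return `csv_path`, invisibly.
#' @export
write_event_csv <- function(log, csv_path, counts_json_path = NULL) {
  stopifnot(inherits(log, "event_log"))
  df <- cbind(video_id = log$video_id, log$events, stringsAsFactors = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(counts_json_path)) {
    jsonlite::write_json(as.list(log$counts), counts_json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Map clutch counts between Si and Xi channel conventions
#'
#' The Si clutch is conjoined (one `CLUTCH` channel); the Xi clutches each
#' controller separately (`CLUTCH_L`, `CLUTCH_R`). To compare logs across
#' generations, Xi clutch counts are pooled into a single `CLUTCH` entry.
#'
#' @param counts named integer vector of per-channel counts.
#' @return Counts with any `CLUTCH_L`/`CLUTCH_R` entries summed into
#'   `CLUTCH`.
#' @export
pool_clutch_counts <- function(counts) {
  lr <- intersect(c("CLUTCH_L", "CLUTCH_R"), names(counts))
  if (!length(lr)) return(counts)
  pooled <- sum(counts[lr]) + if ("CLUTCH" %in% names(counts)) counts[["CLUTCH"]] else 0L
  counts <- counts[setdiff(names(counts), c(lr, "CLUTCH"))]
  c(counts, CLUTCH = as.integer(pooled))
}
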