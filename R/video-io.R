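#' @title Frame-sequence videos
#'
#' @description
#' `surgevents` represents video as an ordered sequence of RGB frames at a
#' fixed frame rate. Two storage backends share one S3 class, `frame_video`:
#' an in-memory list of arrays, and an on-disk frame-sequence directory
#' (`frame_000001.png`, `frame_000002.png`, ... plus a `meta.yaml`). The
#' on-disk form is the package's native interchange format: PNG frames are
#' lossless, so pixel-exact invariants (stereo crop reconstruction, overlay
#' checksums) hold end to end.
#'
#' Frames are `height x width x 3` numeric arrays with values in `[0, 1]`,
#' 0-based pixel coordinates, origin at the top-left corner.
#'
#' @param frames list of `height x width x 3` numeric arrays in `[0, 1]`.
#' @param fps frames per second (> 0).
#' @param video_id optional identifier carried into event logs.
#' @return A `frame_video` object.
#' @examples
#' f <- array(0.5, dim = c(4, 6, 3))
#' v <- frame_video(list(f, f), fps = 15)
#' n_frames(v)
#' @export
frame_video <- function(frames, fps, video_id = "video") {
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("fps must be a single positive number", call. = FALSE)
  }
  d <- dim(frames[[1L]])
  if (length(d) != 3L || d[3L] != 3L) {
    stop("frames must be height x width x 3 arrays", call. = FALSE)
  }
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d)) {
      stop("frame ", i, " has dimensions inconsistent with frame 1", call. = FALSE)
    }
  }
  structure(
    list(frames = frames, dir = NULL, fps = as.numeric(fps),
         width = d[2L], height = d[1L], n_frames = length(frames),
         video_id = video_id),
    class = "frame_video"
  )
}

#' @export
print.frame_video <- function(x, ...) {
  backend <- if (is.null(x$dir)) "in-memory" else paste0("on-disk (", x$dir, ")")
  cat(sprintf("<frame_video '%s'> %dx%d px, %d frames @ %g fps, %s\n",
              x$video_id, x$width, x$height, x$n_frames, x$fps, backend))
  invisible(x)
}

#' Number of frames in a video
#' @param video a `frame_video`.
#' @return Integer frame count.
#' @export
n_frames <- function(video) {
  stopifnot(inherits(video, "frame_video"))
  video$n_frames
}

#' Video metadata
#'
#' @param video a `frame_video`.
#' @return A list with `width`, `height`, `fps`, `n_frames`, `duration_s`.
#' @export
video_meta <- function(video) {
  stopifnot(inherits(video, "frame_video"))
  list(width = video$width, height = video$height, fps = video$fps,
       n_frames = video$n_frames, duration_s = video$n_frames / video$fps)
}

frame_file <- function(dir, i) file.path(dir, sprintf("frame_%06d.png", i))

# time -> frame mapping used everywhere: nearest integer, halves up,
# so frame counts are bit-reproducible and match the documented arithmetic
round_frame <- function(x) as.integer(floor(x + 0.5))

#' Fetch one frame of a video
#'
#' @param video a `frame_video`.
#' @param i 1-based frame number.
#' @return A `height x width x 3` array in `[0, 1]`.
#' @export
get_frame <- function(video, i) {
  stopifnot(inherits(video, "frame_video"))
  if (i < 1L || i > video$n_frames) {
    stop("frame index ", i, " out of range [1, ", video$n_frames, "]",
         call. = FALSE)
  }
  if (!is.null(video$frames)) return(video$frames[[i]])
  path <- frame_file(video$dir, i)
  if (!file.exists(path)) {
    stop("unreadable frame ", i, ": missing file ", path, call. = FALSE)
  }
  img <- png::readPNG(path)
  ensure_rgb(img)
}

# promote grayscale / drop alpha so every frame is H x W x 3
ensure_rgb <- function(img) {
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3L] == 4L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3L] == 2L) {
    img <- array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
  }
  img
}

#' Write a video to a frame-sequence directory
#'
#' Writes one PNG per frame plus a `meta.yaml` describing geometry and frame
#' rate. Writing is deterministic: identical videos produce byte-identical
#' directories.
#'
#' @param video a `frame_video`.
#' @param dir output directory (created if needed; must be empty of frames).
#' @return `dir`, invisibly.
#' @export
write_video <- function(video, dir) {
  stopifnot(inherits(video, "frame_video"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(video$n_frames)) {
    png::writePNG(get_frame(video, i), target = frame_file(dir, i))
  }
  meta <- list(width = video$width, height = video$height,
               fps = video$fps, n_frames = video$n_frames,
               video_id = video$video_id)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Open a frame-sequence directory as a video
#'
#' Frames stay on disk and are decoded lazily by [get_frame()].
#'
#' @param dir directory written by [write_video()].
#' @return A `frame_video` backed by `dir`.
#' @export
read_video <- function(dir) {
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(meta_path)) {
    stop("not a frame-sequence directory (no meta.yaml): ", dir, call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  n_png <- length(list.files(dir, pattern = "^frame_\\d{6}\\.png$"))
  if (n_png < meta$n_frames) {
    stop("truncated video: meta declares ", meta$n_frames, " frames but ",
         n_png, " are present in ", dir, call. = FALSE)
  }
  structure(
    list(frames = NULL, dir = dir, fps = as.numeric(meta$fps),
         width = as.integer(meta$width), height = as.integer(meta$height),
         n_frames = as.integer(meta$n_frames),
         video_id = if (is.null(meta$video_id)) basename(dir) else meta$video_id),
    class = "frame_video"
  )
}

#' Materialize a video in memory
#'
#' @param video a `frame_video`.
#' @return An in-memory `frame_video` with identical pixels.
#' @export
collect_frames <- function(video) {
  frames <- lapply(seq_len(n_frames(video)), function(i) get_frame(video, i))
  frame_video(frames, fps = video$fps, video_id = video$video_id)
}

#' Crop one eye out of a side-by-side stereo recording
#'
#' Console recordings carry the left and right ocular feeds side by side in
#' one frame (e.g. 2560x720); downstream analysis uses a single-eye view
#' (e.g. 1280x720). The left view is columns `[0, w/2)`, the right view
#' `[w/2, w)`; height and frame rate are unchanged.
#'
#' @param video a `frame_video` with even frame width.
#' @param side `"left"` or `"right"`.
#' @param out optional frame-sequence directory to write the result to.
#' @return The cropped `frame_video` (in memory; also written to `out` when
#'   given).
#' @export
crop_stereo <- function(video, side = c("left", "right"), out = NULL) {
  side <- match.arg(side)
  stopifnot(inherits(video, "frame_video"))
  w <- video$width
  if (w %% 2L != 0L) {
    stop("stereo crop requires an even frame width, got ", w, call. = FALSE)
  }
  half <- w %/% 2L
  cols <- if (side == "left") seq_len(half) else (half + 1L):w
  frames <- lapply(seq_len(video$n_frames), function(i) {
    get_frame(video, i)[, cols, , drop = FALSE]
  })
  res <- frame_video(frames, fps = video$fps,
                     video_id = paste0(video$video_id, "_", side))
  if (!is.null(out)) write_video(res, out)
  res
}

#' Keep only selected time intervals of a video
#'
#' Sequences without surgical relevance (instrument changes, instruction
#' breaks) are cut out by listing the intervals to keep. Intervals are
#' half-open `[start_s, end_s)` seconds, mapped to frames by rounding
#' `time * fps`.
#'
#' @param video a `frame_video`.
#' @param keep two-column matrix or data.frame of `start_s`, `end_s`
#'   (sorted, non-overlapping, within duration).
#' @param out optional frame-sequence output directory.
#' @return The concatenated `frame_video` of kept frames.
#' @export
cut_segments <- function(video, keep, out = NULL) {
  stopifnot(inherits(video, "frame_video"))
  keep <- as.matrix(as.data.frame(keep))
  if (nrow(keep) == 0L) {
    stop("empty keep list: refusing to emit an empty video", call. = FALSE)
  }
  if (any(keep[, 2L] <= keep[, 1L])) {
    stop("keep intervals must satisfy end_s > start_s", call. = FALSE)
  }
  o <- order(keep[, 1L])
  keep <- keep[o, , drop = FALSE]
  if (nrow(keep) > 1L &&
      any(keep[-1L, 1L] < keep[-nrow(keep), 2L])) {
    stop("keep intervals overlap", call. = FALSE)
  }
  dur <- video$n_frames / video$fps
  if (any(keep[, 2L] > dur + 1e-9)) {
    stop("keep interval beyond video duration (", signif(dur, 6), " s)",
         call. = FALSE)
  }
  idx <- unlist(lapply(seq_len(nrow(keep)), function(r) {
    a <- round_frame(keep[r, 1L] * video$fps)
    b <- round_frame(keep[r, 2L] * video$fps)
    if (b > a) seq.int(a + 1L, b) else integer(0)  # 1-based frame numbers
  }))
  frames <- lapply(idx, function(i) get_frame(video, i))
  res <- frame_video(frames, fps = video$fps,
                     video_id = paste0(video$video_id, "_cut"))
  if (!is.null(out)) write_video(res, out)
  res
}

#' Temporal offset between two streams from a shared marker event
#'
#' Two independently started recordings (console feed and the overhead
#' motion camera) are aligned with a marker visible in both — a clap or
#' clapperboard. Given the marker's frame index in each stream, the offset
#' is the difference of the two marker times:
#' `offset_s = frame_a / fps_a - frame_b / fps_b`; positive means stream A's
#' marker occurs later on its own clock.
#'
#' @param marker_frame_a,marker_frame_b 0-based marker frame index in each
#'   stream.
#' @param fps_a,fps_b frame rates (> 0).
#' @return A `sync_offset` list with `offset_s`.
#' @examples
#' find_offset(45, 15, 30, 15)$offset_s  # +1 s
#' @export
find_offset <- function(marker_frame_a, fps_a, marker_frame_b, fps_b) {
  if (marker_frame_a < 0 || marker_frame_b < 0) {
    stop("marker frame indices must be non-negative", call. = FALSE)
  }
  if (fps_a <= 0 || fps_b <= 0) stop("fps must be positive", call. = FALSE)
  structure(list(offset_s = marker_frame_a / fps_a - marker_frame_b / fps_b),
            class = "sync_offset")
}

#' Shift record timestamps onto a shared clock
#'
#' Applies a [find_offset()] result to timestamped records (numeric seconds,
#' or a data.frame whose time columns are named in `time_cols`): every time
#' is shifted by `-offset_s`. Times that would become negative are clamped
#' to 0 and flagged.
#'
#' @param x numeric vector of seconds, or a data.frame.
#' @param offset a `sync_offset` (or a single number of seconds).
#' @param time_cols for data.frames, the columns holding seconds.
#' @return Same shape as `x`; data.frames gain a logical `clamped` column.
#' @export
apply_offset <- function(x, offset, time_cols = intersect(
                           c("time_s", "start_s", "stop_s"), names(x))) {
  off <- if (inherits(offset, "sync_offset")) offset$offset_s else as.numeric(offset)
  shift <- function(t) {
    s <- t - off
    neg <- s < 0
    if (any(neg)) {
      warning(sum(neg), " timestamp(s) clamped to 0 after offset", call. = FALSE)
      s[neg] <- 0
    }
    attr(s, "clamped") <- neg
    s
  }
  if (is.numeric(x)) return(shift(x))
  stopifnot(is.data.frame(x), length(time_cols) > 0L)
  clamped <- rep(FALSE, nrow(x))
  for (col in time_cols) {
    s <- shift(x[[col]])
    clamped <- clamped | attr(s, "clamped")
    attributes(s) <- NULL
    x[[col]] <- s
  }
  x$clamped <- clamped
  x
}
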