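#' @title System profiles: indicator geometry and detection configuration
#'
#' @description
#' The two da Vinci generations in common use (Si and Xi) place their
#' on-screen indicator panels differently and differ in semantics: the Si
#' console only allows conjoined clutching (one clutch indicator), while the
#' Xi clutches each hand controller separately (left and right clutch
#' panels). A `system_profile` is the calibration artifact that captures
#' this: per-channel regions of interest (ROIs), the template image each
#' indicator shows when active (and optionally when the foot hovers above
#' the pedal), and the match-score threshold at which the indicator counts
#' as lit.
#'
#' Coordinates are 0-based with the origin at the top-left corner; an ROI
#' `(x, y, w, h)` covers the half-open extent `[x, x+w) x [y, y+h)`.
#' @name profiles
NULL

#' Known event channels
#'
#' Console event channels: cut and coagulation pedals per side, clutch
#' (conjoined on Si; per-side on Xi), third-arm swap, and camera movement.
#' @return Character vector of channel ids.
#' @export
event_channels <- function() {
  c("CUT_L", "CUT_R", "COAG_L", "COAG_R",
    "CLUTCH", "CLUTCH_L", "CLUTCH_R", "THIRD_ARM_SWAP", "CAMERA")
}

#' Side of a channel
#' @param channel channel id(s).
#' @return `"left"`, `"right"` or `"none"` per channel.
#' @export
channel_side <- function(channel) {
  side <- c(CUT_L = "left", CUT_R = "right", COAG_L = "left",
            COAG_R = "right", CLUTCH = "none", CLUTCH_L = "left",
            CLUTCH_R = "right", THIRD_ARM_SWAP = "none", CAMERA = "none")
  unname(side[channel])
}

#' Default match-score thresholds per channel
#'
#' Normalized-correlation thresholds that discriminate a lit indicator from
#' background: 0.95 for the coagulation and clutch indicators, 0.90 for
#' camera movement and third-arm swap. The cut pedals inherit 0.95 — they
#' are pedal indicators of the same family as coagulation.
#'
#' @param channel channel id(s).
#' @return Numeric threshold(s) in (0, 1].
#' @export
default_threshold <- function(channel) {
  thr <- c(CUT_L = 0.95, CUT_R = 0.95, COAG_L = 0.95, COAG_R = 0.95,
           CLUTCH = 0.95, CLUTCH_L = 0.95, CLUTCH_R = 0.95,
           THIRD_ARM_SWAP = 0.90, CAMERA = 0.90)
  unname(thr[channel])
}

#' ROI rectangle
#'
#' @param x,y 0-based pixel offset of the top-left corner.
#' @param w,h extent in pixels (> 0); the ROI covers `[x, x+w) x [y, y+h)`.
#' @return An `roi_spec` list.
#' @export
roi_spec <- function(x, y, w, h) {
  x <- as.integer(x); y <- as.integer(y); w <- as.integer(w); h <- as.integer(h)
  if (is.na(x) || is.na(y) || x < 0L || y < 0L) {
    stop("ROI offsets must be >= 0", call. = FALSE)
  }
  if (is.na(w) || is.na(h) || w <= 0L || h <= 0L) {
    stop("ROI extent must be positive", call. = FALSE)
  }
  structure(list(x = x, y = y, w = w, h = h), class = "roi_spec")
}

#' Indicator detection specification
#'
#' @param channel one of [event_channels()].
#' @param roi an [roi_spec()].
#' @param active_template `h x w x 3` array in `[0,1]`: the indicator's
#'   pressed/active appearance; dimensions must equal the ROI's.
#' @param hover_template optional template for the foot-hover state (green
#'   readiness lines); same geometry. Hover is audited, never counted.
#' @param threshold match score in (0, 1] at which the state is declared;
#'   defaults per [default_threshold()].
#' @return An `indicator_spec` list.
#' @export
indicator_spec <- function(channel, roi, active_template,
                           hover_template = NULL,
                           threshold = default_threshold(channel)) {
  channel <- match.arg(channel, event_channels())
  stopifnot(inherits(roi, "roi_spec"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold for ", channel, " must lie in (0, 1]", call. = FALSE)
  }
  check_tmpl <- function(tmpl, what) {
    d <- dim(tmpl)
    if (length(d) != 3L || d[3L] != 3L) {
      stop(what, " for ", channel, " must be h x w x 3", call. = FALSE)
    }
    if (d[1L] != roi$h || d[2L] != roi$w) {
      stop(what, " for ", channel, " is ", d[2L], "x", d[1L],
           " but the ROI is ", roi$w, "x", roi$h, call. = FALSE)
    }
  }
  check_tmpl(active_template, "active_template")
  if (!is.null(hover_template)) check_tmpl(hover_template, "hover_template")
  structure(list(channel = channel, roi = roi,
                 active_template = active_template,
                 hover_template = hover_template,
                 threshold = as.numeric(threshold)),
            class = "indicator_spec")
}

generation_channels <- function(generation) {
  base <- c("CUT_L", "CUT_R", "COAG_L", "COAG_R", "THIRD_ARM_SWAP", "CAMERA")
  switch(generation,
         SI = c(base, "CLUTCH"),
         XI = c(base, "CLUTCH_L", "CLUTCH_R"))
}

#' System profile for one robot generation
#'
#' Validates all invariants: one indicator per channel at most, every ROI
#' inside the frame, template geometry matching each ROI, and a
#' generation-consistent channel set (Si exposes `CLUTCH` only; Xi exposes
#' `CLUTCH_L`/`CLUTCH_R`, never plain `CLUTCH`).
#'
#' @param generation `"SI"` or `"XI"`.
#' @param frame_width,frame_height frame resolution the profile is
#'   calibrated for, in pixels.
#' @param indicators list of [indicator_spec()]s.
#' @param fps_default nominal frame rate of recordings for this system.
#' @return A `system_profile` object.
#' @export
system_profile <- function(generation = c("XI", "SI"), frame_width,
                           frame_height, indicators, fps_default = 15) {
  generation <- match.arg(toupper(generation), c("XI", "SI"))
  frame_width <- as.integer(frame_width); frame_height <- as.integer(frame_height)
  stopifnot(frame_width > 0L, frame_height > 0L, is.list(indicators))
  allowed <- generation_channels(generation)
  chans <- vapply(indicators, function(s) s$channel, character(1))
  if (anyDuplicated(chans)) {
    stop("duplicate channel in profile: ",
         paste(unique(chans[duplicated(chans)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(chans, allowed)
  if (length(bad)) {
    stop("channel(s) ", paste(bad, collapse = ", "),
         " are not valid for a ", generation, " profile", call. = FALSE)
  }
  for (s in indicators) {
    stopifnot(inherits(s, "indicator_spec"))
    r <- s$roi
    if (r$x + r$w > frame_width || r$y + r$h > frame_height) {
      stop("ROI for ", s$channel, " (", r$x, ",", r$y, ",", r$w, ",", r$h,
           ") exceeds the ", frame_width, "x", frame_height, " frame",
           call. = FALSE)
    }
  }
  names(indicators) <- chans
  structure(list(generation = generation, frame_width = frame_width,
                 frame_height = frame_height, indicators = indicators,
                 fps_default = as.numeric(fps_default)),
            class = "system_profile")
}

#' @export
print.system_profile <- function(x, ...) {
  cat(sprintf("<system_profile %s> %dx%d px @ %g fps, %d indicator(s): %s\n",
              x$generation, x$frame_width, x$frame_height, x$fps_default,
              length(x$indicators), paste(names(x$indicators), collapse = ", ")))
  invisible(x)
}

#' Channels a profile detects
#' @param profile a `system_profile`.
#' @return Character vector of channel ids.
#' @export
profile_channels <- function(profile) {
  stopifnot(inherits(profile, "system_profile"))
  names(profile$indicators)
}

#' Load a system profile from YAML + PNG templates
#'
#' The YAML file declares generation, frame geometry, default fps, and one
#' entry per indicator (channel, roi, template file names, threshold);
#' template images are PNG files resolved relative to the YAML's directory.
#'
#' @param config_path path to the profile YAML.
#' @return A validated `system_profile`.
#' @seealso [save_profile()] for the inverse; the pair round-trips.
#' @export
load_profile <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("profile config not found: ", config_path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(config_path)
  read_tmpl <- function(fname, channel) {
    path <- file.path(base, fname)
    if (!file.exists(path)) {
      stop("template image for channel ", channel, " not found: ", path,
           call. = FALSE)
    }
    ensure_rgb(png::readPNG(path))
  }
  indicators <- lapply(cfg$indicators, function(ind) {
    roi <- roi_spec(ind$roi$x, ind$roi$y, ind$roi$w, ind$roi$h)
    hover <- if (!is.null(ind$hover_template)) {
      read_tmpl(ind$hover_template, ind$channel)
    }
    thr <- if (!is.null(ind$threshold)) ind$threshold else
      default_threshold(ind$channel)
    indicator_spec(ind$channel, roi,
                   active_template = read_tmpl(ind$active_template, ind$channel),
                   hover_template = hover, threshold = thr)
  })
  system_profile(cfg$generation, cfg$frame_width, cfg$frame_height,
                 indicators, fps_default = cfg$fps_default)
}

#' Save a system profile as YAML + PNG templates
#'
#' @param profile a `system_profile`.
#' @param config_path output YAML path; templates are written as
#'   `<channel>_active.png` / `<channel>_hover.png` next to it.
#' @return `config_path`, invisibly.
#' @export
save_profile <- function(profile, config_path) {
  stopifnot(inherits(profile, "system_profile"))
  base <- dirname(config_path)
  dir.create(base, recursive = TRUE, showWarnings = FALSE)
  inds <- lapply(profile$indicators, function(s) {
    act <- paste0(tolower(s$channel), "_active.png")
    png::writePNG(s$active_template, file.path(base, act))
    entry <- list(channel = s$channel,
                  roi = list(x = s$roi$x, y = s$roi$y, w = s$roi$w, h = s$roi$h),
                  active_template = act, threshold = s$threshold)
    if (!is.null(s$hover_template)) {
      hov <- paste0(tolower(s$channel), "_hover.png")
      png::writePNG(s$hover_template, file.path(base, hov))
      entry$hover_template <- hov
    }
    entry
  })
  cfg <- list(generation = profile$generation,
              frame_width = profile$frame_width,
              frame_height = profile$frame_height,
              fps_default = profile$fps_default,
              indicators = unname(inds))
  yaml::write_yaml(cfg, config_path)
  invisible(config_path)
}

#' Check profile geometry against a video's resolution
#'
#' Template matching only works when the target patterns share the video's
#' resolution; against a differently sized recording the matcher simply
#' never fires, silently reporting zero events. This check makes that
#' failure loud: each indicator is reported `OK` when the profile's frame
#' geometry equals the video's (and its ROI fits), `MISMATCH` otherwise.
#' Callers must treat any `MISMATCH` as fatal before detection.
#'
#' @param profile a `system_profile`.
#' @param video_resolution integer `c(width, height)` of the video.
#' @return A data.frame with columns `channel`, `status`, `reason`.
#' @export
validate_templates <- function(profile, video_resolution) {
  stopifnot(inherits(profile, "system_profile"), length(video_resolution) == 2L)
  vw <- as.integer(video_resolution[[1L]])
  vh <- as.integer(video_resolution[[2L]])
  if (length(profile$indicators) == 0L) {
    return(data.frame(channel = character(0), status = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(profile$indicators, function(s) {
    r <- s$roi
    if (profile$frame_width != vw || profile$frame_height != vh) {
      status <- "MISMATCH"
      reason <- sprintf("profile calibrated for %dx%d, video is %dx%d",
                        profile$frame_width, profile$frame_height, vw, vh)
    } else if (r$x + r$w > vw || r$y + r$h > vh) {
      status <- "MISMATCH"
      reason <- "ROI outside video frame"
    } else {
      status <- "OK"; reason <- ""
    }
    data.frame(channel = s$channel, status = status, reason = reason,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}
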