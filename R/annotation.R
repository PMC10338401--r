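#' @title Temporal annotation: behavioral-observation TSV labels
#'
#' @description
#' Temporal labels mark when a surgical behavior starts and stops in a
#' recording. Annotation software in the behavioral-observation tradition
#' (BORIS and kin) exports tab-separated files where each row is a point
#' event with a time (decimal seconds), a behavior name, and a status of
#' `START` or `STOP`; an interval is a START paired with the next STOP of
#' the same behavior. Behaviors live in a two-level schema: categories
#' (suturing, dissection, other) with named subcategories. The module
#' parses the TSV dialect, pairs events into intervals, extracts the
#' annotated video sequences as clips, and aggregates label counts per
#' subcategory and category.
#' @name annotation
NULL

#' Default annotation schema
#'
#' The three basic elements of surgery with their subcategories: suturing
#' (4 subcategories), dissection (3), and other (8, covering suction,
#' camera handling, instrument changes and similar supporting actions).
#'
#' @return A `label_schema`: named list category -> character vector of
#'   subcategory names.
#' @export
default_label_schema <- function() {
  label_schema(list(
    suturing = c("Suture puncture", "Suture handling", "Suture, single",
                 "Suture, running"),
    dissection = c("Dissection, ordinary", "Dissection, clips",
                   "Dissection hemostasis"),
    other = c("Suction", "Camera handling", "Changing instrument", "Cleaning",
              "Holding with 4. Arm", "Holding with other instruments",
              "External instrument (non-robot)", "Catheter placement")
  ))
}

#' Construct a label schema
#'
#' @param categories named list: category name -> character vector of
#'   subcategory names. Subcategory names must be unique across the whole
#'   schema.
#' @return A `label_schema`.
#' @export
label_schema <- function(categories) {
  stopifnot(is.list(categories), !is.null(names(categories)))
  subs <- unlist(categories, use.names = FALSE)
  if (anyDuplicated(subs)) {
    stop("subcategory names must be unique across the schema: ",
         paste(unique(subs[duplicated(subs)]), collapse = ", "), call. = FALSE)
  }
  structure(categories, class = "label_schema")
}

#' Load / save a schema as YAML
#' @param path YAML file path.
#' @return `load_schema`: a `label_schema`. `save_schema`: `path`,
#'   invisibly.
#' @export
load_schema <- function(path) {
  label_schema(yaml::read_yaml(path))
}

#' @rdname load_schema
#' @param schema a `label_schema`.
#' @export
save_schema <- function(schema, path) {
  yaml::write_yaml(lapply(unclass(schema), as.list), path)
  invisible(path)
}

schema_lookup <- function(schema) {
  cats <- rep(names(schema), lengths(schema))
  names(cats) <- unlist(schema, use.names = FALSE)
  cats
}

#' Parse a label TSV file
#'
#' Requires a header with at least Time, Behavior and Status columns
#' (matched case-insensitively; the exporter's extra columns are ignored).
#' Time is decimal seconds; Status is START or STOP (any case). Events are
#' returned sorted by time, ties kept in file order.
#'
#' @param tsv_path path to the tab-separated label file.
#' @param schema a `label_schema` for behavior validation.
#' @param enforce_schema when `TRUE` (default), a behavior absent from the
#'   schema is a parse error naming it.
#' @return A data.frame of label events: `time_s`, `behavior`, `status`.
#' @export
parse_labels <- function(tsv_path, schema = default_label_schema(),
                         enforce_schema = TRUE) {
  if (!file.exists(tsv_path)) stop("label file not found: ", tsv_path,
                                   call. = FALSE)
  raw <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  lc <- tolower(names(raw))
  pick <- function(nm) {
    i <- match(nm, lc)
    if (is.na(i)) stop("label file ", basename(tsv_path),
                       " is missing required column '", nm, "'", call. = FALSE)
    raw[[i]]
  }
  time_raw <- pick("time")
  time_s <- suppressWarnings(as.numeric(time_raw))
  if (anyNA(time_s)) {
    bad <- which(is.na(time_s))[1L]
    stop("unparseable time '", time_raw[bad], "' at line ", bad + 1L,
         " of ", basename(tsv_path), call. = FALSE)
  }
  if (any(time_s < 0)) stop("negative time in ", basename(tsv_path),
                            call. = FALSE)
  behavior <- as.character(pick("behavior"))
  status <- toupper(as.character(pick("status")))
  if (!all(status %in% c("START", "STOP"))) {
    stop("status values must be START or STOP in ", basename(tsv_path),
         call. = FALSE)
  }
  if (enforce_schema) {
    known <- unlist(schema, use.names = FALSE)
    unknown <- setdiff(unique(behavior), known)
    if (length(unknown)) {
      stop("behavior(s) not in schema: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  df <- data.frame(time_s = time_s, behavior = behavior, status = status,
                   stringsAsFactors = FALSE)
  df[order(df$time_s), , drop = FALSE] -> df  # stable: ties keep file order
  rownames(df) <- NULL
  df
}

#' Serialize label events back to TSV
#'
#' Inverse of [parse_labels()]: `parse_labels(serialize_labels(x))`
#' reproduces the event list.
#'
#' @param events data.frame of label events.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
serialize_labels <- function(events, path) {
  out <- data.frame(Time = events$time_s, Behavior = events$behavior,
                    Status = events$status, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair START/STOP events into intervals
#'
#' Each START opens the behavior; each STOP closes the most recently
#' opened START of the same behavior (a per-behavior stack, so identical
#' behaviors may nest). Intervals of different behaviors freely interleave.
#' With `strict = TRUE`, nesting of the same behavior is rejected.
#'
#' @param events data.frame of label events sorted by time (as from
#'   [parse_labels()]).
#' @param strict reject same-behavior nesting.
#' @return A data.frame of intervals: `behavior`, `start_s`, `stop_s`,
#'   `duration_s`, sorted by `start_s`.
#' @export
build_intervals <- function(events, strict = FALSE) {
  stopifnot(is.data.frame(events))
  open <- list()  # behavior -> numeric stack of start times
  out <- list()
  for (i in seq_len(nrow(events))) {
    b <- events$behavior[i]; t <- events$time_s[i]
    if (events$status[i] == "START") {
      if (strict && length(open[[b]])) {
        stop("nested START for behavior '", b, "' at ", t,
             " s (strict pairing)", call. = FALSE)
      }
      open[[b]] <- c(open[[b]], t)
    } else {
      stack <- open[[b]]
      if (!length(stack)) {
        stop("STOP with no open START for behavior '", b, "' at ", t, " s",
             call. = FALSE)
      }
      start <- stack[length(stack)]
      open[[b]] <- stack[-length(stack)]
      if (t <= start) {
        stop("non-positive duration for behavior '", b, "' at ", t, " s",
             call. = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(behavior = b, start_s = start,
                                            stop_s = t,
                                            stringsAsFactors = FALSE)
    }
  }
  dangling <- names(open)[lengths(open) > 0L]
  if (length(dangling)) {
    stop("open START without STOP at end of file for behavior(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  if (!length(out)) {
    return(data.frame(behavior = character(0), start_s = numeric(0),
                      stop_s = numeric(0), duration_s = numeric(0)))
  }
  res <- do.call(rbind, out)
  res$duration_s <- res$stop_s - res$start_s
  res <- res[order(res$start_s, res$stop_s, res$behavior), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract annotated intervals as video clips
#'
#' Each interval `[start_s, stop_s)` maps to the half-open frame range
#' `[round(start_s * fps), round(stop_s * fps))`, so clip frame counts are
#' bit-reproducible. Clips are written as frame-sequence directories named
#' `<video_id>_<behavior>_<start>s`.
#'
#' @param video a `frame_video`.
#' @param intervals data.frame from [build_intervals()].
#' @param out_dir output directory.
#' @return Character vector of clip directories, invisibly.
#' @export
extract_clips <- function(video, intervals, out_dir) {
  stopifnot(inherits(video, "frame_video"), is.data.frame(intervals))
  dur <- video$n_frames / video$fps
  if (nrow(intervals) && any(intervals$stop_s > dur + 1e-9)) {
    bad <- intervals[intervals$stop_s > dur + 1e-9, , drop = FALSE]
    stop("interval(s) beyond video duration (", signif(dur, 6), " s): ",
         paste(sprintf("%s [%g, %g)", bad$behavior, bad$start_s, bad$stop_s),
               collapse = "; "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_len(nrow(intervals))) {
    a <- round_frame(intervals$start_s[i] * video$fps)
    b <- round_frame(intervals$stop_s[i] * video$fps)
    frames <- lapply(seq.int(a + 1L, b), function(j) get_frame(video, j))
    slug <- gsub("[^A-Za-z0-9]+", "-", intervals$behavior[i])
    name <- sprintf("%s_%s_%gs", video$video_id, slug, intervals$start_s[i])
    clip <- frame_video(frames, fps = video$fps, video_id = name)
    path <- file.path(out_dir, name)
    write_video(clip, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Aggregate label counts over one or more files
#'
#' Counts paired START/STOP intervals per subcategory, summed across
#' files, and rolls them up into category totals. Each category total
#' always equals the sum of its subcategory counts.
#'
#' @param label_sets a single events data.frame, or a list of them (one
#'   per parsed file).
#' @param schema a `label_schema`.
#' @return A `count_table` data.frame: `category`, `subcategory`, `count`,
#'   `category_total`.
#' @export
aggregate_label_counts <- function(label_sets, schema = default_label_schema()) {
  if (is.data.frame(label_sets)) label_sets <- list(label_sets)
  subs <- unlist(schema, use.names = FALSE)
  counts <- stats::setNames(integer(length(subs)), subs)
  for (events in label_sets) {
    iv <- build_intervals(events)
    unknown <- setdiff(unique(iv$behavior), subs)
    if (length(unknown)) {
      stop("behavior(s) not in schema: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    tab <- table(iv$behavior)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  cat_of <- schema_lookup(schema)
  df <- data.frame(category = unname(cat_of[subs]), subcategory = subs,
                   count = as.integer(counts), stringsAsFactors = FALSE)
  totals <- tapply(df$count, df$category, sum)
  df$category_total <- as.integer(totals[df$category])
  class(df) <- c("count_table", "data.frame")
  df
}

#' Category totals of a count table
#' @param tab a `count_table`.
#' @return Named integer vector of per-category totals.
#' @export
category_totals <- function(tab) {
  stopifnot(inherits(tab, "count_table"))
  res <- tapply(tab$count, tab$category, sum)
  stats::setNames(as.integer(res), names(res))
}
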