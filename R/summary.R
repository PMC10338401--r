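#' @title Event-data summaries by procedure and experience group
#'
#' @description
#' Event data is tabulated as total usage and uses per minute, grouped by
#' procedure and by experience level. Experience follows the learning-curve
#' convention for robot-assisted surgery: a *novice* has performed fewer
#' than 100 procedures, an *experienced* surgeon 100 or more. Group cells
#' report mean and sample standard deviation; a single-session cell reports
#' its value with SD = NA.
#' @name event_summary
NULL

#' Classify experience from total prior case count
#'
#' Fewer than 100 prior robot-assisted procedures is `novice`; 100 or more
#' is `experienced` (the boundary value 100 is assigned to `experienced`).
#'
#' @param total_prior_cases non-negative integer(s).
#' @return Character vector of `"novice"` / `"experienced"`.
#' @export
classify_experience <- function(total_prior_cases) {
  if (any(is.na(total_prior_cases)) || any(total_prior_cases < 0)) {
    stop("total_prior_cases must be non-negative", call. = FALSE)
  }
  ifelse(total_prior_cases < 100, "novice", "experienced")
}

#' Event rate per minute
#'
#' @param count non-negative event count(s).
#' @param duration_s session duration(s) in seconds (> 0).
#' @return `count / (duration_s / 60)`.
#' @export
per_minute <- function(count, duration_s) {
  if (any(duration_s <= 0)) stop("duration_s must be positive", call. = FALSE)
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  count / (duration_s / 60)
}

# alias so build_event_table can take a `per_minute` flag without shadowing
surgevents_rate_fun <- per_minute

#' Mean and sample standard deviation of a group
#'
#' @param values nonempty numeric vector.
#' @return List with `mean`, `sd` (n-1 denominator; `NA` when n = 1) and
#'   `n`.
#' @export
group_stats <- function(values) {
  if (length(values) == 0L) stop("values must be nonempty", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Format seconds as an mm.ss string
#' @param seconds numeric seconds.
#' @return Character `"mm.ss"` (minutes may exceed 59).
#' @export
format_mmss <- function(seconds) {
  m <- floor(seconds / 60)
  s <- round(seconds - m * 60)
  carry <- s >= 60  # rounding can tip into the next minute
  m[carry] <- m[carry] + 1
  s[carry] <- 0
  sprintf("%02d.%02d", as.integer(m), as.integer(s))
}

#' Session metadata
#'
#' @param video_id recording identifier matching an event log.
#' @param procedure procedure name.
#' @param participant_id participant identifier.
#' @param total_prior_cases prior robot-assisted case count (drives the
#'   experience group via [classify_experience()]).
#' @param duration_s session duration in seconds.
#' @return A one-row data.frame with a derived `group` column.
#' @export
session_meta <- function(video_id, procedure, participant_id,
                         total_prior_cases, duration_s) {
  data.frame(video_id = video_id, procedure = procedure,
             participant_id = participant_id,
             total_prior_cases = as.integer(total_prior_cases),
             group = classify_experience(total_prior_cases),
             duration_s = as.numeric(duration_s),
             stringsAsFactors = FALSE)
}

#' Read session metadata from CSV
#' @param path CSV with columns `video_id`, `procedure`, `participant_id`,
#'   `total_prior_cases`, `duration_s`.
#' @return Metadata data.frame with derived `group`.
#' @export
read_session_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("video_id", "procedure", "participant_id", "total_prior_cases",
            "duration_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$group <- classify_experience(df$total_prior_cases)
  df
}

#' Summarize event logs by procedure and experience group
#'
#' One row per (procedure, group) present in the data, with per-channel
#' mean and sample SD of the per-session values — raw counts by default,
#' or rates per minute with `per_minute = TRUE` — plus session count and
#' mean duration (in seconds and as an mm.ss string). Session order never
#' affects the result.
#'
#' @param logs list of `event_log`s.
#' @param meta metadata data.frame (one row per `video_id`), as from
#'   [read_session_meta()] or [session_meta()].
#' @param per_minute summarize rates per minute instead of raw counts.
#' @return A data.frame with columns `procedure`, `group`, `n`,
#'   `duration_mean_s`, `duration_mean_mmss`, then `<channel>_mean` and
#'   `<channel>_sd` per channel.
#' @export
build_event_table <- function(logs, meta, per_minute = FALSE) {
  stopifnot(is.list(logs), is.data.frame(meta))
  ids <- vapply(logs, function(l) l$video_id, character(1))
  missing_meta <- setdiff(ids, meta$video_id)
  if (length(missing_meta)) {
    stop("no session metadata for video_id(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  as_rate <- isTRUE(per_minute)
  rate_fun <- surgevents_rate_fun
  channels <- sort(unique(unlist(lapply(logs, function(l) names(l$counts)))))
  per_session <- do.call(rbind, lapply(logs, function(l) {
    m <- meta[match(l$video_id, meta$video_id), , drop = FALSE]
    vals <- vapply(channels, function(ch) {
      cnt <- if (ch %in% names(l$counts)) as.numeric(l$counts[[ch]]) else 0
      if (as_rate) rate_fun(cnt, m$duration_s) else cnt
    }, numeric(1))
    cbind(m[, c("procedure", "group", "duration_s")],
          as.data.frame(as.list(vals)))
  }))
  # deterministic row order regardless of input order
  keys <- unique(per_session[, c("procedure", "group")])
  keys <- keys[order(keys$procedure, keys$group), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- per_session[per_session$procedure == keys$procedure[i] &
                         per_session$group == keys$group[i], , drop = FALSE]
    out <- data.frame(procedure = keys$procedure[i], group = keys$group[i],
                      n = nrow(sub),
                      duration_mean_s = mean(sub$duration_s),
                      duration_mean_mmss = format_mmss(mean(sub$duration_s)),
                      stringsAsFactors = FALSE)
    for (ch in channels) {
      st <- group_stats(sub[[make.names(ch)]])
      out[[paste0(ch, "_mean")]] <- st$mean
      out[[paste0(ch, "_sd")]] <- st$sd
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write / re-read a summary table as CSV
#'
#' The table survives its own serialization: `read_event_table(
#' write_event_table(tab, path))` is identical to `tab`.
#'
#' @param tab table from [build_event_table()].
#' @param path CSV path.
#' @return `write_event_table`: `path` invisibly; `read_event_table`: the
#'   table.
#' @export
write_event_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(duration_mean_mmss = "character"))
  df
}
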