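# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package: explicit frame loops
# and repeated-pass merging instead of run-length encoding.

# maximal active runs with gap merging and duration filtering, by frame walk
oracle_events <- function(states, min_duration = 1L, min_gap = 1L) {
  act <- if (is.logical(states)) states else states == "active"
  runs <- list()
  cur <- NA_integer_
  for (i in seq_along(act)) {
    if (act[i] && is.na(cur)) cur <- i - 1L
    if (!act[i] && !is.na(cur)) {
      runs[[length(runs) + 1L]] <- c(cur, i - 1L)
      cur <- NA_integer_
    }
  }
  if (!is.na(cur)) runs[[length(runs) + 1L]] <- c(cur, length(act))
  # merge until fixed point
  repeat {
    merged_any <- FALSE
    if (length(runs) >= 2L) {
      for (i in seq_len(length(runs) - 1L)) {
        if (runs[[i + 1L]][1L] - runs[[i]][2L] < min_gap) {
          runs[[i]] <- c(runs[[i]][1L], runs[[i + 1L]][2L])
          runs[[i + 1L]] <- NULL
          merged_any <- TRUE
          break
        }
      }
    }
    if (!merged_any) break
  }
  runs <- Filter(function(r) r[2L] - r[1L] >= min_duration, runs)
  if (!length(runs)) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  }
  data.frame(start_frame = vapply(runs, `[`, integer(1), 1L),
             end_frame = vapply(runs, `[`, integer(1), 2L))
}

# per-behavior START/STOP matcher: each STOP takes the latest unmatched
# prior START of its behavior
oracle_intervals <- function(events) {
  n <- nrow(events)
  used <- rep(FALSE, n)
  rows <- list()
  for (i in seq_len(n)) {
    if (events$status[i] != "STOP") next
    js <- which(events$status == "START" &
                  events$behavior == events$behavior[i] &
                  seq_len(n) < i & !used)
    stopifnot(length(js) > 0L)
    j <- js[length(js)]
    used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      behavior = events$behavior[i], start_s = events$time_s[j],
      stop_s = events$time_s[i], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$duration_s <- res$stop_s - res$start_s
  res <- res[order(res$start_s, res$stop_s, res$behavior), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# straight loop over segment norms
oracle_path_length <- function(xs, ys) {
  total <- 0
  for (i in seq_len(length(xs) - 1L)) {
    total <- total + sqrt((xs[i + 1L] - xs[i])^2 + (ys[i + 1L] - ys[i])^2)
  }
  total
}

# two-pass mean/SD
oracle_mean_sd <- function(v) {
  m <- sum(v) / length(v)
  ss <- sum((v - m)^2)
  list(mean = m, sd = sqrt(ss / (length(v) - 1L)))
}

# correlation from the raw definition, no stats::cor
oracle_corr <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}
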