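# fixtures built in code: tiny videos, event sequences, label sets

flat_video <- function(n = 5L, w = 32L, h = 18L, fps = 15, value = 0.5,
                       video_id = "flat") {
  f <- array(value, dim = c(h, w, 3L))
  frame_video(replicate(n, f, simplify = FALSE), fps = fps,
              video_id = video_id)
}

# deterministic textured video so pixel-exact checks are meaningful
textured_video <- function(n = 4L, w = 32L, h = 18L, fps = 15,
                           video_id = "textured") {
  frames <- lapply(seq_len(n), function(i) {
    x <- matrix(rep(0:(w - 1L), each = h), nrow = h)
    y <- matrix(rep(0:(h - 1L), times = w), nrow = h)
    arr <- array(0, dim = c(h, w, 3L))
    for (k in 1:3) arr[, , k] <- ((x * k + y + i) %% 7) / 7
    arr
  })
  frame_video(frames, fps = fps, video_id = video_id)
}

random_states <- function(n, p_active = 0.4) {
  ifelse(stats::runif(n) < p_active, "active", "inactive")
}

# well-formed random label event sequence (sorted by time)
random_label_events <- function(schema = default_label_schema(),
                                n_intervals = 10L, duration_s = 100) {
  subs <- unlist(schema, use.names = FALSE)
  rows <- lapply(seq_len(n_intervals), function(i) {
    b <- sample(subs, 1L)
    s <- stats::runif(1, 0, duration_s - 1)
    e <- s + stats::runif(1, 0.1, (duration_s - s))
    data.frame(time_s = c(s, e), behavior = b,
               status = c("START", "STOP"), stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

random_track <- function(n = 50L, w = 320, h = 180, dropout = 0) {
  obs <- data.frame(frame_index = 0:(n - 1L),
                    x = stats::runif(n, 0, w - 1),
                    y = stats::runif(n, 0, h - 1),
                    confidence = 1)
  obs$valid <- stats::runif(n) >= dropout
  obs$confidence[!obs$valid] <- 0
  hand_track("left", "wrist", obs, fps = 15)
}
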