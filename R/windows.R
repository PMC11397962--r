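#' Segment a recording into labeled sliding windows
#'
#' Windows of `window_ms` milliseconds advanced by `increment_ms` (defaults
#' 150 / 25 ms, i.e. L = 288 and S = 48 samples at 1920 Hz). The number of
#' windows is `floor((T - L)/S) + 1`. Each window takes the plurality label
#' of its samples; ties are broken toward the phase occurring later in the
#' window, so transition-spanning windows are attributed to the phase the
#' gait is progressing into (this also resolves the toe-off to heel-strike
#' wrap-around). A recording shorter than one window yields an empty
#' `window_set`, not an error. Windows never cross trial boundaries because
#' one recording is one trial.
#'
#' @param rec An [emg_recording()].
#' @param window_ms,increment_ms Window length and hop in milliseconds;
#'   sample counts are `round(ms * fs / 1000)`.
#' @return Object of class `window_set` with fields `windows` (array
#'   `n_windows x channels x L`), `labels`, `trial_ids`, `subject_id`,
#'   `fs`, `window_ms`, `increment_ms`.
#' @export
make_windows <- function(rec, window_ms = 150, increment_ms = 25) {
  stopifnot(inherits(rec, "emg_recording"))
  L <- as.integer(round(window_ms * rec$fs / 1000))
  S <- as.integer(round(increment_ms * rec$fs / 1000))
  if (L < 2 || S < 1) stop("window/increment too short for this sampling rate")
  T_len <- ncol(rec$samples)
  n_ch <- nrow(rec$samples)
  n_win <- if (T_len < L) 0L else as.integer((T_len - L) %/% S + 1L)
  W <- array(0, dim = c(n_win, n_ch, L))
  labels <- integer(n_win)
  if (n_win > 0) {
    starts <- (seq_len(n_win) - 1L) * S
    idx <- outer(starts, seq_len(L), "+")    # n_win x L sample indices
    for (c in seq_len(n_ch)) W[, c, ] <- matrix(rec$samples[c, idx], n_win, L)
    lab_mat <- matrix(rec$labels[idx], n_win, L)
    labels <- apply(lab_mat, 1, .plurality_label)
  }
  structure(list(windows = W, labels = as.integer(labels),
                 trial_ids = rep(rec$trial_id, n_win),
                 subject_id = rec$subject_id, fs = rec$fs,
                 window_ms = window_ms, increment_ms = increment_ms,
                 channel_names = rec$channel_names),
            class = "window_set")
}

# plurality with ties broken toward the label occurring later in the window
.plurality_label <- function(lab_row) {
  cnt <- table(lab_row)
  best <- as.integer(names(cnt)[cnt == max(cnt)])
  if (length(best) == 1L) return(best)
  last_pos <- vapply(best, function(l) max(which(lab_row == l)), integer(1))
  best[which.max(last_pos)]
}

#' Concatenate window sets from trials of one subject
#'
#' @param sets List of `window_set` objects sharing subject, fs and window
#'   geometry.
#' @return One combined `window_set`.
#' @export
bind_window_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  sets <- Filter(function(s) dim(s$windows)[1] > 0, sets)
  if (length(sets) == 0) stop("no non-empty window sets to bind")
  geom <- vapply(sets, function(s)
    paste(s$subject_id, s$fs, s$window_ms, s$increment_ms), character(1))
  if (length(unique(geom)) != 1)
    stop("window sets must share subject and window geometry")
  W <- do.call(abind3, lapply(sets, `[[`, "windows"))
  out <- sets[[1]]
  out$windows <- W
  out$labels <- unlist(lapply(sets, `[[`, "labels"), use.names = FALSE)
  out$trial_ids <- unlist(lapply(sets, `[[`, "trial_ids"), use.names = FALSE)
  out
}

# rbind for 3-d arrays along the first (window) margin
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    np <- dim(p)[1]
    if (np > 0) out[at + seq_len(np), , ] <- p
    at <- at + np
  }
  out
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %s: %d windows x %d channels x %d samples (%g/%g ms)\n",
              x$subject_id, d[1], d[2], d[3], x$window_ms, x$increment_ms))
  invisible(x)
}

#' Filter and window all trials of one subject
#'
#' Convenience pipeline: band-pass each recording, window it, and bind the
#' per-trial window sets.
#'
#' @param recs List of [emg_recording()]s from one subject.
#' @param low,high,order Band-pass parameters, see [bandpass_filter()].
#' @param window_ms,increment_ms See [make_windows()].
#' @return A combined `window_set`.
#' @export
preprocess_trials <- function(recs, low = 10, high = 400, order = 4,
                              window_ms = 150, increment_ms = 25) {
  bind_window_sets(lapply(recs, function(r)
    make_windows(bandpass_filter(r, low, high, order),
                 window_ms, increment_ms)))
}
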