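#' Scalar time-domain EMG features
#'
#' Single-channel, single-window features used throughout myoelectric
#' pattern recognition. `wl` is the waveform length
#' `sum(|x[i+1] - x[i]|)`; `rms` is `sqrt(mean(x^2))`; `mav` the mean
#' absolute value; `zc` counts sign crossings whose amplitude step exceeds
#' the deadband `threshold`; `ssc` counts slope-sign changes above the
#' threshold; `wamp` (Willison amplitude) counts consecutive-sample
#' differences above the threshold.
#'
#' @param x Numeric sample vector (one channel of one window).
#' @param threshold Non-negative deadband (default 0).
#' @return A non-negative scalar.
#' @examples
#' wl(c(0, 1, 0, 1))   # 3
#' rms(c(3, -4))       # sqrt(12.5)
#' @export
wl <- function(x) {
  if (length(x) < 2) stop("wl needs at least 2 samples")
  sum(abs(diff(x)))
}

#' @rdname wl
#' @export
rms <- function(x) {
  if (length(x) < 1) stop("rms needs a non-empty window")
  sqrt(mean(x^2))
}

#' @rdname wl
#' @export
mav <- function(x) {
  if (length(x) < 1) stop("mav needs a non-empty window")
  mean(abs(x))
}

#' @rdname wl
#' @export
zc <- function(x, threshold = 0) {
  if (length(x) < 2) stop("zc needs at least 2 samples")
  a <- x[-length(x)]; b <- x[-1]
  sum(a * b < 0 & abs(a - b) >= threshold)
}

#' @rdname wl
#' @export
ssc <- function(x, threshold = 0) {
  if (length(x) < 3) stop("ssc needs at least 3 samples")
  xm <- x[2:(length(x) - 1)]
  sum((xm - x[1:(length(x) - 2)]) * (xm - x[3:length(x)]) > threshold)
}

#' @rdname wl
#' @export
wamp <- function(x, threshold = 0) {
  if (length(x) < 2) stop("wamp needs at least 2 samples")
  sum(abs(diff(x)) >= threshold & abs(diff(x)) > 0)
}

# ---- vectorized per-channel helpers on a window_set ------------------------
# X: n_windows x L matrix of one channel

.chan_wl  <- function(X) rowSums(abs(X[, -1, drop = FALSE] -
                                     X[, -ncol(X), drop = FALSE]))
.chan_rms <- function(X) sqrt(rowMeans(X^2))
.chan_mav <- function(X) rowMeans(abs(X))
.chan_zc  <- function(X, thr = 0) {
  A <- X[, -ncol(X), drop = FALSE]; B <- X[, -1, drop = FALSE]
  rowSums(A * B < 0 & abs(A - B) >= thr)
}
.chan_ssc <- function(X, thr = 0) {
  L <- ncol(X)
  M <- X[, 2:(L - 1), drop = FALSE]
  rowSums((M - X[, 1:(L - 2), drop = FALSE]) *
          (M - X[, 3:L, drop = FALSE]) > thr)
}

.check_window_set <- function(win) {
  stopifnot(inherits(win, "window_set"))
  if (dim(win$windows)[1] == 0) stop("window set is empty")
  invisible(win)
}

#' Feature matrix container
#'
#' @param values `n_windows x D` numeric matrix with unique column names.
#' @param labels,trial_ids Per-window phase labels and trial provenance.
#' @param subject_id Subject identifier.
#' @param set_name Name of the feature set (e.g. `"phasor"`).
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, trial_ids, subject_id, set_name) {
  values <- as.matrix(values)
  if (anyDuplicated(colnames(values))) stop("feature names must be unique")
  if (nrow(values) != length(labels)) stop("row count must equal label count")
  if (any(!is.finite(values))) stop("feature matrix contains non-finite values")
  structure(list(values = values, labels = as.integer(labels),
                 trial_ids = trial_ids, subject_id = subject_id,
                 set_name = set_name),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s [%s]: %d windows x %d features, %d classes\n",
              x$subject_id, x$set_name, nrow(x$values), ncol(x$values),
              length(unique(x$labels))))
  invisible(x)
}

.fm_from_blocks <- function(win, blocks, set_name) {
  values <- do.call(cbind, blocks)
  feature_matrix(values, win$labels, win$trial_ids, win$subject_id, set_name)
}

#' Hudgins time-domain feature set (HTD)
#'
#' Per channel: MAV, ZC, SSC, WL (4 features/channel). The deadband
#' threshold for ZC/SSC defaults to 0 and is configurable.
#'
#' @param win A `window_set`.
#' @param threshold ZC/SSC deadband in signal units.
#' @return A [feature_matrix()] with `4 * n_channels` columns.
#' @export
htd_set <- function(win, threshold = 0) {
  .check_window_set(win)
  n_ch <- dim(win$windows)[2]
  blocks <- lapply(seq_len(n_ch), function(c) {
    X <- matrix(win$windows[, c, ], nrow = dim(win$windows)[1])
    v <- cbind(.chan_mav(X), .chan_zc(X, threshold),
               .chan_ssc(X, threshold), .chan_wl(X))
    colnames(v) <- paste0("HTD|ch", c - 1, "|", c("MAV", "ZC", "SSC", "WL"))
    v
  })
  .fm_from_blocks(win, blocks, "htd")
}

# time-domain power spectral descriptors of one channel (6 per channel),
# computed from the first three even spectral moments via time-domain
# derivatives; eps guards every log/div so silent channels stay finite
.chan_tdpsd <- function(X, eps = 1e-12) {
  L <- ncol(X)
  D1 <- X[, -1, drop = FALSE] - X[, -L, drop = FALSE]
  D2 <- D1[, -1, drop = FALSE] - D1[, -(L - 1), drop = FALSE]
  m0 <- sqrt(rowSums(X^2) + eps)^0.1 / 0.1
  m2 <- sqrt(rowSums(D1^2) + eps)^0.1 / 0.1
  m4 <- sqrt(rowSums(D2^2) + eps)^0.1 / 0.1
  sparsi <- m0 / sqrt(abs((m0 - m2) * (m0 - m4)) + eps)
  irf <- m2 / sqrt(m0 * m4 + eps)
  wlr <- rowSums(abs(D1)) / (rowSums(abs(D2)) + eps)
  v <- cbind(m0, m0 - m2, m0 - m4, sparsi, irf, wlr)
  log(abs(v) + eps)
}

#' Time-domain power spectral descriptors (TDPSD)
#'
#' Six descriptors per channel derived from the zeroth, second and fourth
#' spectral moments, estimated in the time domain from the signal and its
#' first and second differences: normalized `m0`, `m0 - m2`, `m0 - m4`,
#' sparseness, irregularity factor and waveform-length ratio, each passed
#' through `log(abs(.) + eps)`.
#'
#' @inheritParams htd_set
#' @param eps Guard added inside logs/divisions (default 1e-12).
#' @return A [feature_matrix()] with `6 * n_channels` columns.
#' @export
tdpsd_set <- function(win, eps = 1e-12) {
  .check_window_set(win)
  n_ch <- dim(win$windows)[2]
  nms <- c("M0", "M0M2", "M0M4", "SPARSE", "IRF", "WLR")
  blocks <- lapply(seq_len(n_ch), function(c) {
    X <- matrix(win$windows[, c, ], nrow = dim(win$windows)[1])
    v <- .chan_tdpsd(X, eps)
    colnames(v) <- paste0("TDPSD|ch", c - 1, "|", nms)
    v
  })
  .fm_from_blocks(win, blocks, "tdpsd")
}

# Burg AR coefficients; zeros for (near-)constant windows
.burg_coefs <- function(x, order) {
  if (stats::sd(x) < 1e-12) return(rep(0, order))
  fit <- try(stats::ar.burg(x, aic = FALSE, order.max = order,
                            demean = TRUE), silent = TRUE)
  if (inherits(fit, "try-error")) return(rep(0, order))
  co <- fit$ar
  if (length(co) < order) co <- c(co, rep(0, order - length(co)))
  co
}

#' Time-domain + autoregressive feature set (TDAR)
#'
#' HTD (MAV, ZC, SSC, WL) plus Burg autoregressive coefficients of order
#' `order` per channel, the usual companion set in myoelectric control.
#' The model order used upstream is unstated; 4 is the common default.
#'
#' @inheritParams htd_set
#' @param order AR model order (default 4).
#' @return A [feature_matrix()] with `(4 + order) * n_channels` columns.
#' @export
tdar_set <- function(win, order = 4, threshold = 0) {
  .check_window_set(win)
  htd <- htd_set(win, threshold)
  n_ch <- dim(win$windows)[2]
  n_win <- dim(win$windows)[1]
  blocks <- lapply(seq_len(n_ch), function(c) {
    X <- matrix(win$windows[, c, ], nrow = n_win)
    v <- t(apply(X, 1, .burg_coefs, order = order))
    colnames(v) <- paste0("TDAR|ch", c - 1, "|AR", seq_len(order))
    v
  })
  fm <- .fm_from_blocks(win, blocks, "tdar")
  feature_matrix(cbind(htd$values, fm$values), win$labels, win$trial_ids,
                 win$subject_id, "tdar")
}

#' Du feature set
#'
#' Integrated EMG, variance, Willison amplitude (threshold defaulting to
#' 0.05 of the window's channel RMS), zero crossings, slope-sign changes
#' and waveform length per channel.
#'
#' @inheritParams htd_set
#' @param wamp_frac Willison threshold as a fraction of per-window channel
#'   RMS (default 0.05).
#' @return A [feature_matrix()] with `6 * n_channels` columns.
#' @export
du_set <- function(win, wamp_frac = 0.05, threshold = 0) {
  .check_window_set(win)
  n_ch <- dim(win$windows)[2]
  n_win <- dim(win$windows)[1]
  L <- dim(win$windows)[3]
  blocks <- lapply(seq_len(n_ch), function(c) {
    X <- matrix(win$windows[, c, ], nrow = n_win)
    thr <- wamp_frac * .chan_rms(X)
    Dabs <- abs(X[, -1, drop = FALSE] - X[, -L, drop = FALSE])
    wampv <- rowSums(Dabs >= thr & Dabs > 0)
    v <- cbind(rowSums(abs(X)), apply(X, 1, stats::var), wampv,
               .chan_zc(X, threshold), .chan_ssc(X, threshold), .chan_wl(X))
    colnames(v) <- paste0("DU|ch", c - 1, "|",
                          c("IEMG", "VAR", "WAMP", "ZC", "SSC", "WL"))
    v
  })
  .fm_from_blocks(win, blocks, "du")
}

#' Write / read a feature matrix as delimited text
#'
#' CSV with one column per named feature plus `label` and `trial_id`
#' columns; the subject and set name travel in a comment-free side header
#' encoded in the file name by the caller or passed back at read time.
#'
#' @param fm A [feature_matrix()].
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$values, check.names = FALSE)
  df$label <- fm$labels
  df$trial_id <- fm$trial_ids
  df$subject_id <- fm$subject_id
  df$set_name <- fm$set_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("label", "trial_id", "subject_id", "set_name")
  feature_matrix(as.matrix(df[setdiff(names(df), meta)]),
                 df$label, df$trial_id, df$subject_id[1], df$set_name[1])
}
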