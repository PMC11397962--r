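#' Phasor channel layout
#'
#' Assigns channel `k` (0-based, in file column order) the complex-plane
#' angle `k * 2 * pi / N`, partitioning the unit circle among the `N`
#' electrodes, and enumerates the `N * (N - 1) / 2` unordered channel pairs
#' in lexicographic order `(k, l), k < l`. Real electrode geometry is the
#' caller's responsibility; radially placed electrodes map naturally onto
#' this layout.
#'
#' @param n_channels Number of channels `N >= 2`.
#' @return Object of class `phasor_layout` with `n_channels`, `angles`
#'   (length `N`), and `pairs` (`M x 2` integer matrix of 0-based ids).
#' @export
phasor_layout <- function(n_channels) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 2) stop("phasor layout needs at least 2 channels")
  angles <- (seq_len(n_channels) - 1L) * 2 * pi / n_channels
  pairs <- t(utils::combn(n_channels, 2)) - 1L   # 0-based, k < l, lexicographic
  structure(list(n_channels = n_channels, angles = angles, pairs = pairs,
                 pair_names = sprintf("(%d,%d)", pairs[, 1], pairs[, 2])),
            class = "phasor_layout")
}

#' Embed per-channel feature values on the unit circle
#'
#' Element `k` of the result is `f[k] * exp(1i * k * 2 * pi / N)`, so the
#' modulus of each element equals `|f[k]|` and the argument encodes the
#' channel position.
#'
#' @param f_values Numeric vector of length `N` (one feature value per
#'   channel).
#' @param layout A [phasor_layout()].
#' @return Complex vector of length `N`.
#' @export
phasor_embed <- function(f_values, layout) {
  stopifnot(inherits(layout, "phasor_layout"))
  if (length(f_values) != layout$n_channels)
    stop("f_values length must equal the layout channel count")
  f_values * exp(1i * layout$angles)
}

#' Pairwise phasor-difference moduli (Df)
#'
#' For every channel pair `(k, l)`, `k < l`, the modulus of the difference
#' of the embedded features, evaluated in closed trigonometric form:
#' `sqrt(f_k^2 + f_l^2 - 2 f_k f_l cos((k - l) 2 pi / N))`. This is the
#' spatial-synergy feature vector of dimension `N (N - 1) / 2`.
#'
#' @param f_values Numeric vector of length `N`, or an
#'   `n_windows x N` matrix of per-channel features.
#' @param layout A [phasor_layout()].
#' @return Numeric vector of length `M = N (N - 1)/2`, or an
#'   `n_windows x M` matrix; always non-negative.
#' @export
pairwise_moduli <- function(f_values, layout) {
  stopifnot(inherits(layout, "phasor_layout"))
  Fm <- if (is.matrix(f_values)) f_values else matrix(f_values, nrow = 1)
  if (ncol(Fm) != layout$n_channels)
    stop("feature dimension must equal the layout channel count")
  k <- layout$pairs[, 1] + 1L
  l <- layout$pairs[, 2] + 1L
  cosd <- cos((layout$pairs[, 1] - layout$pairs[, 2]) * 2 * pi /
                layout$n_channels)
  A <- Fm[, k, drop = FALSE]
  B <- Fm[, l, drop = FALSE]
  D <- sqrt(pmax(A^2 + B^2 -
                   2 * A * B * matrix(cosd, nrow(Fm), length(cosd),
                                      byrow = TRUE), 0))
  colnames(D) <- layout$pair_names
  if (is.matrix(f_values)) D else drop(D)
}

# per-window per-channel base feature matrix (n_windows x N)
.base_feature_matrix <- function(win, base = c("wl", "rms"), differentiate = FALSE) {
  base <- match.arg(base)
  n_win <- dim(win$windows)[1]
  n_ch <- dim(win$windows)[2]
  out <- matrix(0, n_win, n_ch)
  for (c in seq_len(n_ch)) {
    X <- matrix(win$windows[, c, ], nrow = n_win)
    if (differentiate)
      X <- X[, -1, drop = FALSE] - X[, -ncol(X), drop = FALSE]
    out[, c] <- if (base == "wl") .chan_wl(X) else .chan_rms(X)
  }
  out
}

#' Df over numerically differentiated signals (gradient Df)
#'
#' Replaces each window's channel signals by their first differences
#' (`x[i + 1] - x[i]` inside the window, length `L - 1`, no sampling-rate
#' scaling), computes the base feature per channel, then applies
#' [pairwise_moduli()].
#'
#' @param win A `window_set`.
#' @param base Base feature, `"wl"` or `"rms"`.
#' @return `n_windows x M` non-negative matrix.
#' @export
gradient_features <- function(win, base = c("wl", "rms")) {
  .check_window_set(win)
  layout <- phasor_layout(dim(win$windows)[2])
  pairwise_moduli(.base_feature_matrix(win, base, differentiate = TRUE), layout)
}

#' The f-PHASOR feature set
#'
#' For base feature `f` (WL or RMS): the column concatenation of
#' `log(Df + eps)` and `log((Df + eps) / (grad_Df + eps))`, where `Df` are
#' the pairwise phasor-difference moduli of the per-channel feature values
#' and `grad_Df` the same construction over the first-differenced signals.
#' Natural logarithm; `eps` bounds the output on silent channels. For
#' `N = 9` this yields 72 columns.
#'
#' @param win A `window_set`.
#' @param base `"wl"` or `"rms"`.
#' @param eps Log guard (default 1e-12).
#' @return A [feature_matrix()] with `N (N - 1)` columns named
#'   `WLPH|d(k,l)` / `WLPH|r(k,l)` (or `RMSPH|...`).
#' @export
fphasor_set <- function(win, base = c("wl", "rms"), eps = 1e-12) {
  .check_window_set(win)
  base <- match.arg(base)
  layout <- phasor_layout(dim(win$windows)[2])
  Df <- pairwise_moduli(.base_feature_matrix(win, base), layout)
  gDf <- pairwise_moduli(.base_feature_matrix(win, base, TRUE), layout)
  Df <- matrix(Df, nrow = dim(win$windows)[1])
  gDf <- matrix(gDf, nrow = dim(win$windows)[1])
  tag <- if (base == "wl") "WLPH" else "RMSPH"
  vals <- cbind(log(Df + eps), log((Df + eps) / (gDf + eps)))
  colnames(vals) <- c(paste0(tag, "|d", layout$pair_names),
                      paste0(tag, "|r", layout$pair_names))
  feature_matrix(vals, win$labels, win$trial_ids, win$subject_id,
                 paste0(base, "phasor"))
}

#' The combined PHASOR feature set
#'
#' Column concatenation of the WL-PHASOR and RMS-PHASOR sets
#' (`2 N (N - 1)` columns; 144 for `N = 9`).
#'
#' @inheritParams fphasor_set
#' @return A [feature_matrix()].
#' @export
phasor_combined_set <- function(win, eps = 1e-12) {
  a <- fphasor_set(win, "wl", eps)
  b <- fphasor_set(win, "rms", eps)
  feature_matrix(cbind(a$values, b$values), win$labels, win$trial_ids,
                 win$subject_id, "phasor")
}
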