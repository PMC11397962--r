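#' Build a random convolutional kernel bank
#'
#' A minimal comparator in the spirit of the random-convolutional-kernel
#' transforms, at the small 84-kernel size. `mode = "rocket"`: kernel
#' lengths drawn from \{7, 9, 11\}, mean-centered Gaussian weights, bias
#' from U(-1, 1), exponentially scaled dilation (capped so the effective
#' receptive field fits the window), random padding flag and a random
#' channel subset whose responses are summed. `mode = "minirocket"`:
#' the complete set of C(9,3) = 84 length-9 weight patterns with value 2
#' at three positions and -1 elsewhere (exactly where the canonical
#' 84-kernel figure comes from), dilations cycled over powers of two,
#' bias from U(-1, 1), alternating padding. Regeneration is deterministic
#' given `seed`.
#'
#' @param mode `"rocket"` or `"minirocket"`.
#' @param L Window length in samples; must be at least 11.
#' @param n_channels Number of channels.
#' @param n_kernels Bank size (default 84).
#' @param seed Integer seed.
#' @return Object of class `kernel_bank` (list of kernels plus metadata);
#'   serializable as its `(mode, L, n_channels, n_kernels, seed)` tuple.
#' @export
build_bank <- function(mode = c("rocket", "minirocket"), L, n_channels,
                       n_kernels = 84, seed = 1L) {
  mode <- match.arg(mode)
  if (L < 11) stop("window length too short for the kernel bank (need L >= 11)")
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed) %% 2147483647L)
  kernels <- vector("list", n_kernels)
  if (mode == "rocket") {
    for (i in seq_len(n_kernels)) {
      len <- sample(c(7L, 9L, 11L), 1)
      w <- stats::rnorm(len)
      w <- w - mean(w)
      max_exp <- log2((L - 1) / (len - 1))
      dil <- max(1L, as.integer(2^stats::runif(1, 0, max_exp)))
      n_sel <- max(1L, min(n_channels,
                           as.integer(2^stats::runif(1, 0, log2(n_channels + 1)))))
      kernels[[i]] <- list(weights = w, bias = stats::runif(1, -1, 1),
                           dilation = dil,
                           padding = stats::runif(1) < 0.5,
                           channels = sort(sample.int(n_channels, n_sel)))
    }
  } else {
    combos <- utils::combn(9L, 3L)          # 84 columns
    max_exp <- floor(log2((L - 1) / 8))
    dils <- 2L^(0:max(0, max_exp))
    for (i in seq_len(n_kernels)) {
      w <- rep(-1, 9)
      w[combos[, ((i - 1L) %% ncol(combos)) + 1L]] <- 2
      n_sel <- max(1L, min(n_channels, sample.int(min(n_channels, 4L), 1)))
      kernels[[i]] <- list(weights = w, bias = stats::runif(1, -1, 1),
                           dilation = dils[((i - 1L) %% length(dils)) + 1L],
                           padding = (i %% 2L) == 0L,
                           channels = sort(sample.int(n_channels, n_sel)))
    }
  }
  structure(list(mode = mode, L = as.integer(L),
                 n_channels = as.integer(n_channels),
                 n_kernels = as.integer(n_kernels), seed = as.integer(seed),
                 kernels = kernels),
            class = "kernel_bank")
}

# dilated convolution of one channel block: X is n x L, returns n x T_out
.conv_dilated <- function(X, w, dil, pad) {
  L <- ncol(X)
  span <- (length(w) - 1L) * dil
  if (pad) {
    p <- span %/% 2L
    X <- cbind(matrix(0, nrow(X), p), X, matrix(0, nrow(X), span - p))
    L <- ncol(X)
  }
  T_out <- L - span
  A <- matrix(0, nrow(X), T_out)
  for (j in seq_along(w))
    A <- A + w[j] * X[, (1L + (j - 1L) * dil):(T_out + (j - 1L) * dil),
                      drop = FALSE]
  A
}

#' Pooled random-kernel features
#'
#' Convolves every window with every kernel (per-channel responses over the
#' kernel's channel subset are summed, then the bias added) and pools the
#' activation map into the proportion of positive values (PPV) and, by
#' default, the maximum activation (MAX) -- both statistics for both modes,
#' mirroring the comparison this package reproduces. `canonical = TRUE`
#' restores the published Mini-Rocket convention of PPV only.
#'
#' @param win A `window_set` whose window length equals `bank$L`.
#' @param bank A [build_bank()] result.
#' @param stats Pooling statistics, subset of `c("ppv", "max")`.
#' @param canonical If `TRUE` and `bank$mode == "minirocket"`, pool PPV only.
#' @return A [feature_matrix()] with `length(stats) * n_kernels` columns.
#' @export
kernel_transform <- function(win, bank, stats = c("ppv", "max"),
                             canonical = FALSE) {
  .check_window_set(win)
  stopifnot(inherits(bank, "kernel_bank"))
  if (dim(win$windows)[3] != bank$L)
    stop("window length does not match the kernel bank")
  stats <- match.arg(stats, c("ppv", "max"), several.ok = TRUE)
  if (canonical && bank$mode == "minirocket") stats <- "ppv"
  n_win <- dim(win$windows)[1]
  cols <- list()
  for (i in seq_along(bank$kernels)) {
    k <- bank$kernels[[i]]
    A <- NULL
    for (c in k$channels) {
      X <- matrix(win$windows[, c, ], nrow = n_win)
      Ac <- .conv_dilated(X, k$weights, k$dilation, k$padding)
      A <- if (is.null(A)) Ac else A + Ac
    }
    A <- A + k$bias
    tag <- toupper(bank$mode)
    if ("ppv" %in% stats)
      cols[[sprintf("%s|k%02d|PPV", tag, i)]] <- rowMeans(A > 0)
    if ("max" %in% stats)
      cols[[sprintf("%s|k%02d|MAX", tag, i)]] <- apply(A, 1, max)
  }
  vals <- do.call(cbind, cols)
  feature_matrix(vals, win$labels, win$trial_ids, win$subject_id, bank$mode)
}
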