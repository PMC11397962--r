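# Independent oracles used across test files. These deliberately use naive
# loop-based transcriptions, not the package's vectorized code paths.

# waveform length by explicit loop
oracle_wl <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s
}

oracle_rms <- function(x) {
  s <- 0
  for (i in seq_along(x)) s <- s + x[i]^2
  sqrt(s / length(x))
}

# pairwise phasor-difference moduli via complex arithmetic
oracle_pairwise_complex <- function(f, N) {
  z <- f * exp(1i * (seq_len(N) - 1) * 2 * pi / N)
  out <- numeric(0)
  for (k in seq_len(N - 1))
    for (l in (k + 1):N)
      out <- c(out, Mod(z[k] - z[l]))
  out
}

# literal transcription of the separability index: per-class centroids and
# covariances, most-conflicting class under the averaged covariance, mean of
# half-Mahalanobis distances
oracle_si <- function(X, y) {
  classes <- sort(unique(y))
  K <- length(classes)
  m <- list(); S <- list()
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    m[[as.character(cl)]] <- apply(Xc, 2, mean)
    S[[as.character(cl)]] <- cov(Xc)
  }
  total <- 0
  for (i in seq_len(K)) {
    best <- Inf
    for (j in seq_len(K)) {
      if (j == i) next
      Sij <- (S[[i]] + S[[j]]) / 2
      dm <- m[[i]] - m[[j]]
      d <- sqrt(0.5 * drop(t(dm) %*% solve(Sij) %*% dm))
      if (d < best) best <- d
    }
    total <- total + best
  }
  total / K
}

# literal RK multiclass MCC as the triple sum over confusion entries
oracle_mcc_rk <- function(C) {
  K <- nrow(C)
  num <- 0
  for (k in 1:K) for (l in 1:K) for (m in 1:K)
    num <- num + C[k, k] * C[l, m] - C[k, l] * C[m, k]
  d1 <- 0; d2 <- 0
  for (k in 1:K) {
    d1 <- d1 + sum(C[k, ]) * sum(C[-k, ])
    d2 <- d2 + sum(C[, k]) * sum(C[, -k])
  }
  if (d1 == 0 || d2 == 0) return(0)
  num / sqrt(d1 * d2)
}

# naive dilated convolution + pooling for one window (channels x L matrix)
oracle_kernel_pool <- function(Xw, kern) {
  w <- kern$weights; dil <- kern$dilation
  L <- ncol(Xw)
  span <- (length(w) - 1) * dil
  act <- NULL
  for (ch in kern$channels) {
    x <- Xw[ch, ]
    if (kern$padding) {
      p <- span %/% 2
      x <- c(rep(0, p), x, rep(0, span - p))
    }
    Tout <- length(x) - span
    a <- numeric(Tout)
    for (t in seq_len(Tout)) {
      s <- 0
      for (j in seq_along(w)) s <- s + w[j] * x[t + (j - 1) * dil]
      a[t] <- s
    }
    act <- if (is.null(act)) a else act + a
  }
  act <- act + kern$bias
  c(ppv = mean(act > 0), max = max(act))
}

# per-window per-channel base feature via the scalar ops (oracle composition)
.base_feat_for_test <- function(win, base = "wl") {
  fun <- if (base == "wl") wl else rms
  t(apply(win$windows, 1, function(Xw) apply(Xw, 1, fun)))
}

# hand-rolled window_set around a windows array (bypasses the pipeline)
make_win <- function(X3, labels = NULL, trial_ids = NULL) {
  n <- dim(X3)[1]
  structure(list(windows = X3,
                 labels = if (is.null(labels)) rep(0L, n) else labels,
                 trial_ids = if (is.null(trial_ids)) rep("T01", n) else trial_ids,
                 subject_id = "S01", fs = 1920, window_ms = 150,
                 increment_ms = 25,
                 channel_names = paste0("ch", seq_len(dim(X3)[2]) - 1)),
            class = "window_set")
}

# small fast synthetic config shared across tests
tiny_cfg <- function(contrast = 2, noise = 0.05, n_cycles = 1, seed = 7,
                     jitter = 0.1) {
  synth_config(synergy_gains = synergy_gain_matrix(contrast = contrast),
               noise_std = noise, n_cycles = n_cycles, seed = seed,
               duration_jitter = jitter)
}
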