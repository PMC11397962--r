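# phasor embedding and f-PHASOR sets

test_that("phasor embedding places features on the unit-circle angles", {
  lay9 <- phasor_layout(9)
  expect_equal(phasor_embed(rep(0, 9), lay9), rep(0 + 0i, 9))
  lay4 <- phasor_layout(4)
  expect_equal(phasor_embed(rep(1, 4), lay4), c(1 + 0i, 1i, -1 + 0i, -1i),
               tolerance = 1e-15)
  set.seed(1)
  f <- rnorm(9)
  expect_equal(Mod(phasor_embed(f, lay9)), abs(f), tolerance = 1e-14)
  expect_error(phasor_embed(rep(1, 5), lay9), "channel count")
})

test_that("pairwise moduli: analytic cases and complex-arithmetic oracle", {
  expect_equal(pairwise_moduli(c(1, 1), phasor_layout(2)), c("(0,1)" = 2))
  expect_equal(unname(pairwise_moduli(c(1, 1, 1), phasor_layout(3))),
               rep(sqrt(3), 3), tolerance = 1e-12)
  lay9 <- phasor_layout(9)
  set.seed(2)
  f <- rnorm(9)
  d <- pairwise_moduli(f, lay9)
  expect_length(d, 36)
  expect_equal(unname(d), oracle_pairwise_complex(f, 9), tolerance = 1e-12)
  expect_error(pairwise_moduli(1, phasor_layout(2)), "dimension")
})

test_that("trig form equals complex form over random inputs and N (property)", {
  set.seed(3)
  worst <- 0
  for (N in 2:12) {
    lay <- phasor_layout(N)
    for (rep in 1:50) {
      f <- rnorm(N, sd = 10)
      err <- max(abs(pairwise_moduli(f, lay) - oracle_pairwise_complex(f, N)))
      worst <- max(worst, err)
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("Df is invariant as a multiset under cyclic channel shifts", {
  lay <- phasor_layout(7)
  set.seed(4)
  f <- abs(rnorm(7))
  d0 <- sort(pairwise_moduli(f, lay))
  for (s in 1:6) {
    fs_ <- f[((seq_len(7) - 1 + s) %% 7) + 1]
    expect_equal(sort(pairwise_moduli(fs_, lay)), d0, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("positive scaling scales Df linearly and cancels in the log-ratio", {
  set.seed(5)
  W <- array(rnorm(10 * 5 * 128), c(10, 5, 128))
  win <- make_win(W)
  win_s <- make_win(W * 3.7)
  lay <- phasor_layout(5)
  f1 <- fphasor_set(win, "wl", eps = 0)
  f2 <- fphasor_set(win_s, "wl", eps = 0)
  M <- 10  # N(N-1)/2 pairs
  d_cols <- 1:M; r_cols <- (M + 1):(2 * M)
  # log(Df) shifts uniformly by log(alpha); log-ratio block is invariant
  expect_equal(f2$values[, d_cols], f1$values[, d_cols] + log(3.7),
               tolerance = 1e-10)
  expect_equal(f2$values[, r_cols], f1$values[, r_cols], tolerance = 1e-10)
})

test_that("gradient features: constants vanish, ramps behave analytically", {
  L <- 100
  n_ch <- 3
  W <- array(0, c(2, n_ch, L))
  slopes <- c(0.5, -1, 2)
  for (c in 1:n_ch) {
    W[1, c, ] <- 4                       # constant window
    W[2, c, ] <- slopes[c] * (0:(L - 1)) # linear ramp
  }
  win <- make_win(W)
  g <- gradient_features(win, "wl")
  expect_equal(unname(g[1, ]), rep(0, 3))
  # the differentiated ramp is constant, so its waveform length is 0 too
  expect_equal(unname(g[2, ]), rep(0, 3))
  # the undifferentiated WL of the ramp is (L-1)*|s|; Df follows closed form
  lay <- phasor_layout(n_ch)
  fwl <- (L - 1) * abs(slopes)
  Df <- pairwise_moduli(.base_feat_for_test(win, "wl"), lay)
  expect_equal(unname(Df[2, ]), oracle_pairwise_complex(fwl, 3),
               tolerance = 1e-10)
})

test_that("per-window differentiation matches trial-level differentiation", {
  cfg <- tiny_cfg(n_cycles = 1)
  rec <- generate_trial(cfg)
  win <- make_windows(rec)
  L <- dim(win$windows)[3]; S <- round(25 * rec$fs / 1000)
  d_trial <- t(apply(rec$samples, 1, diff))
  for (i in c(1, 10)) {
    start <- (i - 1) * S
    w_diff <- diff(win$windows[i, 2, ])
    expect_equal(w_diff, d_trial[2, (start + 1):(start + L - 1)],
                 ignore_attr = TRUE)
  }
})

test_that("f-PHASOR and combined PHASOR dimensional contracts hold", {
  set.seed(6)
  W <- array(rnorm(8 * 9 * 128), c(8, 9, 128))
  win <- make_win(W)
  fw <- fphasor_set(win, "wl")
  fr <- fphasor_set(win, "rms")
  fc <- phasor_combined_set(win)
  expect_equal(ncol(fw$values), 72)
  expect_equal(ncol(fc$values), 144)
  expect_equal(anyDuplicated(colnames(fc$values)), 0L)
  expect_true(all(grepl("^WLPH|^RMSPH", colnames(fc$values))))
  expect_equal(fc$values, cbind(fw$values, fr$values))
  # compositional oracle: fphasor == [log(Df+eps), log((Df+eps)/(gDf+eps))]
  lay <- phasor_layout(9)
  base <- t(apply(W, 1, function(Xw) apply(Xw, 1, wl)))
  Df <- pairwise_moduli(base, lay)
  based <- t(apply(W, 1, function(Xw) apply(Xw, 1, function(x) wl(diff(x)))))
  gDf <- pairwise_moduli(based, lay)
  eps <- 1e-12
  expect_equal(unname(fw$values), unname(cbind(log(Df + eps),
                                               log((Df + eps) / (gDf + eps)))),
               tolerance = 1e-12)
})

test_that("windows with Df equal to gradient Df zero the log-ratio block", {
  # for the pattern (0, v, 0) the waveform length of the signal (2v) equals
  # that of its first difference (|-v - v| = 2v), so Df == grad_Df elementwise
  v <- c(1, 2.5, 4)
  W <- array(0, c(2, 3, 3))
  for (c in 1:3) W[, c, 2] <- v[c]
  fm <- fphasor_set(make_win(W), "wl")
  ratio_block <- fm$values[, grepl("\\|r\\(", colnames(fm$values))]
  expect_true(all(ratio_block == 0))
})
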