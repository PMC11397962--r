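# separability index and mean semi-principal axis

gauss_clusters <- function(centers, n_per, sds = 1, seed = 1) {
  set.seed(seed)
  D <- ncol(centers)
  X <- NULL; y <- integer(0)
  for (i in seq_len(nrow(centers))) {
    sd_i <- if (is.matrix(sds)) sds[i, ] else rep(sds, D)
    Xi <- sweep(matrix(rnorm(n_per * D), n_per) %*% diag(sd_i, D), 2,
                centers[i, ], "+")
    X <- rbind(X, Xi); y <- c(y, rep(i - 1L, n_per))
  }
  list(X = X, y = y)
}

test_that("most conflicting class is the nearest under equal covariance", {
  centers <- cbind(c(0, 1, 10), 0)
  g <- gauss_clusters(centers, 500, sds = 0.1, seed = 2)
  expect_equal(most_conflicting(g$X, g$y, 0), 1)
  expect_equal(most_conflicting(g$X, g$y, 2), 1)
  # two classes: conflict is necessarily the other
  g2 <- gauss_clusters(cbind(c(0, 3)), 100, seed = 3)
  expect_equal(most_conflicting(g2$X, g2$y, 0), 1)
  expect_equal(most_conflicting(g2$X, g2$y, 1), 0)
})

test_that("SI and conflicts match the literal brute-force transcription", {
  set.seed(4)
  for (rep in 1:5) {
    K <- sample(3:5, 1); D <- sample(2:4, 1)
    centers <- matrix(rnorm(K * D, sd = 3), K)
    g <- gauss_clusters(centers, 60, sds = runif(1, 0.5, 2), seed = rep * 11)
    expect_equal(separability_index(g$X, g$y), oracle_si(g$X, g$y),
                 tolerance = 1e-6)
    for (cl in 0:(K - 1)) {
      st_best <- most_conflicting(g$X, g$y, cl)
      expect_true(st_best %in% setdiff(0:(K - 1), cl))
    }
  }
})

test_that("coincident classes give SI 0; affine maps leave SI unchanged", {
  g <- gauss_clusters(rbind(c(0, 0), c(0, 0)), 400, seed = 5)
  expect_lt(separability_index(g$X, g$y), 0.1)

  g2 <- gauss_clusters(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 5, 0)), 300, seed = 6)
  si0 <- separability_index(g2$X, g2$y)
  set.seed(7)
  A <- matrix(rnorm(9), 3); while (abs(det(A)) < 0.3) A <- matrix(rnorm(9), 3)
  si1 <- separability_index(g2$X %*% A + 2, g2$y)
  expect_equal(si1, si0, tolerance = 1e-6)
})

test_that("SI recovers the closed form d/sqrt(2) for unit-covariance pairs", {
  d <- 4
  centers <- cbind(d * (0:4), matrix(0, 5, 3))
  g <- gauss_clusters(centers, 2000, sds = 1, seed = 8)
  si <- separability_index(g$X, g$y)
  expect_lt(abs(si - d / sqrt(2)) / (d / sqrt(2)), 0.05)
})

test_that("MSA recovers per-axis standard deviations", {
  # spherical: sigma = 0.7 in D = 4
  g <- gauss_clusters(matrix(0, 1, 4), 20000, sds = 0.7, seed = 9)
  g$y <- rep(0L, nrow(g$X))
  # single-class MSA needs no conflict; call the metric directly
  msa <- mean_semi_principal_axis(g$X, g$y)
  expect_lt(abs(msa - 0.7) / 0.7, 0.05)
  # anisotropic (1, 4): geometric mean 2
  g2 <- gauss_clusters(matrix(0, 1, 2), 20000, sds = matrix(c(1, 4), 1), seed = 10)
  msa2 <- mean_semi_principal_axis(g2$X, rep(0L, nrow(g2$X)))
  expect_lt(abs(msa2 - 2) / 2, 0.05)
})

test_that("MSA degenerate and invariance properties", {
  # all classes collapsed to repeated points -> eps floor, effectively 0
  X <- rbind(matrix(1, 50, 3), matrix(2, 50, 3))
  y <- rep(0:1, each = 50)
  expect_warning(mean_semi_principal_axis(matrix(1, 50, 3), rep(0L, 50)),
                 "zero variance")
  msa0 <- suppressWarnings(mean_semi_principal_axis(X, y))
  expect_lt(msa0, 1e-6)
  # rotation invariance and |alpha| scaling
  g <- gauss_clusters(rbind(c(0, 0), c(5, 0)), 500, sds = 1.3, seed = 11)
  m0 <- mean_semi_principal_axis(g$X, g$y)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(mean_semi_principal_axis(g$X %*% R, g$y), m0, tolerance = 1e-9)
  expect_equal(mean_semi_principal_axis(g$X * -2.5, g$y), 2.5 * m0,
               tolerance = 1e-9)
  # raw (unscaled) mode grows with n; scaled mode does not
  mraw <- mean_semi_principal_axis(g$X, g$y, scaled = FALSE)
  expect_gt(mraw, 10 * m0)
})

test_that("SI grows strictly with cluster separation", {
  si <- sapply(c(1, 2.5, 5), function(d) {
    g <- gauss_clusters(cbind(d * (0:2), 0), 400, sds = 1, seed = 12)
    separability_index(g$X, g$y)
  })
  expect_true(all(diff(si) > 0))
})

test_that("degenerate classes raise errors; quality_report aggregates", {
  X <- rbind(matrix(rnorm(20), 10), matrix(5 + rnorm(20), 10))
  y <- c(rep(0L, 10), rep(1L, 9), 2L)
  expect_error(separability_index(X, y), "degenerate")

  g <- gauss_clusters(rbind(c(0, 0), c(4, 0), c(0, 4)), 200, seed = 13)
  fm <- feature_matrix(g$X, g$y, rep("T01", length(g$y)), "S01", "toy")
  qr <- quality_report(fm)
  expect_s3_class(qr, "quality_report")
  expect_equal(qr$K, 3)
  expect_equal(qr$D, 2)
  expect_named(qr$per_class_conflict, c("0", "1", "2"))
  expect_gt(qr$si, 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quality_table(list(qr), path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$SI, qr$si, tolerance = 1e-9)
})
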