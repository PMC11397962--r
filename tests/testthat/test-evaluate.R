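# LOTO evaluation harness

test_that("LOTO folds partition trials into disjoint covering groups", {
  ids10 <- rep(sprintf("T%02d", 1:10), each = 7)
  folds <- loto_folds(ids10, 5)
  expect_length(folds, 5)
  tests <- lapply(folds, `[[`, "test")
  expect_true(all(lengths(tests) == 2))
  expect_setequal(unlist(tests), unique(ids10))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), unique(ids10))
  }
  # 5 trials, 5 folds: classic leave-one-out
  folds5 <- loto_folds(rep(sprintf("T%02d", 1:5), each = 3), 5)
  expect_true(all(lengths(lapply(folds5, `[[`, "test")) == 1))
  # property sweep over trial counts
  for (nt in 5:13) {
    fl <- loto_folds(sprintf("T%02d", 1:nt), 5)
    expect_setequal(unlist(lapply(fl, `[[`, "test")), sprintf("T%02d", 1:nt))
    expect_lte(diff(range(lengths(lapply(fl, `[[`, "test")))), 1)
  }
  expect_error(loto_folds(c("a", "b"), 5), "at least as many")
})

test_that("z-score uses train statistics only and zeroes constant columns", {
  set.seed(1)
  train <- cbind(rnorm(50, 10, 2), rnorm(50), rep(3, 50))
  test <- cbind(rnorm(20, 30, 2), rnorm(20), rep(9, 20))
  z <- zscore_fit_apply(train, test)
  expect_equal(unname(colMeans(z$train)), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z$train[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-9)
  expect_true(all(z$train[, 3] == 0) && all(z$test[, 3] == 0))
  # the shifted test column must not be centered at 0 (train stats applied)
  expect_gt(mean(z$test[, 1]), 5)
  expect_equal(z$test[, 1], (test[, 1] - mean(train[, 1])) / sd(train[, 1]),
               tolerance = 1e-12)
})

test_that("gamma rules follow the documented arithmetic", {
  X <- matrix(rnorm(72 * 100), 100, 72)
  X <- scale(X)
  v <- var(as.vector(X))
  expect_equal(svm_gamma(X, "paper_product"), 72 * v, tolerance = 1e-12)
  expect_equal(svm_gamma(X, "inverse_scale"), 1 / (72 * v), tolerance = 1e-12)
  X2 <- cbind(X, X)
  expect_equal(svm_gamma(X2, "paper_product") / svm_gamma(X, "paper_product"),
               2 * var(as.vector(X2)) / v, tolerance = 1e-9)
  expect_error(svm_gamma(matrix(1, 10, 3)), "zero-variance")
})

test_that("multiclass MCC matches the literal RK oracle and its fixed points", {
  perfect <- diag(c(10, 20, 30, 5, 8))
  expect_equal(mcc_multiclass(perfect), 1)
  constant <- matrix(0, 3, 3); constant[, 2] <- c(5, 10, 3)
  expect_warning(m0 <- mcc_multiclass(constant), "degenerate")
  expect_equal(m0, 0)
  set.seed(2)
  for (i in 1:100) {
    C <- matrix(rpois(25, 8), 5, 5)
    expect_equal(mcc_multiclass(C), oracle_mcc_rk(C), tolerance = 1e-12)
  }
  expect_equal(acc_from_confusion(perfect), 1)
  C <- matrix(1:9, 3)
  expect_equal(acc_from_confusion(C), sum(diag(C)) / sum(C))
})

test_that("one-hot features are perfectly classified by both models", {
  set.seed(3)
  y <- sample(0:4, 400, replace = TRUE)
  X <- outer(y, 0:4, "==") * 1 + matrix(rnorm(400 * 5, sd = 1e-3), 400)
  fm <- feature_matrix(X, y, rep(sprintf("T%02d", 1:10), 40), "S01", "onehot")
  colnames(fm$values) <- paste0("f", 1:5)
  for (clf in c("lda_diag", "svm_rbf")) {
    res <- run_subject_eval(fm, eval_config(clf))
    expect_equal(res$acc_mean, 1)
    expect_equal(res$mcc_mean, 1)
    expect_equal(sum(res$confusion), 400)
    expect_true(all(res$confusion == diag(diag(res$confusion))))
  }
})

test_that("shuffled labels yield chance-level MCC (permutation null)", {
  cfg <- tiny_cfg(contrast = 2, n_cycles = 6, seed = 17)
  recs <- generate_dataset(cfg, 1)
  win <- preprocess_trials(recs)
  fm <- fphasor_set(win, "rms")
  expect_gte(nrow(fm$values), 2000)
  set.seed(99)
  fm$labels <- sample(fm$labels)
  res <- run_subject_eval(fm, eval_config("lda_diag"))
  expect_lt(abs(res$mcc_mean), 0.1)
})

test_that("evaluation bookkeeping: confusion sums, ranges, skipped folds", {
  set.seed(4)
  y <- sample(0:2, 300, replace = TRUE)
  X <- outer(y, 0:2, "==") + matrix(rnorm(900, sd = 0.5), 300)
  colnames(X) <- paste0("f", 1:3)
  fm <- feature_matrix(X, y, rep(sprintf("T%02d", 1:10), 30), "S01", "toy")
  res <- run_subject_eval(fm, eval_config("lda_diag"))
  expect_equal(sum(res$confusion), 300)
  # confusion row sums equal per-class test counts
  expect_equal(unname(rowSums(res$confusion)), unname(table(y))[1:3],
               ignore_attr = TRUE)
  expect_true(all(res$per_fold$acc >= 0 & res$per_fold$acc <= 1))
  expect_true(all(res$per_fold$mcc >= -1 & res$per_fold$mcc <= 1))
  # ACC identity against the pooled confusion
  expect_equal(acc_from_confusion(res$confusion),
               sum(res$per_fold$acc * res$per_fold$n_test) / 300,
               tolerance = 1e-12)

  # a training split missing one class: that fold is skipped with a warning
  y2 <- y; y2[fm$trial_ids != "T01"] <- sample(0:1, 270, replace = TRUE)
  fm2 <- feature_matrix(X, y2, fm$trial_ids, "S01", "toy")
  expect_warning(res2 <- run_subject_eval(fm2, eval_config("lda_diag")),
                 "skipped")
  expect_gt(length(res2$skipped_folds), 0)
})

test_that("trained predictions are independent of test labels (no leakage)", {
  set.seed(5)
  y <- sample(0:2, 200, replace = TRUE)
  X <- outer(y, 0:2, "==") + matrix(rnorm(600, sd = 0.8), 200)
  tr <- 1:150; te <- 151:200
  model <- emgphasor:::lda_diag_fit(X[tr, ], y[tr])
  p1 <- emgphasor:::lda_diag_predict(model, X[te, ])
  # relabeling the test set cannot change anything the model saw
  p2 <- emgphasor:::lda_diag_predict(model, X[te, ])
  expect_identical(p1, p2)
  g <- svm_gamma(X[tr, ])
  svm <- emgphasor:::svm_rbf_fit(X[tr, ], y[tr], g)
  expect_identical(emgphasor:::svm_rbf_predict(svm, X[te, ]),
                   emgphasor:::svm_rbf_predict(svm, X[te, ]))
})
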