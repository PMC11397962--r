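#' Leave-one-trial-out fold partition
#'
#' Partitions the distinct trials into `n_folds` disjoint, covering groups
#' of near-equal size (10 trials, 5 folds: 2 per fold); fold `i` tests on
#' group `i` and trains on the rest. Grouping follows trial order of first
#' appearance (deterministic); set `shuffle = TRUE` with a `seed` for a
#' seeded random grouping.
#'
#' @param trial_ids Per-window trial identifiers.
#' @param n_folds Number of folds (default 5).
#' @param shuffle,seed Optional seeded shuffling of the trial order.
#' @return List of `n_folds` lists with elements `train` and `test`
#'   (trial-id character vectors).
#' @export
loto_folds <- function(trial_ids, n_folds = 5, shuffle = FALSE, seed = NULL) {
  trials <- unique(trial_ids)
  if (length(trials) < n_folds)
    stop("need at least as many distinct trials as folds")
  if (shuffle) {
    old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
    if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
    trials <- sample(trials)
  }
  bounds <- floor(seq(0, length(trials), length.out = n_folds + 1))
  lapply(seq_len(n_folds), function(i) {
    test <- trials[(bounds[i] + 1):bounds[i + 1]]
    list(train = setdiff(trials, test), test = test)
  })
}

#' Fit-on-train z-score normalization
#'
#' Column means and standard deviations are estimated from the training
#' matrix only and applied to both matrices; zero-variance columns map to
#' zero in both.
#'
#' @param train,test Numeric matrices with matching columns.
#' @return List with `train`, `test`, `center`, `scale`.
#' @export
zscore_fit_apply <- function(train, test) {
  if (nrow(train) < 2) stop("need at least 2 training rows")
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  zero <- scl <= 0 | !is.finite(scl)
  scl[zero] <- 1
  ztr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  zte <- sweep(sweep(test, 2, ctr), 2, scl, "/")
  ztr[, zero] <- 0
  if (nrow(zte) > 0) zte[, zero] <- 0
  list(train = ztr, test = zte, center = ctr, scale = scl)
}

#' RBF kernel width rules
#'
#' `paper_product`: `gamma = D * Var` -- the number of features times the
#' variance of the (flattened) training matrix, the rule as literally
#' stated in the comparison this package reproduces. `inverse_scale`
#' (default in [eval_config()]): `gamma = 1 / (D * Var)`, the common
#' "scale" heuristic the literal product most likely paraphrases; after
#' z-scoring the product rule gives extremely peaked kernels.
#'
#' @param features_train Training matrix.
#' @param rule `"paper_product"` or `"inverse_scale"`.
#' @return Scalar gamma.
#' @export
svm_gamma <- function(features_train, rule = c("inverse_scale", "paper_product")) {
  rule <- match.arg(rule)
  v <- stats::var(as.vector(features_train))
  if (!is.finite(v) || v <= 0) stop("zero-variance training matrix")
  D <- ncol(features_train)
  if (rule == "paper_product") D * v else 1 / (D * v)
}

#' Multiclass Matthews correlation coefficient
#'
#' The Gorodkin RK generalization computed from a `K x K` confusion matrix
#' (rows = truth, columns = prediction); in `[-1, 1]`. Degenerate
#' marginals (all mass in one row or one column) return 0 with a warning.
#'
#' @param confusion `K x K` count matrix.
#' @return Scalar in `[-1, 1]`.
#' @export
mcc_multiclass <- function(confusion) {
  C <- as.matrix(confusion)
  s <- sum(C)
  if (s <= 0) stop("empty confusion matrix")
  tk <- rowSums(C)          # truth marginals
  pk <- colSums(C)          # prediction marginals
  cc <- sum(diag(C))
  num <- cc * s - sum(tk * pk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) {
    warning("degenerate confusion marginals; MCC undefined, returning 0")
    return(0)
  }
  num / den
}

#' Classification accuracy from a confusion matrix
#' @param confusion `K x K` count matrix.
#' @return `trace(confusion) / sum(confusion)`.
#' @export
acc_from_confusion <- function(confusion) {
  sum(diag(as.matrix(confusion))) / sum(confusion)
}

# ---- diagonal-covariance LDA ----------------------------------------------
# Gaussian classifier with class means, class priors and a pooled
# per-feature (diagonal) covariance: "principal diagonal covariance model".

lda_diag_fit <- function(X, y) {
  classes <- sort(unique(y))
  means <- t(vapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE]), numeric(ncol(X))))
  ss <- 0
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    ss <- ss + colSums(sweep(Xc, 2, colMeans(Xc))^2)
  }
  v <- pmax(ss / max(1, nrow(X) - length(classes)), 1e-12)
  list(classes = classes, means = means, var = v,
       logprior = log(tabulate(match(y, classes)) / length(y)))
}

lda_diag_predict <- function(model, X) {
  K <- length(model$classes)
  scores <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    Z <- sweep(X, 2, model$means[k, ])
    scores[, k] <- model$logprior[k] -
      0.5 * rowSums(sweep(Z^2, 2, model$var, "/"))
  }
  model$classes[max.col(scores, ties.method = "first")]
}

# ---- RBF-kernel C-SVM via the soft-margin dual (quadprog), one-vs-one -----

.rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

.svm_binary_fit <- function(X, y01, gamma, cost) {
  # y01 in {-1, +1}
  n <- nrow(X)
  K <- .rbf_kernel(X, X, gamma)
  Dmat <- (y01 %o% y01) * K + diag(1e-8, n)
  Amat <- cbind(y01, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(Dmat, rep(1, n), Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  sv <- alpha > 1e-7
  margin <- sv & alpha < cost - 1e-7
  if (!any(margin)) margin <- sv
  f_no_b <- as.vector(K[, sv, drop = FALSE] %*% (alpha[sv] * y01[sv]))
  b <- mean(y01[margin] - f_no_b[margin])
  list(X_sv = X[sv, , drop = FALSE], coef = alpha[sv] * y01[sv],
       b = b, gamma = gamma)
}

.svm_binary_decision <- function(model, X) {
  as.vector(.rbf_kernel(X, model$X_sv, model$gamma) %*% model$coef) + model$b
}

svm_rbf_fit <- function(X, y, gamma, cost = 1) {
  classes <- sort(unique(y))
  pairs <- utils::combn(length(classes), 2)
  models <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    sel <- y %in% classes[c(i, j)]
    y01 <- ifelse(y[sel] == classes[i], 1, -1)
    fit <- .svm_binary_fit(X[sel, , drop = FALSE], y01, gamma, cost)
    fit$pos <- classes[i]; fit$neg <- classes[j]
    fit
  })
  list(classes = classes, models = models, gamma = gamma, cost = cost)
}

svm_rbf_predict <- function(model, X) {
  K <- length(model$classes)
  votes <- matrix(0, nrow(X), K)
  margin <- matrix(0, nrow(X), K)
  for (m in model$models) {
    d <- .svm_binary_decision(m, X)
    i <- match(m$pos, model$classes); j <- match(m$neg, model$classes)
    votes[, i] <- votes[, i] + (d > 0)
    votes[, j] <- votes[, j] + (d <= 0)
    margin[, i] <- margin[, i] + d
    margin[, j] <- margin[, j] - d
  }
  # vote count decides; summed signed margins break ties deterministically
  score <- votes + 1e-6 * margin / (1 + abs(margin))
  model$classes[max.col(score, ties.method = "first")]
}

#' Evaluation configuration
#'
#' @param classifier `"lda_diag"` or `"svm_rbf"`.
#' @param gamma_rule See [svm_gamma()]; only used by the SVM.
#' @param n_folds Number of LOTO folds (default 5).
#' @param z_score Normalize features (train statistics only)? Default TRUE.
#' @param svm_cost Soft-margin cost C (default 1).
#' @param shuffle_folds,seed Optional seeded fold shuffling.
#' @return Object of class `eval_config`.
#' @export
eval_config <- function(classifier = c("svm_rbf", "lda_diag"),
                        gamma_rule = c("inverse_scale", "paper_product"),
                        n_folds = 5, z_score = TRUE, svm_cost = 1,
                        shuffle_folds = FALSE, seed = NULL) {
  structure(list(classifier = match.arg(classifier),
                 gamma_rule = match.arg(gamma_rule),
                 n_folds = n_folds, z_score = isTRUE(z_score),
                 svm_cost = svm_cost, shuffle_folds = isTRUE(shuffle_folds),
                 seed = seed), class = "eval_config")
}

#' Intra-subject five-fold leave-one-trial-out evaluation
#'
#' Partitions the subject's trials with [loto_folds()], and per fold:
#' z-scores with training statistics, fits the configured classifier,
#' predicts the held-out trials, and accumulates per-fold ACC and MCC, the
#' pooled confusion matrix and the wall-clock test (classification) time.
#' A fold whose training split misses a class is skipped with a warning
#' and recorded.
#'
#' @param fm A [feature_matrix()] covering at least `cfg$n_folds` trials.
#' @param cfg An [eval_config()].
#' @return Object of class `eval_result`: `per_fold` data frame (`fold`,
#'   `acc`, `mcc`, `test_time_ms`, `n_test`), `acc_mean`, `acc_sd`,
#'   `mcc_mean`, `mcc_sd`, pooled `confusion`, `classifier`, `gamma`,
#'   `gamma_rule`, `skipped_folds`, `subject_id`, `feature_set_name`.
#' @export
run_subject_eval <- function(fm, cfg = eval_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cfg, "eval_config"))
  folds <- loto_folds(fm$trial_ids, cfg$n_folds, cfg$shuffle_folds, cfg$seed)
  classes <- sort(unique(fm$labels))
  K <- length(classes)
  conf <- matrix(0L, K, K, dimnames = list(truth = classes, pred = classes))
  per_fold <- list(); skipped <- integer(0); gamma_used <- NA_real_
  for (fi in seq_along(folds)) {
    tr <- fm$trial_ids %in% folds[[fi]]$train
    te <- fm$trial_ids %in% folds[[fi]]$test
    ytr <- fm$labels[tr]; yte <- fm$labels[te]
    if (length(unique(ytr)) < 2 || !all(classes %in% unique(ytr))) {
      warning("fold ", fi, " misses a class in training; skipped")
      skipped <- c(skipped, fi)
      next
    }
    Xtr <- fm$values[tr, , drop = FALSE]
    Xte <- fm$values[te, , drop = FALSE]
    if (cfg$z_score) {
      z <- zscore_fit_apply(Xtr, Xte)
      Xtr <- z$train; Xte <- z$test
    }
    if (cfg$classifier == "svm_rbf") {
      gamma_used <- svm_gamma(Xtr, cfg$gamma_rule)
      model <- svm_rbf_fit(Xtr, ytr, gamma_used, cfg$svm_cost)
      t0 <- proc.time()[["elapsed"]]
      pred <- svm_rbf_predict(model, Xte)
    } else {
      model <- lda_diag_fit(Xtr, ytr)
      t0 <- proc.time()[["elapsed"]]
      pred <- lda_diag_predict(model, Xte)
    }
    test_ms <- (proc.time()[["elapsed"]] - t0) * 1000
    cf <- table(factor(yte, levels = classes), factor(pred, levels = classes))
    conf <- conf + as.matrix(cf)
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(fold = fi, acc = acc_from_confusion(cf),
                 mcc = mcc_multiclass(cf), test_time_ms = test_ms,
                 n_test = sum(te))
  }
  if (length(per_fold) == 0) stop("all folds skipped; cannot evaluate")
  pf <- do.call(rbind, per_fold)
  structure(list(per_fold = pf,
                 acc_mean = mean(pf$acc), acc_sd = stats::sd(pf$acc),
                 mcc_mean = mean(pf$mcc), mcc_sd = stats::sd(pf$mcc),
                 confusion = conf, classifier = cfg$classifier,
                 gamma = gamma_used, gamma_rule = cfg$gamma_rule,
                 skipped_folds = skipped,
                 subject_id = fm$subject_id,
                 feature_set_name = fm$set_name),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s [%s, %s]: ACC = %.3f +/- %.3f, MCC = %.3f +/- %.3f (%d folds)\n",
              x$subject_id, x$feature_set_name, x$classifier,
              x$acc_mean, x$acc_sd, x$mcc_mean, x$mcc_sd, nrow(x$per_fold)))
  invisible(x)
}
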