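#' Feature-space quality metrics: separability index and mean semi-principal axis
#'
#' `separability_index` measures between-class spread: for each class `i`,
#' the half-Mahalanobis distance
#' `sqrt(0.5 * (m_i - m_Ci)' S^-1 (m_i - m_Ci))` to its most conflicting
#' class `Ci` (the class minimizing that distance), under the averaged
#' covariance `S = (Sigma_i + Sigma_Ci)/2`; SI is the mean over classes.
#' Higher SI means better separated phases.
#'
#' `mean_semi_principal_axis` measures within-class compactness: each class
#' is approximated as a hyper-ellipsoid via the SVD of its centered data;
#' the singular values, divided by `sqrt(n_i - 1)` so they estimate
#' per-axis standard deviations (set `scaled = FALSE` for raw singular
#' values), are combined by geometric mean, and MSA averages this over
#' classes. Lower MSA means more compact clusters.
#'
#' Both metrics are meant to run on unnormalized features, before any
#' classifier-oriented z-scoring.
#'
#' @param features `n x D` numeric matrix (or a [feature_matrix()]).
#' @param labels Per-row class labels (ignored when `features` is a
#'   `feature_matrix`).
#' @param lambda Covariance ridge, `lambda * trace(S)/D` added to the
#'   diagonal before inversion (default 1e-9; phasor/TDPSD columns can be
#'   collinear).
#' @return `separability_index`, `mean_semi_principal_axis`: a scalar.
#' @export
separability_index <- function(features, labels = NULL, lambda = 1e-9) {
  fx <- .as_features(features, labels)
  st <- .class_stats(fx$X, fx$y)
  K <- length(st$classes)
  mean(vapply(seq_len(K), function(i) {
    d <- .conflict_distances(st, i, lambda)
    min(d, na.rm = TRUE)
  }, numeric(1)))
}

#' @rdname separability_index
#' @param class_i A class label present in `labels`.
#' @return `most_conflicting`: the label of the class whose centroid is
#'   closest to `class_i`'s under the paired-covariance Mahalanobis metric.
#' @export
most_conflicting <- function(features, labels = NULL, class_i, lambda = 1e-9) {
  fx <- .as_features(features, labels)
  st <- .class_stats(fx$X, fx$y)
  i <- match(class_i, st$classes)
  if (is.na(i)) stop("class_i not present in labels")
  d <- .conflict_distances(st, i, lambda)
  st$classes[which.min(d)]
}

#' @rdname separability_index
#' @param scaled If `TRUE` (default) singular values are divided by
#'   `sqrt(n_i - 1)` so MSA estimates per-axis standard deviations and is
#'   sample-size independent; `FALSE` reports raw singular values.
#' @param eps Floor inside the geometric mean for zero-variance directions.
#' @export
mean_semi_principal_axis <- function(features, labels = NULL, scaled = TRUE,
                                     eps = 1e-12) {
  fx <- .as_features(features, labels)
  classes <- sort(unique(fx$y))
  axes <- vapply(classes, function(cl) {
    Xc <- fx$X[fx$y == cl, , drop = FALSE]
    if (nrow(Xc) < 2) stop("degenerate class: fewer than 2 samples")
    Xc <- sweep(Xc, 2, colMeans(Xc))
    sv <- svd(Xc, nu = 0, nv = 0)$d
    if (scaled) sv <- sv / sqrt(nrow(Xc) - 1)
    # D semi-axes; directions beyond rank have zero extent
    sv <- c(sv, rep(0, max(0, ncol(Xc) - length(sv))))
    if (any(sv <= eps))
      warning("class ", cl, " has zero variance in some direction; ",
              "geometric mean floored at eps")
    exp(mean(log(pmax(sv, eps))))
  }, numeric(1))
  mean(axes)
}

.as_features <- function(features, labels) {
  if (inherits(features, "feature_matrix"))
    list(X = features$values, y = features$labels)
  else list(X = as.matrix(features), y = labels)
}

.class_stats <- function(X, y) {
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  means <- list(); covs <- list()
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    if (nrow(Xc) < 2) stop("degenerate class: fewer than 2 samples")
    means[[as.character(cl)]] <- colMeans(Xc)
    covs[[as.character(cl)]] <- stats::cov(Xc)
  }
  list(classes = classes, means = means, covs = covs, D = ncol(X))
}

# half-Mahalanobis distances from class i to every other class (NA at i)
.conflict_distances <- function(st, i, lambda) {
  K <- length(st$classes)
  d <- rep(NA_real_, K)
  mi <- st$means[[i]]; Si <- st$covs[[i]]
  for (j in seq_len(K)) {
    if (j == i) next
    S <- (Si + st$covs[[j]]) / 2
    S <- S + diag(lambda * sum(diag(S)) / st$D, st$D)
    dm <- mi - st$means[[j]]
    q <- tryCatch(drop(crossprod(dm, solve(S, dm))),
                  error = function(e)
                    stop("singular pooled covariance for classes ",
                         st$classes[i], "/", st$classes[j],
                         " even after regularization: ", conditionMessage(e)))
    d[j] <- sqrt(0.5 * max(q, 0))
  }
  d
}

#' Per-subject quality report for one feature set
#'
#' @param fm A [feature_matrix()].
#' @param lambda,scaled,eps Passed to the metric functions.
#' @return Object of class `quality_report`: `si`, `msa`,
#'   `per_class_conflict` (named vector class -> most conflicting class),
#'   `K`, `D`, `subject_id`, `feature_set_name`.
#' @export
quality_report <- function(fm, lambda = 1e-9, scaled = TRUE, eps = 1e-12) {
  stopifnot(inherits(fm, "feature_matrix"))
  classes <- sort(unique(fm$labels))
  conflict <- vapply(classes, function(cl)
    most_conflicting(fm, class_i = cl, lambda = lambda), numeric(1))
  names(conflict) <- classes
  structure(list(si = separability_index(fm, lambda = lambda),
                 msa = mean_semi_principal_axis(fm, scaled = scaled, eps = eps),
                 per_class_conflict = conflict,
                 K = length(classes), D = ncol(fm$values),
                 subject_id = fm$subject_id,
                 feature_set_name = fm$set_name),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %s [%s]: SI = %.4g, MSA = %.4g (K = %d, D = %d)\n",
              x$subject_id, x$feature_set_name, x$si, x$msa, x$K, x$D))
  invisible(x)
}

#' Append quality reports to a delimited results table
#'
#' @param reports List of [quality_report()]s.
#' @param path Output TSV path; appended to if it exists.
#' @export
write_quality_table <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(subject = r$subject_id, feature_set = r$feature_set_name,
               SI = r$si, MSA = r$msa, K = r$K, D = r$D)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
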