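# Backup-capacity prediction from divergence features: feature assembly,
# an RBF-kernel decision function, stratified cross-validation with inner
# hyperparameter search, and rank-based ROC/AUC.

.pb_feature_names <- c("ka", "identity", "expression_divergence", "go_div")

#' Assemble per-pair feature vectors for backup prediction
#'
#' Each pair is described by four functional-divergence metrics —
#' Ka, aligned protein identity, expression divergence and GO-div — plus its
#' buffering flag as the label. WGD and SSD pairs are pooled. Pairs with any
#' non-finite feature are excluded and counted; standardization is *not*
#' applied here but inside each cross-validation training fold, to avoid
#' information leakage.
#'
#' @param pairs data.frame with columns `ka`, `identity`,
#'   `expression_divergence`, `go_div` and `buffering` (logical), plus
#'   optionally `pair_id`.
#' @return list with `x` (numeric matrix, one row per retained pair),
#'   `y` (logical labels), `pair_id`, `n_excluded`.
#' @export
assemble_features <- function(pairs) {
  miss <- setdiff(c(.pb_feature_names, "buffering"), names(pairs))
  if (length(miss))
    pb_stop("input_error", paste0("missing column(s): ", paste(miss, collapse = ", ")))
  x <- as.matrix(pairs[, .pb_feature_names])
  mode(x) <- "double"
  ok <- apply(is.finite(x), 1L, all)
  n_excluded <- sum(!ok)
  if (n_excluded)
    message(sprintf("assemble_features: excluded %d pair(s) with undefined features", n_excluded))
  x <- x[ok, , drop = FALSE]
  y <- as.logical(pairs$buffering)[ok]
  if (!any(y) || all(y))
    pb_stop("single_class_error", "need both positive and negative examples")
  const <- apply(x, 2L, function(col) stats::sd(col) == 0)
  if (any(const))
    warning(paste0("constant feature column(s): ",
                   paste(colnames(x)[const], collapse = ", ")))
  ids <- (pairs$pair_id %||% seq_len(nrow(pairs)))[ok]
  list(x = x, y = y, pair_id = ids, n_excluded = n_excluded)
}

rbf_kernel <- function(a, b, gamma) {
  # ||ai - bj||^2 expanded; a, b are row-sample matrices
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' Train an RBF-kernel decision function
#'
#' Fits a regularized kernel least-squares classifier (the least-squares
#' formulation of the soft-margin kernel machine) on +/-1 labels:
#' `alpha = (K + I/cost)^-1 y` with `K_ij = exp(-gamma ||x_i - x_j||^2)`.
#' The returned model scores new points by `f(x) = k(x, X) alpha`; higher
#' scores mean more likely buffering. Deterministic given data and
#' hyperparameters.
#'
#' @param x numeric feature matrix (rows = examples).
#' @param y logical or 0/1 labels; both classes must be present.
#' @param gamma RBF kernel width parameter.
#' @param cost soft-margin cost; the ridge penalty is `1/cost`.
#' @return an object of class `rbf_classifier`; use [predict()] to score.
#' @export
train_rbf_classifier <- function(x, y, gamma = 1, cost = 1) {
  x <- as.matrix(x); y <- as.logical(y)
  if (!any(y) || all(y))
    pb_stop("single_class_error", "training data contains a single class")
  yy <- ifelse(y, 1, -1)
  K <- rbf_kernel(x, x, gamma)
  alpha <- solve(K + diag(1 / cost, nrow(K)), yy)
  structure(list(x = x, alpha = alpha, gamma = gamma, cost = cost),
            class = "rbf_classifier")
}

#' @export
predict.rbf_classifier <- function(object, newdata, ...) {
  drop(rbf_kernel(as.matrix(newdata), object$x, object$gamma) %*% object$alpha)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counted 1/2 (the Mann-Whitney statistic
#' normalized by n_pos * n_neg).
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param labels logical or 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as.logical(labels)
  if (!any(y) || all(y)) pb_stop("single_class_error", "need both classes for AUC")
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#' @param scores,labels as in [auc()].
#' @return data.frame with columns `fpr`, `tpr`, monotone non-decreasing.
#' @export
roc_points <- function(scores, labels) {
  y <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  tpr <- c(0, cumsum(y) / sum(y))
  fpr <- c(0, cumsum(!y) / sum(!y))
  data.frame(fpr = fpr, tpr = tpr)
}

stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f
}

standardize_fit <- function(x) {
  mu <- colMeans(x); sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1  # constant columns carry no information either way
  list(mu = mu, sd = sdv)
}
standardize_apply <- function(x, st) sweep(sweep(x, 2L, st$mu), 2L, st$sd, "/")

#' Stratified k-fold cross-validation of the kernel classifier
#'
#' Repeats a stratified `folds`-fold split `repeats` times. Within each
#' training fold, features are z-standardized using training-fold statistics
#' only, and `gamma`/`cost` are chosen by an inner stratified 3-fold grid
#' search maximizing AUC — the test fold never influences standardization
#' or hyperparameters. Per-fold test AUC is the rank statistic of [auc()].
#'
#' @param features output of [assemble_features()], or a list with `x`, `y`.
#' @param folds number of outer folds (default 3).
#' @param repeats independent fold draws (default 10); the reported sd is
#'   taken across all fold-level AUCs.
#' @param seed integer seed (mandatory for reproducibility).
#' @param feature_subset optional character vector of feature names (e.g.
#'   `"go_div"`) to restrict the model to.
#' @param gamma_grid,cost_grid hyperparameter grids for the inner search.
#' @return a `cv_result`: list with `auc_mean`, `auc_sd`, `fold_aucs`,
#'   `roc_points` (pooled test scores of the first repeat), `folds`,
#'   `repeats`, `seed`, `feature_subset`.
#' @export
cross_validate <- function(features, folds = 3L, repeats = 10L, seed,
                           feature_subset = NULL,
                           gamma_grid = c(0.01, 0.1, 1, 10),
                           cost_grid = c(0.1, 1, 10, 100)) {
  x <- features$x; y <- features$y
  if (!is.null(feature_subset)) {
    bad <- setdiff(feature_subset, colnames(x))
    if (length(bad))
      pb_stop("input_error", paste0("unknown feature(s): ", paste(bad, collapse = ", ")))
    x <- x[, feature_subset, drop = FALSE]
  }
  if (min(sum(y), sum(!y)) < folds)
    pb_stop("stratification_error", "a class is smaller than the number of folds")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold_aucs <- numeric(0)
  roc <- NULL
  for (rep_i in seq_len(repeats)) {
    f <- stratified_folds(y, folds)
    pooled_scores <- numeric(length(y)); pooled <- FALSE
    for (k in seq_len(folds)) {
      tr <- f != k; te <- f == k
      st <- standardize_fit(x[tr, , drop = FALSE])
      xtr <- standardize_apply(x[tr, , drop = FALSE], st)
      xte <- standardize_apply(x[te, , drop = FALSE], st)
      hp <- inner_grid_search(xtr, y[tr], gamma_grid, cost_grid)
      model <- train_rbf_classifier(xtr, y[tr], hp$gamma, hp$cost)
      sc <- predict(model, xte)
      fold_aucs <- c(fold_aucs, auc(sc, y[te]))
      pooled_scores[te] <- sc; pooled <- TRUE
    }
    if (rep_i == 1L && pooled) roc <- roc_points(pooled_scores, y)
  }
  structure(list(auc_mean = mean(fold_aucs), auc_sd = stats::sd(fold_aucs),
                 fold_aucs = fold_aucs, roc_points = roc,
                 folds = folds, repeats = repeats, seed = seed,
                 feature_subset = feature_subset),
            class = "cv_result")
}

inner_grid_search <- function(x, y, gamma_grid, cost_grid, inner_folds = 3L) {
  if (min(sum(y), sum(!y)) < inner_folds)
    return(list(gamma = gamma_grid[[1L]], cost = cost_grid[[1L]]))
  f <- stratified_folds(y, inner_folds)
  best <- list(gamma = gamma_grid[[1L]], cost = cost_grid[[1L]], auc = -Inf)
  for (g in gamma_grid) for (cc in cost_grid) {
    aucs <- numeric(inner_folds)
    for (k in seq_len(inner_folds)) {
      tr <- f != k
      m <- train_rbf_classifier(x[tr, , drop = FALSE], y[tr], g, cc)
      aucs[[k]] <- auc(predict(m, x[!tr, , drop = FALSE]), y[!tr])
    }
    if (mean(aucs) > best$auc) best <- list(gamma = g, cost = cc, auc = mean(aucs))
  }
  best
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> AUC = %.3f +/- %.3f (%d-fold x %d repeats%s)\n",
              x$auc_mean, x$auc_sd, x$folds, x$repeats,
              if (is.null(x$feature_subset)) ""
              else paste0(", features: ", paste(x$feature_subset, collapse = "+"))))
  invisible(x)
}
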