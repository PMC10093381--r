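#' Fit a Gaussian naive Bayes classifier
#'
#' Binary Gaussian naive Bayes written for the CN-cluster-4 membership
#' model: class priors are the observed class frequencies and each feature
#' gets a per-class sample mean and (unbiased) variance. Variances are
#' floored at `floor_rel` times the largest per-feature pooled variance so
#' constant features never produce degenerate densities.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y class labels, coercible to a factor with exactly two observed
#'   levels; the second level is the positive class.
#' @param floor_rel relative variance floor (default `1e-9`).
#' @return object of class `gnb` with elements `levels`, `prior`, `mean`,
#'   `var` (class x feature matrices) and `var_floor`.
#' @export
fit_gnb <- function(x, y, floor_rel = 1e-9) {
  x <- as.matrix(x)
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) != 2) {
    stop_("fit_gnb: need exactly 2 classes, got ", nlevels(y))
  }
  if (nrow(x) != length(y)) stop_("fit_gnb: x rows and y length differ")
  mu <- rowsum(x, y) / as.vector(table(y))
  v <- rowsum(x^2, y) / as.vector(table(y)) - mu^2
  # unbiased (n-1) per-class variances
  n_k <- as.vector(table(y))
  v <- sweep(v, 1, n_k / pmax(n_k - 1, 1), `*`)
  pooled <- apply(x, 2, stats::var)
  floor_val <- floor_rel * max(pooled, 0)
  if (floor_val <= 0) floor_val <- floor_rel
  v[!is.finite(v) | v < floor_val] <- floor_val
  structure(
    list(levels = levels(y),
         prior = as.vector(table(y)) / length(y),
         mean = mu, var = v, var_floor = floor_val,
         n_features = ncol(x), feature_names = colnames(x)),
    class = "gnb"
  )
}

#' Posterior class probabilities from a Gaussian naive Bayes model
#'
#' Log-space computation: per class, the log prior plus the sum of
#' univariate normal log densities across features, normalised with
#' log-sum-exp.
#'
#' @param object a fitted `gnb` model.
#' @param newdata numeric matrix (or single vector) of feature values; the
#'   number of columns must match the training matrix.
#' @param type `"posterior"` (matrix of class probabilities) or `"class"`.
#' @param threshold posterior cutoff on the positive (second) class used
#'   for `type = "class"`; default 0.5.
#' @param ... unused.
#' @return matrix of posteriors (columns = classes) or factor of classes.
#' @export
predict.gnb <- function(object, newdata, type = c("posterior", "class"),
                        threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop_("predict.gnb: expected ", object$n_features, " features, got ",
          ncol(newdata))
  }
  logp <- sapply(seq_along(object$levels), function(k) {
    mu <- object$mean[k, ]
    v <- object$var[k, ]
    ll <- -0.5 * (log(2 * pi * v)[col(newdata)] +
                    (t(t(newdata) - mu))^2 / v[col(newdata)])
    rowSums(ll) + log(object$prior[k])
  })
  if (is.null(dim(logp))) logp <- matrix(logp, nrow = 1)
  m <- apply(logp, 1, max)
  post <- exp(logp - m)
  post <- post / rowSums(post)
  colnames(post) <- object$levels
  rownames(post) <- rownames(newdata)
  if (type == "posterior") return(post)
  factor(ifelse(post[, 2] >= threshold, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' @export
print.gnb <- function(x, ...) {
  cat("Gaussian naive Bayes:", x$n_features, "features, classes",
      paste(x$levels, collapse = " / "),
      sprintf("(priors %.3f / %.3f)\n", x$prior[1], x$prior[2]))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Splits samples into `k` folds preserving class proportions: within each
#' class the (seed-shuffled) members are dealt round-robin, so per-class
#' fold sizes differ by at most one. The caller's RNG state is untouched.
#'
#' @param y class labels.
#' @param k number of folds (default 5).
#' @param seed integer seed making the assignment reproducible (default 1).
#' @return integer vector of fold ids in `1..k`, aligned with `y`.
#' @export
stratified_folds <- function(y, k = 5, seed = 1) {
  y <- factor(y)
  if (k < 2 || k > length(y)) stop_("k must be in [2, n]")
  small <- table(y) < k
  if (any(small)) {
    stop_("class '", names(which(small))[1], "' has fewer members than folds")
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  fold
}

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation with midranks for ties:
#' `AUC = (sum of positive-score ranks - n1(n1+1)/2) / (n1 * n0)`.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical/0-1 vector of true positives.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

binary_metrics <- function(truth, pred, positive = TRUE) {
  truth <- truth == positive
  pred <- pred == positive
  tp <- sum(truth & pred); fp <- sum(!truth & pred)
  fn <- sum(truth & !pred)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = mean(truth == pred), precision = prec, recall = rec, f1 = f1)
}

#' Stratified k-fold cross-validation of the CN-cluster-4 model
#'
#' Evaluates the Gaussian naive Bayes copy-number model by stratified
#' k-fold cross-validation. When `x` is a `cn_cohort`, the top-gene
#' selection and feature construction are re-run inside every training
#' fold, so held-out samples never influence which genes become features;
#' a plain feature matrix is also accepted (features then fixed a priori).
#'
#' Reported "averaged" metrics are unweighted means over folds; pooled
#' metrics over the concatenated out-of-fold predictions are kept
#' alongside for transparency.
#'
#' @param x a `cn_cohort` (with `genes`) or a numeric feature matrix.
#' @param y binary labels (positive = CN cluster 4 membership).
#' @param genes gene model data frame; required when `x` is a `cn_cohort`.
#' @param spec a [cn_feature_spec()].
#' @param k folds (default 5).
#' @param seed fold-shuffling seed (default 1).
#' @param threshold posterior cutoff for the positive class (default 0.5).
#' @return object of class `cv_report`: per-fold metric data frame,
#'   averaged and pooled metrics, out-of-fold posteriors, fold ids.
#' @export
cross_validate <- function(x, y, genes = NULL, spec = cn_feature_spec(),
                           k = 5, seed = 1, threshold = 0.5) {
  is_cohort <- inherits(x, "cn_cohort")
  if (is_cohort && is.null(genes)) stop_("cross_validate: genes required")
  n <- if (is_cohort) length(x$ploidy) else nrow(x)
  y <- factor(y)
  if (length(y) != n) stop_("cross_validate: labels do not match samples")
  fold <- stratified_folds(y, k = k, seed = seed)
  oof <- rep(NA_real_, n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    if (is_cohort) {
      train_cn <- subset_cn(x, !test)
      test_cn <- subset_cn(x, test)
      tr <- build_cn_features(train_cn, genes, spec)
      te <- build_cn_features(test_cn, genes, spec,
                              selected_genes = tr$selected_genes)
      xtr <- tr$features
      xte <- te$features
    } else {
      xtr <- x[!test, , drop = FALSE]
      xte <- x[test, , drop = FALSE]
    }
    model <- fit_gnb(xtr, y[!test])
    post <- predict(model, xte)[, 2]
    oof[test] <- post
    pred <- post >= threshold
    truth <- y[test] == levels(y)[2]
    per_fold[[f]] <- c(fold = f, binary_metrics(truth, pred),
                       roc_auc = roc_auc(post, truth))
  }
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  truth_all <- y == levels(y)[2]
  pooled <- c(binary_metrics(truth_all, oof >= threshold),
              roc_auc = roc_auc(oof, truth_all))
  structure(
    list(per_fold = per_fold,
         mean = colMeans(per_fold[, -1]),
         pooled = pooled,
         oof_posterior = oof, fold = fold,
         levels = levels(y), k = k, seed = seed),
    class = "cv_report"
  )
}

# restrict a cn_cohort to a logical/integer sample index
subset_cn <- function(cn, idx) {
  samples <- names(cn$ploidy)[idx]
  new_cn_cohort(
    cn$segments[cn$segments$sample %in% samples, , drop = FALSE],
    cn$ploidy[samples]
  )
}

#' @export
print.cv_report <- function(x, digits = 4, ...) {
  cat("Stratified ", x$k, "-fold cross-validation (positive class: ",
      x$levels[2], ")\n", sep = "")
  cat("Fold-averaged:\n")
  print(round(x$mean, digits))
  cat("Pooled out-of-fold:\n")
  print(round(x$pooled, digits))
  invisible(x)
}
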