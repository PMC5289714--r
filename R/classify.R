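#' Fit a logistic-regression classifier
#'
#' Maximum-likelihood logistic regression
#' `F(z) = 1 / (1 + exp(-z))`, `z = alpha + beta_1 X_1 + ... + beta_k X_k`
#' fitted by iteratively reweighted least squares. A tiny ridge penalty
#' (`lambda`, default 1e-6, never applied to the intercept) acts purely
#' as a numerical guard against coefficient divergence when the training
#' classes are linearly separable — common with few instances and
#' strongly selected features — and is negligible otherwise.
#'
#' @param X numeric matrix of predictors (instances x features).
#' @param y logical (or 0/1) response, positive class = `TRUE`.
#' @param lambda ridge strength of the separability guard.
#' @param threshold decision cutoff on the predicted probability.
#' @param maxit,tol IRLS iteration controls.
#' @return Object of class `logistic_model`: list with `alpha`, `beta`,
#'   `threshold`, `feature_names`, `converged`, `iterations`.
#' @export
fit_logistic <- function(X, y, lambda = 1e-6, threshold = 0.5,
                         maxit = 100, tol = 1e-9) {
  X <- as.matrix(X)
  y <- as.numeric(as.logical(y))
  if (length(unique(y)) < 2) stop("both classes must be present in `y`")
  if (anyNA(X)) stop("predictors must not contain NA")
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  Z <- cbind(1, X)
  p <- ncol(Z)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  coefs <- numeric(p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% coefs)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    grad <- crossprod(Z, y - mu) - pen %*% coefs
    H <- crossprod(Z * w, Z) + pen
    step <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-8, p), grad))
    coefs <- coefs + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  structure(list(alpha = coefs[1], beta = coefs[-1], threshold = threshold,
                 feature_names = colnames(X), converged = converged,
                 iterations = it),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> intercept %.3f, %d coefficients, threshold %.2f\n",
              x$alpha, length(x$beta), x$threshold))
  invisible(x)
}

#' Predict from a logistic model
#'
#' Returns `F(z) = 1 / (1 + exp(-z))` per instance and the hard label:
#' positive if and only if `F(z)` strictly exceeds the decision threshold
#' (so `F = 0.5` at the default threshold is classified negative).
#'
#' @param object a [fit_logistic()] model.
#' @param newdata matrix with the same columns the model was fitted on.
#' @param ... unused.
#' @return List with `prob` (numeric) and `label` (logical).
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$beta))
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$beta))
  z <- object$alpha + drop(X %*% object$beta)
  prob <- 1 / (1 + exp(-z))
  list(prob = prob, label = prob > object$threshold)
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and F-measure `2TP/(2TP+FP+FN)`. An empty denominator
#' yields `NA` (undefined), never 0.
#'
#' @param cm named vector or list with `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector with `sensitivity`, `specificity`,
#'   `accuracy`, `f_measure`.
#' @export
confusion_metrics <- function(cm) {
  TP <- cm[["TP"]]; FP <- cm[["FP"]]; TN <- cm[["TN"]]; FN <- cm[["FN"]]
  if (any(c(TP, FP, TN, FN) < 0)) stop("confusion counts must be >= 0")
  divide <- function(a, b) if (b > 0) a / b else NA_real_
  c(sensitivity = divide(TP, TP + FN),
    specificity = divide(TN, TN + FP),
    accuracy = divide(TP + TN, TP + TN + FP + FN),
    f_measure = divide(2 * TP, 2 * TP + FP + FN))
}

# stratified fold assignment at the unit level; units of each class are
# shuffled and dealt round-robin so fold class balance is maximal
.stratified_folds <- function(class, folds) {
  out <- integer(length(class))
  for (cl in unique(class)) {
    idx <- which(class == cl)
    if (length(idx) < folds)
      stop("class '", cl, "' has ", length(idx),
           " units; stratified ", folds, "-fold CV impossible")
    out[sample(idx)] <- rep(seq_len(folds), length.out = length(idx))
  }
  out
}

#' Repeated stratified k-fold cross-validated classification
#'
#' The full train/test-isolated pipeline of one experiment: per repeat a
#' stratified fold assignment is drawn (by default at the subject level,
#' so a subject's EC and EO instances share a fold); within each fold the
#' training instances alone determine the feature standardization, the
#' ROC (or mRMR) ranking, the correlation pruning and the top-k subset;
#' a logistic model is fitted on the training fold and evaluated on the
#' held-out fold; confusion counts are pooled per repeat. Metric
#' distributions over repeats are summarized as mean and SD.
#'
#' @param features a [feature_matrix()].
#' @param k_features subset size passed to [take_top()].
#' @param selector `"roc"` (rank-based, default) or `"mrmr"`.
#' @param folds number of CV folds (default 10).
#' @param repeats number of re-randomized repetitions (default 100).
#' @param seed integer seed controlling fold shuffling.
#' @param r_max correlation-pruning threshold (ROC selector only).
#' @param group_by_subject keep all instances of a subject in one fold
#'   (default `TRUE`); `FALSE` reproduces row-level fold assignment.
#' @param scope standardization scope: `"train-fold"` (z-scores from the
#'   training instances, default), `"reference"` (a fixed external
#'   healthy-control reference), or `"none"` (input is already
#'   standardized).
#' @param reference a [fit_reference()] result, required for
#'   `scope = "reference"`.
#' @param positive positive-class label (see [fm_labels()]).
#' @param threshold decision threshold for [fit_logistic()].
#' @param keep_fold_detail record per-fold selected indices and test
#'   rows (used to audit train/test isolation).
#' @return Object of class `cv_report`: list with `metrics` (repeats x 4
#'   matrix), `summary` (mean/sd per metric), `confusion` (per-repeat
#'   pooled counts), `folds`, `repeats`, `k_features`, `selector`, and
#'   optionally `fold_detail`.
#' @export
cross_validate <- function(features, k_features = 15,
                           selector = c("roc", "mrmr"), folds = 10,
                           repeats = 100, seed = 1, r_max = 0.9,
                           group_by_subject = TRUE,
                           scope = c("train-fold", "reference", "none"),
                           reference = NULL, positive = NULL,
                           threshold = 0.5, keep_fold_detail = FALSE) {
  stopifnot(inherits(features, "feature_matrix"))
  selector <- match.arg(selector)
  scope <- match.arg(scope)
  if (scope == "reference" && is.null(reference))
    stop("`scope = \"reference\"` needs a fitted `reference`")
  pos <- fm_labels(features, positive)
  X <- features$values
  n <- nrow(X)

  if (group_by_subject) {
    subj <- features$instance_meta$subject_id
    units <- unique(subj)
    unit_class <- pos[match(units, subj)]
    unit_of <- match(subj, units)
  } else {
    units <- seq_len(n)
    unit_class <- pos
    unit_of <- seq_len(n)
  }

  if (scope == "reference")
    X <- standardize(features, reference)$values

  set.seed(seed)
  metric_names <- c("sensitivity", "specificity", "accuracy", "f_measure")
  metrics <- matrix(NA_real_, repeats, 4,
                    dimnames = list(NULL, metric_names))
  confusion <- matrix(0L, repeats, 4,
                      dimnames = list(NULL, c("TP", "FP", "TN", "FN")))
  fold_detail <- if (keep_fold_detail) vector("list", repeats) else NULL

  for (r in seq_len(repeats)) {
    unit_fold <- .stratified_folds(unit_class, folds)
    fold_of <- unit_fold[unit_of]
    cm <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    detail <- if (keep_fold_detail) vector("list", folds) else NULL
    for (f in seq_len(folds)) {
      tr <- which(fold_of != f)
      te <- which(fold_of == f)
      if (length(te) == 0) next
      Xtr <- X[tr, , drop = FALSE]
      Xte <- X[te, , drop = FALSE]
      if (scope == "train-fold") {
        mu <- colMeans(Xtr)
        sg <- sqrt(pmax(colMeans(Xtr^2) - mu^2, 0) *
                     length(tr) / (length(tr) - 1))
        sg[sg == 0] <- 1                 # constant-in-fold features pass as 0
        Xtr <- sweep(sweep(Xtr, 2, mu, "-"), 2, sg, "/")
        Xte <- sweep(sweep(Xte, 2, mu, "-"), 2, sg, "/")
      }
      sel <- if (selector == "roc") {
        auc <- .auc_all(Xtr, pos[tr])
        ord <- order(-abs(auc), seq_along(auc))
        if (scope == "train-fold") {
          head(.prune_fast(ord, Xtr, r_max, k_features), k_features)
        } else {
          ranked <- auc_rank(Xtr, labels = pos[tr])
          ranked <- prune_correlated(ranked, Xtr, r_max = r_max,
                                     n_keep = k_features)
          take_top(ranked, min(k_features, length(ranked$retained)))
        }
      } else {
        mrmr_select(Xtr, k_features, labels = pos[tr])
      }
      model <- fit_logistic(Xtr[, sel, drop = FALSE], pos[tr],
                            threshold = threshold)
      pred <- predict(model, Xte[, sel, drop = FALSE])$label
      cm["TP"] <- cm["TP"] + sum(pred & pos[te])
      cm["FP"] <- cm["FP"] + sum(pred & !pos[te])
      cm["TN"] <- cm["TN"] + sum(!pred & !pos[te])
      cm["FN"] <- cm["FN"] + sum(!pred & pos[te])
      if (keep_fold_detail)
        detail[[f]] <- list(selected = sel, test_rows = te)
    }
    metrics[r, ] <- confusion_metrics(cm)
    confusion[r, ] <- cm
    if (keep_fold_detail) fold_detail[[r]] <- detail
  }

  structure(list(
    metrics = metrics,
    summary = data.frame(
      metric = metric_names,
      mean = colMeans(metrics),
      sd = apply(metrics, 2, sd),
      row.names = NULL),
    confusion = confusion,
    folds = folds, repeats = repeats, k_features = k_features,
    selector = selector, scope = scope,
    group_by_subject = group_by_subject,
    fold_detail = fold_detail),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %dx%d-fold CV, %s selector, k = %d\n",
              x$repeats, x$folds, x$selector, x$k_features))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f (+/- %.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Sweep classifier performance over feature-subset sizes
#'
#' Runs [cross_validate()] once per subset size (default: the canonical
#' 12-entry list 1, 2, 3, 4, 5, 10, 15, 20, 25, 30, 35, 50) to expose the
#' over-fitting profile of the classifier as the subset grows.
#'
#' @param features a [feature_matrix()].
#' @param sizes integer vector of subset sizes.
#' @param ... passed to [cross_validate()].
#' @return List of class `subset_sweep`: per-size `cv_report`s plus a
#'   `summary` data frame (one row per size and metric).
#' @export
subset_sweep <- function(features,
                         sizes = c(1, 2, 3, 4, 5, 10, 15, 20, 25, 30, 35, 50),
                         ...) {
  if (max(sizes) > ncol(features$values))
    stop("largest subset size exceeds the available features")
  reports <- lapply(sizes, function(k)
    cross_validate(features, k_features = k, ...))
  names(reports) <- as.character(sizes)
  summary <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    s <- reports[[i]]$summary
    s$subset_size <- sizes[i]
    s
  }))
  structure(list(reports = reports, summary = summary, sizes = sizes),
            class = "subset_sweep")
}

#' Combine the best features of several extraction methods
#'
#' Column-wise concatenation of the top `k_each` features per method
#' (e.g. 15 wavelet + 15 STFT + 15 EMD = 45 columns), on identical
#' instances.
#'
#' @param fms named list of [feature_matrix()] objects, one per method.
#' @param rankings optional list of [auc_rank()] results aligned with
#'   `fms`; when supplied, the top `k_each` retained features of each are
#'   taken, otherwise the matrices are used as passed.
#' @param k_each features to take per method.
#' @return A combined [feature_matrix()].
#' @export
combine_features <- function(fms, rankings = NULL, k_each = 15) {
  stopifnot(length(fms) >= 1)
  base_meta <- fms[[1]]$instance_meta
  parts <- lapply(seq_along(fms), function(i) {
    fm <- fms[[i]]
    if (!identical(dim(fm$values)[1], dim(fms[[1]]$values)[1]) ||
        !identical(fm$instance_meta$subject_id, base_meta$subject_id))
      stop("feature matrices must share identical instances")
    if (!is.null(rankings))
      fm <- fm_subset(fm, cols = take_top(rankings[[i]], k_each))
    fm
  })
  values <- do.call(cbind, lapply(parts, function(p) p$values))
  meta <- do.call(rbind, lapply(parts, function(p) p$feature_meta))
  meta$feature <- make.unique(meta$feature)
  feature_matrix(values, meta, base_meta)
}
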