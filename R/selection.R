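#' Fit the healthy-control normalization reference
#'
#' Per-feature means and standard deviations (n-1 denominator) computed
#' over the healthy-control instances. Zero-variance features cannot be
#' standardized and are dropped with a warning.
#'
#' @param controls a [feature_matrix()] of control instances (>= 2 rows).
#' @return Object of class `normalization_reference`: list with `mu`,
#'   `sigma`, `features` (names of retained columns), `n_reference`.
#' @export
fit_reference <- function(controls) {
  stopifnot(inherits(controls, "feature_matrix"))
  X <- controls$values
  if (nrow(X) < 2) stop("reference requires >= 2 control instances")
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  keep <- sigma > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance feature(s) dropped from the reference")
  structure(list(mu = mu[keep], sigma = sigma[keep],
                 features = colnames(X)[keep], n_reference = nrow(X)),
            class = "normalization_reference")
}

#' Standardize features against a reference
#'
#' Replaces every feature value by its z-score
#' `z = (x - mu) / sigma` with `mu`, `sigma` from the healthy-control
#' reference (or any [fit_reference()] result). Columns absent from the
#' reference (e.g. dropped for zero variance) are removed.
#'
#' @param patients a [feature_matrix()].
#' @param ref a [fit_reference()] result.
#' @return The standardized [feature_matrix()].
#' @export
standardize <- function(patients, ref) {
  stopifnot(inherits(patients, "feature_matrix"),
            inherits(ref, "normalization_reference"))
  cols <- match(ref$features, colnames(patients$values))
  if (anyNA(cols))
    stop("feature columns do not align with the reference")
  out <- fm_subset(patients, cols = cols)
  out$values <- sweep(sweep(out$values, 2, ref$mu, "-"), 2, ref$sigma, "/")
  out
}

## ---- ROC / AUC rank-based feature selection -------------------------------

# Empirical-ROC trapezoid AUC for one feature, the textbook-faithful
# route: stable descending sort (ties broken by original instance index),
# cumulative true/false-positive rates, trapezoid area, minus the chance
# area 0.5. Runs of tied feature values are collapsed to a single ROC
# step, which makes the result identical to the Mann-Whitney statistic
# with half credit for ties. Returns the per-instance trace used by the
# worked example.
.auc_trapezoid <- function(x, pos) {
  n <- length(x)
  ord <- order(x, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
  xs <- x[ord]
  ps <- pos[ord]
  n_pos <- sum(pos); n_neg <- n - n_pos
  tp <- cumsum(ps) / n_pos
  fp <- cumsum(!ps) / n_neg
  Y <- (tp[-1] + tp[-n]) / 2
  X <- fp[-1] - fp[-n]
  last <- c(xs[-n] != xs[-1], TRUE)   # last element of each tie run
  tpk <- c(0, tp[last]); fpk <- c(0, fp[last])
  auc <- sum(diff(fpk) * (tpk[-1] + tpk[-length(tpk)]) / 2) - 0.5
  list(auc = auc,
       trace = data.frame(value = xs, label = ifelse(ps, "+", "-"),
                          p = cumsum(ps), n = cumsum(!ps),
                          tp = tp, fp = fp),
       Y = Y, X = X)
}

# Vectorized Mann-Whitney formulation of the same quantity (midranks give
# exactly the tie-collapsed trapezoid area); used when ranking thousands
# of columns inside cross-validation folds. All columns are ranked with
# one radix sort; tied values (rare in continuous data) fall back to
# midranks column by column.
.auc_all <- function(X, pos) {
  n <- nrow(X); p <- ncol(X)
  colv <- rep.int(seq_len(p), rep.int(n, p))
  o <- order(colv, X, method = "radix")
  r <- numeric(n * p)
  r[o] <- rep.int(seq_len(n), p)
  xs <- X[o]
  ties <- xs[-1] == xs[-length(xs)] & colv[-1] == colv[-length(colv)]
  if (any(ties))
    for (j in unique(colv[o][which(ties)]))
      r[((j - 1) * n + 1):(j * n)] <- rank(X[, j])
  R <- matrix(r, n, p)
  n_pos <- sum(pos); n_neg <- n - n_pos
  (colSums(R[pos, , drop = FALSE]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg) - 0.5
}

# correlation pruning for columns that are already standardized
# (zero mean, unit n-1 variance): Pearson r = crossprod / (n - 1)
.prune_fast <- function(ord, X, r_max, n_keep) {
  kept <- integer(0)
  K <- NULL
  nm1 <- nrow(X) - 1
  for (j in ord) {
    if (length(kept) == 0 ||
        all(abs(crossprod(K, X[, j])) / nm1 < r_max)) {
      kept <- c(kept, j)
      K <- cbind(K, X[, j])
    }
    if (length(kept) >= n_keep) break
  }
  kept
}

#' Rank features by ROC area (the per-feature "z-value")
#'
#' For every feature the signed area between the empirical ROC curve and
#' the chance diagonal is computed: instances are sorted by descending
#' feature value, cumulative true- and false-positive rates accumulated,
#' and the trapezoid area minus 0.5 taken. The value lies in
#' `[-0.5, 0.5]`; its magnitude (the ranking key) measures the feature's
#' univariate ability to separate the two classes, and equals the
#' Mann-Whitney AUC minus one half (ties receiving half credit).
#' Features are ranked by `|auc|` in descending order.
#'
#' @param features a [feature_matrix()] with binary labels, or a plain
#'   matrix combined with `labels`.
#' @param labels optional logical vector of positive-class indicators
#'   (required when `features` is a plain matrix).
#' @param positive positive-class label passed to [fm_labels()].
#' @param trace keep the per-feature tp/fp/Y/X trace (memory-heavy; only
#'   sensible for small feature sets).
#' @return Object of class `ranked_features`: list with `order` (feature
#'   indices by descending `|auc|`), `auc` (signed, in input column
#'   order), `retained` (initialized to `order`; see
#'   [prune_correlated()]), `n_pos`, `n_neg`, and optionally `trace`.
#' @export
auc_rank <- function(features, labels = NULL, positive = NULL,
                     trace = FALSE) {
  if (inherits(features, "feature_matrix")) {
    X <- features$values
    pos <- fm_labels(features, positive)
  } else {
    X <- as.matrix(features)
    pos <- as.logical(labels)
  }
  if (is.null(pos) || length(unique(pos)) != 2)
    stop("both classes must be present")
  if (anyNA(X)) stop("feature matrix must not contain NA")
  if (trace) {
    per <- lapply(seq_len(ncol(X)), function(j) .auc_trapezoid(X[, j], pos))
    auc <- vapply(per, `[[`, numeric(1), "auc")
  } else {
    auc <- .auc_all(X, pos)
    per <- NULL
  }
  ord <- order(-abs(auc), seq_along(auc))
  structure(list(order = ord, auc = auc, retained = ord,
                 n_pos = sum(pos), n_neg = sum(!pos),
                 trace = per),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features> %d features (%d+/%d-), %d retained\n",
              length(x$auc), x$n_pos, x$n_neg, length(x$retained)))
  k <- min(5, length(x$order))
  cat("  top |auc|:", paste(sprintf("#%d=%.3f", x$order[1:k],
                                    x$auc[x$order[1:k]]), collapse = " "), "\n")
  invisible(x)
}

#' Discard highly correlated features from a ranking
#'
#' Greedy top-down pass over the ranked list: a feature is retained only
#' if its absolute Pearson correlation with every already-retained
#' feature stays below `r_max`, so of any highly correlated (redundant)
#' group only the best-ranked member survives.
#'
#' @param ranked an [auc_rank()] result over `features`.
#' @param features the same [feature_matrix()] (or matrix) the ranking
#'   was computed from.
#' @param r_max absolute-correlation threshold (default 0.9).
#' @param n_keep stop after retaining this many features (the downstream
#'   subset size); `Inf` scans the whole list.
#' @return The `ranked_features` object with `retained` updated.
#' @export
prune_correlated <- function(ranked, features, r_max = 0.9, n_keep = Inf) {
  stopifnot(inherits(ranked, "ranked_features"))
  X <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  Xc <- scale(X)                      # zero-variance -> NaN, never retained first?
  Xc[, apply(X, 2, sd) == 0] <- 0
  kept <- integer(0)
  n <- nrow(X)
  for (j in ranked$order) {
    if (length(kept) == 0) {
      kept <- j
    } else {
      r <- abs(crossprod(Xc[, kept, drop = FALSE], Xc[, j]) / (n - 1))
      if (all(r < r_max, na.rm = TRUE)) kept <- c(kept, j)
    }
    if (length(kept) >= n_keep) break
  }
  ranked$retained <- kept
  ranked
}

#' Take the top-k retained features
#'
#' First `k` indices of the pruned ranking. Inside cross-validation the
#' indices are always derived from the training fold and then reused,
#' unchanged, to column-subset the test fold.
#'
#' @param ranked a [prune_correlated()] (or [auc_rank()]) result.
#' @param k subset size; must not exceed the number retained.
#' @return Integer vector of feature column indices.
#' @export
take_top <- function(ranked, k) {
  stopifnot(inherits(ranked, "ranked_features"))
  if (k > length(ranked$retained))
    stop("k = ", k, " exceeds the ", length(ranked$retained),
         " retained features")
  head(ranked$retained, k)
}

## ---- mRMR -----------------------------------------------------------------

# equal-frequency 3-bin discretization (rank-based, robust to ties)
.discretize3 <- function(x) {
  r <- rank(x, ties.method = "first")
  cut(r, breaks = quantile(r, probs = seq(0, 1, length.out = 4)),
      include.lowest = TRUE, labels = FALSE)
}

.mutual_info <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy mRMR with the mutual-information difference (MID) criterion:
#' features are discretized into 3 equal-frequency bins, the first
#' selected feature maximizes `I(feature; label)`, and each subsequent
#' feature maximizes relevance minus mean redundancy
#' `I(f; y) - mean_s I(f; s)` over the already-selected set.
#'
#' @param features a [feature_matrix()] (or matrix plus `labels`).
#' @param k number of features to select (`<=` feature count).
#' @param labels,positive as in [auc_rank()].
#' @return Integer vector of `k` selected column indices, in selection
#'   order.
#' @export
mrmr_select <- function(features, k, labels = NULL, positive = NULL) {
  if (inherits(features, "feature_matrix")) {
    X <- features$values
    pos <- fm_labels(features, positive)
  } else {
    X <- as.matrix(features)
    pos <- as.logical(labels)
  }
  p <- ncol(X)
  if (k > p) stop("k = ", k, " exceeds the ", p, " available features")
  D <- apply(X, 2, .discretize3)
  rel <- apply(D, 2, .mutual_info, b = pos)
  selected <- unname(which.max(rel))
  red_sum <- numeric(p)
  while (length(selected) < k) {
    last <- selected[length(selected)]
    red_sum <- red_sum + apply(D, 2, .mutual_info, b = D[, last])
    score <- rel - red_sum / length(selected)
    score[selected] <- -Inf
    selected <- c(selected, unname(which.max(score)))
  }
  selected
}
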