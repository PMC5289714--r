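#' Kolmogorov-Smirnov standard-normality gate
#'
#' One-sample KS test of the (already standardized) feature values
#' against the standard normal distribution; returns 1 when standard
#' normality is rejected at the 5% level. Used to justify the
#' non-parametric rank-sum test for the topographic maps.
#'
#' @param x numeric vector (n >= 5).
#' @param alpha significance level.
#' @return Integer 0/1 decision.
#' @export
ks_normality <- function(x, alpha = 0.05) {
  if (length(x) < 5) stop("KS normality gate needs n >= 5")
  if (sd(x) == 0) {
    warning("constant input: standard normality rejected trivially")
    return(1L)
  }
  p <- suppressWarnings(ks.test(x, "pnorm")$p.value)
  as.integer(p < alpha)
}

#' Wilcoxon rank-sum topographic map
#'
#' Per scalp location, pools the selected delta/theta features of that
#' channel into one scalar per instance (the mean of the standardized
#' values by default), runs a two-sided Wilcoxon rank-sum test between
#' the two groups, and records the 0/1 decision at the 5% level: 1 means
#' the equal-medians null is rejected (displayed red), 0 not (blue).
#' Channels missing from the top-ranked subset are covered by extending
#' the ranking to `fallback_top_n` features; channels still absent fall
#' back to all of their features.
#'
#' @param features a standardized [feature_matrix()] with binary labels.
#' @param ranked optional [auc_rank()] result over the same matrix;
#'   `NULL` uses all features per channel.
#' @param top_n primary number of top-ranked features considered.
#' @param fallback_top_n extended ranking depth used to cover channels
#'   absent from the first `top_n`.
#' @param stratum_sex optional `"F"` or `"M"` restriction (gender
#'   stratification); `NULL` pools both.
#' @param stratum_condition optional `"EC"` or `"EO"` restriction.
#' @param aggregate `"mean"` pools a channel's features by averaging;
#'   `"best-p"` tests each feature and keeps the channel's smallest
#'   p-value (no correction, matching per-location 5% maps).
#' @param alpha per-channel significance level.
#' @param positive positive-class label.
#' @return Object of class `topo_map`: data frame with `channel`,
#'   `statistic`, `p`, `H`, plus attributes `stratum` and `montage`.
#' @export
wilcoxon_channel_map <- function(features, ranked = NULL, top_n = 15,
                                 fallback_top_n = 100,
                                 stratum_sex = NULL,
                                 stratum_condition = NULL,
                                 aggregate = c("mean", "best-p"),
                                 alpha = 0.05, positive = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  aggregate <- match.arg(aggregate)
  rows <- seq_len(nrow(features$values))
  im <- features$instance_meta
  if (!is.null(stratum_sex)) rows <- rows[im$sex[rows] == stratum_sex]
  if (!is.null(stratum_condition))
    rows <- rows[im$condition[rows] == stratum_condition]
  if (length(rows) == 0) {
    warning("empty stratum: skipped")
    return(NULL)
  }
  fm <- fm_subset(features, rows = rows)
  pos <- fm_labels(fm, positive)
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("each group needs >= 2 instances in the stratum")

  channels <- montage_1020()
  chan_of <- fm$feature_meta$channel
  sel_primary <- if (is.null(ranked)) seq_len(ncol(fm$values)) else
    head(ranked$order, top_n)
  sel_fallback <- if (is.null(ranked)) integer(0) else
    head(ranked$order, fallback_top_n)

  stat <- p <- rep(NA_real_, length(channels))
  for (ci in seq_along(channels)) {
    cols <- intersect(sel_primary, which(chan_of == channels[ci]))
    if (length(cols) == 0)
      cols <- intersect(sel_fallback, which(chan_of == channels[ci]))
    if (length(cols) == 0)
      cols <- which(chan_of == channels[ci])
    if (length(cols) == 0) next   # channel absent from the feature set
    if (aggregate == "mean") {
      v <- rowMeans(fm$values[, cols, drop = FALSE])
      wt <- suppressWarnings(wilcox.test(v[pos], v[!pos]))
      stat[ci] <- wt$statistic
      # fully tied samples degenerate the approximation: no evidence
      p[ci] <- if (is.na(wt$p.value)) 1 else wt$p.value
    } else {
      ps <- vapply(cols, function(j) {
        suppressWarnings(wilcox.test(fm$values[pos, j],
                                     fm$values[!pos, j])$p.value)
      }, numeric(1))
      best <- which.min(ps)
      stat[ci] <- NA_real_
      p[ci] <- ps[best]
    }
  }
  out <- data.frame(channel = channels, statistic = stat, p = p,
                    H = as.integer(!is.na(p) & p < alpha),
                    stringsAsFactors = FALSE)
  attr(out, "stratum") <- c(sex = stratum_sex %||% "all",
                            condition = stratum_condition %||% "all")
  attr(out, "montage") <- montage_coordinates()
  class(out) <- c("topo_map", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interpolate a binary topographic map onto a head disc
#'
#' Inverse-distance interpolation of the per-channel 0/1 decisions from
#' the two nearest electrodes onto a regular grid inside the unit head
#' disc. At an electrode location the surface equals that electrode's
#' value exactly.
#'
#' @param map a [wilcoxon_channel_map()] result (or any data frame with
#'   `channel` and `H`).
#' @param grid_n grid resolution per axis.
#' @param k number of nearest electrodes used (default 2).
#' @return List with `x`, `y` (grid axes) and `z` (matrix, `NA` outside
#'   the head disc).
#' @export
interpolate_topomap <- function(map, grid_n = 67, k = 2) {
  coords <- montage_coordinates()
  m <- merge(map, coords, by = "channel")
  miss <- is.na(m$H)
  if (any(miss)) m <- m[!miss, , drop = FALSE]
  ax <- seq(-1, 1, length.out = grid_n)
  z <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    gx <- ax[i]; gy <- ax[j]
    if (gx^2 + gy^2 > 1) next
    d <- sqrt((m$x - gx)^2 + (m$y - gy)^2)
    nearest <- order(d)[seq_len(min(k, length(d)))]
    if (d[nearest[1]] < 1e-9) {
      z[i, j] <- m$H[nearest[1]]
    } else {
      w <- 1 / d[nearest]
      z[i, j] <- sum(w * m$H[nearest]) / sum(w)
    }
  }
  list(x = ax, y = ax, z = z)
}

#' Plot a topographic map
#'
#' Base-graphics rendering of [interpolate_topomap()]: red marks
#' channels/regions with a significant group difference (H = 1), blue
#' without.
#'
#' @param x a `topo_map` object.
#' @param ... ignored.
#' @return Invisibly, the interpolated field.
#' @export
plot.topo_map <- function(x, ...) {
  field <- interpolate_topomap(x)
  cols <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
  graphics::image(field$x, field$y, field$z, zlim = c(0, 1), col = cols,
                  asp = 1, axes = FALSE, xlab = "", ylab = "",
                  main = paste("Rank-sum map,",
                               paste(attr(x, "stratum"), collapse = "/")))
  coords <- attr(x, "montage")
  graphics::points(coords$x, coords$y, pch = 21,
                   bg = ifelse(merge(coords, x, by = "channel",
                                     sort = FALSE)$H == 1, "red", "blue"))
  graphics::text(coords$x, coords$y + 0.08, coords$channel, cex = 0.6)
  invisible(field)
}

#' PCA scatter of a reduced feature set
#'
#' Principal components of the (standardized, typically top-15) feature
#' matrix; the first two component scores give the 2-D scatter
#' representation of the instances, with the fraction of variance each
#' component explains.
#'
#' @param features a [feature_matrix()] or plain matrix (>= 3 instances,
#'   >= 2 features).
#' @return List with `scores` (instances x 2), `variance_explained`
#'   (per component, full length), `groups` (instance labels when
#'   available).
#' @export
pca_scatter <- function(features) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  if (nrow(X) < 3 || ncol(X) < 2)
    stop("PCA scatter needs >= 3 instances and >= 2 features")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12)
    stop("feature matrix has rank < 2")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, 1:2, drop = FALSE],
       variance_explained = ve,
       groups = if (inherits(features, "feature_matrix"))
         features$instance_meta$group else NULL)
}
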