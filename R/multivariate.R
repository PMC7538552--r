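#' PCA of a feature-selected omics matrix
#'
#' Singular value decomposition of the per-feature centered matrix
#' (samples as observations). Variance explained by component k is
#' `sigma_k^2 / sum(sigma^2)`. The sign convention fixes each component so
#' that its largest-magnitude loading is positive, making results
#' reproducible across SVD implementations.
#'
#' @param m Numeric features x samples matrix (already restricted to the
#'   features of interest, e.g. [top_variable_features()]).
#' @param n_components Number of components to keep (default
#'   `min(dim) `, capped at the available rank dimensions).
#' @return A `pca_result` list: `scores` (samples x components, zero
#'   column means), `loadings` (features x components), and
#'   `variance_explained`.
#' @export
pca <- function(m, n_components = NULL) {
  n <- ncol(m)
  if (n < 2) stop("need at least two samples")
  max_comp <- min(n, nrow(m))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > n)
    stop("fewer samples than requested components")
  n_components <- min(n_components, max_comp)
  x <- t(m - rowMeans(m))                 # samples x features, feature-centered
  sv <- svd(x)
  flip <- vapply(seq_along(sv$d), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u %*% diag(sv$d, length(sv$d)), 2, flip, "*")
  loadings <- sweep(sv$v, 2, flip, "*")
  ve <- sv$d^2 / sum(sv$d^2)
  keep <- seq_len(n_components)
  dimnames(scores) <- list(colnames(m), paste0("PC", seq_along(sv$d)))
  dimnames(loadings) <- list(rownames(m), paste0("PC", seq_along(sv$d)))
  structure(
    list(scores = scores[, keep, drop = FALSE],
         loadings = loadings[, keep, drop = FALSE],
         variance_explained = ve[keep]),
    class = "pca_result"
  )
}

#' 95% group confidence ellipse in a 2D score space
#'
#' Classical bivariate confidence region for a group's mean scatter:
#' center at the group mean, axes along the eigenvectors of the 2x2 sample
#' covariance, semi-axis lengths `sqrt(lambda_j) * sqrt(2 * qf(level, 2,
#' n - 2))` — the bivariate Student/Hotelling scaling. A singular
#' covariance (e.g. collinear scores) yields a degenerate ellipse flagged
#' `degenerate = TRUE` with the zero axis reported as 0 (a segment), not
#' an error.
#'
#' @param scores2d Numeric n x 2 matrix of one group's scores.
#' @param level Coverage level in (0, 1), default 0.95.
#' @return An `ellipse_spec` list: `center`, `axes` (semi-axis lengths,
#'   decreasing), `angle` (radians, orientation of the major axis),
#'   `level`, `degenerate`.
#' @export
confidence_ellipse <- function(scores2d, level = 0.95) {
  scores2d <- as.matrix(scores2d)
  if (ncol(scores2d) != 2) stop("scores2d must have two columns")
  n <- nrow(scores2d)
  if (n < 3) stop("need >= 3 samples in the group")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  center <- colMeans(scores2d)
  cv <- stats::cov(scores2d)
  eg <- eigen(cv, symmetric = TRUE)
  radius <- sqrt(2 * stats::qf(level, 2, n - 2))
  lam <- pmax(eg$values, 0)
  axes <- sqrt(lam) * radius
  structure(
    list(center = center, axes = axes,
         angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
         level = level, degenerate = any(lam < .Machine$double.eps * max(lam, 1))),
    class = "ellipse_spec"
  )
}

#' Points on a confidence ellipse outline
#'
#' @param ellipse An `ellipse_spec`.
#' @param n_points Number of outline points.
#' @return n x 2 matrix of coordinates.
#' @export
ellipse_outline <- function(ellipse, n_points = 100) {
  th <- seq(0, 2 * pi, length.out = n_points)
  unit <- cbind(ellipse$axes[1] * cos(th), ellipse$axes[2] * sin(th))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  sweep(unit %*% t(rot), 2, ellipse$center, "+")
}

#' PCA scatter with group confidence ellipses
#'
#' Base-graphics PC1/PC2 scatter of a [pca()] result, one color per group,
#' with each group's [confidence_ellipse()] outline.
#'
#' @param pc A `pca_result`.
#' @param group Group factor per sample.
#' @param level Ellipse coverage (default 0.95).
#' @param main Plot title.
#' @export
plot_pca_groups <- function(pc, group, level = 0.95, main = "PCA") {
  group <- as.factor(group)
  s <- pc$scores[, 1:2, drop = FALSE]
  cols <- c("#1b6ca8", "#c0392b")[as.integer(group)]
  plot(s, col = cols, pch = 19, main = main,
       xlab = sprintf("PC1 (%.1f%%)", 100 * pc$variance_explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * pc$variance_explained[2]))
  for (g in levels(group)) {
    gs <- s[group == g, , drop = FALSE]
    if (nrow(gs) >= 3) {
      el <- confidence_ellipse(gs, level)
      if (!el$degenerate)
        graphics::lines(ellipse_outline(el),
                        col = c("#1b6ca8", "#c0392b")[match(g, levels(group))])
    }
  }
  invisible(pc)
}

#' Silhouette of a two-group split along one coordinate
#'
#' Mean silhouette width of the group labels using absolute distance on a
#' single axis (used to quantify PC1 group separation).
#'
#' @param x Numeric vector (e.g. PC1 scores).
#' @param group Two-level factor.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_1d <- function(x, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2)
  d <- abs(outer(x, x, "-"))
  sil <- vapply(seq_along(x), function(i) {
    own <- group == group[i]
    a <- mean(d[i, own & seq_along(x) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
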