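#' Principal component analysis of Procrustes shape coordinates
#'
#' Covariance-matrix PCA of the flattened aligned coordinates about their
#' mean — the universal ordination of geometric morphometrics. Components
#' with negligible eigenvalues (below `1e-10` of the leading one, or
#' beyond the shape-space dimension `3p - 7`) are dropped. On raw chord
#' coordinates the unit-size constraint leaves one second-order radial
#' component (around `1e-4` of the leading eigenvalue) that this cap
#' truncates; fits made with `gpa_align(project_tangent = TRUE)` have
#' exactly `3p - 7` non-zero components and conserve the total
#' coordinate variance exactly. Eigenvector
#' signs are fixed by making each component's largest-magnitude loading
#' positive, so score plots are reproducible.
#'
#' @param fit A `gpa_fit` with at least 3 records.
#' @return An object of class `shape_pca`: list with `scores` (`n x m`),
#'   `eigenvalues`, `percent_variance`, `loadings` (`3p x m`), `center`
#'   and `info`.
#' @export
shape_pca <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  n <- dim(fit$aligned)[3]
  if (n < 3L) stop("need at least 3 records")
  p <- dim(fit$aligned)[1]
  y <- t(apply(fit$aligned, 3, as.vector))
  ctr <- colMeans(y)
  yc <- sweep(y, 2, ctr)
  pc <- stats::prcomp(yc, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  m <- min(sum(ev > 1e-10 * ev[1]), shape_dimension(p), n - 1L)
  ev <- ev[seq_len(m)]
  load <- pc$rotation[, seq_len(m), drop = FALSE]
  scores <- pc$x[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  rownames(scores) <- dimnames(fit$aligned)[[3]]
  structure(list(scores = scores, eigenvalues = ev,
                 percent_variance = 100 * ev / sum(ev),
                 loadings = load, center = ctr, info = fit$info),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA:", nrow(x$scores), "records,", length(x$eigenvalues),
      "components\n  PC1-PC3 %var:",
      paste(sprintf("%.1f", utils::head(x$percent_variance, 3)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Export PC scores with two grouping labels for scatterplots
#'
#' @param pca A `shape_pca`.
#' @param labels_a,labels_b Character vectors, one label per record (e.g.
#'   sex and operator).
#' @param axes Two component indices to export (default PC1, PC2).
#' @return A list with `scores` (data frame: record, both labels, the two
#'   PC columns) and `centroids` (per-group mean scores for each
#'   labelling, stacked with a `label_set` column).
#' @export
group_scatter_export <- function(pca, labels_a, labels_b, axes = c(1, 2)) {
  stopifnot(inherits(pca, "shape_pca"))
  n <- nrow(pca$scores)
  if (length(labels_a) != n || length(labels_b) != n)
    stop("label vectors must have one entry per record")
  if (any(axes > ncol(pca$scores))) stop("requested axes beyond rank")
  sc <- pca$scores[, axes, drop = FALSE]
  colnames(sc) <- paste0("PC", axes)
  out <- data.frame(record = rownames(pca$scores),
                    label_a = as.character(labels_a),
                    label_b = as.character(labels_b),
                    sc, stringsAsFactors = FALSE, row.names = NULL)
  cent <- function(lab, set) {
    agg <- stats::aggregate(sc, by = list(group = lab), FUN = mean)
    data.frame(label_set = set, agg, stringsAsFactors = FALSE)
  }
  list(scores = out,
       centroids = rbind(cent(out$label_a, "a"), cent(out$label_b, "b")))
}

#' Scatterplot of two principal components with group symbols
#'
#' Base-graphics scatter of the requested PC scores, using one plotting
#' symbol per group.
#'
#' @param x A `shape_pca`.
#' @param labels Character vector of group labels, one per record.
#' @param axes Two component indices (default PC1, PC2).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the score matrix plotted.
#' @export
plot_shape_pca <- function(x, labels = NULL, axes = c(1, 2), ...) {
  stopifnot(inherits(x, "shape_pca"))
  sc <- x$scores[, axes, drop = FALSE]
  pv <- x$percent_variance[axes]
  grp <- if (is.null(labels)) factor(rep(1, nrow(sc))) else factor(labels)
  graphics::plot(sc, pch = as.integer(grp), col = as.integer(grp),
                 xlab = sprintf("PC%d (%.1f%%)", axes[1], pv[1]),
                 ylab = sprintf("PC%d (%.1f%%)", axes[2], pv[2]), ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(grp),
                     pch = seq_len(nlevels(grp)), col = seq_len(nlevels(grp)))
  invisible(sc)
}
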