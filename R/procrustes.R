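#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the standard size measure removed before shape
#' analysis. Invariant to translation and rotation; scales linearly with
#' the coordinates.
#'
#' @param config Numeric `p x 3` matrix of landmark coordinates (mm).
#' @return Positive scalar (mm).
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 3L) stop("need at least 3 landmarks")
  centred <- sweep(config, 2, colMeans(config))
  cs <- sqrt(sum(centred^2))
  if (cs <= .Machine$double.eps * nrow(config))
    stop("degenerate configuration: all landmarks coincide")
  cs
}

# Optimal rotation-only (det = +1) alignment of X onto Y (both centred),
# via SVD of the cross-product matrix with sign correction.
rotation_onto <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Generalized Procrustes superimposition
#'
#' Iterative least-squares alignment of all configurations: each is
#' centred, scaled to unit centroid size, and rotated (rotations only,
#' `det = +1`; reflections are never used, so true left-right anatomy is
#' preserved) onto the current consensus; the consensus is then
#' re-estimated and re-normalised to unit centroid size, until its
#' Procrustes displacement falls below `tol`. The first record's
#' orientation seeds the initial consensus, making the output
#' deterministic. No tangent-space projection is applied by default;
#' distances computed from the fit are Procrustes chord distances.
#'
#' @param dataset A [landmark_dataset()] with at least 2 records.
#' @param tol Convergence threshold on the consensus displacement.
#' @param max_iter Maximum number of iterations.
#' @param project_tangent If `TRUE`, orthogonally project aligned shapes
#'   onto the tangent plane at the consensus. Off by default.
#' @return An object of class `gpa_fit` with elements `aligned`
#'   (`p x 3 x n` shape coordinates), `centroid_sizes` (mm), `mean_shape`
#'   (`p x 3`, unit centroid size), `iterations`, `final_change`,
#'   `objective_trace` (sum of squared distances to the consensus after
#'   each iteration), `info` and `panel`.
#' @export
gpa_align <- function(dataset, tol = 1e-10, max_iter = 100,
                      project_tangent = FALSE) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- n_records(dataset)
  if (n < 2L) stop("need at least 2 configurations")
  p <- dim(dataset$coords)[1]
  cs <- numeric(n)
  aligned <- array(0, c(p, 3, n), dimnames = dimnames(dataset$coords))
  for (r in seq_len(n)) {
    X <- dataset$coords[, , r]
    X <- sweep(X, 2, colMeans(X))
    cs[r] <- centroid_size(dataset$coords[, , r])
    aligned[, , r] <- X / cs[r]
  }
  mean_shape <- aligned[, , 1]
  trace <- numeric(0)
  final_change <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (r in seq_len(n))
      aligned[, , r] <- aligned[, , r] %*% rotation_onto(aligned[, , r],
                                                         mean_shape)
    new_mean <- apply(aligned, c(1, 2), mean)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    final_change <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    trace <- c(trace, sum(apply(aligned, 3,
                                function(a) sum((a - mean_shape)^2))))
    if (final_change < tol) break
  }
  if (final_change >= tol)
    stop("GPA did not converge in ", max_iter,
         " iterations; objective trace: ",
         paste(signif(trace, 6), collapse = ", "))
  if (project_tangent) {
    mu <- as.vector(mean_shape)
    mu <- mu / sqrt(sum(mu^2))
    for (r in seq_len(n)) {
      v <- as.vector(aligned[, , r])
      aligned[, , r] <- array(v - sum(v * mu) * mu + mu, dim = c(p, 3))
    }
  }
  # report the coordinate-wise mean of the aligned sample (the unit-size
  # consensus is an internal iteration device)
  mean_shape <- apply(aligned, c(1, 2), mean)
  dimnames(mean_shape) <- dimnames(aligned)[1:2]
  structure(list(aligned = aligned, centroid_sizes = cs,
                 mean_shape = mean_shape, iterations = iter,
                 final_change = final_change, objective_trace = trace,
                 info = dataset$info, panel = dataset$panel),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes fit:", dim(x$aligned)[3], "records,",
      dim(x$aligned)[1], "landmarks;", x$iterations,
      "iterations (final change", format(x$final_change, digits = 3), ")\n")
  invisible(x)
}

#' Pairwise Procrustes shape distances of a fitted sample
#'
#' Entry (i, j) is the square root of the summed squared differences of
#' the aligned coordinates of records i and j — the full Procrustes chord
#' distance, a close approximation to the Riemannian distance at small
#' shape variation.
#'
#' @param fit A `gpa_fit`.
#' @return An object of class `shape_dist`: a symmetric `n x n` matrix
#'   with zero diagonal, dimnames set to the record ids.
#' @export
shape_distance_matrix <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  n <- dim(fit$aligned)[3]
  flat <- t(apply(fit$aligned, 3, as.vector))
  d <- as.matrix(stats::dist(flat))
  dimnames(d) <- list(dimnames(fit$aligned)[[3]], dimnames(fit$aligned)[[3]])
  structure(d, class = c("shape_dist", "matrix"))
}

#' Procrustes distance of every record to the sample mean shape
#'
#' @param fit A `gpa_fit`.
#' @return Named numeric vector of length n.
#' @export
distance_to_mean <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  d <- apply(fit$aligned, 3, function(a) sqrt(sum((a - fit$mean_shape)^2)))
  names(d) <- dimnames(fit$aligned)[[3]]
  d
}

#' Euclidean inter-landmark distance on raw coordinates
#'
#' Computed per record on the unsuperimposed mm coordinates, so the values
#' are in mm and invariant under rigid motion of each record.
#'
#' @param dataset A `landmark_dataset`.
#' @param landmark_a,landmark_b Landmark labels on the dataset's panel.
#' @return Named numeric vector, one distance (mm) per record.
#' @export
interlandmark_distance <- function(dataset, landmark_a, landmark_b) {
  ia <- match(landmark_a, dataset$panel$names)
  ib <- match(landmark_b, dataset$panel$names)
  if (is.na(ia)) stop("unknown landmark label: ", landmark_a)
  if (is.na(ib)) stop("unknown landmark label: ", landmark_b)
  d <- apply(dataset$coords, 3,
             function(m) sqrt(sum((m[ia, ] - m[ib, ])^2)))
  names(d) <- dimnames(dataset$coords)[[3]]
  d
}
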