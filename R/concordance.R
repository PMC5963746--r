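#' Pairwise inter-operator correlations of centroid size
#'
#' Pearson correlations between operators' centroid-size vectors over the
#' individuals both operators measured, plus the mean of the off-diagonal
#' pairs.
#'
#' @param cs Numeric vector of centroid sizes, one per record.
#' @param operator_ids,individual_ids Character vectors aligned with `cs`.
#' @return A list with `matrix` (symmetric operator-by-operator Pearson
#'   correlation matrix, unit diagonal) and `mean_pairwise`.
#' @export
pairwise_size_correlation <- function(cs, operator_ids, individual_ids) {
  stopifnot(length(cs) == length(operator_ids),
            length(cs) == length(individual_ids))
  ops <- sort(unique(operator_ids))
  m <- diag(1, length(ops))
  dimnames(m) <- list(ops, ops)
  for (i in seq_along(ops)) for (j in seq_along(ops)) {
    if (j <= i) next
    a <- operator_ids == ops[i]
    b <- operator_ids == ops[j]
    shared <- intersect(individual_ids[a], individual_ids[b])
    if (length(shared) < 3L)
      stop("operators ", ops[i], " and ", ops[j],
           " share fewer than 3 individuals")
    va <- cs[a][match(shared, individual_ids[a])]
    vb <- cs[b][match(shared, individual_ids[b])]
    m[i, j] <- m[j, i] <- stats::cor(va, vb)
  }
  list(matrix = m, mean_pairwise = mean(m[lower.tri(m)]))
}

#' Correlation of two shape distance matrices
#'
#' Pearson correlation over the strictly-lower-triangle entries of two
#' distance matrices sharing labels and order. No permutation (Mantel) P
#' is computed by default — the correlation is a congruence diagnostic,
#' not a bias test; set `mantel_perm > 0` for a seeded Mantel P value.
#'
#' @param dist_a,dist_b Symmetric matrices with identical dimnames, n >= 4.
#' @param mantel_perm Number of Mantel permutations (0 = none).
#' @param seed Seed for the Mantel permutations.
#' @return The correlation, with attribute `n_pairs`; if `mantel_perm > 0`
#'   also attribute `mantel_p`.
#' @export
distance_matrix_correlation <- function(dist_a, dist_b, mantel_perm = 0,
                                        seed = 1) {
  dist_a <- as.matrix(dist_a); dist_b <- as.matrix(dist_b)
  if (!identical(dimnames(dist_a)[[1]], dimnames(dist_b)[[1]]))
    stop("distance matrices must share labels in the same order")
  n <- nrow(dist_a)
  if (n < 4L) stop("need at least 4 records")
  lt <- lower.tri(dist_a)
  r <- stats::cor(dist_a[lt], dist_b[lt])
  attr(r, "n_pairs") <- sum(lt)
  if (mantel_perm > 0) {
    set.seed(as.integer(seed))
    perm_r <- replicate(mantel_perm, {
      o <- sample(n)
      stats::cor(dist_a[lt], dist_b[o, o][lt])
    })
    attr(r, "mantel_p") <- (1 + sum(perm_r >= as.numeric(r))) /
      (1 + mantel_perm)
  }
  r
}

#' UPGMA phenogram of a distance matrix
#'
#' Standard unweighted pair-group agglomeration with arithmetic averaging
#' (average linkage): merge heights are non-decreasing and the tree is
#' ultrametric. Ties between equal minimum distances are broken by the
#' lexicographic order of the cluster representatives' labels, so trees
#' are deterministic across platforms.
#'
#' @param distance_matrix Symmetric matrix with zero diagonal and labels.
#' @return An object of class `upgma_tree`: list with `merge`, `height`,
#'   `labels` (hclust-compatible), `hclust` and `phylo` (an
#'   [ape::as.phylo()] tree whose leaf-to-root path lengths equal half
#'   the merge heights).
#' @export
upgma_tree <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) < 2L) stop("need at least 2 records")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  ord <- order(labels)
  d <- d[ord, ord]
  labels <- labels[ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 hclust = hc, phylo = phy),
            class = "upgma_tree")
}

#' Write a phenogram as a newick file
#'
#' @param tree A `upgma_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenogram <- function(tree, path) {
  stopifnot(inherits(tree, "upgma_tree"))
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

# leaf index sets of every internal node of an hclust merge matrix
merge_leaf_sets <- function(merge) {
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    kids <- merge[i, ]
    sets[[i]] <- unlist(lapply(kids, function(k)
      if (k < 0) -k else sets[[k]]))
  }
  sets
}

#' Within-individual clustering counts on a replica phenogram
#'
#' Counts how many individuals' replicas cluster together on the tree:
#' a *triplet* individual is one whose k replica leaves form an exclusive
#' clade; a *pair-or-better* individual has at least two replicas forming
#' an exclusive two-leaf clade (or satisfies the triplet condition).
#'
#' @param tree A `upgma_tree` whose leaves are record ids.
#' @param individual_ids Named character vector mapping every leaf label
#'   to its individual id.
#' @return A list with `n_individuals`, `n_triplets`,
#'   `n_pairs_or_better`, and per-individual logical vectors `triplet`
#'   and `pair_or_better`.
#' @export
replica_cluster_counts <- function(tree, individual_ids) {
  stopifnot(inherits(tree, "upgma_tree"))
  leaves <- tree$labels
  unmapped <- setdiff(leaves, names(individual_ids))
  if (length(unmapped))
    stop("leaf/leaves without an individual mapping: ",
         paste(unmapped, collapse = ", "))
  ind_of_leaf <- individual_ids[leaves]
  inds <- unique(ind_of_leaf)
  sets <- merge_leaf_sets(tree$merge)
  clade_inds <- lapply(sets, function(s) ind_of_leaf[s])
  triplet <- pair <- stats::setNames(logical(length(inds)), inds)
  for (ind in inds) {
    k <- sum(ind_of_leaf == ind)
    triplet[ind] <- any(vapply(clade_inds, function(ci)
      length(ci) == k && all(ci == ind), TRUE))
    pair[ind] <- triplet[ind] || any(vapply(clade_inds, function(ci)
      length(ci) == 2L && all(ci == ind), TRUE))
  }
  list(n_individuals = length(inds),
       n_triplets = sum(triplet),
       n_pairs_or_better = sum(pair),
       triplet = triplet, pair_or_better = pair)
}

#' Relative (and trimmed) range of shape distances to the mean
#'
#' The ratio of the largest to the smallest per-record Procrustes
#' distance to the sample mean shape — a unit-free measure of how widely
#' a configuration's shape varies in the sample. The trimmed version
#' removes the `ceiling(trim_fraction/2 * n)` largest and smallest
#' distances (symmetric trimming: the statistic uses both extremes)
#' before taking the ratio, guarding against outliers. For very small
#' samples the trim is capped so that at least two distances remain, so
#' `trimmed_ratio` degrades gracefully to `ratio`.
#'
#' @param distances_to_mean Positive distances, n >= 3.
#' @param trim_fraction Total fraction to trim (default 0.05).
#' @return A list with `ratio`, `trimmed_ratio`, `trim_fraction`,
#'   `trim_method`.
#' @export
relative_range <- function(distances_to_mean, trim_fraction = 0.05) {
  d <- as.numeric(distances_to_mean)
  if (length(d) < 3L) stop("need at least 3 distances")
  if (any(d <= 0)) stop("zero or negative distance: ratio undefined")
  s <- sort(d)
  cut <- ceiling(trim_fraction / 2 * length(d))
  cut <- min(cut, (length(d) - 2L) %/% 2L)   # keep at least two values
  trimmed <- s[seq.int(cut + 1L, length(d) - cut)]
  list(ratio = max(s) / min(s),
       trimmed_ratio = max(trimmed) / min(trimmed),
       trim_fraction = trim_fraction,
       trim_method = "symmetric: ceil(f/2*n) dropped from each tail")
}
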