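# Independent oracles used across the suite. Each re-derives a quantity by
# the most direct route available (direct summation, closed form, exhaustive
# enumeration) without touching the code paths it checks.

# centroid size by direct summation
brute_centroid_size <- function(X) {
  ctr <- colMeans(X)
  sqrt(sum(apply(X, 1, function(v) sum((v - ctr)^2))))
}

# closed-form two-configuration orthogonal Procrustes distance:
# both centred and scaled to unit CS, optimal rotation (det +1) by SVD,
# distance = sqrt(sum((A - B R)^2))
brute_pair_procrustes <- function(A, B) {
  norm_cfg <- function(X) {
    X <- sweep(X, 2, colMeans(X))
    X / sqrt(sum(X^2))
  }
  A <- norm_cfg(A); B <- norm_cfg(B)
  s <- svd(crossprod(B, A))
  R <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
  sqrt(sum((A - B %*% R)^2))
}

# ODEV / AVEDEV by explicit loops over individuals, landmarks, operators
brute_odev <- function(dataset) {
  info <- dataset$info
  ops <- sort(unique(info$operator_id))
  out <- list()
  for (ind in unique(info$individual_id)) {
    rec <- which(info$individual_id == ind)
    rec <- rec[match(ops, info$operator_id[rec])]
    for (lm in seq_len(dim(dataset$coords)[1])) {
      pos <- t(sapply(rec, function(r) dataset$coords[lm, , r]))
      ctr <- colMeans(pos)
      od <- sapply(seq_along(ops), function(o) sqrt(sum((pos[o, ] - ctr)^2)))
      out[[length(out) + 1]] <- data.frame(
        individual_id = ind, landmark = dataset$panel$names[lm],
        operator_id = ops, odev = od, avedev = mean(od),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# exhaustive UPGMA: repeatedly merge the closest pair, averaging distances
# weighted by cluster size; returns merge heights and leaf partitions
brute_upgma <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(nrow(d)))
  active <- rep(TRUE, nrow(d))
  heights <- numeric(0)
  members <- list()
  dd <- d
  sizes <- rep(1, nrow(d))
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); bestv <- Inf
    for (i in idx) for (j in idx) if (i < j && dd[i, j] < bestv) {
      bestv <- dd[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bestv)
    newclu <- c(clusters[[i]], clusters[[j]])
    members[[length(members) + 1]] <- sort(labels[newclu])
    for (k in idx) if (k != i && k != j)
      dd[i, k] <- dd[k, i] <-
        (sizes[i] * dd[i, k] + sizes[j] * dd[j, k]) / (sizes[i] + sizes[j])
    sizes[i] <- sizes[i] + sizes[j]
    clusters[[i]] <- newclu
    active[j] <- FALSE
  }
  list(heights = heights, members = members)
}

# percentile by sorting and linear interpolation between order statistics
brute_percentile <- function(v, prob) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * prob + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# small deterministic fixture: random configurations around the template
random_dataset <- function(n_ind = 4, operators = c("A", "B"), seed = 42,
                           noise = 1, panel = default_panel()) {
  set.seed(seed)
  template <- make_template(panel)
  p <- nrow(template)
  n_rec <- n_ind * length(operators)
  coords <- array(0, c(p, 3, n_rec))
  info <- data.frame(individual_id = rep(sprintf("i%02d", seq_len(n_ind)),
                                         each = length(operators)),
                     operator_id = rep(operators, n_ind),
                     sex = "F", replicate_id = "r1",
                     stringsAsFactors = FALSE)
  base <- lapply(seq_len(n_ind), function(i)
    template + matrix(rnorm(p * 3, sd = 2), p, 3))
  r <- 0L
  for (i in seq_len(n_ind)) for (o in operators) {
    r <- r + 1L
    coords[, , r] <- base[[i]] + matrix(rnorm(p * 3, sd = noise), p, 3)
  }
  landmark_dataset(panel, coords, info)
}

# random rigid motion (rotation with det +1, plus translation)
random_rigid <- function(X, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(M))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(X %*% q, 2, rnorm(3, sd = 10), `+`)
}

# leaf sets of each internal node of an hclust-style merge matrix
merge_leaf_sets_test <- function(merge) {
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    sets[[i]] <- unlist(lapply(merge[i, ], function(k)
      if (k < 0) -k else sets[[k]]))
  }
  sets
}

record_ids_test <- function(info) {
  paste(info$individual_id, info$operator_id, info$replicate_id, sep = "_")
}
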