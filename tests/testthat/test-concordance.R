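test_that("size correlations: limits and the textbook formula", {
  ind <- rep(sprintf("i%02d", 1:20), each = 2)
  op <- rep(c("A", "B"), 20)
  set.seed(3)
  v <- rnorm(20, mean = 100, sd = 5)
  # identical vectors
  cs <- v[match(ind, sprintf("i%02d", 1:20))]
  res <- pairwise_size_correlation(cs, op, ind)
  expect_equal(res$matrix["A", "B"], 1)
  # one vector negated around its mean
  cs2 <- cs
  cs2[op == "B"] <- 2 * mean(v) - cs2[op == "B"]
  expect_equal(pairwise_size_correlation(cs2, op, ind)$matrix["A", "B"], -1)
  # random data vs direct covariance/SD computation
  w <- v + rnorm(20)
  cs3 <- ifelse(op == "A", v[match(ind, sprintf("i%02d", 1:20))],
                w[match(ind, sprintf("i%02d", 1:20))])
  r <- pairwise_size_correlation(cs3, op, ind)$matrix["A", "B"]
  direct <- mean((v - mean(v)) * (w - mean(w))) /
    (stats::sd(v) * stats::sd(w)) * 20 / 19
  expect_equal(r, direct)
  expect_error(pairwise_size_correlation(cs[1:4], op[1:4], ind[1:4]),
               "fewer than 3")
})

test_that("distance-matrix correlation uses the n(n-1)/2 lower triangle", {
  set.seed(5)
  y <- matrix(rnorm(20 * 3), 20)
  d <- as.matrix(dist(y))
  dimnames(d) <- list(paste0("r", 1:20), paste0("r", 1:20))
  r <- distance_matrix_correlation(d, d)
  expect_equal(as.numeric(r), 1)
  expect_equal(attr(r, "n_pairs"), 190)
  expect_equal(as.numeric(distance_matrix_correlation(d, 2 * d + 3)), 1)
  d2 <- d[c(2, 1, 3:20), c(2, 1, 3:20)]
  expect_error(distance_matrix_correlation(d, d2), "labels")
})

test_that("UPGMA on a hand-computable 3-leaf matrix", {
  d <- matrix(c(0, 2, 10, 2, 0, 10, 10, 10, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d)
  expect_equal(sort(tr$height), c(2, 10))
  # ultrametric leaf depths: A,B at 1; C joins at 5
  phy <- tr$phylo
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_equal(unname(depths[match(c("A", "B", "C"), phy$tip.label)]),
               c(5, 5, 5))
  # the first merge is the exclusive (A, B) clade at height 2 -> branch 1
  counts <- replica_cluster_counts(tr, c(A = "x", B = "x", C = "y"))
  expect_equal(counts$n_pairs_or_better, 1)
})

test_that("UPGMA matches the exhaustive reference on random 6-leaf matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    y <- matrix(rnorm(18), 6)
    d <- as.matrix(dist(y))
    dimnames(d) <- list(paste0("t", 1:6), paste0("t", 1:6))
    tr <- upgma_tree(d)
    ref <- brute_upgma(d)
    expect_equal(sort(tr$height), sort(ref$heights), tolerance = 1e-12)
    sets <- lapply(merge_leaf_sets_test(tr$merge),
                   function(s) sort(tr$labels[s]))
    expect_setequal(lapply(sets, paste, collapse = "|"),
                    lapply(ref$members, paste, collapse = "|"))
  }
})

test_that("merge heights are non-decreasing along every path (ultrametricity)", {
  sim <- generate_replica_study(synthetic_spec(n_individuals = 8), seed = 83)
  fit <- gpa_align(sim$dataset)
  tr <- upgma_tree(shape_distance_matrix(fit))
  expect_true(all(diff(tr$height) >= -1e-12))
  # exactly ultrametric input is reconstructed exactly
  phy <- tr$phylo
  coph <- ape::cophenetic.phylo(phy)
  tr2 <- upgma_tree(coph)
  expect_equal(sort(tr2$height), sort(tr$height), tolerance = 1e-9)
})

test_that("asymmetric input is rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(upgma_tree(d), "symmetric")
})

test_that("zero-noise replicas cluster in triplets for all individuals", {
  spec <- synthetic_spec(noise_sd_bone = 0, noise_sd_soft = 0,
                         operator_bias = 0)
  sim <- generate_replica_study(spec, seed = 89)
  ds <- sim$dataset
  fit <- gpa_align(ds)
  tr <- upgma_tree(shape_distance_matrix(fit))
  leaf_map <- setNames(ds$info$individual_id,
                       paste(ds$info$individual_id, ds$info$operator_id,
                             ds$info$replicate_id, sep = "_"))
  counts <- replica_cluster_counts(tr, leaf_map)
  expect_equal(counts$n_triplets, 20)
  expect_equal(counts$n_pairs_or_better, 20)
})

test_that("a grafted replica breaks exactly the affected triplet", {
  # constructed ultrametric distances: individual x's replicas tight,
  # individual y's third replica closer to z's cluster
  labs <- c("x:1", "x:2", "x:3", "y:1", "y:2", "y:3", "z:1", "z:2", "z:3")
  d <- matrix(8, 9, 9, dimnames = list(labs, labs))
  diag(d) <- 0
  tight <- function(i, j, v) d[i, j] <<- d[j, i] <<- v
  tight("x:1", "x:2", 1); tight("x:1", "x:3", 1); tight("x:2", "x:3", 1)
  tight("y:1", "y:2", 1)
  tight("z:1", "z:2", 1); tight("z:1", "z:3", 1); tight("z:2", "z:3", 1)
  # y:3 sits inside z's neighbourhood
  tight("y:3", "z:1", 2); tight("y:3", "z:2", 2); tight("y:3", "z:3", 2)
  for (a in c("y:1", "y:2")) tight(a, "y:3", 6)
  tr <- upgma_tree(d)
  counts <- replica_cluster_counts(tr, setNames(sub(":.*", "", labs), labs))
  expect_false(counts$triplet[["y"]])
  expect_true(counts$triplet[["x"]])
  expect_true(counts$triplet[["z"]])
  expect_true(counts$pair_or_better[["y"]])   # y:1,y:2 still a pair
  expect_equal(counts$n_triplets, 2)
  expect_gte(counts$n_pairs_or_better, counts$n_triplets)
})

test_that("triplet counts do not increase with digitizing noise", {
  noise <- c(0.1, 0.6, 1.2, 2.5, 5, 10)
  trip <- sapply(noise, function(s) {
    spec <- synthetic_spec(noise_sd_bone = s, noise_sd_soft = s,
                           operator_bias = 0)
    sim <- generate_replica_study(spec, seed = 1000)
    fit <- gpa_align(sim$dataset)
    tr <- upgma_tree(shape_distance_matrix(fit))
    info <- sim$dataset$info
    leaf_map <- setNames(info$individual_id, record_ids_test(info))
    replica_cluster_counts(tr, leaf_map)$n_triplets
  })
  expect_true(all(diff(trip) <= 1))  # non-increasing up to one-step jitter
  expect_gt(trip[1], trip[length(trip)])
})

test_that("relative range: ratio, trimming and the sort-and-slice oracle", {
  expect_equal(relative_range(c(1, 2, 4))$ratio, 4)
  expect_equal(relative_range(rep(3, 10))$ratio, 1)
  set.seed(13)
  d <- rlnorm(100)
  rr <- relative_range(d, trim_fraction = 0.05)
  s <- sort(d)
  cut <- ceiling(0.025 * 100)
  expect_equal(rr$trimmed_ratio, s[100 - cut] / s[cut + 1])
  expect_gte(rr$ratio, rr$trimmed_ratio)
  expect_gte(rr$trimmed_ratio, 1)
  expect_error(relative_range(c(0, 1, 2)), "undefined")
})

test_that("newick export round-trips through ape", {
  sim <- generate_replica_study(synthetic_spec(n_individuals = 4), seed = 97)
  fit <- gpa_align(sim$dataset)
  tr <- upgma_tree(shape_distance_matrix(fit))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_phenogram(tr, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, tr$labels)
})
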