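test_that("r2_from_ss reproduces published-table arithmetic", {
  expect_equal(round(r2_from_ss(2548.6, 2609.9)), 98)
  expect_equal(round(r2_from_ss(0.0626, 0.1940)), 32)
  expect_equal(r2_from_ss(0, 5), 0)
  expect_error(r2_from_ss(1, 0), "positive")
  expect_error(r2_from_ss(2, 1))
})

test_that("the adopted ICC formula reproduces all six published MS pairs", {
  pairs <- list(c(134.1, 1.5), c(100.3, 1.6), c(24.1, 2.5),
                c(0.000203, 0.000037), c(0.000301, 0.000068),
                c(0.001970, 0.000206))
  printed <- c(0.98, 0.97, 0.81, 0.69, 0.63, 0.81)
  got <- sapply(pairs, function(p) icc_from_ms(p[1], p[2])$icc)
  expect_equal(round(got, 2), printed)
  # the classical one-way k=3 variant does NOT reproduce them
  oneway <- sapply(pairs, function(p)
    icc_from_ms(p[1], p[2], variant = "oneway", k = 3)$icc)
  expect_false(all(round(oneway, 2) == printed))
  # limits
  expect_equal(icc_from_ms(5, 0)$icc, 1)
  expect_equal(icc_from_ms(5, 5)$icc, 0)
  expect_error(icc_from_ms(0, 0), "undefined")
})

test_that("shape repeatability df follow the (3p-7)-scaled convention", {
  sim <- generate_replica_study(synthetic_spec(), seed = 43)
  ds <- sim$dataset
  for (cfg in list(list("all", 722, 1520), list("bone", 437, 920),
                   list("nose", 152, 320))) {
    fit <- gpa_align(select_subset(ds, cfg[[1]]))
    tab <- repeatability_anova(fit, ds$info$individual_id, "shape")$anova
    expect_equal(tab$rows$df[1], cfg[[2]])
    expect_equal(tab$rows$df[2], cfg[[3]])
  }
  # size stays univariate
  cs <- apply(ds$coords, 3, centroid_size)
  tabz <- repeatability_anova(cs, ds$info$individual_id, "size")$anova
  expect_equal(tabz$rows$df[1:2], c(19, 40))
})

test_that("every emitted table satisfies SS additivity and R2 conservation", {
  sim <- generate_replica_study(synthetic_spec(), seed = 47)
  ds <- sim$dataset
  fit <- gpa_align(ds)
  tabs <- list(
    repeatability_anova(fit, ds$info$individual_id, "shape")$anova,
    repeatability_anova(fit$centroid_sizes, ds$info$individual_id, "size")$anova,
    grouping_anova(fit, ds$info$operator_id, "shape"),
    grouping_anova(fit$centroid_sizes, ds$info$operator_id, "size"))
  st <- generate_study_sample(seed = 47)
  fit2 <- gpa_align(st$dataset)
  tabs <- c(tabs, list(
    hierarchical_anova(fit2, st$dataset$info$sex,
                       st$dataset$info$operator_id, "shape"),
    hierarchical_anova(fit2$centroid_sizes, st$dataset$info$sex,
                       st$dataset$info$operator_id, "size")))
  for (tab in tabs) {
    rows <- tab$rows
    eff <- rows$effect != "total"
    tot <- rows$SS[!eff]
    expect_equal(sum(rows$SS[eff]), tot, tolerance = 1e-9)
    expect_equal(sum(rows$df[eff]), rows$df[!eff])
    expect_equal(sum(rows$R2[eff]), 100, tolerance = 1e-6)
    expect_equal(rows$MS[eff], rows$SS[eff] / rows$df[eff])
  }
})

test_that("shape ANOVA on one retained coordinate equals the univariate oracle", {
  sim <- generate_replica_study(synthetic_spec(n_individuals = 8), seed = 53)
  ds <- sim$dataset
  fit <- gpa_align(ds)
  # a single aligned coordinate treated as a univariate response
  y <- fit$aligned[4, 2, ]
  ind <- ds$info$individual_id
  fitaov <- stats::aov(y ~ factor(ind))
  ss <- summary(fitaov)[[1]][["Sum Sq"]]
  tab <- repeatability_anova(y, ind, "size")$anova
  expect_equal(tab$rows$SS[1], ss[1], tolerance = 1e-9)
  expect_equal(tab$rows$SS[2], ss[2], tolerance = 1e-9)
  expect_equal(tab$rows$F[1], summary(fitaov)[[1]][["F value"]][1],
               tolerance = 1e-9)
})

test_that("ICC recovers the one-way variance-component expectation", {
  # sigma2_between = 9, sigma2_within = 1, n = 200, k = 3:
  # expected symmetric ICC = (MSa - MSw)/(MSa + MSw) with
  # E[MSa] = k*sb2 + sw2 = 28, E[MSw] = 1 -> 27/29 = 0.931
  set.seed(99)
  n <- 200; k <- 3
  mu <- rnorm(n, sd = 3)
  y <- rep(mu, each = k) + rnorm(n * k, sd = 1)
  ind <- rep(sprintf("i%03d", 1:n), each = k)
  res <- repeatability_anova(y, ind, "size")
  expect_equal(res$icc$icc, 27 / 29, tolerance = 0.05)
})

test_that("unbalanced replication is rejected", {
  sim <- generate_replica_study(synthetic_spec(n_individuals = 4), seed = 57)
  ds <- filter_records(sim$dataset, seq_len(12) != 2)
  fitcs <- apply(ds$coords, 3, centroid_size)
  expect_error(repeatability_anova(fitcs, ds$info$individual_id, "size"),
               "unbalanced")
})

test_that("grouping ANOVA: null R2 matches the exchangeable expectation", {
  # with g groups of equal size and no group structure,
  # E[R2] = (g - 1)/(n - 1)
  set.seed(7)
  r2s <- replicate(50, {
    y <- rnorm(30)
    g <- sample(rep(c("A", "B", "C"), 10))
    grouping_anova(y, g, "size")$rows$R2[1] / 100
  })
  expect_equal(mean(r2s), 2 / 29, tolerance = 0.03)
})

test_that("identical groups with zero within-replica noise give zero between-SS", {
  spec <- synthetic_spec(noise_sd_bone = 0, noise_sd_soft = 0,
                         operator_bias = 0)
  sim <- generate_replica_study(spec, seed = 59)
  fit <- gpa_align(sim$dataset)
  tab <- grouping_anova(fit, sim$dataset$info$operator_id, "shape")
  expect_lt(tab$rows$SS[1], 1e-18)
})

test_that("hierarchical ANOVA: single sex reduces to the grouping table", {
  sim <- generate_replica_study(synthetic_spec(n_individuals = 6), seed = 61)
  ds <- sim$dataset
  fit <- gpa_align(ds)
  h <- hierarchical_anova(fit, ds$info$sex, ds$info$operator_id, "shape")
  g <- grouping_anova(fit, ds$info$operator_id, "shape")
  expect_equal(h$rows$SS, g$rows$SS)
  expect_equal(h$rows$R2, g$rows$R2)
})

test_that("hierarchical ANOVA recovers designed dimorphism with no bias", {
  sex_r2 <- sapply(1:10, function(s) {
    spec <- synthetic_spec(replicate_design = "partition", operator_bias = 0)
    sim <- generate_study_sample(spec, seed = 700 + s)
    ds <- sim$dataset
    fit <- gpa_align(ds)
    tabz <- hierarchical_anova(fit$centroid_sizes, ds$info$sex,
                               ds$info$operator_id, "size")
    c(sex = tabz$rows$R2[1],
      op = hierarchical_anova(fit, ds$info$sex, ds$info$operator_id,
                              "shape")$rows$R2[2])
  })
  # operator R2 below 1% when no bias was designed in
  expect_lt(max(sex_r2["op", ]), 1)
  # size sex R2 within 5 points of its across-seed mean and far from 0
  expect_lt(max(abs(sex_r2["sex", ] - mean(sex_r2["sex", ]))), 5)
  expect_gt(min(sex_r2["sex", ]), 30)
})

test_that("balanced subsample draws the requested design and is seeded", {
  sim <- generate_study_sample(seed = 67)
  b1 <- balanced_subsample_r2(sim$dataset, 50, seed = 7, trait = "size")
  expect_equal(b1$n, 300)
  expect_equal(length(b1$sampled_ids), 300)
  b2 <- balanced_subsample_r2(sim$dataset, 50, seed = 7, trait = "size")
  expect_identical(b1$sampled_ids, b2$sampled_ids)
  expect_equal(b1$anova$rows$R2, b2$anova$rows$R2)
  expect_error(balanced_subsample_r2(sim$dataset, 500), "fewer")
})

test_that("balanced and unbalanced R2 agree on bias-free data", {
  diffs <- sapply(1:10, function(s) {
    spec <- synthetic_spec(replicate_design = "partition", operator_bias = 0)
    sim <- generate_study_sample(spec, seed = 800 + s)
    ds <- sim$dataset
    cs <- apply(ds$coords, 3, centroid_size)
    full <- hierarchical_anova(cs, ds$info$sex, ds$info$operator_id, "size")
    bal <- balanced_subsample_r2(ds, 50, seed = s, trait = "size")
    full$rows$R2[1] - bal$anova$rows$R2[1]
  })
  # the balanced estimate is a single 300-record draw with a sampling SD
  # of roughly 2 R2 points, so bound the mean tightly and the worst single
  # draw loosely (~3 SD)
  expect_lt(mean(abs(diffs)), 2.5)
  expect_lt(max(abs(diffs)), 8)
})

test_that("permutation P of the repeatability F is uniform under the null", {
  set.seed(11)
  pvals <- replicate(150, {
    y <- rnorm(24)               # 8 pseudo-individuals x 3 replicas, pure noise
    ind <- rep(sprintf("i%d", 1:8), each = 3)
    repeatability_anova(y, ind, "size", n_perm = 99,
                        perm_seed = sample.int(1e6, 1))$anova$rows$P_perm[1]
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("parametric F equals the mean-square ratio", {
  sim <- generate_replica_study(synthetic_spec(n_individuals = 5), seed = 71)
  fit <- gpa_align(sim$dataset)
  tab <- repeatability_anova(fit, sim$dataset$info$individual_id,
                             "shape")$anova
  expect_equal(tab$rows$F[1], tab$rows$MS[1] / tab$rows$MS[2])
})
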