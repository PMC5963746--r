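#' Percent of total sum of squares attributable to an effect
#'
#' @param ss_effect Effect sum of squares, `0 <= ss_effect <= ss_total`.
#' @param ss_total Total sum of squares, `> 0`.
#' @return Percent, `100 * ss_effect / ss_total`.
#' @export
r2_from_ss <- function(ss_effect, ss_total) {
  if (any(ss_total <= 0)) stop("ss_total must be positive")
  if (any(ss_effect < 0) || any(ss_effect > ss_total + 1e-12 * ss_total))
    stop("ss_effect must lie in [0, ss_total]")
  100 * ss_effect / ss_total
}

#' Intraclass correlation coefficient from ANOVA mean squares
#'
#' The default (`variant = "symmetric"`) form is
#' `(ms_among - ms_within) / (ms_among + ms_within)`; it equals the
#' classical one-way formula at k = 2 and is the variant whose values are
#' consistent with published repeatability tables computed this way (the
#' standard one-way k-replicate form is available via
#' `variant = "oneway"`, which uses
#' `(ms_among - ms_within) / (ms_among + (k - 1) * ms_within)`).
#'
#' @param ms_among Mean square among individuals (>= 0).
#' @param ms_within Mean square within individuals / residual (>= 0); the
#'   two must not both be zero.
#' @param variant `"symmetric"` (default) or `"oneway"`.
#' @param k Number of replicates per individual, used by the one-way
#'   variant.
#' @return An object of class `icc_result`: list with `icc`, `ms_among`,
#'   `ms_within`, `variant`.
#' @export
icc_from_ms <- function(ms_among, ms_within,
                        variant = c("symmetric", "oneway"), k = 3) {
  variant <- match.arg(variant)
  if (ms_among < 0 || ms_within < 0) stop("mean squares must be nonnegative")
  if (ms_among == 0 && ms_within == 0)
    stop("both mean squares are zero; ICC undefined")
  icc <- switch(variant,
                symmetric = (ms_among - ms_within) / (ms_among + ms_within),
                oneway = (ms_among - ms_within) /
                  (ms_among + (k - 1) * ms_within))
  structure(list(icc = icc, ms_among = ms_among, ms_within = ms_within,
                 variant = variant),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("ICC =", format(x$icc, digits = 4), "(", x$variant, "variant )\n")
  invisible(x)
}

# number of shape dimensions for p 3D landmarks after removing
# translation (3), rotation (3) and scale (1)
shape_dimension <- function(p) 3L * p - 7L

# flatten a gpa_fit into an n x 3p matrix, or pass a numeric vector
# (centroid sizes) through as an n x 1 matrix; returns list(y, D)
trait_matrix <- function(x, trait) {
  if (trait == "shape") {
    stopifnot(inherits(x, "gpa_fit"))
    p <- dim(x$aligned)[1]
    list(y = t(apply(x$aligned, 3, as.vector)), D = shape_dimension(p))
  } else {
    y <- as.numeric(x)
    list(y = matrix(y, ncol = 1), D = 1L)
  }
}

new_anova_table <- function(trait, rows, k_replicates = NA_integer_,
                            shape_dim = NA_integer_, subset = NA_character_) {
  ss_tot <- rows$SS[rows$effect == "total"]
  ss_sum <- sum(rows$SS[rows$effect != "total"])
  stopifnot(abs(ss_sum - ss_tot) <= 1e-9 * max(ss_tot, 1e-300) + 1e-300)
  stopifnot(sum(rows$df[rows$effect != "total"]) ==
              rows$df[rows$effect == "total"])
  structure(list(trait = trait, subset = subset, rows = rows,
                 k_replicates = k_replicates, shape_dim = shape_dim),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Procrustes ANOVA (", x$trait,
      if (!is.na(x$subset)) paste0(", subset '", x$subset, "'"), ")\n", sep = "")
  df <- x$rows
  df$R2 <- sprintf("%.0f%%", df$R2)
  print(format(df, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Repeatability Procrustes ANOVA with R2 and ICC
#'
#' Partitions variance in centroid size or shape between individuals
#' (the 'true' sample variation) and the residual differences among the k
#' replicate digitizations of each individual. For shape, sums of squares
#' are accumulated over all aligned coordinates and the classical degrees
#' of freedom are multiplied by the shape dimension `3p - 7`; for size a
#' one-way ANOVA on centroid size is used. F is the ratio of mean
#' squares with a parametric (Goodall-style) P from the F distribution on
#' the stated df; an optional permutation P shuffles replicas across
#' individuals. ICC is computed from the mean-square pair via
#' [icc_from_ms()].
#'
#' @param x A `gpa_fit` when `trait = "shape"`, or a numeric vector of
#'   centroid sizes when `trait = "size"`.
#' @param individual_ids Character vector, one individual id per record;
#'   every individual must have the same number k >= 2 of replicas.
#' @param trait `"shape"` or `"size"`.
#' @param n_perm Number of permutation rounds for an additional
#'   permutation P value (0 = parametric only).
#' @param perm_seed Seed for the permutation stream.
#' @param icc_variant Passed to [icc_from_ms()].
#' @return A list with `anova` (an `anova_table`) and `icc`
#'   (an `icc_result`); `anova$rows` also carries `P_perm` when
#'   `n_perm > 0`.
#' @export
repeatability_anova <- function(x, individual_ids,
                                trait = c("shape", "size"),
                                n_perm = 0, perm_seed = 1,
                                icc_variant = "symmetric") {
  trait <- match.arg(trait)
  tm <- trait_matrix(x, trait)
  y <- tm$y
  individual_ids <- as.character(individual_ids)
  stopifnot(nrow(y) == length(individual_ids))
  counts <- table(individual_ids)
  k <- unique(as.integer(counts))
  if (length(k) != 1L || k < 2L)
    stop("unbalanced replication: every individual needs the same ",
         "number (>= 2) of replicas")
  n <- length(counts)
  ss <- repeat_ss(y, individual_ids)
  D <- tm$D
  df_ind <- (n - 1L) * D
  df_err <- n * (k - 1L) * D
  ms_ind <- ss$ind / df_ind
  ms_err <- ss$err / df_err
  f <- if (ss$err == 0) Inf else ms_ind / ms_err
  p_val <- stats::pf(f, df_ind, df_err, lower.tail = FALSE)
  rows <- data.frame(
    effect = c("individual", "error", "total"),
    SS = c(ss$ind, ss$err, ss$tot),
    df = c(df_ind, df_err, df_ind + df_err),
    MS = c(ms_ind, ms_err, NA),
    F = c(f, NA, NA),
    P = c(p_val, NA, NA),
    R2 = c(r2_from_ss(ss$ind, ss$tot), r2_from_ss(ss$err, ss$tot), 100),
    stringsAsFactors = FALSE)
  if (n_perm > 0) {
    set.seed(as.integer(perm_seed))
    f_perm <- replicate(n_perm, {
      perm <- sample(nrow(y))
      ssp <- repeat_ss(y[perm, , drop = FALSE], individual_ids)
      if (ssp$err == 0) Inf else (ssp$ind / df_ind) / (ssp$err / df_err)
    })
    rows$P_perm <- c((1 + sum(f_perm >= f)) / (1 + n_perm), NA, NA)
  }
  tab <- new_anova_table(trait, rows, k_replicates = k,
                         shape_dim = if (trait == "shape") D else 1L)
  icc <- icc_from_ms(ms_ind, ms_err, variant = icc_variant, k = k)
  list(anova = tab, icc = icc)
}

# individual / error / total sums of squares over all columns of y
repeat_ss <- function(y, individual_ids) {
  grand <- colMeans(y)
  ind_means <- rowsum(y, individual_ids) / as.vector(table(individual_ids))
  k <- nrow(y) / nrow(ind_means)
  ss_tot <- sum(sweep(y, 2, grand)^2)
  ss_ind <- k * sum(sweep(ind_means, 2, grand)^2)
  ss_err <- sum((y - ind_means[individual_ids, , drop = FALSE])^2)
  list(ind = ss_ind, err = ss_err, tot = ss_tot)
}

#' One-way grouping Procrustes ANOVA
#'
#' Partitions size or shape variance between and within the levels of a
#' grouping factor (typically the operator), giving the group-effect R2
#' used as an approximate measure of systematic inter-operator bias.
#'
#' @inheritParams repeatability_anova
#' @param group_labels Character vector, one group label per record; at
#'   least two non-empty groups.
#' @param n_perm Optional permutation rounds (labels freely permuted).
#' @return An `anova_table` with effects `group`, `residual`, `total`.
#' @export
grouping_anova <- function(x, group_labels, trait = c("shape", "size"),
                           n_perm = 0, perm_seed = 1) {
  trait <- match.arg(trait)
  tm <- trait_matrix(x, trait)
  y <- tm$y
  group_labels <- as.character(group_labels)
  stopifnot(nrow(y) == length(group_labels))
  g <- length(unique(group_labels))
  if (g < 2L) stop("need at least 2 groups")
  n <- nrow(y)
  ss <- group_ss(y, group_labels)
  D <- tm$D
  df_b <- (g - 1L) * D
  df_w <- (n - g) * D
  ms_b <- ss$between / df_b
  ms_w <- ss$within / df_w
  f <- if (ss$within == 0) Inf else ms_b / ms_w
  rows <- data.frame(
    effect = c("group", "residual", "total"),
    SS = c(ss$between, ss$within, ss$total),
    df = c(df_b, df_w, df_b + df_w),
    MS = c(ms_b, ms_w, NA),
    F = c(f, NA, NA),
    P = c(stats::pf(f, df_b, df_w, lower.tail = FALSE), NA, NA),
    R2 = c(r2_from_ss(ss$between, ss$total),
           r2_from_ss(ss$within, ss$total), 100),
    stringsAsFactors = FALSE)
  if (n_perm > 0) {
    if (any(table(group_labels) < 2L))
      stop("permutation test needs every group non-singleton")
    set.seed(as.integer(perm_seed))
    f_perm <- replicate(n_perm, {
      ssp <- group_ss(y, sample(group_labels))
      if (ssp$within == 0) Inf else (ssp$between / df_b) / (ssp$within / df_w)
    })
    rows$P_perm <- c((1 + sum(f_perm >= f)) / (1 + n_perm), NA, NA)
  }
  new_anova_table(trait, rows, shape_dim = if (trait == "shape") D else 1L)
}

group_ss <- function(y, labels) {
  grand <- colMeans(y)
  means <- rowsum(y, labels) / as.vector(table(labels))
  ngrp <- as.vector(table(labels))
  ss_tot <- sum(sweep(y, 2, grand)^2)
  ss_b <- sum(ngrp * rowSums(sweep(means, 2, grand)^2))
  list(between = ss_b, within = ss_tot - ss_b, total = ss_tot)
}

#' Hierarchical (sex above operator) Procrustes ANOVA
#'
#' Sequential (enter-order) decomposition for the partitioned study
#' design: the sex sum of squares is removed first, then the operator sum
#' of squares adjusted for sex, leaving the residual. The operator R2 is
#' therefore the share of variance unrelated to sex — the quantity
#' compared against sexual dimorphism when judging inter-operator bias.
#' The two factors are treated as crossed (all operators measure both
#' sexes); an empty sex-by-operator cell triggers a warning but the
#' sequential decomposition still proceeds.
#'
#' @inheritParams repeatability_anova
#' @param sex_labels,operator_labels Character vectors, one per record;
#'   both factors must vary.
#' @return An `anova_table` with effects `sex`, `operator`, `residual`,
#'   `total`; R2 values sum to 100.
#' @export
hierarchical_anova <- function(x, sex_labels, operator_labels,
                               trait = c("shape", "size")) {
  trait <- match.arg(trait)
  tm <- trait_matrix(x, trait)
  y <- tm$y
  sex_labels <- as.character(sex_labels)
  operator_labels <- as.character(operator_labels)
  stopifnot(nrow(y) == length(sex_labels),
            nrow(y) == length(operator_labels))
  if (length(unique(sex_labels)) < 2L) {
    # degenerate: single sex; the model reduces to a plain grouping ANOVA
    return(grouping_anova(x, operator_labels, trait))
  }
  if (length(unique(operator_labels)) < 2L)
    stop("operator factor is constant")
  cells <- table(sex_labels, operator_labels)
  if (any(cells == 0))
    warning("empty sex x operator cell(s); sequential decomposition ",
            "proceeds on the observed cells")
  n <- nrow(y)
  grand <- colMeans(y)
  yc <- sweep(y, 2, grand)
  ss_tot <- sum(yc^2)
  sx <- factor(sex_labels)
  op <- factor(operator_labels)
  rss1 <- sum(stats::lm.fit(stats::model.matrix(~sx), yc)$residuals^2)
  fit2 <- stats::lm.fit(stats::model.matrix(~sx + op), yc)
  rss2 <- sum(fit2$residuals^2)
  ss_sex <- ss_tot - rss1
  ss_op <- rss1 - rss2
  ss_res <- rss2
  D <- tm$D
  df_sex <- (nlevels(sx) - 1L) * D
  df_op <- (nlevels(op) - 1L) * D
  df_res <- (n - 1L - (nlevels(sx) - 1L) - (nlevels(op) - 1L)) * D
  ms <- c(ss_sex / df_sex, ss_op / df_op, ss_res / df_res)
  f <- if (ss_res == 0) c(Inf, Inf) else ms[1:2] / ms[3]
  rows <- data.frame(
    effect = c("sex", "operator", "residual", "total"),
    SS = c(ss_sex, ss_op, ss_res, ss_tot),
    df = c(df_sex, df_op, df_res, df_sex + df_op + df_res),
    MS = c(ms, NA),
    F = c(f, NA, NA),
    P = c(stats::pf(f, c(df_sex, df_op), df_res, lower.tail = FALSE), NA, NA),
    R2 = c(r2_from_ss(ss_sex, ss_tot), r2_from_ss(ss_op, ss_tot),
           r2_from_ss(ss_res, ss_tot), 100),
    stringsAsFactors = FALSE)
  new_anova_table(trait, rows, shape_dim = if (trait == "shape") D else 1L)
}

#' Balanced-subsample robustness check
#'
#' Randomly selects `n_per_cell` individuals within every sex-by-operator
#' cell (without replacement, seeded), then reruns the hierarchical
#' sex-above-operator ANOVA on the fully balanced subsample. Used to
#' verify that effect-size estimates from an unbalanced study design are
#' not artefacts of the imbalance.
#'
#' @param dataset A partition-design `landmark_dataset` (one record per
#'   individual) with sex labels.
#' @param n_per_cell Individuals to draw per sex-by-operator cell.
#' @param seed Integer sampling seed.
#' @param trait `"shape"` or `"size"`.
#' @param subset_name Panel subset to analyse (default `"all"`).
#' @return A list with `anova` (an `anova_table`), `sampled_ids` and
#'   `n` (the subsample size).
#' @export
balanced_subsample_r2 <- function(dataset, n_per_cell = 50, seed = 1,
                                  trait = c("shape", "size"),
                                  subset_name = "all") {
  trait <- match.arg(trait)
  info <- dataset$info
  cells <- split(seq_len(nrow(info)),
                 list(info$sex, info$operator_id), drop = TRUE)
  short <- names(cells)[lengths(cells) < n_per_cell]
  if (length(short))
    stop("cell(s) with fewer than ", n_per_cell, " individuals: ",
         paste(short, collapse = ", "))
  set.seed(as.integer(seed))
  take <- sort(unlist(lapply(cells, sample, size = n_per_cell)))
  sub <- filter_records(select_subset(dataset, subset_name),
                        seq_len(n_records(dataset)) %in% take)
  x <- if (trait == "shape") gpa_align(sub) else
    apply(sub$coords, 3, centroid_size)
  tab <- hierarchical_anova(x, sub$info$sex, sub$info$operator_id, trait)
  tab$subset <- subset_name
  list(anova = tab, sampled_ids = info$individual_id[take], n = length(take))
}
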