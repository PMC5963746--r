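# Full-study orchestration: the three-stage error analysis run per
# landmark subset (all / bone / nose), mirroring the order in which a
# reproducibility study proceeds: absolute landmark error first, then
# size/shape repeatability and concordance, then operator bias against a
# biological factor.

anova_to_list <- function(res) {
  if (is.list(res) && !inherits(res, "anova_table") && "anova" %in% names(res)) {
    out <- list(table = res$anova$rows)
    if (!is.null(res$icc)) out$icc <- res$icc$icc
    if (!is.null(res$n)) out$n <- res$n
    out
  } else list(table = res$rows)
}

replica_design_ok <- function(info) {
  ops <- sort(unique(info$operator_id))
  inds <- unique(info$individual_id)
  length(ops) >= 2 && all(vapply(inds, function(i)
    identical(sort(info$operator_id[info$individual_id == i]), ops), TRUE))
}

#' Full reproducibility analysis of a replica-design dataset
#'
#' Runs the first two analysis stages on the subsets `all`, `bone` and
#' `nose` (or whichever of these the panel defines): (I) absolute
#' per-landmark error (ODEV/AVEDEV profile and the bone/soft contrast,
#' computed once on the full panel), and (II) per-subset generalized
#' Procrustes superimposition followed by the repeatability Procrustes
#' ANOVA with R2 and ICC for size and shape, the operator-grouping
#' ANOVAs, inter-operator size correlations and shape distance-matrix
#' correlations, the UPGMA phenogram with within-individual clustering
#' counts, and the relative range of shape distances to the mean. The
#' report is deterministic for a given input.
#'
#' @param dataset A full-replica [landmark_dataset()]: every individual
#'   digitized by every operator.
#' @return A `study_report` list: `design`, `n_records`, `provenance`,
#'   `absolute_error` and one block per subset.
#' @export
run_replica_analysis <- function(dataset) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (!replica_design_ok(dataset$info))
    stop("not a full-replica design (every individual x every operator); ",
         "for partitioned study samples use run_study_analysis()")
  info <- dataset$info
  ops <- sort(unique(info$operator_id))
  err <- compute_odev_avedev(dataset)
  report <- list(design = "replica",
                 n_records = n_records(dataset),
                 provenance = report_provenance(dataset),
                 absolute_error = list(
                   profile = error_profile(err),
                   tissue_contrast = tryCatch(tissue_error_contrast(err),
                                              error = function(e) NULL)))
  for (ss in intersect(c("all", "bone", "nose"), names(dataset$panel$subsets))) {
    sub <- select_subset(dataset, ss)
    fit <- gpa_align(sub)
    cs <- fit$centroid_sizes
    rep_size <- repeatability_anova(cs, info$individual_id, "size")
    rep_shape <- repeatability_anova(fit, info$individual_id, "shape")
    grp_size <- grouping_anova(cs, info$operator_id, "size")
    grp_shape <- grouping_anova(fit, info$operator_id, "shape")
    dmat <- shape_distance_matrix(fit)
    # per-operator distance matrices over the shared individuals
    op_dmats <- lapply(ops, function(o) {
      sel <- info$operator_id == o
      m <- dmat[sel, sel]
      dimnames(m) <- list(info$individual_id[sel], info$individual_id[sel])
      ord <- order(rownames(m))
      m[ord, ord]
    })
    names(op_dmats) <- ops
    shape_cor <- diag(1, length(ops))
    dimnames(shape_cor) <- list(ops, ops)
    for (i in seq_along(ops)) for (j in seq_along(ops)) if (j > i)
      shape_cor[i, j] <- shape_cor[j, i] <-
        as.numeric(distance_matrix_correlation(op_dmats[[i]], op_dmats[[j]]))
    tree <- upgma_tree(dmat)
    leaf_map <- stats::setNames(info$individual_id, record_ids(info))
    counts <- replica_cluster_counts(tree, leaf_map)
    d2m <- distance_to_mean(fit)
    report[[ss]] <- list(
      repeatability = list(size = anova_to_list(rep_size),
                           shape = anova_to_list(rep_shape)),
      operator_grouping = list(size = anova_to_list(grp_size),
                               shape = anova_to_list(grp_shape)),
      size_correlation = pairwise_size_correlation(cs, info$operator_id,
                                                   info$individual_id),
      shape_matrix_correlation = list(
        matrix = shape_cor,
        mean_pairwise = mean(shape_cor[lower.tri(shape_cor)])),
      cluster_counts = counts[c("n_individuals", "n_triplets",
                                "n_pairs_or_better")],
      relative_range = tryCatch(relative_range(d2m),
                                error = function(e) NULL))
  }
  structure(report, class = "study_report")
}

#' Inter-operator bias analysis of a partitioned study sample
#'
#' For each subset (`all`, `bone`, `nose`), superimposes the
#' configurations and runs the hierarchical sex-above-operator Procrustes
#' ANOVA for size and for shape, plus the shape PCA with per-group
#' centroids on PC1-PC2. Optionally repeats the ANOVAs on a fully
#' balanced random subsample of `balanced_n` individuals per
#' sex-by-operator cell.
#'
#' @param dataset A partition-design [landmark_dataset()] (one record per
#'   individual) with sex labels `F`/`M`.
#' @param balanced_n If not `NULL`, the per-cell size of the balanced
#'   subsample check.
#' @param seed Seed for the balanced subsampling.
#' @return A `study_report` list with one block per subset.
#' @export
run_study_analysis <- function(dataset, balanced_n = NULL, seed = 1) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  info <- dataset$info
  if (anyDuplicated(info$individual_id))
    stop("study design expects one record per individual")
  if (all(info$sex == "unknown")) stop("sex labels are required")
  report <- list(design = "study",
                 n_records = n_records(dataset),
                 provenance = report_provenance(dataset))
  for (ss in intersect(c("all", "bone", "nose"), names(dataset$panel$subsets))) {
    sub <- select_subset(dataset, ss)
    fit <- gpa_align(sub)
    cs <- fit$centroid_sizes
    h_size <- hierarchical_anova(cs, info$sex, info$operator_id, "size")
    h_shape <- hierarchical_anova(fit, info$sex, info$operator_id, "shape")
    pca <- shape_pca(fit)
    scatter <- group_scatter_export(pca, info$sex, info$operator_id)
    block <- list(
      hierarchical = list(size = anova_to_list(h_size),
                          shape = anova_to_list(h_shape)),
      pca = list(percent_variance = utils::head(pca$percent_variance, 5),
                 centroids = scatter$centroids))
    if (!is.null(balanced_n)) {
      bal_size <- balanced_subsample_r2(dataset, balanced_n, seed, "size", ss)
      bal_shape <- balanced_subsample_r2(dataset, balanced_n, seed, "shape", ss)
      block$balanced <- list(n = bal_size$n,
                             size = anova_to_list(bal_size),
                             shape = anova_to_list(bal_shape))
    }
    report[[ss]] <- block
  }
  structure(report, class = "study_report")
}

report_provenance <- function(dataset) {
  list(package_version = as.character(utils::packageVersion("procerror")),
       n_records = n_records(dataset),
       n_landmarks = dim(dataset$coords)[1],
       coordinate_checksum = signif(sum(dataset$coords^2), 15))
}

#' Serialise a study report to JSON
#'
#' Every numeric table of the report is written unrounded; the JSON is the
#' machine-readable counterpart of the printed summary.
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (", x$design, " design, ", x$n_records, " records)\n",
      sep = "")
  for (ss in intersect(c("all", "bone", "nose"), names(x))) {
    blk <- x[[ss]]
    cat("subset '", ss, "':\n", sep = "")
    if (!is.null(blk$repeatability)) {
      for (tr in c("size", "shape")) {
        tab <- blk$repeatability[[tr]]$table
        err_r2 <- tab$R2[tab$effect == "error"]
        cat(sprintf("  %-5s error R2 %3.0f%%  ICC %.2f   operator R2 %3.0f%%\n",
                    tr, err_r2, blk$repeatability[[tr]]$icc,
                    blk$operator_grouping[[tr]]$table$R2[1]))
      }
      cat(sprintf("  triplets %d/%d, pairs-or-better %d/%d\n",
                  blk$cluster_counts$n_triplets,
                  blk$cluster_counts$n_individuals,
                  blk$cluster_counts$n_pairs_or_better,
                  blk$cluster_counts$n_individuals))
    }
    if (!is.null(blk$hierarchical)) {
      for (tr in c("size", "shape")) {
        tab <- blk$hierarchical[[tr]]$table
        cat(sprintf("  %-5s R2: sex %4.1f%%  operator %4.1f%%  residual %4.1f%%\n",
                    tr, tab$R2[tab$effect == "sex"],
                    tab$R2[tab$effect == "operator"],
                    tab$R2[tab$effect == "residual"]))
      }
    }
  }
  invisible(x)
}
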