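#' Build a landmark dataset from a coordinate array and record metadata
#'
#' A `landmark_dataset` bundles a panel, a `p x 3 x n` coordinate array
#' (mm; axes X = right-left, Y = posterior-anterior, Z = superior-inferior)
#' and an `n`-row metadata table with columns `individual_id`,
#' `operator_id`, `sex` and `replicate_id`.
#'
#' @param panel A [landmark_panel()].
#' @param coords Numeric array `p x 3 x n`; rows must follow `panel$names`.
#' @param info Data frame with `n` rows and columns `individual_id`,
#'   `operator_id`, `sex` (one of `"F"`, `"M"`, `"unknown"`) and
#'   `replicate_id`.
#' @return An object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(panel, coords, info) {
  stopifnot(inherits(panel, "landmark_panel"))
  p <- length(panel$names)
  if (length(dim(coords)) != 3L || dim(coords)[1] != p || dim(coords)[2] != 3L)
    stop("coords must be a ", p, " x 3 x n array matching the panel")
  n <- dim(coords)[3]
  required <- c("individual_id", "operator_id", "sex", "replicate_id")
  if (!all(required %in% names(info)))
    stop("info must have columns ", paste(required, collapse = ", "))
  if (nrow(info) != n)
    stop("info has ", nrow(info), " rows but coords has ", n, " records")
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  for (cl in required) info[[cl]] <- as.character(info[[cl]])
  bad_sex <- !info$sex %in% c("F", "M", "unknown")
  if (any(bad_sex)) stop("sex must be 'F', 'M' or 'unknown'")
  if (!all(is.finite(coords))) {
    idx <- which(!is.finite(coords), arr.ind = TRUE)[1, ]
    stop("non-finite coordinate for record '",
         record_ids(info)[idx[3]], "', landmark '", panel$names[idx[1]], "'")
  }
  ids <- record_ids(info)
  if (anyDuplicated(ids))
    stop("duplicated (individual, operator, replicate) triple: ",
         ids[duplicated(ids)][1])
  dimnames(coords) <- list(panel$names, c("x", "y", "z"), ids)
  structure(list(panel = panel, coords = coords, info = info),
            class = "landmark_dataset")
}

# "_" rather than ":" so record ids survive newick export unmangled
record_ids <- function(info) {
  paste(info$individual_id, info$operator_id, info$replicate_id, sep = "_")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("Landmark dataset:", dim(x$coords)[3], "records x",
      dim(x$coords)[1], "landmarks (3D, mm)\n")
  cat("  individuals:", length(unique(x$info$individual_id)),
      " operators:", length(unique(x$info$operator_id)), "\n")
  invisible(x)
}

#' Number of records in a landmark dataset
#' @param dataset A `landmark_dataset`.
#' @return Integer record count.
#' @export
n_records <- function(dataset) dim(dataset$coords)[3]

#' Restrict a dataset to a named landmark subset
#'
#' Returns a new dataset containing only the landmarks of the requested
#' panel subset (e.g. the ten bone landmarks or the five nasal soft-tissue
#' ones); record metadata is unchanged.
#'
#' @param dataset A `landmark_dataset`.
#' @param subset_name Name of a subset defined on the dataset's panel.
#' @return A `landmark_dataset` on the reduced panel.
#' @export
select_subset <- function(dataset, subset_name) {
  sub_panel <- panel_subset(dataset$panel, subset_name)
  idx <- match(sub_panel$names, dataset$panel$names)
  landmark_dataset(sub_panel,
                   dataset$coords[idx, , , drop = FALSE],
                   dataset$info)
}

#' Keep only the records for which a predicate on the metadata holds
#'
#' @param dataset A `landmark_dataset`.
#' @param keep Logical vector of length `n_records(dataset)`.
#' @return A `landmark_dataset` with the selected records, in input order.
#' @export
filter_records <- function(dataset, keep) {
  keep <- as.logical(keep)
  stopifnot(length(keep) == n_records(dataset), !anyNA(keep))
  landmark_dataset(dataset$panel,
                   dataset$coords[, , keep, drop = FALSE],
                   dataset$info[keep, , drop = FALSE])
}
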