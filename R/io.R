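#' Read a landmark dataset from disk
#'
#' Two plain-text formats are supported. The canonical long CSV has one row
#' per (individual, operator, replicate, landmark) with columns
#' `individual_id`, `operator_id`, `sex`, `replicate_id`, `landmark`, `x`,
#' `y`, `z`. The Morphologika-style format carries `[individuals]`,
#' `[landmarks]`, `[dimensions]`, `[names]` and `[rawpoints]` blocks; any
#' other block is ignored with a warning. Record metadata in Morphologika
#' files is packed into the individual name as
#' `individual:operator:sex:replicate`.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"morphologika"`.
#' @param panel Panel to validate against. The default uses
#'   [default_panel()] when the file has 15 landmarks whose labels match,
#'   otherwise a generic panel is constructed (CSV keeps its own labels).
#' @return A [landmark_dataset()]; record order follows the file.
#' @export
read_landmark_table <- function(path, format = c("csv", "morphologika"),
                                panel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         csv = read_landmark_csv(path, panel),
         morphologika = read_morphologika(path, panel))
}

#' Write a landmark dataset to disk
#'
#' Coordinates are written with 12 significant digits, enough for a
#' lossless round trip at sub-nanometre precision. See
#' [read_landmark_table()] for the formats.
#'
#' @param dataset A `landmark_dataset`; must contain at least one record.
#' @param path Output path.
#' @param format `"csv"` or `"morphologika"`.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(dataset, path,
                                 format = c("csv", "morphologika")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (n_records(dataset) == 0L)
    stop("refusing to write an empty dataset")
  switch(format,
         csv = write_landmark_csv(dataset, path),
         morphologika = write_morphologika(dataset, path))
  invisible(path)
}

fmt_num <- function(x) formatC(x, digits = 12, format = "g")

read_landmark_csv <- function(path, panel = NULL) {
  # read everything as character: type inference would turn a sex column
  # holding only "F" into logical FALSE
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("individual_id", "operator_id", "sex", "replicate_id",
                "landmark", "x", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  for (ax in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[ax]]))
    if (anyNA(v)) stop("coordinate column '", ax, "' is not numeric")
    df[[ax]] <- v
  }
  key <- paste(df$individual_id, df$operator_id, df$replicate_id, sep = ":")
  rec_keys <- unique(key)
  landmarks <- unique(df$landmark)
  p <- length(landmarks)
  if (is.null(panel)) {
    dp <- default_panel()
    panel <- if (p == 15L && setequal(landmarks, dp$names)) dp else
      landmark_panel(landmarks, rep("bone", p), rep("midline", p))
  }
  coords <- array(NA_real_, c(length(panel$names), 3, length(rec_keys)))
  row_rec <- match(key, rec_keys)
  row_lm <- match(df$landmark, panel$names)
  if (anyNA(row_lm))
    stop("unknown landmark label(s): ",
         paste(unique(df$landmark[is.na(row_lm)]), collapse = ", "))
  coords[cbind(rep(row_lm, 3), rep(1:3, each = nrow(df)),
               rep(row_rec, 3))] <- c(df$x, df$y, df$z)
  for (r in seq_along(rec_keys)) {
    miss <- which(is.na(coords[, 1, r]))
    if (length(miss))
      stop("record '", rec_keys[r], "' is missing landmark(s): ",
           paste(panel$names[miss], collapse = ", "))
  }
  first <- !duplicated(key)
  info <- data.frame(individual_id = df$individual_id[first],
                     operator_id = df$operator_id[first],
                     sex = df$sex[first],
                     replicate_id = df$replicate_id[first],
                     stringsAsFactors = FALSE)
  landmark_dataset(panel, coords, info)
}

write_landmark_csv <- function(dataset, path) {
  p <- dim(dataset$coords)[1]
  n <- n_records(dataset)
  info <- dataset$info
  df <- data.frame(
    individual_id = rep(info$individual_id, each = p),
    operator_id = rep(info$operator_id, each = p),
    sex = rep(info$sex, each = p),
    replicate_id = rep(info$replicate_id, each = p),
    landmark = rep(dataset$panel$names, n),
    x = fmt_num(as.vector(dataset$coords[, 1, ])),
    y = fmt_num(as.vector(dataset$coords[, 2, ])),
    z = fmt_num(as.vector(dataset$coords[, 3, ])),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_morphologika <- function(path, panel = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  is_hdr <- grepl("^\\[.*\\]$", lines)
  hdr_pos <- which(is_hdr)
  blocks <- list()
  for (i in seq_along(hdr_pos)) {
    nm <- tolower(gsub("\\[|\\]", "", lines[hdr_pos[i]]))
    to <- if (i < length(hdr_pos)) hdr_pos[i + 1] - 1L else length(lines)
    blocks[[nm]] <- lines[seq(hdr_pos[i] + 1L, length.out = max(0L, to - hdr_pos[i]))]
  }
  known <- c("individuals", "landmarks", "dimensions", "names", "rawpoints")
  extra <- setdiff(names(blocks), known)
  if (length(extra))
    warning("ignoring Morphologika block(s): ", paste(extra, collapse = ", "))
  need <- setdiff(c("individuals", "landmarks", "dimensions", "rawpoints"),
                  names(blocks))
  if (length(need))
    stop("Morphologika file lacks block(s): ", paste(need, collapse = ", "))
  n <- as.integer(blocks$individuals[1])
  p <- as.integer(blocks$landmarks[1])
  k <- as.integer(blocks$dimensions[1])
  if (k != 3L) stop("only 3-dimensional Morphologika files are supported")
  pts <- blocks$rawpoints
  name_lines <- grepl("^'", pts)
  rec_names <- if (!is.null(blocks$names)) blocks$names else
    sub("^'", "", pts[name_lines])
  coord_lines <- pts[!name_lines]
  if (length(coord_lines) != n * p)
    stop("expected ", n * p, " coordinate rows, found ", length(coord_lines))
  vals <- do.call(rbind, lapply(strsplit(coord_lines, "[ \t]+"), as.numeric))
  if (ncol(vals) != 3L || anyNA(vals))
    stop("malformed coordinate row in [rawpoints]")
  if (is.null(panel)) {
    dp <- default_panel()
    panel <- if (p == 15L) dp else
      landmark_panel(paste0("L", seq_len(p)), rep("bone", p), rep("midline", p))
  }
  coords <- array(NA_real_, c(p, 3, n))
  for (r in seq_len(n))
    coords[, , r] <- vals[seq((r - 1) * p + 1, r * p), , drop = FALSE]
  meta <- strsplit(rec_names[seq_len(n)], ":", fixed = TRUE)
  info <- data.frame(
    individual_id = vapply(meta, `[`, "", 1),
    operator_id = vapply(meta, function(m) if (length(m) >= 2) m[2] else "OP1", ""),
    sex = vapply(meta, function(m) if (length(m) >= 3) m[3] else "unknown", ""),
    replicate_id = vapply(meta, function(m) if (length(m) >= 4) m[4] else "r1", ""),
    stringsAsFactors = FALSE)
  landmark_dataset(panel, coords, info)
}

write_morphologika <- function(dataset, path) {
  n <- n_records(dataset)
  p <- dim(dataset$coords)[1]
  info <- dataset$info
  nm <- paste(info$individual_id, info$operator_id, info$sex,
              info$replicate_id, sep = ":")
  out <- c("[individuals]", n, "[landmarks]", p, "[dimensions]", 3,
           "[names]", nm, "[rawpoints]")
  for (r in seq_len(n)) {
    out <- c(out, paste0("'", nm[r]),
             apply(dataset$coords[, , r, drop = FALSE], 1,
                   function(v) paste(fmt_num(v), collapse = " ")))
  }
  writeLines(out, path)
}
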