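#' Landmark panel: the named set of landmarks carried by a study
#'
#' A `landmark_panel` records the ordered landmark labels, a per-landmark
#' tissue tag (`"bone"` or `"soft"`), a per-landmark side tag (`"midline"`,
#' `"left"` or `"right"`), and named index subsets used throughout the
#' analyses (at minimum `"all"`).
#'
#' @param names Character vector of landmark labels (unique, non-empty).
#' @param tissue Character vector, one of `"bone"`/`"soft"` per landmark.
#' @param side Character vector, one of `"midline"`/`"left"`/`"right"` per
#'   landmark. Every `"left"` landmark must have a `"right"` partner whose
#'   label differs only in its side suffix.
#' @param subsets Named list of integer index vectors into `names`. A subset
#'   `"all"` covering every landmark is added if absent.
#' @return An object of class `landmark_panel`.
#' @seealso [default_panel()] for the 15-landmark adult-face panel.
#' @export
landmark_panel <- function(names, tissue, side, subsets = list()) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("duplicated landmark labels: ",
                                 paste(names[duplicated(names)], collapse = ", "))
  p <- length(names)
  if (p < 1L) stop("panel must contain at least one landmark")
  tissue <- match.arg(as.character(tissue), c("bone", "soft"), several.ok = TRUE)
  side <- match.arg(as.character(side), c("midline", "left", "right"),
                    several.ok = TRUE)
  if (length(tissue) != p || length(side) != p)
    stop("'tissue' and 'side' must have one entry per landmark")
  if (sum(side == "left") != sum(side == "right"))
    stop("every bilateral landmark needs a contralateral partner")
  if (!"all" %in% names(subsets)) subsets$all <- seq_len(p)
  for (nm in names(subsets)) {
    idx <- subsets[[nm]]
    if (!all(idx %in% seq_len(p)) || anyDuplicated(idx))
      stop("subset '", nm, "' indexes landmarks outside the panel")
  }
  structure(list(names = names, tissue = tissue, side = side,
                 subsets = subsets),
            class = "landmark_panel")
}

#' The default 15-landmark adult-face panel
#'
#' Fifteen 3D craniofacial landmarks: ten located on bone (glabella, hard
#' nasion, anterior nasal spine, sella, and the bilateral orbitale, porion
#' and zygion) and five nasal soft-tissue points (soft nasion, pronasale,
#' subnasale and the bilateral alare). The panel defines three subsets:
#' `"all"` (15), `"bone"` (10) and `"nose"` (5); the bone and nose subsets
#' are disjoint and together cover the full panel. Glabella belongs to the
#' bone subset.
#'
#' @return A `landmark_panel` with 15 landmarks.
#' @examples
#' pan <- default_panel()
#' lengths(pan$subsets)
#' @export
default_panel <- function() {
  nm <- c("Glabella", "SoftNasion", "HardNasion", "Pronasale", "Subnasale",
          "AntNasalSpine", "Sella", "Alare_L", "Alare_R", "Orbitale_L",
          "Orbitale_R", "Porion_L", "Porion_R", "Zygion_L", "Zygion_R")
  soft <- c("SoftNasion", "Pronasale", "Subnasale", "Alare_L", "Alare_R")
  tissue <- ifelse(nm %in% soft, "soft", "bone")
  side <- rep("midline", length(nm))
  side[grepl("_L$", nm)] <- "left"
  side[grepl("_R$", nm)] <- "right"
  landmark_panel(nm, tissue, side,
                 subsets = list(all = seq_along(nm),
                                bone = which(tissue == "bone"),
                                nose = which(tissue == "soft")))
}

#' @export
print.landmark_panel <- function(x, ...) {
  cat("Landmark panel:", length(x$names), "landmarks\n")
  cat("  subsets:", paste(sprintf("%s (%d)", names(x$subsets),
                                  lengths(x$subsets)), collapse = ", "), "\n")
  invisible(x)
}

# restrict a panel to a named subset, keeping relative landmark order
panel_subset <- function(panel, subset_name) {
  if (!subset_name %in% names(panel$subsets))
    stop("unknown subset '", subset_name, "'; available: ",
         paste(names(panel$subsets), collapse = ", "))
  idx <- sort(panel$subsets[[subset_name]])
  sub_subsets <- list(all = seq_along(idx))
  # retain any other subset fully contained in the selection
  for (nm in setdiff(names(panel$subsets), c("all", subset_name))) {
    other <- panel$subsets[[nm]]
    if (all(other %in% idx)) sub_subsets[[nm]] <- match(sort(other), idx)
  }
  sub_subsets[[subset_name]] <- seq_along(idx)
  side <- panel$side[idx]
  # bilateral partners may be split apart by a subset; demote orphans
  if (sum(side == "left") != sum(side == "right")) {
    side[side %in% c("left", "right")] <- "midline"
  }
  landmark_panel(panel$names[idx], panel$tissue[idx], side,
                 subsets = sub_subsets)
}
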