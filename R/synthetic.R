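#' Template configuration: an idealised adult face
#'
#' Returns a single anatomically plausible configuration for the given
#' panel, with bilateral pairs mirrored exactly across the X = 0
#' midsagittal plane, centroid at the origin and centroid size scaled to
#' `mean_size`. It is the fixed starting point from which the synthetic
#' generators build individuals.
#'
#' @param panel A [landmark_panel()]; defaults to [default_panel()]. Panels
#'   that are subsets of the default panel are also accepted.
#' @param mean_size Target centroid size in mm.
#' @return A `p x 3` matrix (mm) with rownames `panel$names`.
#' @export
make_template <- function(panel = default_panel(), mean_size = 250) {
  base <- rbind(
    Glabella      = c(0,    85,  30),
    SoftNasion    = c(0,    88,  22),
    HardNasion    = c(0,    82,  20),
    Pronasale     = c(0,   100, -10),
    Subnasale     = c(0,    88, -20),
    AntNasalSpine = c(0,    84, -18),
    Sella         = c(0,    25,  15),
    Alare_L       = c(-17,  78, -14),
    Alare_R       = c(17,   78, -14),
    Orbitale_L    = c(-33,  62,   6),
    Orbitale_R    = c(33,   62,   6),
    Porion_L      = c(-60,   0,  10),
    Porion_R      = c(60,    0,  10),
    Zygion_L      = c(-65,  28,  -4),
    Zygion_R      = c(65,   28,  -4))
  idx <- match(panel$names, rownames(base))
  if (anyNA(idx))
    stop("template undefined for landmark(s): ",
         paste(panel$names[is.na(idx)], collapse = ", "))
  X <- base[idx, , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  X <- X * (mean_size / centroid_size(X))
  rownames(X) <- panel$names
  colnames(X) <- c("x", "y", "z")
  X
}

# Fixed displacement fields used by the default study conditions. They are
# produced from a dedicated constant-seeded stream so the defaults are
# reproducible constants, independent of the user's simulation seed.
fixed_field <- function(p, stream, rms = 1) {
  # uses a private constant seed; the caller's RNG state is untouched
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(20180522L + stream)
  rng <- matrix(stats::rnorm(p * 3), p, 3)
  rng * (rms / sqrt(mean(rng^2)))
}

#' Specification of a synthetic multi-operator landmark study
#'
#' Collects every knob of the generator. The defaults describe the study
#' conditions emulated throughout the package: a replica design of 20
#' single-sex individuals digitized by 3 operators (60 observations), or a
#' partitioned study design of 906 individuals with unbalanced
#' female/male counts per operator (102/61, 106/163, 252/222). Digitizing
#' noise is isotropic Gaussian per coordinate, 65% larger on bone than on
#' nasal soft-tissue landmarks; each operator applies a fixed systematic
#' bias field; individual shape deviations are Gaussian with a larger SD
#' on the soft-tissue points (the nose varies relatively more among
#' individuals than the bony face).
#'
#' @param n_individuals Number of distinct individuals.
#' @param operators Character vector of operator ids.
#' @param replicate_design `"full"` (every operator digitizes everyone) or
#'   `"partition"` (each individual digitized by exactly one operator).
#' @param sex_counts For partition designs, a data frame with columns
#'   `operator`, `sex`, `n` summing to `n_individuals`.
#' @param mean_size Template centroid size (mm).
#' @param individual_shape_sd Per-coordinate SD (mm) of individual shape
#'   deviations from the template; a scalar, or a vector of length p for
#'   per-landmark control.
#' @param individual_size_sd SD (mm) of individual centroid size.
#' @param sex_size_shift Added to male mean centroid size (mm).
#' @param sex_shape_magnitude Per-coordinate RMS (mm) of the fixed
#'   male-minus-female shape displacement field.
#' @param operator_bias Either a per-operator list of `p x 3` offset
#'   matrices (mm), or a scalar giving the per-coordinate RMS of fixed,
#'   zero-mean-across-operators bias fields generated internally.
#' @param noise_sd_bone,noise_sd_soft Per-coordinate digitizing-noise SD
#'   (mm) on bone and soft-tissue landmarks.
#' @param panel The landmark panel; defaults to [default_panel()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_individuals = 20,
                           operators = c("OP1", "OP2", "OP3"),
                           replicate_design = c("full", "partition"),
                           sex_counts = NULL,
                           mean_size = 250,
                           individual_shape_sd = NULL,
                           individual_size_sd = 6.5,
                           sex_size_shift = 15,
                           sex_shape_magnitude = 0.7,
                           operator_bias = 1.25,
                           noise_sd_bone = 1.485,
                           noise_sd_soft = 0.9,
                           panel = default_panel()) {
  replicate_design <- match.arg(replicate_design)
  p <- length(panel$names)
  if (is.null(individual_shape_sd)) {
    # nasal soft tissue varies about twice as much among individuals
    individual_shape_sd <- ifelse(panel$tissue == "soft", 2.8, 2.0)
  }
  if (length(individual_shape_sd) == 1L)
    individual_shape_sd <- rep(individual_shape_sd, p)
  stopifnot(length(individual_shape_sd) == p,
            all(individual_shape_sd >= 0),
            individual_size_sd >= 0, noise_sd_bone >= 0, noise_sd_soft >= 0)
  if (is.numeric(operator_bias) && length(operator_bias) == 1L) {
    rms <- operator_bias
    # per-landmark bias magnitude follows the noise ratio (larger on bone),
    # normalised so the mean per-coordinate bias variance equals rms^2
    sd_lm <- ifelse(panel$tissue == "soft", noise_sd_soft, noise_sd_bone)
    w <- if (all(sd_lm == 0)) rep(1, p) else sd_lm / sqrt(mean(sd_lm^2))
    operator_bias <- lapply(seq_along(operators),
                            function(i) fixed_field(p, i, rms) * w)
    # centre across operators so biases shift no overall mean
    mean_field <- Reduce(`+`, operator_bias) / length(operator_bias)
    operator_bias <- lapply(operator_bias, function(b) b - mean_field)
    names(operator_bias) <- operators
  }
  stopifnot(is.list(operator_bias), length(operator_bias) == length(operators))
  if (replicate_design == "partition") {
    if (is.null(sex_counts)) {
      sex_counts <- data.frame(
        operator = rep(c("OP1", "OP2", "OP3"), each = 2),
        sex = rep(c("F", "M"), 3),
        n = c(102, 61, 106, 163, 252, 222))
      n_individuals <- sum(sex_counts$n)
    }
    if (sum(sex_counts$n) != n_individuals)
      stop("sex_counts sum to ", sum(sex_counts$n),
           " but n_individuals is ", n_individuals)
  }
  structure(list(n_individuals = n_individuals, operators = operators,
                 replicate_design = replicate_design, sex_counts = sex_counts,
                 mean_size = mean_size,
                 individual_shape_sd = individual_shape_sd,
                 individual_size_sd = individual_size_sd,
                 sex_size_shift = sex_size_shift,
                 sex_shape_magnitude = sex_shape_magnitude,
                 operator_bias = operator_bias,
                 noise_sd_bone = noise_sd_bone,
                 noise_sd_soft = noise_sd_soft,
                 panel = panel),
            class = "synthetic_spec")
}

noise_sd_by_landmark <- function(spec) {
  ifelse(spec$panel$tissue == "soft", spec$noise_sd_soft, spec$noise_sd_bone)
}

# one individual's true (pre-noise, pre-bias) configuration
draw_true_config <- function(spec, template, sex) {
  p <- nrow(template)
  dev <- matrix(stats::rnorm(p * 3, sd = rep(spec$individual_shape_sd, 3)),
                p, 3)
  X <- template + dev
  if (sex == "M")
    X <- X + fixed_field(p, stream = 99L, rms = 1) * spec$sex_shape_magnitude
  target_cs <- spec$mean_size +
    (sex == "M") * spec$sex_size_shift +
    stats::rnorm(1, sd = spec$individual_size_sd)
  X <- sweep(X, 2, colMeans(X))
  X * (target_cs / centroid_size(X))
}

add_noise <- function(spec, X) {
  p <- nrow(X)
  sd_lm <- noise_sd_by_landmark(spec)
  X + matrix(stats::rnorm(p * 3, sd = rep(sd_lm, 3)), p, 3)
}

# expected variance shares per coordinate, averaged over landmarks, for a
# full-replica design; size variation is excluded (it is removed by GPA)
design_fractions <- function(spec) {
  ind <- mean(spec$individual_shape_sd^2)
  sd_lm <- noise_sd_by_landmark(spec)
  noise <- mean(sd_lm^2)
  bias_mats <- spec$operator_bias
  mean_field <- Reduce(`+`, bias_mats) / length(bias_mats)
  bias <- mean(Reduce(`+`, lapply(bias_mats, function(b)
    (b - mean_field)^2)) / length(bias_mats))
  tot <- ind + noise + bias
  c(individual = ind / tot, operator = bias / tot, noise = noise / tot)
}

#' Generate a full-replica synthetic study
#'
#' Every operator digitizes every individual once, producing
#' `n_individuals * length(operators)` records (60 under the defaults).
#' Each record is the individual's true configuration plus the operator's
#' fixed bias field plus independent Gaussian digitizing noise, larger on
#' bone than on soft-tissue landmarks. The same seed always reproduces
#' the same dataset.
#'
#' @param spec A [synthetic_spec()] with `replicate_design = "full"`.
#' @param seed Integer seed for the single pseudo-random stream.
#' @param sex Sex assigned to all individuals (the replica design is
#'   single-sex by construction).
#' @return A list with elements `dataset` (a [landmark_dataset()]) and
#'   `truth` (class `synthetic_truth`: true configurations, bias fields,
#'   noise SDs, expected variance fractions, and the seed).
#' @export
generate_replica_study <- function(spec = synthetic_spec(), seed = 1,
                                   sex = "F") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$replicate_design != "full")
    stop("generate_replica_study requires replicate_design = 'full'")
  set.seed(as.integer(seed))
  template <- make_template(spec$panel, spec$mean_size)
  p <- nrow(template)
  n <- spec$n_individuals
  ops <- spec$operators
  ind_ids <- sprintf("ind%02d", seq_len(n))
  true_configs <- array(0, c(p, 3, n), dimnames = list(spec$panel$names,
                                                       c("x", "y", "z"),
                                                       ind_ids))
  for (i in seq_len(n)) true_configs[, , i] <- draw_true_config(spec, template, sex)
  n_rec <- n * length(ops)
  coords <- array(0, c(p, 3, n_rec))
  info <- data.frame(individual_id = rep(ind_ids, each = length(ops)),
                     operator_id = rep(ops, n),
                     sex = sex, replicate_id = "r1",
                     stringsAsFactors = FALSE)
  r <- 0L
  for (i in seq_len(n)) for (o in ops) {
    r <- r + 1L
    coords[, , r] <- add_noise(spec, true_configs[, , i] + spec$operator_bias[[o]])
  }
  dataset <- landmark_dataset(spec$panel, coords, info)
  truth <- structure(list(spec = spec, seed = as.integer(seed),
                          true_configs = true_configs,
                          operator_bias = spec$operator_bias,
                          noise_sd = noise_sd_by_landmark(spec),
                          design_fractions = design_fractions(spec)),
                     class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' Generate a partitioned synthetic study sample
#'
#' Each individual is digitized once, by a single operator; the default
#' per-(operator, sex) counts reproduce the unbalanced design of a large
#' population study (F/M: 102/61, 106/163, 252/222; 906 records in
#' total). Sex effects (a size shift and a fixed shape displacement
#' field) are applied to the true configurations before operator bias
#' and digitizing noise.
#'
#' @param spec A [synthetic_spec()] with `replicate_design = "partition"`.
#' @param seed Integer seed.
#' @return As [generate_replica_study()].
#' @export
generate_study_sample <- function(spec = synthetic_spec(replicate_design = "partition"),
                                  seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$replicate_design != "partition")
    stop("generate_study_sample requires replicate_design = 'partition'")
  set.seed(as.integer(seed))
  template <- make_template(spec$panel, spec$mean_size)
  p <- nrow(template)
  cells <- spec$sex_counts
  n <- sum(cells$n)
  coords <- array(0, c(p, 3, n))
  info <- data.frame(individual_id = sprintf("ind%03d", seq_len(n)),
                     operator_id = rep(cells$operator, cells$n),
                     sex = rep(cells$sex, cells$n),
                     replicate_id = "r1", stringsAsFactors = FALSE)
  true_configs <- array(0, c(p, 3, n))
  for (i in seq_len(n)) {
    true_configs[, , i] <- draw_true_config(spec, template, info$sex[i])
    coords[, , i] <- add_noise(spec, true_configs[, , i] +
                                 spec$operator_bias[[info$operator_id[i]]])
  }
  dataset <- landmark_dataset(spec$panel, coords, info)
  truth <- structure(list(spec = spec, seed = as.integer(seed),
                          true_configs = true_configs,
                          operator_bias = spec$operator_bias,
                          noise_sd = noise_sd_by_landmark(spec),
                          design_fractions = design_fractions(spec)),
                     class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}
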