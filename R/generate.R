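#' Configuration for the synthetic descriptor-table generator
#'
#' Builds a validated configuration describing a synthetic literature-style
#' Kd compilation: replicate log Kd measurements over compounds split into
#' four charge classes, each class with its own linear dependence of log Kd
#' on log Kow, plus molecular-descriptor columns with known signal,
#' redundancy and noise structure.
#'
#' The defaults emulate a compilation of 297 measurements over 148
#' pharmaceuticals (92 uncharged / 105 positive / 76 negative /
#' 24 zwitterion measurements over 44 / 60 / 28 / 16 compounds), with
#' class-wise slopes on log Kow of 0.42 / 0.45 / 0 / 0.1, intercepts
#' 1.07 / 1.53 / 1.73 / 1.5, and a mean replicate log Kd range of 0.91
#' log units for compounds measured more than once.
#'
#' @param n_compounds Total number of compounds.
#' @param class_measurement_counts Named vector (uncharged, positive,
#'   negative, zwitterion) of measurement counts per charge class.
#' @param class_compound_counts Named vector of compound counts per class;
#'   must sum to `n_compounds` with each class having no more compounds
#'   than measurements.
#' @param n_descriptors Total number of descriptor columns (signal +
#'   redundant + noise).
#' @param n_redundant Number of near-collinear descriptor columns built as
#'   linear combinations of 2-3 signal columns.
#' @param class_slopes,class_intercepts Named vectors of the true linear
#'   dependence of latent log Kd on log Kow within each class.
#' @param nonlinearity_amplitude Amplitude of a smooth bounded nonlinear
#'   term added to the latent log Kd (0 = purely linear truth). The term is
#'   a mixture of a cosine ridge and a shifted tanh ridge over standard
#'   normal signal descriptors, i.e. exactly the kind of low-dimensional
#'   smooth structure a small tanh network can represent but a linear model
#'   cannot.
#' @param compound_noise_sd Standard deviation (log units) of the
#'   per-compound deviation from the class line.
#' @param replicate_spread_target Target mean range (max - min, log units)
#'   of replicate log Kd values over compounds with >= 2 measurements.
#'   Replicate noise is uniform on an interval whose width is calibrated
#'   from the realised replicate-count mix so the expected mean range
#'   equals this target (the range of k iid uniforms on width w has
#'   expectation w (k-1)/(k+1)). Set to 0 for replicate-noise-free data.
#' @param redundancy_noise_sd Noise added to the redundant columns on top
#'   of their generating linear combinations.
#' @param logkow_mean,logkow_sd Distribution of compound log Kow values.
#' @param max_replicates Cap on measurements per compound.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return An object of class `kd_generator_config` (a named list).
#' @export
generator_config <- function(n_compounds = 148L,
                             class_measurement_counts = c(uncharged = 92L, positive = 105L,
                                                          negative = 76L, zwitterion = 24L),
                             class_compound_counts = c(uncharged = 44L, positive = 60L,
                                                       negative = 28L, zwitterion = 16L),
                             n_descriptors = 25L,
                             n_redundant = 4L,
                             class_slopes = c(uncharged = 0.42, positive = 0.45,
                                              negative = 0.0, zwitterion = 0.1),
                             class_intercepts = c(uncharged = 1.07, positive = 1.53,
                                                  negative = 1.73, zwitterion = 1.5),
                             nonlinearity_amplitude = 0.8,
                             compound_noise_sd = 0.2,
                             replicate_spread_target = 0.91,
                             redundancy_noise_sd = 0.02,
                             logkow_mean = 2.0,
                             logkow_sd = 2.6,
                             max_replicates = 12L,
                             seed = 1L) {
  classes <- kd_charge_classes()
  bad_field <- function(field, msg) {
    abort(sprintf("Invalid generator configuration: `%s` %s", field, msg),
          class = "sorbkd_config_error")
  }
  check_count(n_compounds, "n_compounds")

  for (nmv in c("class_measurement_counts", "class_compound_counts",
                "class_slopes", "class_intercepts")) {
    v <- get(nmv)
    if (!all(classes %in% names(v))) {
      bad_field(nmv, sprintf("must be named with all of: %s.",
                             paste(classes, collapse = ", ")))
    }
  }
  class_measurement_counts <- class_measurement_counts[classes]
  class_compound_counts <- class_compound_counts[classes]
  if (any(class_measurement_counts < 0)) {
    bad_field("class_measurement_counts", "must be non-negative.")
  }
  if (sum(class_compound_counts) != n_compounds) {
    bad_field("class_compound_counts",
              sprintf("must sum to n_compounds (%d).", n_compounds))
  }
  if (any(class_compound_counts > class_measurement_counts)) {
    bad_field("class_compound_counts",
              "cannot exceed class_measurement_counts in any class.")
  }
  if (any(class_compound_counts < 1 & class_measurement_counts > 0)) {
    bad_field("class_compound_counts",
              "must be >= 1 in every class with measurements.")
  }
  check_count(n_descriptors, "n_descriptors")
  if (!is.numeric(n_redundant) || n_redundant < 0 || n_redundant != round(n_redundant)) {
    bad_field("n_redundant", "must be a non-negative integer.")
  }
  if (n_redundant >= n_descriptors) {
    bad_field("n_redundant", "must be smaller than n_descriptors.")
  }
  # 6 structural signal columns (exact log Kow copy, 3 charge surrogates,
  # 2 nonlinearity inputs) must fit.
  if (n_descriptors < 6 + n_redundant) {
    bad_field("n_descriptors",
              sprintf("must be at least %d (6 signal + n_redundant columns).",
                      6 + n_redundant))
  }
  if (!is.numeric(replicate_spread_target) || replicate_spread_target < 0) {
    bad_field("replicate_spread_target", "must be >= 0.")
  }
  if (!is.numeric(compound_noise_sd) || compound_noise_sd < 0) {
    bad_field("compound_noise_sd", "must be >= 0.")
  }
  if (!is.numeric(nonlinearity_amplitude) || nonlinearity_amplitude < 0) {
    bad_field("nonlinearity_amplitude", "must be >= 0.")
  }
  check_count(max_replicates, "max_replicates")
  check_count(abs(seed) + 1, "seed")

  structure(
    list(
      n_compounds = as.integer(n_compounds),
      class_measurement_counts = class_measurement_counts,
      class_compound_counts = class_compound_counts,
      n_descriptors = as.integer(n_descriptors),
      n_redundant = as.integer(n_redundant),
      class_slopes = class_slopes[classes],
      class_intercepts = class_intercepts[classes],
      nonlinearity_amplitude = nonlinearity_amplitude,
      compound_noise_sd = compound_noise_sd,
      replicate_spread_target = replicate_spread_target,
      redundancy_noise_sd = redundancy_noise_sd,
      logkow_mean = logkow_mean,
      logkow_sd = logkow_sd,
      max_replicates = as.integer(max_replicates),
      seed = as.integer(seed)
    ),
    class = "kd_generator_config"
  )
}

# Distribute `total` measurements over `n` compounds: everyone gets 1, the
# remainder is allocated by preferential attachment (probability
# proportional to current count), giving the 1-3 bulk / long-tail mix seen
# in literature compilations, capped at `cap`.
allocate_replicates <- function(n, total, cap) {
  counts <- rep(1L, n)
  extra <- total - n
  while (extra > 0L) {
    open <- which(counts < cap)
    if (length(open) == 0L) break
    pick <- if (length(open) == 1L) open else {
      open[sample.int(length(open), 1L, prob = counts[open])]
    }
    counts[pick] <- counts[pick] + 1L
    extra <- extra - 1L
  }
  counts
}

# Smooth bounded nonlinear truth: cosine ridge (an even function, so it
# carries no linear signal) plus a shifted saturating ridge, both over
# signal descriptors independent of log Kow so the class slopes stay
# recoverable by univariate regression. Centred analytically
# (E[cos(1.3 z)] = exp(-1.69/2) for z ~ N(0,1); the tanh mean by
# quadrature) so the configured class lines are the conditional means.
kd_nonlinear_term <- function(s1, s2) {
  (cos(1.3 * (0.8 * s1 + 0.6 * s2)) - 0.4295573582) +
    0.35 * (tanh(1.2 * s2 - 0.5) + 0.2643937065)
}

#' Generate a synthetic descriptor table with known ground truth
#'
#' Draws compounds with class labels, log Kow values and descriptor
#' profiles, then replicate log Kd measurements around a class-wise linear
#' (plus optional smooth nonlinear) truth. Identical seeds give
#' bit-identical output.
#'
#' @param config A [generator_config()].
#' @return A list with elements
#'   \describe{
#'     \item{data}{A tibble descriptor table: reserved columns
#'       (`compound_id`, `charge_class`, `log_kow`, `log_dow_74`,
#'       `log_kd`, `study_id`) plus `n_descriptors` numeric descriptor
#'       columns (`d_logkow`, charge surrogates `chg_*`, signal columns
#'       `s01`/`s02`, redundant columns `r01`..., noise columns `n01`...).}
#'     \item{truth}{Ground truth: class slopes/intercepts, per-compound
#'       latent log Kd, signal/redundant/noise column names, the redundant
#'       columns' generating combinations, and the calibrated replicate
#'       noise width.}
#'   }
#' @export
generate_dataset <- function(config = generator_config()) {
  if (!inherits(config, "kd_generator_config")) {
    abort("`config` must be created by generator_config().",
          class = "sorbkd_config_error")
  }
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  classes <- kd_charge_classes()
  n_cmp <- config$n_compounds

  cls <- rep(classes, times = config$class_compound_counts)
  compound_id <- sprintf("C%03d", seq_len(n_cmp))

  # replicate counts per compound, class by class so class measurement
  # margins are exact
  reps <- integer(n_cmp)
  for (cc in classes) {
    idx <- which(cls == cc)
    if (length(idx) == 0L) next
    reps[idx] <- allocate_replicates(length(idx),
                                     config$class_measurement_counts[[cc]],
                                     config$max_replicates)
  }

  # per-compound attributes
  log_kow <- rnorm(n_cmp, config$logkow_mean, config$logkow_sd)
  s1 <- rnorm(n_cmp)
  s2 <- rnorm(n_cmp)
  chg <- cbind(
    chg_pos = as.numeric(cls == "positive") + rnorm(n_cmp, 0, 0.05),
    chg_neg = as.numeric(cls == "negative") + rnorm(n_cmp, 0, 0.05),
    chg_zwit = as.numeric(cls == "zwitterion") + rnorm(n_cmp, 0, 0.05)
  )
  dow_shift <- c(uncharged = 0, positive = -1.5, negative = -2, zwitterion = -1)
  log_dow <- log_kow + dow_shift[cls] + rnorm(n_cmp, 0, 0.3)

  e_cmp <- if (config$compound_noise_sd > 0) {
    rnorm(n_cmp, 0, config$compound_noise_sd)
  } else {
    rep(0, n_cmp)
  }
  nonlin <- if (config$nonlinearity_amplitude > 0) {
    config$nonlinearity_amplitude * kd_nonlinear_term(s1, s2)
  } else {
    rep(0, n_cmp)
  }
  latent <- config$class_intercepts[cls] + config$class_slopes[cls] * log_kow +
    nonlin + e_cmp

  # descriptor blocks (per compound)
  n_noise <- config$n_descriptors - 6L - config$n_redundant
  noise_block <- matrix(rnorm(n_cmp * n_noise), n_cmp, n_noise)
  colnames(noise_block) <- sprintf("n%02d", seq_len(max(n_noise, 0L)))
  signal_block <- cbind(d_logkow = log_kow, chg, s01 = s1, s02 = s2)

  redundant <- NULL
  redundant_truth <- list()
  if (config$n_redundant > 0L) {
    redundant <- matrix(0, n_cmp, config$n_redundant)
    colnames(redundant) <- sprintf("r%02d", seq_len(config$n_redundant))
    for (j in seq_len(config$n_redundant)) {
      k <- sample(2:3, 1L)
      parents <- sample(colnames(signal_block), k)
      coefs <- runif(k, 0.5, 1.5) * sample(c(-1, 1), k, replace = TRUE)
      redundant[, j] <- signal_block[, parents, drop = FALSE] %*% coefs +
        rnorm(n_cmp, 0, config$redundancy_noise_sd)
      redundant_truth[[colnames(redundant)[j]]] <-
        list(parents = parents, coefficients = coefs,
             noise_sd = config$redundancy_noise_sd)
    }
  }
  desc_cmp <- cbind(signal_block, redundant, noise_block)

  # expand to measurement rows
  row_cmp <- rep(seq_len(n_cmp), times = reps)
  n_meas <- length(row_cmp)

  # calibrate uniform replicate-noise width from realised replicate counts:
  # E[range of k iid U(0, w)] = w (k-1)/(k+1)
  k_multi <- reps[reps >= 2L]
  factor <- if (length(k_multi) > 0L) mean((k_multi - 1) / (k_multi + 1)) else 1 / 3
  width <- if (config$replicate_spread_target > 0) {
    config$replicate_spread_target / factor
  } else {
    0
  }
  repl_noise <- if (width > 0) runif(n_meas, -width / 2, width / 2) else rep(0, n_meas)

  data <- tibble::tibble(
    compound_id = compound_id[row_cmp],
    charge_class = cls[row_cmp],
    log_kow = log_kow[row_cmp],
    log_dow_74 = as.numeric(log_dow[row_cmp]),
    log_kd = as.numeric(latent[row_cmp] + repl_noise),
    study_id = sprintf("S%03d", seq_len(n_meas))
  )
  data <- dplyr::bind_cols(
    data,
    tibble::as_tibble(desc_cmp[row_cmp, , drop = FALSE])
  )
  attr(data, "provenance") <- "synthetic"

  truth <- list(
    class_slopes = config$class_slopes,
    class_intercepts = config$class_intercepts,
    compound_latent = tibble::tibble(
      compound_id = compound_id, charge_class = cls, log_kow = log_kow,
      latent_log_kd = as.numeric(latent), n_measurements = reps
    ),
    signal_columns = colnames(signal_block),
    nonlinear_columns = c("s01", "s02", "d_logkow"),
    redundant_columns = redundant_truth,
    noise_columns = colnames(noise_block),
    replicate_noise_width = width,
    replicate_count_factor = factor,
    nonlinearity_amplitude = config$nonlinearity_amplitude
  )
  list(data = data, truth = truth)
}

#' Replicate spread of log Kd over compounds measured more than once
#'
#' For every compound with at least two measurements, computes the range
#' (max - min) of its log Kd values, and returns the mean and median range
#' over those compounds. Returns zeros if no compound has replicates.
#'
#' @param data A descriptor table with `compound_id` and `log_kd` columns.
#' @return A one-row tibble with columns `mean_range`, `median_range`,
#'   `n_compounds_multi`.
#' @export
replicate_range_statistic <- function(data) {
  if (!all(c("compound_id", "log_kd") %in% names(data)) || nrow(data) == 0L) {
    abort("`data` must be a nonempty table with compound_id and log_kd.",
          class = "sorbkd_input_error")
  }
  counts <- table(data$compound_id)
  multi <- names(counts)[counts >= 2L]
  if (length(multi) == 0L) {
    return(tibble::tibble(mean_range = 0, median_range = 0,
                          n_compounds_multi = 0L))
  }
  ranges <- vapply(multi, function(id) {
    v <- data$log_kd[data$compound_id == id]
    max(v) - min(v)
  }, numeric(1))
  tibble::tibble(
    mean_range = mean(ranges),
    median_range = median(ranges),
    n_compounds_multi = length(ranges)
  )
}
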