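#' Simulation configuration
#'
#' Collects every parameter of the neuron-population voxel simulator.  Each
#' voxel's signal is the sum of `n_neurons` circular-Gaussian-tuned neurons
#' with randomly drawn preferred features, bandwidths and amplitudes.  Per
#' trial, i.i.d. Gaussian noise (SD `noise_sd`) is added to each neuron's
#' response and the condition's multiplicative gain is then applied, so gain
#' scales signal and noise together.
#'
#' @param n_voxels Number of simulated voxels.
#' @param n_neurons Neurons per voxel.
#' @param orientations Stimulus feature values, degrees; default 8 evenly
#'   spaced orientations covering the 180-degree space.
#' @param n_trials_per_cell Trials per orientation x condition cell; must be
#'   even so a balanced train/test split exists.
#' @param gains Per-condition multiplicative gain factors (condition 1
#'   first); the default contrasts g = 1 against g = 1.8.
#' @param noise_sd SD of the per-neuron additive Gaussian noise, response
#'   units; 0 gives a deterministic (given the populations) dataset.
#' @param tuning_sd_range Range (degrees) from which each neuron's tuning
#'   bandwidth sigma is drawn uniformly.
#' @param amplitude_range Range (response units) from which each neuron's
#'   peak amplitude is drawn uniformly.
#' @param seed RNG seed; the whole dataset is a pure function of this config
#'   including the seed.
#' @param space A [feature_space()].
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(noise_sd = 0, seed = 1)
#' @export
sim_config <- function(n_voxels = 100, n_neurons = 100,
                       orientations = NULL, n_trials_per_cell = 8,
                       gains = c(1, 1.8), noise_sd = 0,
                       tuning_sd_range = c(10, 40),
                       amplitude_range = c(0.5, 1.5),
                       seed = 1, space = feature_space()) {
  if (is.null(orientations)) {
    orientations <- space$period * (0:7) / 8
  }
  cfg <- structure(
    list(n_voxels = as.integer(n_voxels), n_neurons = as.integer(n_neurons),
         orientations = as.numeric(orientations),
         n_trials_per_cell = as.integer(n_trials_per_cell),
         gains = as.numeric(gains), noise_sd = as.numeric(noise_sd),
         tuning_sd_range = as.numeric(tuning_sd_range),
         amplitude_range = as.numeric(amplitude_range),
         seed = as.integer(seed), space = space),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg, ...) if (!ok) stop_iemr("iemr_invalid_parameter", msg, ...)
  chk(length(cfg$seed) == 1L && !is.na(cfg$seed), "`seed` must be a single integer")
  chk(cfg$n_voxels >= 1, "`n_voxels` must be >= 1")
  chk(cfg$n_neurons >= 1, "`n_neurons` must be >= 1")
  chk(cfg$n_trials_per_cell >= 1, "`n_trials_per_cell` must be >= 1")
  chk(length(cfg$orientations) >= 1 && all(cfg$orientations >= 0) &&
        all(cfg$orientations < cfg$space$period),
      "`orientations` must lie in [0, period)")
  chk(all(cfg$gains > 0), "`gains` must all be positive")
  chk(cfg$noise_sd >= 0, "`noise_sd` must be >= 0")
  rng_ok <- function(r) length(r) == 2L && all(r > 0) && r[1] <= r[2]
  chk(rng_ok(cfg$tuning_sd_range), "`tuning_sd_range` must be positive and ordered")
  chk(rng_ok(cfg$amplitude_range), "`amplitude_range` must be positive and ordered")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulation config: %d voxels x %d neurons; %d orientations x %d conditions x %d trials\n",
    "gains: %s; neural noise SD %g; sigma in [%g, %g] deg; amplitude in [%g, %g]; seed %d\n"),
    x$n_voxels, x$n_neurons, length(x$orientations), length(x$gains),
    x$n_trials_per_cell, paste(x$gains, collapse = ", "), x$noise_sd,
    x$tuning_sd_range[1], x$tuning_sd_range[2],
    x$amplitude_range[1], x$amplitude_range[2], x$seed))
  invisible(x)
}

#' Circular-Gaussian neuron tuning function
#'
#' Response of a neuron with preferred feature `center`, bandwidth `sigma`
#' and peak `amplitude` to a stimulus at `theta`:
#' `amplitude * exp(-d(theta, center)^2 / (2 sigma^2))` with `d` the
#' circular distance, so the response is periodic in the feature.
#'
#' @param theta Stimulus feature, degrees (vectorized).
#' @param center Preferred feature, degrees.
#' @param sigma Tuning bandwidth, degrees (> 0).
#' @param amplitude Peak response, response units.
#' @param period Feature period, degrees.
#' @return Responses in `(0, amplitude]`.
#' @export
neuron_response <- function(theta, center, sigma, amplitude = 1, period = 180) {
  if (any(sigma <= 0)) {
    stop_iemr("iemr_invalid_parameter", "`sigma` must be > 0")
  }
  d <- circ_dist(theta, center, period)
  amplitude * exp(-d^2 / (2 * sigma^2))
}

#' Draw neuron populations for every voxel
#'
#' Each voxel receives its own independent population of `n_neurons`
#' neurons: preferred features uniform on `[0, period)`, bandwidths uniform
#' on `tuning_sd_range`, amplitudes uniform on `amplitude_range`.
#'
#' @param config A [sim_config()].
#' @param seed Seed for the draw; defaults to `config$seed`. Pass `NULL` to
#'   use the current RNG state (as [simulate_dataset()] does after seeding).
#' @return A list of `n_voxels` populations, each a list with numeric
#'   vectors `centers`, `bandwidths`, `amplitudes` of length `n_neurons`.
#' @export
sample_populations <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  period <- config$space$period
  lapply(seq_len(config$n_voxels), function(v) {
    list(
      centers = stats::runif(config$n_neurons, 0, period),
      bandwidths = stats::runif(config$n_neurons, config$tuning_sd_range[1],
                                config$tuning_sd_range[2]),
      amplitudes = stats::runif(config$n_neurons, config$amplitude_range[1],
                                config$amplitude_range[2])
    )
  })
}

#' Simulate a voxel-level dataset from tuned neuron populations
#'
#' Generates the trial structure (every orientation crossed with every
#' condition, `n_trials_per_cell` repeats), draws the neuron populations,
#' and computes each voxel's activation per trial as the sum over its
#' neurons of `neuron_response(theta) + noise` multiplied by the condition's
#' gain (noise added before gain).  Trials are assigned to balanced train
#' and test halves within every orientation x condition cell.
#'
#' @param config A [sim_config()].
#' @return An object of class `"iem_dataset"`: a list with `activations`
#'   (voxels x trials matrix), `orientation`, `condition`, `split` (trial
#'   label vectors), `config`, and `populations` (the sampled ground truth).
#' @examples
#' ds <- simulate_dataset(sim_config(n_voxels = 4, n_neurons = 10, seed = 2))
#' dim(ds$activations)
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  pops <- sample_populations(config, seed = NULL)

  n_ori <- length(config$orientations)
  n_cond <- length(config$gains)
  cells <- expand.grid(rep = seq_len(config$n_trials_per_cell),
                       condition = seq_len(n_cond),
                       orientation = config$orientations)
  n_trials <- nrow(cells)
  ori_idx <- match(cells$orientation, config$orientations)

  ## tuning of every neuron (all voxels stacked) at the distinct orientations
  centers <- unlist(lapply(pops, `[[`, "centers"))
  sigmas <- unlist(lapply(pops, `[[`, "bandwidths"))
  amps <- unlist(lapply(pops, `[[`, "amplitudes"))
  d <- outer(centers, config$orientations, circ_dist, period = config$space$period)
  tuning <- amps * exp(-d^2 / (2 * sigmas^2))      # (voxels*neurons) x n_ori

  resp <- tuning[, ori_idx, drop = FALSE]          # expand to trials
  if (config$noise_sd > 0) {
    resp <- resp + matrix(stats::rnorm(length(resp), 0, config$noise_sd),
                          nrow = nrow(resp))
  }
  resp <- sweep(resp, 2, config$gains[cells$condition], `*`)
  voxel_id <- rep(seq_len(config$n_voxels), each = config$n_neurons)
  activations <- rowsum(resp, voxel_id)
  dimnames(activations) <- list(sprintf("vox%03d", seq_len(config$n_voxels)),
                                sprintf("trial%03d", seq_len(n_trials)))

  ## balanced halves: within each cell the first half of the repeats trains
  split <- ifelse(cells$rep <= config$n_trials_per_cell / 2, "train", "test")
  if (config$n_trials_per_cell %% 2 == 1) split <- rep(NA_character_, n_trials)

  structure(
    list(activations = activations,
         orientation = cells$orientation,
         condition = as.integer(cells$condition),
         split = split,
         config = config,
         populations = pops),
    class = "iem_dataset"
  )
}

#' @export
print.iem_dataset <- function(x, ...) {
  cat(sprintf("Simulated IEM dataset: %d signals x %d trials (%d orientations x %d conditions)\n",
              nrow(x$activations), ncol(x$activations),
              length(unique(x$orientation)), length(unique(x$condition))))
  if (!is.null(x$config)) {
    cat(sprintf("gains: %s; neural noise SD %g; seed %d\n",
                paste(x$config$gains, collapse = ", "),
                x$config$noise_sd, x$config$seed))
  }
  invisible(x)
}

#' Split a dataset into balanced train and test halves
#'
#' Returns two disjoint views of the dataset, each holding exactly half of
#' every orientation x condition cell's trials, so both halves are balanced
#' across stimulus type and experimental condition.  Uses the split labels
#' assigned at simulation time, or assigns a deterministic balanced split if
#' the dataset carries none.
#'
#' @param dataset An `iem_dataset`.
#' @return A list with elements `train` and `test`, each an `iem_dataset`.
#' @export
split_train_test <- function(dataset) {
  split <- dataset$split
  if (is.null(split) || anyNA(split)) {
    cell <- interaction(dataset$orientation, dataset$condition, drop = TRUE)
    counts <- table(cell)
    if (any(counts %% 2 != 0)) {
      stop_iemr("iemr_invalid_input",
                "cannot split: orientation x condition cells have odd trial counts (%s)",
                paste(counts[counts %% 2 != 0], collapse = ", "))
    }
    split <- rep(NA_character_, length(cell))
    for (lv in levels(cell)) {
      idx <- which(cell == lv)
      split[idx] <- rep(c("train", "test"), each = length(idx) / 2)
    }
  }
  list(train = subset_dataset(dataset, split == "train"),
       test = subset_dataset(dataset, split == "test"))
}

subset_dataset <- function(dataset, idx) {
  out <- dataset
  out$activations <- dataset$activations[, idx, drop = FALSE]
  out$orientation <- dataset$orientation[idx]
  out$condition <- dataset$condition[idx]
  out$split <- dataset$split[idx]
  out
}
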