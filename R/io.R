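## File dialect shared by all writers: UTF-8, comma-delimited numeric
## matrices with one header row, full float precision (%.17g, lossless
## round trip), JSON sidecar next to the matrix for all metadata.

write_matrix_csv <- function(m, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  cols <- colnames(m)
  if (is.null(cols)) cols <- sprintf("col%03d", seq_len(ncol(m)))
  writeLines(paste(c("row", cols), collapse = ","), con)
  rows <- rownames(m)
  if (is.null(rows)) rows <- sprintf("row%03d", seq_len(nrow(m)))
  body <- apply(m, 1, function(x) paste(sprintf("%.17g", x), collapse = ","))
  writeLines(paste(rows, body, sep = ","), con)
  invisible(path)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

sidecar_path <- function(path) sub("\\.csv$", "", path) |> paste0(".json")

#' Write / read a simulated dataset
#'
#' The activation matrix goes to `<path>` as a delimited matrix (rows =
#' signals, columns = trials); trial labels and the full generative truth
#' (config and sampled neuron populations) go to a JSON sidecar
#' `<path basename>.json`.  The round trip is lossless at full float
#' precision.
#'
#' @param dataset An `iem_dataset`.
#' @param path Path of the CSV matrix file (sidecar written next to it).
#' @return `path`, invisibly (`write_dataset`); an `iem_dataset`
#'   (`read_dataset`).
#' @export
write_dataset <- function(dataset, path) {
  write_matrix_csv(dataset$activations, path)
  cfg <- dataset$config
  meta <- list(
    orientation = dataset$orientation,
    condition = dataset$condition,
    split = dataset$split,
    config = if (!is.null(cfg)) {
      c(unclass(cfg)[setdiff(names(cfg), "space")],
        list(period = cfg$space$period, n_grid = cfg$space$n_grid))
    },
    populations = dataset$populations,
    units = "response units"
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  m <- read_matrix_csv(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  cfg <- NULL
  if (!is.null(meta$config)) {
    mc <- meta$config
    cfg <- sim_config(
      n_voxels = mc$n_voxels, n_neurons = mc$n_neurons,
      orientations = mc$orientations, n_trials_per_cell = mc$n_trials_per_cell,
      gains = mc$gains, noise_sd = mc$noise_sd,
      tuning_sd_range = mc$tuning_sd_range, amplitude_range = mc$amplitude_range,
      seed = mc$seed, space = feature_space(mc$period, mc$n_grid)
    )
  }
  structure(
    list(activations = m,
         orientation = as.numeric(meta$orientation),
         condition = as.integer(meta$condition),
         split = if (!is.null(meta$split)) as.character(meta$split),
         config = cfg,
         populations = meta$populations),
    class = "iem_dataset"
  )
}

#' Write / read a channel basis set
#'
#' Channels x grid sensitivity matrix as delimited text plus a JSON sidecar
#' holding centers, exponent, kind, lineage and period.
#'
#' @param basis An `iem_basis`.
#' @param path Path of the CSV matrix file.
#' @return `path`, invisibly (`write_basis`); an `iem_basis` (`read_basis`).
#' @export
write_basis <- function(basis, path) {
  m <- basis$values
  colnames(m) <- sprintf("deg%.6g", basis$space$grid)
  write_matrix_csv(m, path)
  jsonlite::write_json(
    list(centers = basis$centers, exponent = basis$exponent, kind = basis$kind,
         canonical = basis$canonical, lineage = basis$lineage,
         period = basis$space$period, n_grid = basis$space$n_grid),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  sp <- feature_space(meta$period, meta$n_grid)
  exponent <- if (is.null(meta$exponent) || is.na(meta$exponent)) NA_real_ else meta$exponent
  new_basis(as.numeric(meta$centers), exponent, kind = meta$kind,
            canonical = meta$canonical,
            lineage = matrix(as.numeric(meta$lineage), length(meta$centers)),
            space = sp)
}

#' Write reconstructed channel response profiles
#'
#' Per-trial profiles as a delimited table (rows = trials, columns =
#' channels) and, when condition labels exist, condition-averaged profiles
#' alongside; the JSON sidecar records basis lineage, scheme and the units
#' convention ("arbitrary units").
#'
#' @param recon An `iem_recon`.
#' @param path Path of the per-trial CSV file.
#' @param extra Optional named list merged into the sidecar (e.g. seed,
#'   config hash).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(recon, path, extra = list()) {
  write_matrix_csv(t(recon$profiles), path)
  avg_path <- sub("\\.csv$", "_condition_average.csv", path)
  write_matrix_csv(t(condition_average(recon)), avg_path)
  meta <- c(list(
    units = recon$units, scheme = recon$scheme,
    orientation = recon$orientation, condition = recon$condition,
    basis = list(kind = recon$basis$kind, centers = recon$basis$centers,
                 exponent = recon$basis$exponent,
                 canonical = recon$basis$canonical,
                 lineage = recon$basis$lineage,
                 period = recon$basis$space$period),
    tie_break = "peak/argmax reporting: lowest channel index wins"
  ), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Write a gain-estimate table
#'
#' @param tab Result of [gain_recovery_experiment()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gain_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
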