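#' Fit a voxel-wise forward encoding model
#'
#' Models each measured signal (e.g. voxel) as a linear combination of
#' channel responses: `B = W C + E`, where `B` is the signals x trials
#' activation matrix, `C = channel_design(basis, orientations)` is the
#' k x trials matrix of modeled channel responses, and `W` (signals x k)
#' holds the encoding weights.  `W` is the ordinary least-squares solution
#' per signal (no regularization, so invertible linear transforms of the
#' basis leave the fit quality exactly unchanged).
#'
#' @param activations Signals x trials numeric matrix of training data.
#' @param orientations Stimulus feature per training trial, degrees.
#' @param basis An `iem_basis`.
#' @param tol Relative rank tolerance for the channel design matrix.
#' @return An object of class `"iem"` with components `weights`
#'   (signals x k), `basis`, `fit_r2` (training variance explained per
#'   signal), `train_rss` (total training residual sum of squares), and the
#'   training design. Methods: [coef.iem()], [predict.iem()],
#'   [fitted.iem()], [residuals.iem()], `print`, `summary`.
#' @examples
#' ds <- simulate_dataset(sim_config(n_voxels = 10, n_neurons = 20, seed = 3))
#' halves <- split_train_test(ds)
#' fit <- iem(halves$train$activations, halves$train$orientation, cosine_basis(8))
#' fit
#' @export
iem <- function(activations, orientations, basis, tol = 1e-8) {
  activations <- as_activation_matrix(activations)
  if (length(orientations) != ncol(activations)) {
    stop_iemr("iemr_shape_error",
              "%d orientation labels for %d trial columns",
              length(orientations), ncol(activations))
  }
  C <- channel_design(basis, orientations)
  k <- nrow(C)
  if (ncol(C) < k) {
    stop_iemr("iemr_rank_error",
              "need at least k = %d training trials, got %d", k, ncol(C))
  }
  s <- svd(C, nu = 0, nv = 0)$d
  if (min(s) <= tol * max(s)) {
    stop_iemr("iemr_rank_error",
              "channel design matrix is rank deficient: rank %d < k = %d channels (the training orientations do not span the channel space)",
              sum(s > tol * max(s)), k)
  }
  ## normal equations per signal: W = B C' (C C')^{-1}
  G <- C %*% t(C)
  W <- t(solve(G, C %*% t(activations)))
  dimnames(W) <- list(rownames(activations), rownames(C))
  fitted <- W %*% C
  res <- activations - fitted
  tss <- rowSums(sweep(activations, 1, rowMeans(activations))^2)
  r2 <- 1 - rowSums(res^2) / ifelse(tss > 0, tss, NA_real_)
  structure(
    list(weights = W, basis = basis, fit_r2 = r2,
         train_rss = sum(res^2), design = C, residuals = res,
         train_orientations = orientations, call = match.call()),
    class = "iem"
  )
}

as_activation_matrix <- function(x) {
  if (inherits(x, "iem_dataset")) x <- x$activations
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_iemr("iemr_invalid_parameter",
              "activations must be a numeric signals x trials matrix")
  }
  x
}

#' @export
print.iem <- function(x, ...) {
  cat(sprintf("Forward encoding model: %d signals x %d channels (%s basis), %d training trials\n",
              nrow(x$weights), ncol(x$weights), x$basis$kind, ncol(x$design)))
  cat(sprintf("training RSS %.6g; median per-signal R^2 %.4f\n",
              x$train_rss, stats::median(x$fit_r2, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.iem <- function(object, ...) {
  structure(list(
    n_signals = nrow(object$weights), k = ncol(object$weights),
    basis_kind = object$basis$kind, n_train = ncol(object$design),
    train_rss = object$train_rss,
    r2 = summary(object$fit_r2)
  ), class = "summary.iem")
}

#' @export
print.summary.iem <- function(x, ...) {
  cat(sprintf("Forward encoding model (%s basis): %d signals, %d channels, %d training trials\n",
              x$basis_kind, x$n_signals, x$k, x$n_train))
  cat(sprintf("training residual sum of squares: %.6g\n", x$train_rss))
  cat("per-signal training R^2:\n")
  print(x$r2)
  invisible(x)
}

#' Encoding weight matrix of a fitted model
#' @param object An `"iem"` fit.
#' @param ... Unused.
#' @return The signals x channels weight matrix `W`.
#' @export
coef.iem <- function(object, ...) object$weights

#' @export
fitted.iem <- function(object, ...) object$weights %*% object$design

#' @export
residuals.iem <- function(object, ...) object$residuals

#' Invert a fitted encoding model: reconstruct channel response profiles
#'
#' The inversion step of the IEM technique: given new activation patterns
#' `B` over the same signals, estimates the channel responses per trial as
#' the least-squares solution `Chat = (W'W)^{-1} W' B`.  Reconstructed
#' channel responses are in arbitrary units.
#'
#' @param object An `"iem"` fit.
#' @param newdata Signals x trials activation matrix (or `iem_dataset`)
#'   to reconstruct; signal count must match the training data.
#' @param tol Relative rank tolerance for the weight matrix.
#' @param ... Unused.
#' @return A k x trials matrix of reconstructed channel responses
#'   (arbitrary units).
#' @export
predict.iem <- function(object, newdata, tol = 1e-8, ...) {
  B <- as_activation_matrix(newdata)
  W <- object$weights
  if (nrow(B) != nrow(W)) {
    stop_iemr("iemr_shape_error",
              "newdata has %d signals but the model was fit on %d", nrow(B), nrow(W))
  }
  s <- svd(W, nu = 0, nv = 0)$d
  if (min(s) <= tol * max(s)) {
    stop_iemr("iemr_rank_error",
              "weight matrix is rank deficient (rank %d < %d channels); the model cannot be inverted",
              sum(s > tol * max(s)), ncol(W))
  }
  Chat <- solve(t(W) %*% W, t(W) %*% B)
  dimnames(Chat) <- list(colnames(W), colnames(B))
  Chat
}

#' Reconstruct channel response profiles under a training scheme
#'
#' Runs the full IEM pipeline on a dataset: estimates encoding weights on
#' training trials and reconstructs every designated test trial exactly
#' once.  Two schemes are supported:
#'
#' * `"fixed"` — a single fixed encoding model estimated on a neutral
#'   training partition balanced across conditions (by default the
#'   dataset's train half); activation patterns from all conditions are
#'   transformed into the same modeled information space, so conditions can
#'   be compared on equal footing.
#' * `"kfold"` — within-dataset k-fold cross-validation (with
#'   `folds = n_trials`, leave-one-trial-out): each fold is reconstructed
#'   by a model fit on the remaining folds; folds are balanced across
#'   orientation x condition cells.
#'
#' @param dataset An `iem_dataset` (simulated or loaded).
#' @param basis An `iem_basis`.
#' @param scheme `"fixed"` or `"kfold"`.
#' @param folds Number of folds for `scheme = "kfold"`; must divide every
#'   cell's trial count. Defaults to 2.
#' @param train,test Optional explicit trial indices for `scheme = "fixed"`,
#'   overriding the dataset's split; they must be disjoint (training on
#'   test trials is leakage and is refused).
#' @return An object of class `"iem_recon"`: `profiles` (k x n_test matrix,
#'   arbitrary units), `orientation`/`condition` labels for the
#'   reconstructed trials, `basis`, `scheme`, and for the fixed scheme the
#'   underlying `"iem"` fit.
#' @examples
#' ds <- simulate_dataset(sim_config(n_voxels = 10, n_neurons = 20, seed = 4))
#' rec <- reconstruct(ds, cosine_basis(8), scheme = "fixed")
#' rec
#' @export
reconstruct <- function(dataset, basis, scheme = c("fixed", "kfold"),
                        folds = 2, train = NULL, test = NULL) {
  scheme <- match.arg(scheme)
  n_trials <- ncol(dataset$activations)
  if (scheme == "fixed") {
    if (is.null(train) != is.null(test)) {
      stop_iemr("iemr_invalid_parameter",
                "provide both `train` and `test` indices, or neither")
    }
    if (is.null(train)) {
      halves <- split_train_test(dataset)
      train_ds <- halves$train
      test_ds <- halves$test
    } else {
      if (length(intersect(train, test)) > 0) {
        stop_iemr("iemr_leakage_error",
                  "training and test partitions overlap in %d trial(s); a fixed encoding model must be estimated on data disjoint from the test set",
                  length(intersect(train, test)))
      }
      train_ds <- subset_dataset(dataset, train)
      test_ds <- subset_dataset(dataset, test)
    }
    fit <- iem(train_ds$activations, train_ds$orientation, basis)
    profiles <- predict(fit, test_ds$activations)
    out_ori <- test_ds$orientation
    out_cond <- test_ds$condition
  } else {
    cell <- interaction(dataset$orientation, dataset$condition, drop = TRUE)
    counts <- table(cell)
    if (folds < 2 || folds > n_trials) {
      stop_iemr("iemr_invalid_parameter", "`folds` must be in [2, n_trials]")
    }
    if (folds == n_trials) {
      fold_id <- seq_len(n_trials)                 # leave-one-trial-out
    } else {
      if (any(counts %% folds != 0)) {
        stop_iemr("iemr_invalid_input",
                  "folds = %d does not divide every orientation x condition cell evenly",
                  folds)
      }
      fold_id <- integer(n_trials)
      for (lv in levels(cell)) {
        idx <- which(cell == lv)
        fold_id[idx] <- rep(seq_len(folds), length.out = length(idx))
      }
    }
    profiles <- matrix(NA_real_, n_channels(basis), n_trials,
                       dimnames = list(sprintf("ch%02d", seq_len(n_channels(basis))),
                                       colnames(dataset$activations)))
    fit <- NULL
    for (f in unique(fold_id)) {
      hold <- fold_id == f
      fold_fit <- iem(dataset$activations[, !hold, drop = FALSE],
                      dataset$orientation[!hold], basis)
      profiles[, hold] <- predict(fold_fit, dataset$activations[, hold, drop = FALSE])
    }
    stopifnot(!anyNA(profiles))                    # every trial reconstructed once
    out_ori <- dataset$orientation
    out_cond <- dataset$condition
  }
  structure(
    list(profiles = profiles, orientation = out_ori, condition = out_cond,
         basis = basis, scheme = scheme,
         fit = if (scheme == "fixed") fit else NULL,
         units = "arbitrary units"),
    class = "iem_recon"
  )
}

#' @export
print.iem_recon <- function(x, ...) {
  cat(sprintf("Reconstructed channel response profiles (%s): %d channels x %d trials, %s scheme\n",
              x$units, nrow(x$profiles), ncol(x$profiles), x$scheme))
  cat(sprintf("basis: %s (k = %d)\n", x$basis$kind, n_channels(x$basis)))
  invisible(x)
}

#' @export
plot.iem_recon <- function(x, recenter = x$basis$kind != "transformed", ...) {
  prof <- if (recenter) recenter_profiles(x)$profiles else x$profiles
  avg <- condition_average(prof, x$condition)
  graphics::matplot(avg, type = "b", pch = 16, lty = 1,
                    xlab = "channel", ylab = sprintf("channel response (%s)", x$units),
                    main = "Condition-averaged channel response profiles", ...)
  graphics::legend("topright", legend = paste("condition", seq_len(ncol(avg))),
                   col = seq_len(ncol(avg)), lty = 1, bty = "n")
  invisible(x)
}

#' Recenter channel response profiles on the true stimulus feature
#'
#' Circularly shifts each trial's k-vector so the channel tuned to that
#' trial's orientation lands at a common reference slot, after which
#' averaging across trials and conditions is meaningful.  Requires a
#' unimodal (cosine) or delta basis with evenly spaced centers and stimulus
#' orientations coinciding with channel centers: a bimodal or other
#' oddly-shaped transformed channel cannot be related to a single feature
#' value, so transformed bases are refused — map them back through the
#' lineage inverse first (see [unmix_profiles()]).
#'
#' @param profiles An `iem_recon`, or a k x trials profile matrix.
#' @param orientations Trial orientations, degrees (taken from the
#'   `iem_recon` if omitted).
#' @param basis The `iem_basis` the profiles were computed under (taken
#'   from the `iem_recon` if omitted).
#' @param ref_slot Index of the reference channel slot the tuned channel is
#'   aligned to; default `floor(k / 2) + 1` (the middle of the profile).
#' @return Same shape as the input, with the `recentered` attribute set and
#'   each column shifted; for an `iem_recon`, a recentered copy.
#' @export
recenter_profiles <- function(profiles, orientations = NULL, basis = NULL,
                              ref_slot = NULL) {
  if (inherits(profiles, "iem_recon")) {
    rec <- profiles
    out <- rec
    out$profiles <- recenter_profiles(rec$profiles, rec$orientation, rec$basis,
                                      ref_slot = ref_slot)
    return(out)
  }
  if (is.null(orientations) || is.null(basis)) {
    stop_iemr("iemr_invalid_parameter",
              "`orientations` and `basis` are required when recentering a bare matrix")
  }
  if (basis$kind == "transformed") {
    stop_iemr("iemr_recenter_error",
              "cannot recenter profiles from a transformed basis: its channels are not tuned to single feature values; apply unmix_profiles() (lineage inverse) first")
  }
  k <- n_channels(basis)
  spacing <- basis$space$period / k
  if (max(abs(diff(c(diff(basis$centers), spacing)))) > 1e-8) {
    stop_iemr("iemr_invalid_input", "recentering requires evenly spaced channel centers")
  }
  if (is.null(ref_slot)) ref_slot <- floor(k / 2) + 1
  theta_idx <- match_center(orientations, basis$centers, basis$space$period)
  out <- profiles
  for (t in seq_len(ncol(profiles))) {
    shift <- ref_slot - theta_idx[t]
    out[, t] <- profiles[((seq_len(k) - 1 - shift) %% k) + 1, t]
  }
  rownames(out) <- sprintf("offset%+03.0f", (seq_len(k) - ref_slot) * spacing)
  attr(out, "recentered") <- TRUE
  attr(out, "ref_slot") <- ref_slot
  out
}

match_center <- function(orientations, centers, period, tol = 1e-6) {
  idx <- vapply(orientations, function(o) {
    d <- circ_dist(o, centers, period)
    j <- which.min(d)                              # ties: lowest channel index
    if (d[j] > tol) {
      stop_iemr("iemr_invalid_input",
                "trial orientation %g deg does not coincide with any channel center",
                o)
    }
    j
  }, integer(1))
  idx
}

#' Map transformed-basis profiles back to canonical channels
#'
#' Multiplies reconstructed profiles by the inverse of the basis lineage,
#' losslessly converting e.g. bimodal channel response profiles back into
#' the unimodal profiles of the canonical cosine basis.
#'
#' @param profiles An `iem_recon` from a transformed basis, or a k x trials
#'   matrix.
#' @param basis The transformed `iem_basis` (taken from the `iem_recon` if
#'   omitted).
#' @return Profiles expressed in the canonical basis; for an `iem_recon`,
#'   the `basis` is replaced by the canonical one so recentering becomes
#'   valid.
#' @export
unmix_profiles <- function(profiles, basis = NULL) {
  if (inherits(profiles, "iem_recon")) {
    rec <- profiles
    out <- rec
    out$profiles <- unmix_profiles(rec$profiles, rec$basis)
    out$basis <- canonical_basis(rec$basis)
    return(out)
  }
  if (is.null(basis)) {
    stop_iemr("iemr_invalid_parameter", "`basis` is required for a bare matrix")
  }
  out <- solve(basis$lineage, profiles)
  dimnames(out) <- dimnames(profiles)
  out
}

#' Average profiles within conditions
#'
#' Arithmetic mean of the per-trial profiles within each condition
#' (recenter first for unimodal bases so trials with different stimulus
#' orientations align).
#'
#' @param profiles k x trials matrix (or an `iem_recon`, whose labels are
#'   used).
#' @param conditions Condition label per trial.
#' @return A k x n_conditions matrix, columns ordered by sorted unique
#'   condition.
#' @export
condition_average <- function(profiles, conditions = NULL) {
  if (inherits(profiles, "iem_recon")) {
    conditions <- profiles$condition
    profiles <- profiles$profiles
  }
  if (length(conditions) != ncol(profiles)) {
    stop_iemr("iemr_shape_error", "%d condition labels for %d profile columns",
              length(conditions), ncol(profiles))
  }
  lev <- sort(unique(conditions))
  out <- vapply(lev, function(cc) rowMeans(profiles[, conditions == cc, drop = FALSE]),
                numeric(nrow(profiles)))
  colnames(out) <- paste0("condition", lev)
  out
}
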