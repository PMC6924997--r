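#' Raised-cosine channel basis set
#'
#' Constructs `k` unit-normalized channels tuned to evenly spaced feature
#' values: channel `i` is centered at `period * (i - 1) / k` and its
#' sensitivity at feature `theta` is
#' `max(0, cos(pi * d / period))^exponent`, where `d` is the circular
#' distance to the center.  Channels peak at 1 at their own center
#' (unit-normalized) and are zero at features `period / 2` away.
#'
#' The default exponent is the largest even integer not exceeding `k`
#' (8 for the standard 8-channel set).  An even power of the cosine is a
#' trigonometric polynomial band-limited to its exponent, which buys two
#' exact properties at once: for even `exponent < 2k` the channel sum is
#' exactly constant across the feature axis (steerable tiling), and for
#' `exponent >= k` the design matrix at the `k` channel centers retains
#' full rank (the Nyquist harmonic of the center lattice is present).  Odd
#' powers — including the common `k - 1` convention — leave a small
#' high-order ripple in the coverage; even powers below `k` lose design
#' rank when the stimuli coincide with the channel centers.
#'
#' @param k Number of channels (>= 2).
#' @param exponent Cosine power (>= 1).
#' @param space A [feature_space()].
#' @return An object of class `"iem_basis"`; see Details.
#' @details An `iem_basis` carries: `centers` (degrees), `exponent`, `kind`
#'   (`"cosine"`, `"delta"` or `"transformed"`), `values` (k x n_grid channel
#'   sensitivity matrix over `space$grid`, arbitrary units), `lineage` (the
#'   cumulative k x k transform applied to the canonical basis; identity for
#'   canonical bases) and `space`. Channel evaluation at arbitrary features
#'   is closed-form (see [channel_design()]), not grid interpolation.
#' @examples
#' b <- cosine_basis(8)
#' range(colSums(b$values))  # flat coverage
#' @seealso [delta_basis()], [apply_transform()], [channel_design()]
#' @export
cosine_basis <- function(k = 8, exponent = 2 * (k %/% 2),
                         space = feature_space()) {
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k)) {
    stop_iemr("iemr_invalid_parameter", "`k` must be an integer >= 2")
  }
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent < 1) {
    stop_iemr("iemr_invalid_parameter", "`exponent` must be >= 1")
  }
  k <- as.integer(k)
  centers <- space$period * (seq_len(k) - 1) / k
  b <- new_basis(centers, exponent, kind = "cosine", canonical = "cosine",
                 lineage = diag(k), space = space)
  b
}

#' Delta ("stick") channel basis set
#'
#' Orthogonal one-hot channels imposing no smoothness: channel `i` responds 1
#' when the stimulus feature coincides with its center and 0 otherwise.
#' Stimulus features used downstream must coincide with the channel centers;
#' predicted channel responses for stimuli at the `k` centers form an
#' identity-patterned matrix.
#'
#' @inheritParams cosine_basis
#' @return An object of class `"iem_basis"` with `kind = "delta"`.
#' @export
delta_basis <- function(k = 8, space = feature_space()) {
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k)) {
    stop_iemr("iemr_invalid_parameter", "`k` must be an integer >= 2")
  }
  k <- as.integer(k)
  centers <- space$period * (seq_len(k) - 1) / k
  new_basis(centers, exponent = NA_real_, kind = "delta", canonical = "delta",
            lineage = diag(k), space = space)
}

## assemble an iem_basis; `values` tabulates lineage %*% canonical channels
## on the grid, kept for plotting/serialization (evaluation is closed-form)
new_basis <- function(centers, exponent, kind, canonical, lineage, space) {
  b <- structure(
    list(centers = centers, exponent = exponent, kind = kind,
         canonical = canonical, lineage = lineage, space = space,
         values = NULL),
    class = "iem_basis"
  )
  b$values <- eval_channels(b, space$grid)
  rownames(b$values) <- sprintf("ch%02d", seq_along(centers))
  b
}

## closed-form channel evaluation (canonical channels, then lineage mixing)
eval_channels <- function(basis, theta) {
  k <- length(basis$centers)
  d <- outer(basis$centers, theta, circ_dist, period = basis$space$period)
  if (basis$canonical == "cosine") {
    raw <- pmax(0, cos(pi * d / basis$space$period))^basis$exponent
  } else {
    raw <- (d < 1e-8) * 1
  }
  dim(raw) <- c(k, length(theta))
  basis$lineage %*% raw
}

#' Number of channels in a basis
#' @param basis An `iem_basis`.
#' @return Integer channel count.
#' @export
n_channels <- function(basis) length(basis$centers)

#' @export
print.iem_basis <- function(x, ...) {
  cat(sprintf("%s channel basis: k = %d, period %g deg%s\n",
              x$kind, n_channels(x), x$space$period,
              if (x$kind == "cosine") sprintf(", exponent %g", x$exponent) else ""))
  cat(sprintf("centers (deg): %s\n", paste(format(x$centers), collapse = " ")))
  if (x$kind == "transformed") {
    cat(sprintf("lineage: %d x %d transform of a canonical %s basis (condition number %.3g)\n",
                nrow(x$lineage), ncol(x$lineage), x$canonical, kappa_2(x$lineage)))
  }
  invisible(x)
}

#' @export
plot.iem_basis <- function(x, ...) {
  graphics::matplot(x$space$grid, t(x$values), type = "l", lty = 1,
                    xlab = sprintf("feature (deg, period %g)", x$space$period),
                    ylab = "channel sensitivity (arb. units)",
                    main = sprintf("%s basis, k = %d", x$kind, n_channels(x)), ...)
  invisible(x)
}

kappa_2 <- function(m) {
  s <- svd(m, nu = 0, nv = 0)$d
  if (min(s) == 0) Inf else max(s) / min(s)
}

#' Invertible channel-mixing transform
#'
#' Validates a square matrix as an invertible linear transform of a channel
#' basis. Invertibility is tolerance-guarded: the smallest singular value
#' must exceed `tol` times the largest.
#'
#' @param mat A numeric k x k matrix.
#' @param tol Relative smallest-singular-value tolerance (default `1e-8`).
#' @return An object of class `"iem_transform"` with elements `mat` and
#'   `condition_number`.
#' @examples
#' as_iem_transform(matrix(c(0, 1, 1, 0), 2))  # channel relabeling
#' @export
as_iem_transform <- function(mat, tol = 1e-8) {
  if (inherits(mat, "iem_transform")) return(mat)
  if (!is.matrix(mat) || nrow(mat) != ncol(mat) || !is.numeric(mat)) {
    stop_iemr("iemr_invalid_parameter", "transform must be a square numeric matrix")
  }
  s <- svd(mat, nu = 0, nv = 0)$d
  if (min(s) <= tol * max(s)) {
    stop_iemr("iemr_rank_error",
              "transform is not invertible at tolerance %g (singular values %g .. %g)",
              tol, min(s), max(s))
  }
  structure(list(mat = mat, condition_number = max(s) / min(s)),
            class = "iem_transform")
}

#' @export
print.iem_transform <- function(x, ...) {
  cat(sprintf("%d x %d invertible channel transform, condition number %.4g\n",
              nrow(x$mat), ncol(x$mat), x$condition_number))
  invisible(x)
}

#' Bimodal channel-mixing transform
#'
#' Builds the transform `T = I + alpha * S`, with `S` the circular
#' shift-by-`k/2` permutation.  Applied to a unimodal cosine basis it
#' produces bimodal channels whose two modes are separated by half the
#' feature period, while remaining invertible (eigenvalues `1 +/- alpha`
#' for even `k`), so reconstructions under the bimodal basis can be mapped
#' losslessly back to the unimodal ones.
#'
#' @param k Number of channels; must be even so the half-period shift is a
#'   channel permutation.
#' @param alpha Mixing weight in `(0, 1)`; `alpha = 1` would make `T`
#'   singular (an eigenvalue `1 - alpha` hits zero).
#' @return An `"iem_transform"`.
#' @examples
#' bimodal_transform(8, 0.5)
#' @export
bimodal_transform <- function(k = 8, alpha = 0.5) {
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k) || k %% 2 != 0) {
    stop_iemr("iemr_invalid_parameter", "`k` must be an even integer >= 2")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_iemr("iemr_invalid_parameter",
              "`alpha` must lie strictly between 0 and 1 (alpha = 1 is singular)")
  }
  k <- as.integer(k)
  shift <- diag(k)[, c((k / 2 + 1):k, 1:(k / 2)), drop = FALSE]
  as_iem_transform(diag(k) + alpha * shift)
}

#' Apply an invertible linear transform to a basis set
#'
#' Mixes the channels of `basis` by `transform`: the new channel sensitivity
#' matrix is `T %*% old`, and the recorded lineage is composed so the
#' transformed basis can always be mapped back to its canonical parent.
#'
#' @param basis An `iem_basis`.
#' @param transform An `iem_transform` or invertible k x k matrix.
#' @return A new `iem_basis` with `kind = "transformed"`.
#' @examples
#' b  <- cosine_basis(8)
#' bb <- apply_transform(b, bimodal_transform(8, 0.5))
#' @export
apply_transform <- function(basis, transform) {
  transform <- as_iem_transform(transform)
  k <- n_channels(basis)
  if (nrow(transform$mat) != k) {
    stop_iemr("iemr_shape_error",
              "transform is %d x %d but basis has %d channels",
              nrow(transform$mat), ncol(transform$mat), k)
  }
  new_basis(basis$centers, basis$exponent, kind = "transformed",
            canonical = basis$canonical,
            lineage = transform$mat %*% basis$lineage, space = basis$space)
}

#' Invert a transformed basis back to its canonical parent
#'
#' @param basis An `iem_basis`.
#' @return The canonical (`cosine` or `delta`) basis the lineage descends
#'   from.
#' @export
canonical_basis <- function(basis) {
  k <- n_channels(basis)
  new_basis(basis$centers, basis$exponent, kind = basis$canonical,
            canonical = basis$canonical, lineage = diag(k), space = basis$space)
}

#' Predicted channel responses (the design matrix)
#'
#' Evaluates every channel of `basis` at each trial's stimulus feature,
#' giving the k x trials matrix of modeled channel responses used as the
#' regressors of the forward model.  Cosine and delta channels are evaluated
#' in closed form; transformed bases apply their lineage to the canonical
#' evaluation, so `channel_design(apply_transform(b, T), theta)` equals
#' `T %*% channel_design(b, theta)` exactly.
#'
#' @param basis An `iem_basis`.
#' @param orientations Stimulus feature value per trial, degrees.
#' @return A k x length(orientations) numeric matrix.
#' @examples
#' channel_design(cosine_basis(8), c(0, 22.5, 90))
#' @export
channel_design <- function(basis, orientations) {
  if (!is.numeric(orientations) || length(orientations) == 0) {
    stop_iemr("iemr_invalid_parameter", "`orientations` must be a numeric vector")
  }
  C <- eval_channels(basis, orientations %% basis$space$period)
  rownames(C) <- sprintf("ch%02d", seq_len(n_channels(basis)))
  C
}
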