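test_that("forward fit solves the per-signal least-squares problem", {
  # self-fit and scaling: B = C gives identity weights, B = 2C doubles them
  set.seed(1)
  b <- cosine_basis(4)
  theta <- runif(20, 0, 180)
  C <- channel_design(b, theta)
  fit1 <- iem(C, theta, b)
  expect_equal(unname(coef(fit1)), diag(4), tolerance = 1e-8)
  fit2 <- iem(2 * C, theta, b)
  expect_equal(unname(coef(fit2)), 2 * diag(4), tolerance = 1e-8)
  expect_equal(fit2$train_rss, 0, tolerance = 1e-12)
  expect_equal(unname(fitted(fit2)), unname(2 * C), tolerance = 1e-10)
  expect_equal(unname(residuals(fit2)), matrix(0, 4, 20), tolerance = 1e-10)
})

test_that("fit matches an independent QR least-squares oracle on random instances", {
  set.seed(101)
  b <- cosine_basis(6)
  for (i in 1:20) {
    theta <- runif(12, 0, 180)
    B <- matrix(rnorm(4 * 12), 4)
    fit <- iem(B, theta, b)
    W_oracle <- oracle_fit_weights(B, channel_design(b, theta))
    expect_lt(max(abs(coef(fit) - W_oracle)), 1e-8)
  }
})

test_that("fit refuses rank-deficient designs and undersized training sets", {
  b <- cosine_basis(8)
  B <- matrix(rnorm(5 * 12), 5)
  # a single repeated orientation cannot span 8 channels
  err <- expect_error(iem(B, rep(45, 12), b), class = "iemr_rank_error")
  expect_match(conditionMessage(err), "rank")
  expect_error(iem(matrix(rnorm(5 * 4), 5), runif(4, 0, 180), b),
               class = "iemr_rank_error")
  expect_error(iem(B, runif(5, 0, 180), b), class = "iemr_shape_error")
})

test_that("inversion recovers channel responses on the weight column space", {
  k <- 5
  W_id <- diag(k)
  fit <- list(weights = W_id, basis = cosine_basis(k))
  class(fit) <- "iem"
  B <- matrix(rnorm(k * 7), k)
  expect_equal(unname(predict(fit, B)), unname(B), tolerance = 1e-10)

  set.seed(7)
  W <- matrix(rnorm(9 * k), 9)
  fitW <- structure(list(weights = W, basis = cosine_basis(k)),
                    class = "iem")
  cvec <- matrix(rnorm(k * 3), k)
  expect_lt(max(abs(predict(fitW, W %*% cvec) - cvec)), 1e-10)

  # independent per-trial oracle on random instances
  for (i in 1:20) {
    inst <- random_instance(8, 4, 6)
    fit_i <- structure(list(weights = inst$W[, 1:4],
                            basis = cosine_basis(4)),
                       class = "iem")
    expect_lt(max(abs(predict(fit_i, inst$B) -
                        oracle_invert(inst$W[, 1:4], inst$B))), 1e-8)
  }

  bad <- structure(list(weights = cbind(W[, 1], W[, 1], W[, 2:5]),
                        basis = cosine_basis(6)), class = "iem")
  expect_error(predict(bad, matrix(rnorm(9 * 2), 9)), class = "iemr_rank_error")
  expect_error(predict(fitW, matrix(rnorm(4 * 2), 4)), class = "iemr_shape_error")
})

test_that("fixed-model scheme reconstructs exactly the held-out trials", {
  ds <- simulate_dataset(tiny_config())
  rec <- reconstruct(ds, cosine_basis(8), scheme = "fixed")
  expect_equal(ncol(rec$profiles), sum(ds$split == "test"))
  expect_equal(rec$orientation, ds$orientation[ds$split == "test"])
  expect_s3_class(rec$fit, "iem")
  expect_equal(rec$units, "arbitrary units")

  # explicit overlapping partitions are refused as leakage
  expect_error(reconstruct(ds, cosine_basis(8), scheme = "fixed",
                           train = 1:40, test = 35:64),
               class = "iemr_leakage_error")
})

test_that("k-fold cross-validation reconstructs every trial exactly once", {
  ds <- simulate_dataset(tiny_config())
  n <- ncol(ds$activations)
  rec <- reconstruct(ds, cosine_basis(8), scheme = "kfold", folds = 2)
  expect_equal(ncol(rec$profiles), n)
  expect_false(anyNA(rec$profiles))
  expect_equal(colnames(rec$profiles), colnames(ds$activations))

  # leave-one-trial-out is the folds = n_trials special case
  small <- simulate_dataset(sim_config(n_voxels = 10, n_neurons = 8,
                                       n_trials_per_cell = 1, seed = 12))
  loo <- reconstruct(small, cosine_basis(8), scheme = "kfold",
                     folds = ncol(small$activations))
  expect_equal(ncol(loo$profiles), ncol(small$activations))
  expect_false(anyNA(loo$profiles))

  expect_error(reconstruct(ds, cosine_basis(8), scheme = "kfold", folds = 3),
               class = "iemr_invalid_input")
})

test_that("reconstruction is equivariant under invertible basis transforms", {
  ds <- simulate_dataset(tiny_config(noise_sd = 5))
  b <- cosine_basis(8)
  rec <- reconstruct(ds, b, scheme = "fixed")
  set.seed(33)
  for (i in 1:5) {
    Tm <- random_transform(8, max_kappa = 1e3)
    rec_t <- reconstruct(ds, apply_transform(b, Tm), scheme = "fixed")
    expect_lt(max(abs(rec_t$profiles - Tm %*% rec$profiles)), 1e-8)
    # and the training fit is exactly as good in either coordinate system
    expect_equal(rec_t$fit$train_rss, rec$fit$train_rss,
                 tolerance = 1e-8)
  }
})

test_that("recentering aligns the tuned channel and averages peak at the center", {
  ds <- simulate_dataset(tiny_config())
  b <- cosine_basis(8)
  rec <- reconstruct(ds, b, scheme = "fixed")
  cen <- recenter_profiles(rec)

  # a trial at the reference channel's own center is left untouched
  ref_slot <- floor(8 / 2) + 1
  at_ref <- which(rec$orientation == b$centers[ref_slot])
  expect_equal(unname(cen$profiles[, at_ref]), unname(rec$profiles[, at_ref]))

  # equivariance: advancing the orientation by one channel step shifts the
  # reconstructed (noiseless) profile by exactly one slot after recentering
  step <- 180 / 8
  t1 <- which(rec$orientation == 0 & rec$condition == 1)[1]
  t2 <- which(rec$orientation == step & rec$condition == 1)[1]
  expect_equal(unname(cen$profiles[, t1]), unname(cen$profiles[, t2]),
               tolerance = 1e-8)

  # noiseless condition-averaged profile peaks at the reference slot
  avg <- condition_average(cen)
  expect_equal(which.max(avg[, 1]), ref_slot, ignore_attr = TRUE)
  expect_equal(which.max(avg[, 2]), ref_slot, ignore_attr = TRUE)

  # transformed bases cannot be recentered directly...
  bb <- apply_transform(b, bimodal_transform(8, 0.5))
  rec_b <- reconstruct(ds, bb, scheme = "fixed")
  expect_error(recenter_profiles(rec_b), class = "iemr_recenter_error")
  # ...but can after mapping back through the lineage inverse
  undone <- unmix_profiles(rec_b)
  expect_equal(undone$basis$kind, "cosine")
  cen_b <- recenter_profiles(undone)
  expect_equal(cen_b$profiles, cen$profiles, tolerance = 1e-8)

  # orientations off the channel centers are refused
  ds_off <- ds
  ds_off$orientation <- ds$orientation + 3
  rec_off <- rec
  rec_off$orientation <- rec$orientation + 3
  expect_error(recenter_profiles(rec_off), class = "iemr_invalid_input")
})

test_that("condition averaging validates labels and returns one column per condition", {
  p <- matrix(1:12, 3)
  avg <- condition_average(p, c(1, 1, 2, 2))
  expect_equal(dim(avg), c(3L, 2L))
  expect_equal(unname(avg[, 1]), rowMeans(p[, 1:2]))
  expect_error(condition_average(p, c(1, 2)), class = "iemr_shape_error")
})
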