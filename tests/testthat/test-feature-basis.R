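test_that("circular distance is symmetric, bounded and wraps correctly", {
  expect_equal(circ_dist(10, 10), 0)
  expect_equal(circ_dist(0, 170), 10)
  expect_equal(circ_dist(0, 90), 90)   # maximal distance = period / 2
  set.seed(1)
  a <- runif(200, 0, 180); b <- runif(200, 0, 180)
  expect_equal(circ_dist(a, b), circ_dist(b, a))
  expect_true(all(circ_dist(a, b) >= 0 & circ_dist(a, b) <= 90))
  expect_equal(circ_dist(a + 180, b), circ_dist(a, b))
  sp <- feature_space(period = 360)
  expect_equal(circ_dist(10, 350, sp), 20)
})

test_that("feature space validates its parameters and spaces its grid evenly", {
  sp <- feature_space(180, 180)
  expect_equal(sp$grid[2] - sp$grid[1], 1)
  expect_true(all(diff(sp$grid) > 0))
  expect_true(all(sp$grid >= 0 & sp$grid < 180))
  expect_error(feature_space(-1), class = "iemr_invalid_parameter")
  expect_error(feature_space(180, 1), class = "iemr_invalid_parameter")
})

test_that("raised-cosine channels are unit-normalized, nonnegative and evenly centered", {
  b <- cosine_basis(8)
  expect_equal(b$centers, 180 * (0:7) / 8)
  expect_true(all(b$values >= 0))
  # unit peak at the channel's own center; zero a quarter-period away
  D <- channel_design(b, b$centers)
  expect_equal(diag(D), rep(1, 8))
  expect_equal(as.numeric(channel_design(b, 90)[1, ]), 0)
  expect_true(all(D >= 0 & D <= 1))
  expect_error(cosine_basis(1), class = "iemr_invalid_parameter")
  expect_error(cosine_basis(8, exponent = 0.5), class = "iemr_invalid_parameter")
})

test_that("default cosine basis tiles the feature space with constant coverage", {
  # frozen from the brute-force grid oracle: k = 8, exponent 8 gives the
  # exact steerable constant 2.1875 = 8 * choose(8, 4) / 2^8
  cov_oracle <- oracle_coverage(8, 8, n = 1000)
  expect_lt(diff(range(cov_oracle)), 1e-6)
  expect_equal(mean(cov_oracle), 2.1875, tolerance = 1e-10)

  b <- cosine_basis(8, space = feature_space(180, 1000))
  expect_lt(diff(range(colSums(b$values))), 1e-6)
  expect_equal(unname(colSums(b$values)), cov_oracle, tolerance = 1e-10)
})

test_that("even cosine powers below 2k tile exactly; odd powers only approximately", {
  for (k in c(4, 6, 8)) {
    even <- oracle_coverage(k, k)
    expect_lt(diff(range(even)), 1e-10)
  }
  # the common k - 1 (odd) convention leaves a small high-order ripple
  expect_gt(diff(range(oracle_coverage(8, 7))), 1e-6)
})

test_that("delta channels are orthogonal one-hot indicators of their centers", {
  b <- delta_basis(8)
  D <- channel_design(b, b$centers)
  expect_equal(unname(D), diag(8))       # identity-patterned at the k centers
  G <- D %*% t(D)
  expect_equal(unname(G), diag(8))       # distinct channels orthogonal
  expect_equal(as.numeric(channel_design(b, 13.7)), rep(0, 8))
})

test_that("bimodal transform has eigenvalues 1 +/- alpha and creates two modes", {
  Tx <- bimodal_transform(8, 0.5)
  # eigen-decomposition oracle on the explicit matrix
  S <- diag(8)[, c(5:8, 1:4)]
  ev <- eigen(diag(8) + 0.5 * S, only.values = TRUE)$values
  expect_equal(min(abs(ev)), 0.5, tolerance = 1e-12)
  expect_equal(sort(unique(round(Mod(ev), 10))), c(0.5, 1.5))
  expect_equal(Tx$condition_number, 3, tolerance = 1e-10)

  # grid argmax oracle: transformed channel centered at 0 peaks at 0 and 90
  b <- apply_transform(cosine_basis(8, space = feature_space(180, 720)),
                       bimodal_transform(8, 0.5))
  v <- b$values[1, ]
  grid <- b$space$grid
  local_max <- which(v > c(v[length(v)], v[-length(v)]) &
                       v > c(v[-1], v[1]))
  expect_setequal(grid[local_max], c(0, 90))
  expect_equal(v[grid == 0], 1, ignore_attr = TRUE)
  expect_equal(v[grid == 90], 0.5, ignore_attr = TRUE)

  # alpha -> 0 limit approaches the identity
  Teps <- bimodal_transform(8, 1e-9)
  expect_lt(max(abs(Teps$mat - diag(8))), 1e-8)
  expect_error(bimodal_transform(8, 1), class = "iemr_invalid_parameter")
  expect_error(bimodal_transform(8, 0), class = "iemr_invalid_parameter")
  expect_error(bimodal_transform(7, 0.5), class = "iemr_invalid_parameter")
})

test_that("applying transforms mixes channels reversibly and records lineage", {
  b <- cosine_basis(8)
  # identity transform leaves channel values unchanged
  bi <- apply_transform(b, diag(8))
  expect_equal(bi$values, b$values)
  expect_equal(bi$kind, "transformed")

  # row-swap permutation on a 2-channel basis relabels the channels
  b2 <- cosine_basis(2, exponent = 2)
  bs <- apply_transform(b2, matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(bs$values), unname(b2$values[2:1, ]))

  # round trip through T and T^{-1} recovers the original values
  set.seed(42)
  for (i in 1:5) {
    Tm <- random_transform(8, max_kappa = 1e6)
    bt <- apply_transform(apply_transform(b, Tm), solve(Tm))
    expect_lt(max(abs(bt$values - b$values)), 1e-8)
    expect_equal(bt$centers, b$centers)
  }

  expect_error(apply_transform(b, diag(4)), class = "iemr_shape_error")
  singular <- diag(8); singular[8, 8] <- 0
  expect_error(apply_transform(b, singular), class = "iemr_rank_error")
})

test_that("transformed design matrices factor through the transform exactly", {
  b <- cosine_basis(8)
  Tm <- bimodal_transform(8, 0.4)
  theta <- runif(25, 0, 180)
  expect_lt(max(abs(channel_design(apply_transform(b, Tm), theta) -
                      Tm$mat %*% channel_design(b, theta))), 1e-10)
})

test_that("basis sets round-trip through their delimited/JSON serialization", {
  dir <- withr::local_tempdir()
  for (b in list(cosine_basis(8),
                 delta_basis(4),
                 apply_transform(cosine_basis(8), bimodal_transform(8, 0.5)))) {
    p <- file.path(dir, paste0(b$kind, ".csv"))
    write_basis(b, p)
    b2 <- read_basis(p)
    expect_equal(b2$values, b$values)
    expect_equal(b2$centers, b$centers)
    expect_equal(b2$kind, b$kind)
    expect_equal(b2$lineage, b$lineage, ignore_attr = TRUE)
  }
})
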