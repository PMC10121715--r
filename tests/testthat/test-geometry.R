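test_that("the homogeneous von Mises population has the stated state space", {
  code <- vonmises_population(n_neurons = 36)
  expect_equal(nrow(code$rates), 720)           # 180 orientations x 4 gains
  expect_equal(ncol(code$rates), 36)
  g1 <- code$rates[code$states$condition == 1, ]
  g025 <- code$rates[code$states$condition == 0.25, ]
  expect_equal(g1, 4 * g025, tolerance = 1e-12)
  # homogeneous code: per-state population activity constant over orientation
  act <- rowSums(g1)
  expect_lt(diff(range(act)) / mean(act), 0.01)
})

test_that("representational distances obey the transform scalings", {
  code <- vonmises_population(n_neurons = 12, n_orient = 30)
  D <- representational_distance(code)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # under no transform, scaling rates by g scales distances by g;
  # under sqrt, by sqrt(g)
  code2 <- code
  code2$rates <- 3 * code$rates
  expect_equal(representational_distance(code2), 3 * D, tolerance = 1e-10)
  expect_equal(representational_distance(code2, "sqrt"),
               sqrt(3) * representational_distance(code, "sqrt"),
               tolerance = 1e-10)
})

test_that("classical MDS reconstructs planar configurations", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  pts <- cbind(3 * cos(th), 3 * sin(th))
  D <- as.matrix(dist(pts))
  emb <- classical_mds(D, d = 2)
  r <- sqrt(rowSums(emb$points^2))
  expect_true(all(abs(r - 3) < 0.03))           # radius within 1%
  # exactness: embedding distances reproduce a rank-2 Euclidean matrix
  expect_equal(as.matrix(dist(emb$points)), D, tolerance = 1e-8)
  expect_true(all(abs(colMeans(emb$points)) < 1e-10))
  expect_true(!is.unsorted(-emb$eig[1:5]))
  expect_warning(classical_mds(D, d = 5), "padding")
})

test_that("multiplicative gain produces a cone with radius proportional to gain", {
  code <- vonmises_population(n_neurons = 48)
  gains <- c(0.25, 0.5, 0.75, 1)
  emb <- classical_mds(representational_distance(code), d = 3)
  radii <- sapply(gains, function(g)
    representation_radius(emb$points, code$states$condition == g))
  expect_true(all(diff(radii) > 0))             # strictly increasing in gain
  expect_equal(radii / radii[4], gains, tolerance = 0.01)
  # monotonicity also holds under the variance-stabilizing transform
  embs <- classical_mds(representational_distance(code, "sqrt"), d = 3)
  radii_s <- sapply(gains, function(g)
    representation_radius(embs$points, code$states$condition == g))
  expect_true(all(diff(radii_s) > 0))
})

test_that("characteristic states summarize block clusters deterministically", {
  set.seed(19)
  n <- 6; B <- 80
  centers <- rbind(rep(-2, n), rep(2, n))
  lab <- rep(1:2, each = B / 2)
  scores <- t(centers[lab, ] + matrix(rnorm(B * n, sd = 0.3), B, n))
  cs <- characteristic_states(scores, k = 2, seed = 20)
  expect_equal(dim(cs$states), c(2, n))
  expect_true(all(abs(cs$states[1, ] - (-2)) < 0.2))
  expect_true(all(abs(cs$states[2, ] - 2) < 0.2))
  expect_true(!is.unsorted(rowSums(cs$states)))
  cs2 <- characteristic_states(scores, k = 2, seed = 20)
  expect_identical(cs$cluster, cs2$cluster)
  # k = 1: the global mean score vector
  cs1 <- characteristic_states(scores, k = 1, seed = 1)
  expect_equal(cs1$states[1, ], rowMeans(scores), tolerance = 1e-12)
  expect_error(characteristic_states(scores, k = 100, seed = 1), "blocks")
})

test_that("shift augmentation rotates tuning on the circular domain", {
  code <- vonmises_population(n_neurons = 5, n_orient = 36)  # 5-deg bins
  aug <- shift_augment(code, n_shifts = 8, step = 20)
  expect_equal(ncol(aug$rates), 45)              # 1 original + 8 shifts
  # a copy shifted by 20 deg responds at o as the original at o - 20
  o20 <- which(code$states$orientation == 20 & code$states$condition == 1)
  o0 <- which(code$states$orientation == 0 & code$states$condition == 1)
  expect_equal(aug$rates[o20, 6:10], unname(code$rates[o0, ]))
  # shifting 9 x 20 = 180 deg returns the original tuning
  aug9 <- shift_augment(code, n_shifts = 9, step = 20)
  expect_equal(aug9$rates[, 46:50], unname(code$rates), tolerance = 1e-12)
  expect_error(shift_augment(code, step = 7), "multiple")
})

test_that("shift augmentation evens out a biased neuron sample", {
  # preferred orientations all bunched in one quadrant
  orient <- seq(0, 175, by = 5)
  prefs <- c(10, 20, 25, 30, 40)
  tc <- exp(cos(2 * outer(orient, prefs, "-") * pi / 180))
  code <- population_code(tc, orient, rep(1, length(orient)), orient)
  act0 <- rowSums(code$rates)
  act1 <- rowSums(shift_augment(code, n_shifts = 8, step = 20)$rates)
  expect_lt(diff(range(act1)) / mean(act1),
            diff(range(act0)) / mean(act0))
})

test_that("representation radius behaves on exact circles and degenerate groups", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  emb <- cbind(2 * cos(th), 2 * sin(th), rnorm(12))
  expect_equal(representation_radius(emb, 1:12), 2, tolerance = 1e-10)
  expect_warning(r0 <- representation_radius(matrix(1, 5, 2), 1:5),
                 "degenerate")
  expect_equal(r0, 0)
  expect_error(representation_radius(emb, 1:2), "at least 3")
})
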