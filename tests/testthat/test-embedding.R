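test_that("weighted sample sets validate their invariants", {
  X <- matrix(rnorm(6), 3)
  Y <- matrix(rnorm(3), 3)
  w <- weighted_sample_set(X, Y)
  expect_equal(w$weights, rep(1 / 3, 3))
  expect_error(weighted_sample_set(X, Y[1:2, , drop = FALSE]),
               class = "ehecco_dim_error")
  expect_error(weighted_sample_set(X, Y, c(0.5, 0.5, 0.5)),
               class = "ehecco_validation_error")
  expect_error(weighted_sample_set(X, Y, c(1.2, -0.1, -0.1)),
               class = "ehecco_validation_error")
  expect_error(weighted_sample_set(X, Y, c(1, 0)),
               class = "ehecco_validation_error")
})

test_that("MMD matches closed forms for singletons and limits", {
  # identical sets cancel exactly
  X <- matrix(rnorm(10), 5)
  expect_equal(mmd_squared(X, X, 0.7), 0, tolerance = 1e-12)
  # singleton pair: 2 (1 - exp(-d^2 / 2 b^2)) with b the effective bandwidth
  expect_equal(mmd_squared(matrix(0), matrix(1), 1, convention = "bandwidth"),
               2 * (1 - exp(-1 / 8)), tolerance = 1e-12)
  expect_equal(mmd_squared(matrix(0), matrix(1), 1, convention = "variance"),
               2 * (1 - exp(-1 / 4)), tolerance = 1e-12)
  expect_equal(mmd_squared(matrix(0), matrix(1), 1, convention = "plain"),
               2 * (1 - exp(-1 / 2)), tolerance = 1e-12)
  # separation limit: cross term vanishes
  expect_equal(mmd_squared(matrix(0), matrix(1e6), 1), 2, tolerance = 1e-12)
  expect_error(mmd_squared(matrix(0, 1, 2), matrix(0, 1, 3), 1),
               class = "ehecco_dim_error")
})

test_that("EHECCO is zero on identical inputs and matches the singleton form", {
  set.seed(21)
  P <- random_wss(6, 3, 2)
  expect_equal(ehecco_squared(P, P, 1, 1), 0, tolerance = 1e-12)
  expect_equal(ehecco_squared_oracle(P, P, 1, 1), 0, tolerance = 1e-12)
  # concentrated weights reduce to the closed form 2(1 - k_phi k_psi)
  x <- matrix(c(0, 0.5), 1); z <- matrix(c(1, -1), 1)
  y <- matrix(0.2, 1); l <- matrix(-0.4, 1)
  P1 <- weighted_sample_set(x, y)
  R1 <- weighted_sample_set(z, l)
  kphi <- exp(-sum((x - z)^2) / (2 * 1.3^2))
  kpsi <- exp(-sum((y - l)^2) / (2 * 0.8^2))
  expect_equal(ehecco_squared(P1, R1, 1.3, 0.8), 2 * (1 - kphi * kpsi),
               tolerance = 1e-14)
  expect_equal(ehecco_squared_oracle(P1, R1, 1.3, 0.8), 2 * (1 - kphi * kpsi),
               tolerance = 1e-14)
})

test_that("weight concentration on one index reproduces the singleton form", {
  set.seed(33)
  n <- 5; m <- 7
  P <- weighted_sample_set(matrix(rnorm(n * 3), n), matrix(rnorm(n * 2), n),
                           c(0, 0, 1, 0, 0))
  R <- weighted_sample_set(matrix(rnorm(m * 3), m), matrix(rnorm(m * 2), m),
                           c(0, 1, rep(0, m - 2)))
  kphi <- exp(-sum((P$primary[3, ] - R$primary[2, ])^2) / 2)
  kpsi <- exp(-sum((P$latent[3, ] - R$latent[2, ])^2) / 2)
  expect_equal(ehecco_squared(P, R, 1, 1), 2 * (1 - kphi * kpsi),
               tolerance = 1e-12)
})

test_that("vectorized estimator agrees with the nested-loop oracle", {
  set.seed(77)
  for (i in 1:40) {
    V <- sample(1:6, 1); Q <- sample(1:3, 1)
    P <- random_wss(sample(1:20, 1), V, Q, uniform = i %% 2 == 0)
    R <- random_wss(sample(1:20, 1), V, Q, uniform = i %% 3 == 0)
    sp <- runif(1, 0.3, 3); sl <- runif(1, 0.3, 3)
    a <- ehecco_squared(P, R, sp, sl)
    b <- ehecco_squared_oracle(P, R, sp, sl)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("EHECCO is symmetric in its arguments", {
  set.seed(88)
  for (i in 1:25) {
    P <- random_wss(sample(2:12, 1), 3, 2, uniform = FALSE)
    R <- random_wss(sample(2:12, 1), 3, 2, uniform = FALSE)
    expect_equal(ehecco_squared(P, R, 1.2, 0.9), ehecco_squared(R, P, 1.2, 0.9),
                 tolerance = 1e-12)
  }
})

test_that("EHECCO with a constant latent view reduces to uniform-weight MMD", {
  # a constant latent coordinate makes the latent kernel matrix exactly
  # all-ones, collapsing the joint estimator onto the marginal one
  set.seed(99)
  for (i in 1:10) {
    n <- sample(2:10, 1); m <- sample(2:10, 1)
    X <- matrix(rnorm(n * 4), n); Z <- matrix(rnorm(m * 4), m)
    P <- weighted_sample_set(X, matrix(0, n, 1))
    R <- weighted_sample_set(Z, matrix(0, m, 1))
    s <- runif(1, 0.5, 2)
    expect_equal(ehecco_squared(P, R, s, 1),
                 mmd_squared(X, Z, s, convention = "plain"), tolerance = 1e-12)
  }
})

test_that("EHECCO separates joint laws with identical marginals", {
  # (X, +X) vs (X, -X): both coordinates are standard normal in both laws,
  # but the coupling differs; the joint metric must see it
  set.seed(42)
  n <- 100
  X1 <- matrix(rnorm(n)); X2 <- matrix(rnorm(n)); X3 <- matrix(rnorm(n))
  between <- ehecco_squared(weighted_sample_set(X1, X1),
                            weighted_sample_set(X2, -X2), 1, 1)
  within <- ehecco_squared(weighted_sample_set(X1, X1),
                           weighted_sample_set(X3, X3), 1, 1)
  expect_gt(between, within)
})

test_that("pairwise distance matrix is symmetric with zero diagonal", {
  set.seed(55)
  reps <- lapply(1:4, function(i) random_wss(5, 3, 2))
  D <- pairwise_distance_matrix(reps, 1, 1)
  expect_equal(D, t(D), tolerance = 0)
  expect_equal(diag(D), rep(0, 4))
  # entries equal sqrt of the independently recomputed oracle
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(D[i, j],
                 sqrt(ehecco_squared_oracle(reps[[i]], reps[[j]], 1, 1)),
                 tolerance = 1e-10)
  # duplicated representation at two indices gives distance 0
  dup <- reps; dup[[2]] <- dup[[1]]
  D2 <- pairwise_distance_matrix(dup, 1, 1)
  expect_equal(D2[1, 2], 0, tolerance = 1e-7)
  # squared mode
  Dsq <- pairwise_distance_matrix(reps, 1, 1, squared = TRUE)
  expect_equal(Dsq[3, 4], D[3, 4]^2, tolerance = 1e-12)
})

test_that("incompatible representations name the offending index", {
  reps <- list(random_wss(4, 3, 2), random_wss(4, 2, 2))
  expect_error(pairwise_distance_matrix(reps, 1, 1), "reps\\[\\[2\\]\\]")
})

test_that("distance matrices round-trip through CSV and binary forms", {
  set.seed(66)
  D <- pairwise_distance_matrix(lapply(1:3, function(i) random_wss(4, 2, 1)), 1, 1)
  rownames(D) <- colnames(D) <- c("a", "b", "c")
  csv <- tempfile(fileext = ".csv")
  bin <- tempfile(fileext = ".bin")
  write_distance_matrix(D, csv)
  write_distance_matrix(D, bin)
  Dc <- read_distance_matrix(csv)
  expect_equal(unname(Dc), unname(D), tolerance = 1e-15)
  expect_equal(rownames(Dc), c("a", "b", "c"))
  Db <- read_distance_matrix(bin)
  expect_identical(as.vector(Db), as.vector(D))  # exact float round trip
})
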