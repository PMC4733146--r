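high_g0 <- matrix(c(1.0, 0.4, 0.6,
                    0.4, 1.5, 0.9,
                    0.6, 0.9, 2.5), 3, 3, byrow = TRUE)

test_that("compose_cov builds L diag(v) L' with the stated entry structure", {
  # zero dependencies: diagonal covariance
  expect_equal(compose_cov(chol_params(c(1, 2.5, 4))), diag(c(1, 2.5, 4)))

  # entry (2,1) is kappa_12 * v1 exactly
  p <- chol_params(c(1.7, 1, 1), c(0.31, -0.2, 0.5))
  expect_equal(compose_cov(p)[2, 1], 0.31 * 1.7)

  # parameters recovered by decompose_cov reproduce the high-heritability G0
  p <- decompose_cov(high_g0)
  expect_equal(p$variances[1:2], c(1.0, 1.5 - 0.4^2))
  expect_equal(p$dependencies[1:2], c(0.4, 0.6))
  expect_equal(p$dependencies[3], (0.9 - 0.4 * 0.6) / 1.34)
  expect_equal(compose_cov(p), high_g0, tolerance = 1e-12)

  expect_error(chol_params(c(1, -1, 2)), "positive")
  expect_error(chol_params(1:3, 1:2), "dependency")
})

test_that("decompose_cov matches the closed-form three-trait identities", {
  set.seed(1)
  for (rep in 1:20) {
    C <- random_pd(3)
    p <- decompose_cov(C)
    v1 <- C[1, 1]
    k12 <- C[1, 2] / v1
    k13 <- C[1, 3] / v1
    v2 <- C[2, 2] - k12^2 * v1
    k23 <- (C[2, 3] - k12 * k13 * v1) / v2
    v3 <- C[3, 3] - k13^2 * v1 - k23^2 * v2
    expect_equal(p$variances, c(v1, v2, v3), tolerance = 1e-12)
    expect_equal(p$dependencies, c(k12, k13, k23), tolerance = 1e-12)
  }
  expect_equal(decompose_cov(diag(3))$dependencies, rep(0, 3))
  expect_error(decompose_cov(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("compose/decompose round-trip to 1e-10 and compose is always PD", {
  set.seed(2)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    C <- random_pd(n)
    expect_lt(max(abs(compose_cov(decompose_cov(C)) - C)), 1e-10)
  }
  # PD for arbitrarily wide-ranging dependencies (the selling point of the
  # unconstrained parameterization)
  for (rep in 1:50) {
    n <- sample(2:5, 1)
    p <- chol_params(exp(stats::runif(n, -4, 4)),
                     stats::runif(n * (n - 1) / 2, -50, 50))
    ev <- eigen(compose_cov(p), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  # parameter-side round trip at moderate ranges (extreme dependency values
  # make the inverse ill-conditioned, as for any LDL' factorization)
  for (rep in 1:50) {
    n <- sample(2:5, 1)
    p <- chol_params(exp(stats::runif(n, -2, 2)),
                     stats::runif(n * (n - 1) / 2, -4, 4))
    p2 <- decompose_cov(compose_cov(p))
    expect_equal(p2$variances, p$variances, tolerance = 1e-8)
    expect_equal(p2$dependencies, p$dependencies, tolerance = 1e-8)
  }
})

test_that("the stacked operator W = L (x) I acts blockwise", {
  # zero dependencies: identity
  op <- build_w(chol_params(c(1, 1, 1)), n_ind = 4)
  x <- stats::rnorm(12)
  expect_equal(apply_w(op, x), x)

  # four traits need exactly 6 dependency parameters
  expect_length(chol_params(rep(1, 4))$dependencies, 6L)

  # second block of W a is kappa_12 * a1 + a2
  p <- chol_params(c(1, 1, 1), c(0.5, 0, 0))
  op <- build_w(p, n_ind = 2)
  a <- stats::rnorm(6)
  out <- apply_w(op, a)
  expect_equal(out[3:4], 0.5 * a[1:2] + a[3:4])

  # agrees with the dense Kronecker product
  p <- chol_params(c(1, 1, 1), c(0.4, 0.6, -0.3))
  op <- build_w(p, n_ind = 3)
  x <- stats::rnorm(9)
  expect_equal(apply_w(op, x), as.vector(as.matrix(op) %*% x),
               tolerance = 1e-12)
})

test_that("back_transform maps samples through both covariance sides", {
  hp <- hyper_params(chol_params(c(1.0, 1, 1), c(0.4, 0, 0)),
                     chol_params(c(2, 3, 4)))
  out <- back_transform(list(hp))
  expect_length(out, 1L)
  # genetic covariance (1,2) = kappa_12 * v_a1
  expect_equal(out[[1]]$genetic[1, 2], 0.4)
  expect_equal(out[[1]]$residual, diag(c(2, 3, 4)))

  # point mass: identical matrices for every sample
  th <- matrix(rep(theta_transform(hp), each = 50), nrow = 50)
  out <- back_transform(th, n_traits = 3)
  expect_true(all(vapply(out, function(s)
    identical(s$genetic, out[[1]]$genetic), logical(1))))

  expect_error(back_transform(list()), "empty")
})

test_that("correlations and heritabilities follow from the matrices", {
  r0 <- matrix(0.5, 3, 3); diag(r0) <- 1
  expect_equal(round(implied_correlations(high_g0)[lower.tri(high_g0)], 2),
               c(0.33, 0.38, 0.46))
  expect_equal(implied_correlations(r0)[lower.tri(r0)], rep(0.5, 3))
  expect_equal(implied_correlations(diag(c(2, 3))), diag(2))

  expect_equal(round(implied_heritability(high_g0, r0), 2),
               c(0.50, 0.60, 0.71), ignore_attr = TRUE)
  expect_equal(implied_heritability(high_g0, high_g0),
               rep(0.5, 3), ignore_attr = TRUE)

  # correlation invariant under common variance rescaling
  c1 <- implied_correlations(compose_cov(chol_params(c(1, 2), 0.7)))
  c2 <- implied_correlations(compose_cov(chol_params(10 * c(1, 2), 0.7)))
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("hyperparameters round-trip through the transformed scale and files", {
  hp <- hyper_params(chol_params(c(1, 1.34, 2), c(0.4, 0.6, 0.49)),
                     chol_params(c(0.9, 1.1, 1.3), c(-0.2, 0.1, 0.3)))
  th <- theta_transform(hp)
  hp2 <- theta_untransform(th, 3)
  expect_equal(hp2, hp, tolerance = 1e-15)

  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_params(hp, path)
    hp3 <- read_params(path, n_traits = 3)
    expect_equal(hp3$genetic$variances, hp$genetic$variances)
    expect_equal(hp3$residual$dependencies, hp$residual$dependencies)
  }
})
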