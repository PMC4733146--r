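small_fit_data <- function(seed = 1, n_seed = 4, n_pollen = 4) {
  A <- build_a_matrix(make_factorial_pedigree(n_seed, n_pollen))
  sc <- scenario_high_h2()
  sim <- simulate_traits(A, sc$g0, sc$r0, seed = seed)
  list(data = mt_data(sim$phenotypes, A), sim = sim)
}

test_that("single-trait REML recovers the phenotypic variance split", {
  n <- 400
  set.seed(8)
  y <- matrix(sqrt(1.2) * stats::rnorm(n) + sqrt(0.8) * stats::rnorm(n) + 3,
              n, 1)
  d <- mt_data(y, diag(n))
  f <- fit_reml(d)
  tot <- f$g0_hat[1, 1] + f$r0_hat[1, 1]
  # va and ve are not separately identifiable with K = I, but their sum is
  expect_lt(abs(tot - stats::var(y[, 1])) / stats::var(y[, 1]), 0.05)
})

test_that("the REML optimum is stable across random restarts", {
  # at the full factorial-design size the restricted likelihood is
  # effectively unimodal and every restart lands on the same optimum;
  # smaller designs leave flat ridges where only the optimum value matches
  d <- small_fit_data(seed = 3, n_seed = 25, n_pollen = 25)$data
  f0 <- fit_reml(d)
  expect_true(f0$diagnostics$converged)
  expect_lt(f0$diagnostics$gradient_norm, 1e-3)
  set.seed(99)
  for (s in 1:5) {
    init <- theta_untransform(f0$theta_vec + stats::rnorm(12, 0, 0.5), 3)
    fs <- fit_reml(d, init = init)
    expect_equal(fs$loglik, f0$loglik, tolerance = 1e-8)
    expect_lt(max(abs(fs$theta_vec - f0$theta_vec)), 1e-4)
  }
})

test_that("laplace fits are bit-reproducible given the seed", {
  d <- small_fit_data(seed = 5)$data
  f1 <- fit_laplace(d, n_samples = 300, seed = 42)
  f2 <- fit_laplace(d, n_samples = 300, seed = 42)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$g0_hat, f2$g0_hat)
  f3 <- fit_laplace(d, n_samples = 300, seed = 43)
  expect_false(identical(f1$g0_hat, f3$g0_hat))
})

test_that("mcmc chains are reproducible and adapt to a sane acceptance rate", {
  d <- small_fit_data(seed = 6, n_seed = 3, n_pollen = 3)$data
  f1 <- fit_mcmc(d, n_iter = 4000, n_burnin = 1500, seed = 7)
  f2 <- fit_mcmc(d, n_iter = 4000, n_burnin = 1500, seed = 7)
  expect_identical(f1$summary, f2$summary)
  expect_gt(f1$diagnostics$acceptance_rate, 0.05)
  expect_lt(f1$diagnostics$acceptance_rate, 0.8)
  expect_equal(nrow(f1$theta_samples), 2500L)
})

test_that("back-transformed covariance estimates are positive definite", {
  d <- small_fit_data(seed = 12)$data
  f <- fit_laplace(d, n_samples = 200, seed = 1)
  covs <- back_transform(f$theta_samples, 3)
  min_ev <- min(vapply(covs, function(s)
    min(eigen(s$genetic, symmetric = TRUE, only.values = TRUE)$values,
        eigen(s$residual, symmetric = TRUE, only.values = TRUE)$values),
    numeric(1)))
  expect_gt(min_ev, 0)
  expect_gt(min(eigen(f$g0_hat, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_gt(min(eigen(f$r0_hat, symmetric = TRUE, only.values = TRUE)$values), 0)
  # intervals bracket the mean estimate
  ok <- with(f$summary, lower <= estimate & estimate <= upper)
  expect_true(all(ok))
})

test_that("laplace and mcmc agree on a conjugate-like single-trait problem", {
  # K = I leaves only va + ve identified by the data, so a tight prior is
  # needed to pin the ridge; the posterior is then nearly Gaussian on the
  # log scale and the two engines must agree
  n <- 150
  set.seed(13)
  y <- matrix(stats::rnorm(n, 0, sqrt(2)), n, 1)
  d <- mt_data(y, diag(n))
  tight <- list(ig_shape = 20, ig_rate = 20)
  fl <- fit_laplace(d, n_samples = 3000, seed = 2, prior = tight)
  fm <- fit_mcmc(d, n_iter = 20000, n_burnin = 5000, seed = 2, prior = tight)
  ml <- mean(fl$samples[, "ve1"])
  mm <- mean(fm$samples[, "ve1"])
  se <- sqrt(stats::sd(fl$samples[, "ve1"])^2 / nrow(fl$samples) +
               mcse_chain(fm$samples[, "ve1"])^2)
  expect_lt(abs(ml - mm), 3 * se)
})

test_that("fitted model objects expose the standard modelling interface", {
  parts <- small_fit_data(seed = 20)
  f <- mtam(parts$data, engine = "reml")
  expect_s3_class(f, "mtam")
  expect_output(print(f), "Genetic covariance")
  expect_output(print(summary(f)), "log-likelihood")
  expect_length(coef(f), 3L)             # one intercept per trait
  expect_named(coef(f, "hyper"))
  expect_s3_class(logLik(f), "logLik")

  bl <- predict(f, truth = parts$sim$truth)
  expect_s3_class(bl, "mtam_blup")
  expect_true(all(abs(bl$accuracy$per_trait) <= 1))
  res <- residuals(f)
  expect_equal(dim(res), dim(parts$data$Y))
  expect_equal(fitted(f) + res, parts$data$Y, tolerance = 1e-10)

  sims <- simulate(f, nsim = 2, seed = 3)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]$phenotypes), dim(parts$data$Y))

  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$engine, "reml")
  expect_length(parsed$g0_hat, 3L)
})
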