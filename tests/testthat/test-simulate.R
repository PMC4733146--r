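test_that("trait simulation is reproducible and additive", {
  A <- build_a_matrix(make_factorial_pedigree(3, 3))
  sc <- scenario_high_h2()
  s1 <- simulate_traits(A, sc$g0, sc$r0, seed = 9)
  s2 <- simulate_traits(A, sc$g0, sc$r0, seed = 9)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_false(identical(
    s1$phenotypes, simulate_traits(A, sc$g0, sc$r0, seed = 10)$phenotypes))
  # phenotype = breeding value + residual
  expect_equal(s1$phenotypes,
               s1$truth$true_breeding_values + s1$truth$true_residuals)
})

test_that("simulated moments match the target covariances", {
  nrep <- 5000
  K <- unclass(build_a_matrix(random_pedigree(10)))
  sc <- scenario_high_h2()

  # g0 -> 0 limit: phenotypes are pure residuals with covariance r0
  g_tiny <- diag(1e-10, 3)
  set.seed(3)
  ys <- do.call(rbind, lapply(seq_len(nrep), function(r)
    simulate_traits(K, g_tiny, sc$r0, seed = 50000 + r)$phenotypes))
  S <- stats::cov(ys)
  mc_se <- sqrt((outer(diag(sc$r0), diag(sc$r0)) + sc$r0^2) / nrow(ys))
  expect_true(all(abs(S - sc$r0) < 3.5 * mc_se))

  # r0 -> 0, K = I: per-trait variances approach diag(g0)
  r_tiny <- diag(1e-10, 3)
  ys <- do.call(rbind, lapply(seq_len(nrep %/% 5), function(r)
    simulate_traits(diag(10), sc$g0, r_tiny, seed = 90000 + r)$phenotypes))
  v <- apply(ys, 2, stats::var)
  se <- diag(sc$g0) * sqrt(2 / nrow(ys))
  expect_true(all(abs(v - diag(sc$g0)) < 3.5 * se))
})

test_that("stacked covariance over replicates converges to g0xK + r0xI", {
  ped <- pedigree(c("f1", "f2", "o"), c(NA, NA, "f1"), c(NA, NA, "f2"))
  K <- unclass(build_a_matrix(ped))
  g0 <- matrix(c(1, 0.4, 0.4, 0.8), 2)
  r0 <- matrix(c(0.6, -0.2, -0.2, 0.9), 2)
  target <- kronecker(g0, K) + kronecker(r0, diag(3))
  ys <- vapply(seq_len(6000), function(r)
    as.vector(simulate_traits(K, g0, r0, seed = 1e6 + r)$phenotypes),
    numeric(6))
  S <- stats::cov(t(ys))
  mc_se <- sqrt((outer(diag(target), diag(target)) + target^2) / ncol(ys))
  expect_true(all(abs(S - target) < 3.5 * mc_se))
})

test_that("packaged scenario fixtures match the built-in scenarios", {
  for (nm in c("high_h2", "low_h2")) {
    path <- system.file("extdata", paste0("scenario_", nm, ".yaml"),
                        package = "mtam")
    sc <- read_scenario(path)
    ref <- if (nm == "high_h2") scenario_high_h2() else scenario_low_h2()
    expect_equal(sc$g0, ref$g0)
    expect_equal(sc$r0, ref$r0)
  }
})

test_that("scenario configurations round-trip through YAML", {
  sc <- scenario_low_h2()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2$g0, sc$g0)
  expect_equal(sc2$r0, sc$r0)
  expect_equal(sc2$n_seed, 25L)

  expect_equal(round(implied_heritability(sc$g0, sc$r0), 2),
               c(0.20, 0.20, 0.22), ignore_attr = TRUE)
  expect_equal(round(implied_correlations(sc$g0)[1, 2], 2), -0.34)
})

test_that("phenotype and truth tables are written as CSV", {
  A <- build_a_matrix(make_factorial_pedigree(2, 2))
  sim <- simulate_traits(A, diag(3), diag(3), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  paths <- write_sim_data(sim, path)
  ph <- read_phenotypes(paths[1])
  expect_equal(ph, sim$phenotypes, tolerance = 1e-12)
  truth <- utils::read.csv(paths[2])
  expect_equal(ncol(truth), 7L)  # id + 3 breeding values + 3 residuals
})
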