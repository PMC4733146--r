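make_instance <- function(n, t_, seed = 1) {
  set.seed(seed)
  ped <- random_pedigree(n)
  A <- build_a_matrix(ped)
  g0 <- random_pd(t_)
  r0 <- random_pd(t_)
  sim <- simulate_traits(A, g0, r0, seed = seed + 100)
  list(A = A, data = mt_data(sim$phenotypes, A),
       hp = hyper_params(decompose_cov(g0), decompose_cov(r0)))
}

test_that("eigen-path likelihood equals the dense-V oracle", {
  for (cfg in list(c(4, 2), c(6, 3), c(10, 3), c(20, 3))) {
    inst <- make_instance(cfg[1], cfg[2], seed = sum(cfg))
    d <- inst$data
    ll <- log_restricted_likelihood(inst$hp, d)
    ll_dense <- dense_reml(d$Y, unclass(d$K), d$X,
                           compose_cov(inst$hp$genetic),
                           compose_cov(inst$hp$residual))
    expect_equal(ll, ll_dense, tolerance = 1e-8)
  }
})

test_that("marginal covariance operator matches dense construction", {
  inst <- make_instance(5, 2, seed = 11)
  d <- inst$data
  G0 <- compose_cov(inst$hp$genetic)
  R0 <- compose_cov(inst$hp$residual)
  V <- kronecker(G0, unclass(d$K)) + kronecker(R0, diag(d$n_ind))
  mc <- marginal_covariance(inst$hp, d)
  expect_equal(mc$logdet, as.numeric(determinant(V)$modulus),
               tolerance = 1e-10)
  set.seed(1)
  v <- stats::rnorm(nrow(V))
  expect_equal(mc$solve(v), as.vector(solve(V, v)), tolerance = 1e-8)
})

test_that("single-trait identity-kinship case has closed-form pieces", {
  n <- 30
  set.seed(5)
  y <- matrix(stats::rnorm(n, 2, 1.5), n, 1)
  d <- mt_data(y, diag(n))
  hp <- hyper_params(chol_params(0.8), chol_params(0.5))
  # V = (va + ve) I, X = intercept: closed-form restricted likelihood
  s2 <- 0.8 + 0.5
  ll_closed <- -0.5 * ((n - 1) * log(2 * pi) + n * log(s2) +
                         log(n / s2) + sum((y - mean(y))^2) / s2)
  expect_equal(log_restricted_likelihood(hp, d), ll_closed, tolerance = 1e-8)
  expect_equal(marginal_covariance(hp, d)$logdet, n * log(s2),
               tolerance = 1e-10)
})

test_that("restricted likelihood is a function of error contrasts only", {
  inst <- make_instance(8, 3, seed = 21)
  d <- inst$data
  ll <- log_restricted_likelihood(inst$hp, d)
  # translate along the column space of X (per-trait intercepts)
  d2 <- mt_data(sweep(d$Y, 2, c(5, -3, 100), `+`), d$K)
  expect_equal(log_restricted_likelihood(inst$hp, d2), ll, tolerance = 1e-8)
})

test_that("likelihood is invariant under relabeling of individuals", {
  inst <- make_instance(9, 2, seed = 31)
  d <- inst$data
  perm <- sample(d$n_ind)
  d2 <- mt_data(d$Y[perm, ], unclass(d$K)[perm, perm])
  expect_equal(log_restricted_likelihood(inst$hp, d2),
               log_restricted_likelihood(inst$hp, d), tolerance = 1e-8)
})

test_that("posterior = restricted likelihood + data-independent prior terms", {
  # inverse-Gamma(0.5, 0.5) log-density at sigma2 = 1
  expect_equal(mtam:::.dinvgamma_log(1, 0.5, 0.5),
               0.5 * log(0.5) - lgamma(0.5) - 0.5)
  # N(0, 10) at 0
  expect_equal(stats::dnorm(0, 0, sqrt(10), log = TRUE),
               -0.5 * log(2 * pi * 10))

  inst1 <- make_instance(8, 2, seed = 41)
  inst2 <- make_instance(12, 2, seed = 43)
  hp <- inst1$hp
  gap1 <- log_posterior(hp, inst1$data) -
    log_restricted_likelihood(hp, inst1$data)
  gap2 <- log_posterior(hp, inst2$data) -
    log_restricted_likelihood(hp, inst2$data)
  expect_equal(gap1, gap2, tolerance = 1e-10)
  # and the gap equals the explicit prior + Jacobian sum
  v <- c(hp$genetic$variances, hp$residual$variances)
  dep <- c(hp$genetic$dependencies, hp$residual$dependencies)
  expect_equal(gap1,
               sum(mtam:::.dinvgamma_log(v, 0.5, 0.5)) + sum(log(v)) +
                 sum(stats::dnorm(dep, 0, sqrt(10), log = TRUE)),
               tolerance = 1e-10)
})

test_that("data assembly validates inputs", {
  A <- build_a_matrix(make_factorial_pedigree(2, 2))
  Y <- matrix(stats::rnorm(16), 8, 2, dimnames = list(rownames(A), NULL))
  expect_error(mt_data(Y, A, X = matrix(1, 8, 2)), "rank deficient")
  Yna <- Y; Yna[3, 1] <- NA
  expect_message(d <- mt_data(Yna, A), "incomplete")
  expect_equal(d$n_ind, 7L)
  rownames(Y)[1] <- "nobody"
  expect_error(mt_data(Y, A), "missing from")
})
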