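# Estimation engines: REML mode, Laplace-approximate posterior, adaptive
# random-walk Metropolis. All three act on the same collapsed likelihood /
# posterior surface over the transformed hyperparameter coordinates.

.num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    (f(xp) - f(xm)) / (2 * hi)
  }, numeric(1))
}

.num_hess <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  hs <- h * pmax(1, abs(x))
  f0 <- f(x)
  for (i in seq_len(k)) {
    xp <- x; xp[i] <- x[i] + hs[i]
    xm <- x; xm[i] <- x[i] - hs[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / hs[i]^2
    for (j in seq_len(i - 1L)) {
      xpp <- x; xpp[i] <- x[i] + hs[i]; xpp[j] <- x[j] + hs[j]
      xpm <- x; xpm[i] <- x[i] + hs[i]; xpm[j] <- x[j] - hs[j]
      xmp <- x; xmp[i] <- x[i] - hs[i]; xmp[j] <- x[j] + hs[j]
      xmm <- x; xmm[i] <- x[i] - hs[i]; xmm[j] <- x[j] - hs[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * hs[i] * hs[j])
    }
  }
  H
}

# single-trait REML fit used for starting values
.uni_init <- function(data) {
  t_ <- data$n_traits
  va <- ve <- numeric(t_)
  for (i in seq_len(t_)) {
    sub <- list(n_traits = 1L, n_ind = data$n_ind, p = data$p[i],
                lambda = data$lambda,
                Ytil = data$Ytil[, i, drop = FALSE],
                Xtil = data$Xtil[i])
    class(sub) <- "mt_data"
    obj <- .obj_reml(sub)
    s2 <- stats::var(data$Y[, i])
    op <- stats::optim(log(c(s2 / 2, s2 / 2)), obj, method = "Nelder-Mead",
                       control = list(fnscale = -1, maxit = 400,
                                      reltol = 1e-10))
    va[i] <- exp(op$par[1]); ve[i] <- exp(op$par[2])
  }
  hyper_params(chol_params(va), chol_params(ve))
}

# maximize obj from theta0 with BFGS + Newton polishing; returns par, value,
# gradient norm, convergence flag
.maximize <- function(obj, theta0, maxit = 400) {
  op <- stats::optim(theta0, obj, method = "BFGS",
                     control = list(fnscale = -1, maxit = maxit,
                                    reltol = 1e-12))
  par <- .clamp_theta(op$par); val <- obj(par)
  for (it in 1:25) {
    g <- .num_grad(obj, par)
    if (sqrt(sum(g^2)) < 1e-7) break
    H <- .num_hess(obj, par)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    # Newton direction for a maximum: -H^{-1} g with H negative definite
    alpha <- 1
    repeat {
      v <- obj(par - alpha * step)
      if (v >= val || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    if (v < val || max(abs(alpha * step)) < 1e-12) break
    par <- .clamp_theta(par - alpha * step)
    val <- v
  }
  g <- .num_grad(obj, par)
  list(par = par, value = val, gradient_norm = sqrt(sum(g^2)),
       optim_convergence = op$convergence)
}

.multistart <- function(obj, theta0, n_starts, seed = NULL) {
  starts <- list(theta0)
  if (n_starts > 1) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(if (is.null(seed)) 1907L else as.integer(seed) + 77L)
    for (s in seq_len(n_starts - 1L))
      starts[[s + 1L]] <- theta0 + stats::rnorm(length(theta0), 0, 0.3)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  fits <- lapply(starts, function(s) .maximize(obj, s))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "value"))]]
  # escalate if the single start clearly failed
  if (n_starts == 1 && (best$optim_convergence != 0 ||
                        best$gradient_norm > 1e-2))
    best <- Recall(obj, theta0, 5L, seed)
  best
}

#' Fit a multi-trait animal model
#'
#' The front door of the package: estimates the genetic and residual trait
#' covariance matrices (G0, R0) of the animal model
#' `y_i = X_i beta_i + u_i + eps_i`, `u ~ N(0, G0 (x) K)`,
#' `eps ~ N(0, R0 (x) I)`, under the modified-Cholesky parameterization of
#' both matrices, and back-transforms to original-scale (co)variances,
#' correlations and heritabilities.
#'
#' Engines: `"reml"` maximizes the restricted likelihood; `"laplace"`
#' maximizes the posterior (inverse-Gamma(0.5, 0.5) priors on transformed
#' variances, N(0, 10) on dependency parameters), forms a Gaussian
#' approximation from the negative inverse Hessian at the mode, and draws
#' `n_samples` hyperparameter vectors that are back-transformed to
#' original-scale quantities; `"mcmc"` runs an adaptive random-scan
#' random-walk Metropolis sampler on the same posterior (step sizes adapted
#' during burn-in only, then frozen).
#'
#' @param phenotypes phenotype matrix/data frame, or an [mt_data] object
#'   (in which case `K` and `X` are ignored).
#' @param K relationship matrix (see [mt_data()]).
#' @param X fixed-effect design(s) (see [mt_data()]); default intercept-only.
#' @param engine one of `"reml"`, `"laplace"`, `"mcmc"`.
#' @param ... passed to [fit_reml()], [fit_laplace()] or [fit_mcmc()].
#' @return An object of class `mtam`; see [fit_reml()] for its contents.
#' @examples
#' ped <- make_factorial_pedigree(4, 4)
#' A <- build_a_matrix(ped)
#' sc <- scenario_high_h2()
#' sim <- simulate_traits(A, sc$g0, sc$r0, seed = 1)
#' fit <- mtam(sim$phenotypes, A, engine = "reml")
#' fit
#' @export
mtam <- function(phenotypes, K = NULL, X = NULL,
                 engine = c("reml", "laplace", "mcmc"), ...) {
  engine <- match.arg(engine)
  data <- if (inherits(phenotypes, "mt_data")) phenotypes
          else mt_data(phenotypes, K, X)
  switch(engine,
         reml    = fit_reml(data, ...),
         laplace = fit_laplace(data, ...),
         mcmc    = fit_mcmc(data, ...))
}

#' REML engine
#'
#' Maximizes the restricted likelihood over the transformed hyperparameters
#' (quasi-Newton with Newton polishing). Starting values come from
#' single-trait REML fits with zero dependencies unless `init` is given;
#' jittered restarts are run when `n_starts > 1` or automatically when the
#' first start fails to converge.
#'
#' @param data an [mt_data] object.
#' @param init optional [hyper_params] starting values.
#' @param n_starts number of optimizer starts (first = univariate init,
#'   remainder jittered).
#' @param seed seed used only for jittered restarts.
#' @return An object of class `mtam` with components `engine`,
#'   `theta_mode` ([hyper_params]), `g0_hat`/`r0_hat` (point estimates;
#'   posterior means for the sampling engines), `g0_mode`/`r0_mode`,
#'   `beta_hat`, `summary` (per-parameter table with 95% equal-tail
#'   intervals where samples exist), `samples` (back-transformed scalar
#'   draws, sampling engines), `theta_samples`, `laplace_covariance`,
#'   `loglik`, `diagnostics`, `data`, `call`.
#' @export
fit_reml <- function(data, init = NULL, n_starts = 1, seed = NULL) {
  stopifnot(inherits(data, "mt_data"))
  theta0 <- theta_transform(if (is.null(init)) .uni_init(data) else init)
  obj <- .obj_reml(data)
  best <- .multistart(obj, theta0, n_starts, seed)
  hp <- theta_untransform(best$par, data$n_traits)
  .make_fit(data, engine = "reml", theta_vec = best$par, hp = hp,
            loglik = best$value,
            diagnostics = list(gradient_norm = best$gradient_norm,
                               optim_convergence = best$optim_convergence,
                               converged = best$optim_convergence == 0 &&
                                 best$gradient_norm < 1e-2),
            call = sys.call(-1))
}

#' Laplace engine (deterministic Bayesian approximation)
#'
#' Because the latent genetic effects and fixed effects are Gaussian and
#' integrable in closed form, a nested approximation collapses to a Laplace
#' approximation of the hyperparameter posterior: the engine finds the
#' posterior mode on the transformed scale, approximates the posterior by a
#' Gaussian with covariance equal to the negative inverse Hessian (central
#' finite differences, step 1e-4), draws `n_samples` hyperparameter vectors
#' and maps them through [back_transform()]. Reported summaries are sample
#' means, kernel-density modes and equal-tail 95% intervals.
#'
#' @inheritParams fit_reml
#' @param n_samples number of posterior draws (>= 1000 recommended).
#' @param seed integer seed for the draws; summaries are bit-reproducible
#'   given the seed.
#' @param prior see [log_posterior()].
#' @return An object of class `mtam`; see [fit_reml()].
#' @export
fit_laplace <- function(data, n_samples = 2000, seed = 1, init = NULL,
                        n_starts = 1, prior = list()) {
  stopifnot(inherits(data, "mt_data"), n_samples >= 1)
  theta0 <- theta_transform(if (is.null(init)) .uni_init(data) else init)
  obj <- .obj_posterior(data, prior = prior)
  best <- .multistart(obj, theta0, n_starts, seed)
  H <- .num_hess(obj, best$par, h = 1e-4)
  Sigma <- tryCatch(solve(-H), error = function(e) NULL)
  ch <- if (!is.null(Sigma)) tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch))
    stop("Hessian at the posterior mode is not negative definite; ",
         "consider reparameterizing (e.g. rescaling traits) or more data")
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n_samples * length(best$par)), n_samples)
  draws <- sweep(Z %*% ch, 2L, best$par, `+`)
  colnames(draws) <- names(theta_transform(theta_untransform(best$par,
                                                             data$n_traits)))
  hp <- theta_untransform(best$par, data$n_traits)
  .make_fit(data, engine = "laplace", theta_vec = best$par, hp = hp,
            theta_samples = draws, laplace_covariance = Sigma,
            loglik = log_restricted_likelihood(hp, data),
            diagnostics = list(gradient_norm = best$gradient_norm,
                               optim_convergence = best$optim_convergence,
                               converged = best$optim_convergence == 0 &&
                                 best$gradient_norm < 1e-2,
                               n_samples = n_samples),
            call = sys.call(-1))
}

#' MCMC engine (adaptive random-walk Metropolis cross-check)
#'
#' Random-scan Metropolis on the transformed-scale posterior: each iteration
#' perturbs one randomly chosen coordinate with a Gaussian step. Step sizes
#' are adapted per coordinate in batches during burn-in, targeting
#' acceptance in 0.2-0.4, and frozen afterwards so the post-burn-in chain
#' satisfies detailed balance. Posterior modes of scalar summaries use a
#' Gaussian-kernel density with Silverman bandwidth.
#'
#' @inheritParams fit_reml
#' @param n_iter total chain length.
#' @param n_burnin burn-in iterations discarded (must be < `n_iter`).
#' @param seed integer seed.
#' @param thin keep every `thin`-th post-burn-in state (default keeps at
#'   most ~10000 states).
#' @param prior see [log_posterior()].
#' @return An object of class `mtam`; see [fit_reml()]. The result carries
#'   `diagnostics$acceptance_rate`; a rate below 0.05 after adaptation is
#'   flagged via `diagnostics$converged = FALSE`.
#' @export
fit_mcmc <- function(data, n_iter = 50000, n_burnin = 10000, seed = 1,
                     init = NULL, thin = NULL, prior = list()) {
  stopifnot(inherits(data, "mt_data"), n_iter > n_burnin, n_burnin >= 0)
  obj <- .obj_posterior(data, prior = prior)
  theta <- theta_transform(if (is.null(init)) .uni_init(data) else init)
  k <- length(theta)
  if (is.null(thin)) thin <- max(1L, (n_iter - n_burnin) %/% 10000L)
  set.seed(as.integer(seed))
  steps <- rep(0.25, k)
  lp <- obj(theta)
  n_keep <- (n_iter - n_burnin) %/% thin
  out <- matrix(NA_real_, n_keep, k)
  lp_keep <- numeric(n_keep)
  acc <- att <- numeric(k)
  acc_post <- att_post <- 0
  batch <- 50L * k
  kept <- 0L
  coords <- sample.int(k, n_iter, replace = TRUE)
  for (it in seq_len(n_iter)) {
    i <- coords[it]
    prop <- theta
    prop[i] <- prop[i] + stats::rnorm(1, 0, steps[i])
    lp_prop <- obj(prop)
    accept <- log(stats::runif(1)) < lp_prop - lp
    if (accept) { theta <- prop; lp <- lp_prop }
    if (it <= n_burnin) {
      att[i] <- att[i] + 1; acc[i] <- acc[i] + accept
      if (it %% batch == 0L) {
        rate <- ifelse(att > 0, acc / pmax(att, 1), 0.3)
        steps <- steps * exp(0.3 * (rate > 0.4) - 0.3 * (rate < 0.2))
        acc[] <- att[] <- 0
      }
    } else {
      att_post <- att_post + 1; acc_post <- acc_post + accept
      if ((it - n_burnin) %% thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- theta
        lp_keep[kept] <- lp
      }
    }
  }
  out <- out[seq_len(kept), , drop = FALSE]
  acc_rate <- acc_post / max(att_post, 1)
  # MAP-like point: highest-posterior retained state
  theta_map <- out[which.max(lp_keep[seq_len(kept)]), ]
  colnames(out) <- names(theta_transform(theta_untransform(theta_map,
                                                           data$n_traits)))
  hp <- theta_untransform(theta_map, data$n_traits)
  .make_fit(data, engine = "mcmc", theta_vec = theta_map, hp = hp,
            theta_samples = out,
            loglik = log_restricted_likelihood(hp, data),
            diagnostics = list(acceptance_rate = acc_rate,
                               converged = acc_rate >= 0.05,
                               n_iter = n_iter, n_burnin = n_burnin,
                               thin = thin, n_samples = nrow(out)),
            call = sys.call(-1))
}

# ---- shared result assembly ------------------------------------------------

# scalar components derived from a hyperparameter vector
.derived_scalars <- function(hp) {
  G0 <- compose_cov(hp$genetic)
  R0 <- compose_cov(hp$residual)
  n <- hp$n_traits
  pr <- .dep_pairs(n)
  gcor <- implied_correlations(G0)
  rcor <- implied_correlations(R0)
  h2 <- implied_heritability(G0, R0)
  vals <- c(diag(G0), G0[cbind(pr[, 1], pr[, 2])],
            diag(R0), R0[cbind(pr[, 1], pr[, 2])],
            gcor[cbind(pr[, 1], pr[, 2])], rcor[cbind(pr[, 1], pr[, 2])],
            h2)
  names(vals) <- c(paste0("va", seq_len(n)),
                   sprintf("cov_g_%d_%d", pr[, 1], pr[, 2]),
                   paste0("ve", seq_len(n)),
                   sprintf("cov_e_%d_%d", pr[, 1], pr[, 2]),
                   sprintf("r_g_%d_%d", pr[, 1], pr[, 2]),
                   sprintf("r_e_%d_%d", pr[, 1], pr[, 2]),
                   paste0("h2_", seq_len(n)))
  vals
}

.kernel_mode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x)      # Silverman's bandwidth (bw.nrd0 default)
  d$x[which.max(d$y)]
}

.make_fit <- function(data, engine, theta_vec, hp, loglik, diagnostics,
                      call, theta_samples = NULL, laplace_covariance = NULL) {
  point <- .derived_scalars(hp)
  if (!is.null(theta_samples)) {
    scal <- t(apply(theta_samples, 1L, function(th)
      .derived_scalars(theta_untransform(th, data$n_traits))))
    est <- colMeans(scal)
    smry <- data.frame(
      parameter = names(point),
      estimate = est,
      mode = apply(scal, 2L, .kernel_mode),
      lower = apply(scal, 2L, stats::quantile, 0.025),
      upper = apply(scal, 2L, stats::quantile, 0.975),
      row.names = NULL)
    covs <- back_transform(theta_samples, data$n_traits)
    g0_hat <- Reduce(`+`, lapply(covs, `[[`, "genetic")) / length(covs)
    r0_hat <- Reduce(`+`, lapply(covs, `[[`, "residual")) / length(covs)
  } else {
    scal <- NULL
    smry <- data.frame(parameter = names(point), estimate = point,
                       mode = point, lower = NA_real_, upper = NA_real_,
                       row.names = NULL)
    g0_hat <- compose_cov(hp$genetic)
    r0_hat <- compose_cov(hp$residual)
  }
  dimnames(g0_hat) <- dimnames(r0_hat) <-
    list(data$trait_names, data$trait_names)
  beta <- .mt_eval(hp, data)$beta
  structure(list(
    engine = engine,
    theta_mode = hp,
    theta_vec = theta_vec,
    theta_samples = theta_samples,
    laplace_covariance = laplace_covariance,
    samples = scal,
    g0_hat = g0_hat, r0_hat = r0_hat,
    g0_mode = compose_cov(hp$genetic), r0_mode = compose_cov(hp$residual),
    beta_hat = beta,
    summary = smry,
    loglik = loglik,
    diagnostics = diagnostics,
    data = data,
    call = call
  ), class = "mtam")
}
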