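#' Assemble multi-trait animal-model data
#'
#' Combines phenotypes, per-trait fixed-effect design matrices and a
#' relationship matrix into the data object consumed by [mtam()] and the
#' likelihood functions. Rows of the phenotype matrix are matched to the
#' relationship matrix by id. Only complete cases are modelled: rows with
#' any missing trait are dropped with a message.
#'
#' The eigendecomposition of the relationship matrix (restricted to the
#' phenotyped individuals) is computed once here and reused by every
#' likelihood evaluation; eigenvalues below `-1e-8` (relative) are an error,
#' small negatives are clipped to zero.
#'
#' @param phenotypes `n x t` numeric matrix (rownames = ids) or data frame
#'   with an `id` column.
#' @param K a [relationship_matrix] (or plain symmetric matrix with ids as
#'   dimnames) covering at least the phenotyped individuals.
#' @param X fixed-effect design: `NULL` for intercept-only (default), a
#'   single matrix shared by all traits, or a list of one matrix per trait.
#'   Each design must have full column rank.
#' @param trait_names optional trait labels.
#' @return An object of class `mt_data`.
#' @export
mt_data <- function(phenotypes, K, X = NULL, trait_names = NULL) {
  if (is.data.frame(phenotypes)) {
    if ("id" %in% names(phenotypes)) {
      ids <- as.character(phenotypes$id)
      phenotypes <- as.matrix(phenotypes[setdiff(names(phenotypes), "id")])
      rownames(phenotypes) <- ids
    } else phenotypes <- as.matrix(phenotypes)
  }
  Y <- as.matrix(phenotypes)
  if (is.null(rownames(Y))) rownames(Y) <- as.character(seq_len(nrow(Y)))
  keep <- stats::complete.cases(Y)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " incomplete rows (complete-case analysis)")
    Y <- Y[keep, , drop = FALSE]
  }
  n <- nrow(Y); t_ <- ncol(Y)
  if (t_ < 1 || n < 2) stop("need at least 2 individuals and 1 trait")
  Km <- as.matrix(K)
  kid <- rownames(Km) %||% as.character(seq_len(nrow(Km)))
  dimnames(Km) <- list(kid, kid)
  if (!all(rownames(Y) %in% kid))
    stop("phenotype ids missing from the relationship matrix: ",
         paste(utils::head(setdiff(rownames(Y), kid)), collapse = ", "))
  Km <- Km[rownames(Y), rownames(Y)]
  if (is.null(trait_names))
    trait_names <- colnames(Y) %||% paste0("trait", seq_len(t_))
  colnames(Y) <- trait_names

  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.list(X)) X <- rep(list(as.matrix(X)), t_)
  if (length(X) != t_) stop("X must have one design matrix per trait")
  X <- lapply(X, as.matrix)
  for (i in seq_len(t_)) {
    if (nrow(X[[i]]) != n) stop("design matrix ", i, " has wrong row count")
    if (qr(X[[i]])$rank < ncol(X[[i]]))
      stop("design matrix for trait ", i, " is rank deficient")
  }

  eK <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
  if (min(eK$values) < -1e-8 * max(1, max(eK$values)))
    stop("relationship matrix is not positive semi-definite")
  lambda <- pmax(eK$values, 0)
  Q <- eK$vectors

  structure(list(
    Y = Y, K = Km, X = X,
    n_ind = n, n_traits = t_,
    p = vapply(X, ncol, 1L),
    trait_names = trait_names,
    ids = rownames(Y),
    Q = Q, lambda = lambda,
    Ytil = crossprod(Q, Y),
    Xtil = lapply(X, function(x) crossprod(Q, x))
  ), class = "mt_data")
}

#' @export
print.mt_data <- function(x, ...) {
  cat("Multi-trait animal-model data:", x$n_ind, "individuals,",
      x$n_traits, "traits (", paste(x$trait_names, collapse = ", "), ")\n")
  cat("fixed-effect columns per trait:", paste(x$p, collapse = ", "), "\n")
  invisible(x)
}

# Core evaluation on the collapsed scale.
#
# With K = Q diag(lambda) Q' and the generalized eigendecomposition
# S' R0 S = I, S' G0 S = diag(d), the rotation (S' (x) Q') turns
# V = G0 (x) K + R0 (x) I into diag(lambda_j d_k + 1), so log|V|, GLS and
# the REML quadratic form are weighted-least-squares quantities.
#
# Returns log-restricted-likelihood pieces plus the GLS beta-hat.
.mt_eval <- function(hp, data, beta_prior_var = NULL) {
  t_ <- data$n_traits; n <- data$n_ind
  G0 <- compose_cov(hp$genetic)
  R0 <- compose_cov(hp$residual)
  U <- chol(R0)                              # R0 = U'U
  S <- backsolve(U, diag(t_))                # S'R0S = I
  eg <- eigen(crossprod(S, G0 %*% S), symmetric = TRUE)
  S2 <- S %*% eg$vectors
  d <- pmax(eg$values, 0)

  W <- data$Ytil %*% S2                      # n x t transformed responses
  vmat <- outer(data$lambda, d) + 1          # per-datum variances
  logdetV <- 2 * n * sum(log(diag(U))) + sum(log(vmat))

  p_tot <- sum(data$p)
  Xstar <- matrix(0, n * t_, p_tot)
  col_off <- c(0L, cumsum(data$p))
  for (k in seq_len(t_)) {
    rows <- (k - 1L) * n + seq_len(n)
    for (i in seq_len(t_)) {
      if (S2[i, k] == 0) next
      cols <- col_off[i] + seq_len(data$p[i])
      Xstar[rows, cols] <- S2[i, k] * data$Xtil[[i]]
    }
  }
  ystar <- as.vector(W)
  w <- 1 / as.vector(vmat)

  XtWX <- crossprod(Xstar, Xstar * w)
  XtWy <- crossprod(Xstar, ystar * w)
  prior_pen <- 0
  if (!is.null(beta_prior_var)) {
    XtWX <- XtWX + diag(1 / beta_prior_var, p_tot)
    prior_pen <- p_tot * log(beta_prior_var)
  }
  ch <- tryCatch(chol(XtWX), error = function(e)
    stop("fixed-effect system is singular"))
  beta <- backsolve(ch, backsolve(ch, XtWy, transpose = TRUE))
  resid <- ystar - Xstar %*% beta
  quad <- sum(w * resid^2)
  if (!is.null(beta_prior_var)) quad <- quad + sum(beta^2) / beta_prior_var
  logdetXVX <- 2 * sum(log(diag(ch)))

  N <- n * t_
  df <- if (is.null(beta_prior_var)) N - p_tot else N
  ll <- -0.5 * (df * log(2 * pi) + logdetV + logdetXVX + prior_pen + quad)

  list(ll = ll, beta = as.vector(beta), logdetV = logdetV,
       quad = quad, G0 = G0, R0 = R0, S2 = S2, d = d, vmat = vmat)
}

#' Marginal covariance operator of the collapsed model
#'
#' Represents `V = G0 (x) K + R0 (x) I` (trait-major stacking) without
#' forming it: the relationship matrix is diagonalized once (cached in the
#' data object) and the trait pair (G0, R0) is jointly diagonalized, so `V`
#' reduces to a diagonal weight matrix in rotated coordinates.
#'
#' @param theta a [hyper_params] object.
#' @param data an [mt_data] object.
#' @return list with `logdet` (log-determinant of V) and `solve(v)`, a
#'   function applying `V^{-1}` to a stacked vector of length
#'   `n_ind * n_traits`.
#' @export
marginal_covariance <- function(theta, data) {
  stopifnot(inherits(theta, "hyper_params"), inherits(data, "mt_data"))
  ev <- .mt_eval(theta, data)
  n <- data$n_ind; t_ <- data$n_traits
  Q <- data$Q; S2 <- ev$S2; vmat <- ev$vmat
  S2inv_t <- t(solve(S2))
  list(
    logdet = ev$logdetV,
    solve = function(v) {
      Vm <- matrix(v, n, t_)
      star <- crossprod(Q, Vm) %*% S2        # (S2' (x) Q') v
      as.vector(Q %*% ((star / vmat) %*% t(S2)))  # V^{-1} = T' diag(1/v) T
    }
  )
}

#' Log restricted likelihood of the hyperparameters
#'
#' The Patterson-Thompson restricted likelihood of the collapsed Gaussian
#' model, `-0.5 * [(N - p) log(2 pi) + log|V| + log|X'V^{-1}X| + y'Py]`,
#' i.e. the exact Gaussian integral over the fixed effects under a flat
#' prior. With `beta_prior_var` set, the proper-Gaussian-prior analogue is
#' returned instead.
#'
#' @param theta a [hyper_params] object.
#' @param data an [mt_data] object.
#' @param beta_prior_var optional finite variance of a mean-zero Gaussian
#'   prior on the fixed effects (default `NULL`: flat prior / REML).
#' @return scalar log-likelihood.
#' @export
log_restricted_likelihood <- function(theta, data, beta_prior_var = NULL) {
  stopifnot(inherits(theta, "hyper_params"), inherits(data, "mt_data"))
  .mt_eval(theta, data, beta_prior_var)$ll
}

# log inverse-gamma density, shape/rate convention
.dinvgamma_log <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

#' Log posterior of the hyperparameters (transformed scale)
#'
#' Restricted likelihood plus the priors of the reparameterized model:
#' inverse-Gamma(shape 0.5, rate 0.5) on every transformed-scale variance,
#' Gaussian mean 0 / variance 10 on every dependency parameter, plus the
#' Jacobian of the log-variance transform (the density is with respect to
#' the unconstrained coordinates of [theta_transform()]). The shape/RATE
#' reading of "inverse-Gamma(0.5, 0.5)" follows the convention of latent
#' Gaussian model software.
#'
#' @inheritParams log_restricted_likelihood
#' @param prior list overriding the prior constants: `ig_shape`, `ig_rate`,
#'   `dep_var`.
#' @return scalar log posterior density (unnormalized).
#' @export
log_posterior <- function(theta, data, beta_prior_var = NULL,
                          prior = list()) {
  pr <- utils::modifyList(list(ig_shape = 0.5, ig_rate = 0.5, dep_var = 10),
                          prior)
  ll <- log_restricted_likelihood(theta, data, beta_prior_var)
  v <- c(theta$genetic$variances, theta$residual$variances)
  dep <- c(theta$genetic$dependencies, theta$residual$dependencies)
  lp <- sum(.dinvgamma_log(v, pr$ig_shape, pr$ig_rate)) + sum(log(v)) +
    sum(stats::dnorm(dep, 0, sqrt(pr$dep_var), log = TRUE))
  ll + lp
}

# objective wrappers on the transformed coordinate vector; coordinates are
# clamped to +-40 (a log-variance of -40 is numerically a boundary estimate)
# so that optimizer excursions cannot underflow exp()
.clamp_theta <- function(th) pmin(pmax(th, -40), 40)

.obj_reml <- function(data, beta_prior_var = NULL) {
  t_ <- data$n_traits
  function(th) {
    out <- tryCatch(
      .mt_eval(theta_untransform(.clamp_theta(th), t_), data,
               beta_prior_var)$ll,
      error = function(e) -Inf)
    if (!is.finite(out)) -1e10 else out
  }
}

.obj_posterior <- function(data, beta_prior_var = NULL, prior = list()) {
  t_ <- data$n_traits
  function(th) {
    out <- tryCatch(
      log_posterior(theta_untransform(.clamp_theta(th), t_), data,
                    beta_prior_var, prior),
      error = function(e) -Inf)
    if (!is.finite(out)) -1e10 else out
  }
}
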