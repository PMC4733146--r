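#' Modified-Cholesky covariance parameters
#'
#' A trait covariance matrix is parameterized as `L diag(v) L'` with `L` unit
#' lower triangular. The `n(n-1)/2` strictly-lower entries of `L` are the
#' unconstrained "dependency" parameters (kappa for the genetic side, alpha
#' for the residual side) and `v` the per-trait variances on the transformed
#' scale. Any real dependencies and positive variances yield a valid
#' (positive-definite) covariance matrix, which is the point of the
#' parameterization.
#'
#' Dependencies are stored column-major over the strictly-lower triangle,
#' i.e. in pair order (1,2), (1,3), (2,3), ... matching the subscripts
#' kappa[1,2], kappa[1,3], kappa[2,3].
#'
#' @param variances positive numeric vector, one per trait.
#' @param dependencies numeric vector of length `n(n-1)/2` (default all 0).
#' @return An object of class `chol_params`.
#' @export
chol_params <- function(variances, dependencies = NULL) {
  variances <- as.numeric(variances)
  n <- length(variances)
  if (any(!is.finite(variances)) || any(variances <= 0))
    stop("variances must be strictly positive")
  ndep <- n * (n - 1L) / 2L
  if (is.null(dependencies)) dependencies <- numeric(ndep)
  dependencies <- as.numeric(dependencies)
  if (length(dependencies) != ndep)
    stop("expected ", ndep, " dependency parameters, got ",
         length(dependencies))
  structure(list(variances = variances, dependencies = dependencies,
                 n_traits = n),
            class = "chol_params")
}

#' @export
print.chol_params <- function(x, ...) {
  cat("Modified-Cholesky parameters,", x$n_traits, "traits\n")
  cat("  variances:   ", paste(signif(x$variances, 4), collapse = " "), "\n")
  if (length(x$dependencies))
    cat("  dependencies:", paste(signif(x$dependencies, 4), collapse = " "),
        "\n")
  invisible(x)
}

# unit lower-triangular factor from dependency parameters
.dep_L <- function(params) {
  n <- params$n_traits
  L <- diag(n)
  L[lower.tri(L)] <- params$dependencies   # column-major = (1,2),(1,3),(2,3)...
  L
}

#' Compose a covariance matrix from Cholesky parameters
#'
#' Returns `L diag(v) L'`; symmetric positive definite by construction for
#' any dependency values and positive variances. For three traits, entry
#' (2,1) equals `kappa[1,2] * v1`, entry (2,2) equals
#' `kappa[1,2]^2 * v1 + v2`, and so on.
#'
#' @param params a [chol_params] object.
#' @return symmetric positive-definite matrix.
#' @export
compose_cov <- function(params) {
  stopifnot(inherits(params, "chol_params"))
  L <- .dep_L(params)
  C <- L %*% (params$variances * t(L))
  (C + t(C)) / 2
}

#' Decompose a covariance matrix into Cholesky parameters
#'
#' Inverse of [compose_cov()]: the unique LDL' factorization computed by
#' pivot recursion. For three traits this reproduces the closed-form
#' back-transform identities, e.g. `kappa[1,2] = c12 / c11` and
#' `v2 = c22 - kappa[1,2]^2 * c11`.
#'
#' @param cov symmetric positive-definite matrix.
#' @return a [chol_params] object with
#'   `compose_cov(decompose_cov(cov)) == cov` to machine precision.
#' @export
decompose_cov <- function(cov) {
  cov <- as.matrix(cov)
  n <- nrow(cov)
  if (ncol(cov) != n) stop("covariance must be square")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance must be symmetric")
  L <- diag(n)
  d <- numeric(n)
  for (k in seq_len(n)) {
    m <- seq_len(k - 1L)
    d[k] <- cov[k, k] - sum(L[k, m]^2 * d[m])
    if (d[k] <= 0)
      stop("matrix is not positive definite (pivot ", k, " = ",
           format(d[k]), ")")
    if (k < n) {
      i <- (k + 1L):n
      L[i, k] <- (cov[i, k] -
                    if (k > 1L) L[i, m, drop = FALSE] %*% (L[k, m] * d[m])
                    else 0) / d[k]
    }
  }
  chol_params(d, L[lower.tri(L)])
}

#' Stacked Cholesky transform operator
#'
#' The operator `W = L (x) I` that maps independent per-trait stacked vectors
#' to correlated ones (trait-major stacking: trait 1 for all individuals,
#' then trait 2, ...). The Kronecker product is not materialized; use
#' [apply_w()] or `as.matrix()` on the result.
#'
#' @param params a [chol_params] object (its dependencies define `L`).
#' @param n_ind number of individuals (>= 1).
#' @return An object of class `transform_operator`.
#' @export
build_w <- function(params, n_ind) {
  stopifnot(inherits(params, "chol_params"), n_ind >= 1)
  structure(list(L = .dep_L(params), n_ind = as.integer(n_ind)),
            class = "transform_operator")
}

#' Apply a stacked transform operator
#'
#' @param op a `transform_operator` from [build_w()].
#' @param x stacked vector of length `n_traits * n_ind` (trait-major), or a
#'   matrix with that many rows.
#' @return the transformed vector/matrix, same shape as `x`.
#' @export
apply_w <- function(op, x) {
  stopifnot(inherits(op, "transform_operator"))
  n <- op$n_ind
  t_ <- nrow(op$L)
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (nrow(x) != n * t_) stop("x must have n_traits * n_ind rows")
  out <- apply(x, 2L, function(col) {
    as.vector(matrix(col, n, t_) %*% t(op$L))   # (L (x) I) vec(X) = vec(X L')
  })
  if (vec) as.vector(out) else out
}

#' @export
as.matrix.transform_operator <- function(x, ...) {
  kronecker(x$L, diag(x$n_ind))
}

#' @export
print.transform_operator <- function(x, ...) {
  cat("Stacked Cholesky operator: ", nrow(x$L), " traits (x) ",
      x$n_ind, " individuals\n", sep = "")
  print(round(x$L, 4))
  invisible(x)
}

#' Back-transform hyperparameter samples to original-scale covariances
#'
#' Maps each sample of transformed-scale hyperparameters through
#' [compose_cov()] on both the genetic and residual side, yielding
#' original-scale (co)variance matrices (e.g. the genetic covariance of
#' traits 1 and 2 is `kappa[1,2] * v_a1`).
#'
#' @param theta_samples a list of [hyper_params] objects, or a numeric matrix
#'   of transformed-scale draws (one row per sample, columns as in
#'   [theta_transform()]) with `n_traits` supplied.
#' @param n_traits required when `theta_samples` is a matrix.
#' @return list with one element per sample, each a
#'   `list(genetic = , residual = )` pair of covariance matrices.
#' @export
back_transform <- function(theta_samples, n_traits = NULL) {
  if (is.matrix(theta_samples)) {
    if (is.null(n_traits)) stop("n_traits is required for matrix input")
    theta_samples <- lapply(seq_len(nrow(theta_samples)), function(s)
      theta_untransform(theta_samples[s, ], n_traits))
  }
  if (!length(theta_samples)) stop("empty sample set")
  lapply(theta_samples, function(hp) {
    stopifnot(inherits(hp, "hyper_params"))
    list(genetic = compose_cov(hp$genetic),
         residual = compose_cov(hp$residual))
  })
}

#' Correlation matrix implied by a covariance matrix
#'
#' @param cov symmetric positive-definite matrix.
#' @return correlation matrix with unit diagonal.
#' @export
implied_correlations <- function(cov) {
  cov <- as.matrix(cov)
  if (any(diag(cov) <= 0)) stop("covariance diagonal must be positive")
  stats::cov2cor(cov)
}

#' Per-trait narrow-sense heritabilities implied by G0 and R0
#'
#' `h2_i = g0[i,i] / (g0[i,i] + r0[i,i])`, each trait separately; covariances
#' between traits are not involved.
#'
#' @param g0 genetic covariance matrix.
#' @param r0 residual covariance matrix of the same dimension.
#' @return numeric vector of heritabilities in (0, 1).
#' @export
implied_heritability <- function(g0, r0) {
  g <- diag(as.matrix(g0)); r <- diag(as.matrix(r0))
  if (length(g) != length(r)) stop("g0 and r0 dimensions differ")
  h <- g / (g + r)
  names(h) <- rownames(as.matrix(g0)) %||% paste0("trait", seq_along(h))
  h
}

#' Serialize Cholesky parameters to a flat named vector
#'
#' Genetic and residual parameter sets are concatenated with names
#' `a1_var, a2_var, ..., dep_g_1_2, ..., e1_var, ..., dep_e_1_2, ...`.
#'
#' @param hp a [hyper_params] object.
#' @return named numeric vector.
#' @export
flatten_params <- function(hp) {
  stopifnot(inherits(hp, "hyper_params"))
  n <- hp$genetic$n_traits
  pr <- .dep_pairs(n)
  out <- c(hp$genetic$variances, hp$genetic$dependencies,
           hp$residual$variances, hp$residual$dependencies)
  names(out) <- c(paste0("a", seq_len(n), "_var"),
                  sprintf("dep_g_%d_%d", pr[, 1], pr[, 2]),
                  paste0("e", seq_len(n), "_var"),
                  sprintf("dep_e_%d_%d", pr[, 1], pr[, 2]))
  out
}

# pair (j, i) labels in storage order: (1,2), (1,3), (2,3), ...
.dep_pairs <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  cbind(idx[, 2], idx[, 1])
}
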