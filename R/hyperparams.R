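#' Joint hyperparameters of the multi-trait model
#'
#' Bundles the genetic and residual [chol_params] sets. Optimizers and
#' samplers work on the unconstrained transformed scale produced by
#' [theta_transform()]: the log of every variance, dependencies unchanged.
#'
#' @param genetic,residual [chol_params] objects with the same number of
#'   traits.
#' @return An object of class `hyper_params`.
#' @export
hyper_params <- function(genetic, residual) {
  stopifnot(inherits(genetic, "chol_params"), inherits(residual, "chol_params"))
  if (genetic$n_traits != residual$n_traits)
    stop("genetic and residual parameter sets must have the same trait count")
  structure(list(genetic = genetic, residual = residual,
                 n_traits = genetic$n_traits),
            class = "hyper_params")
}

#' @export
print.hyper_params <- function(x, ...) {
  cat("Hyperparameters for", x$n_traits, "traits\n")
  cat("genetic:\n"); print(x$genetic)
  cat("residual:\n"); print(x$residual)
  invisible(x)
}

#' Transform hyperparameters to the unconstrained scale
#'
#' Layout: `log(genetic variances)`, genetic dependencies,
#' `log(residual variances)`, residual dependencies.
#'
#' @param hp a [hyper_params] object.
#' @return named numeric vector.
#' @export
theta_transform <- function(hp) {
  stopifnot(inherits(hp, "hyper_params"))
  n <- hp$n_traits
  pr <- .dep_pairs(n)
  out <- c(log(hp$genetic$variances), hp$genetic$dependencies,
           log(hp$residual$variances), hp$residual$dependencies)
  names(out) <- c(paste0("log_va", seq_len(n)),
                  sprintf("kappa_%d_%d", pr[, 1], pr[, 2]),
                  paste0("log_ve", seq_len(n)),
                  sprintf("alpha_%d_%d", pr[, 1], pr[, 2]))
  out
}

#' Inverse of [theta_transform()]
#'
#' @param theta numeric vector on the transformed scale.
#' @param n_traits number of traits.
#' @return a [hyper_params] object.
#' @export
theta_untransform <- function(theta, n_traits) {
  n <- n_traits
  ndep <- n * (n - 1L) / 2L
  if (length(theta) != 2L * (n + ndep))
    stop("theta has length ", length(theta), ", expected ", 2L * (n + ndep))
  i <- 0L
  take <- function(k) {
    out <- theta[i + seq_len(k)]
    i <<- i + k
    out
  }
  hyper_params(
    chol_params(exp(take(n)), take(ndep)),
    chol_params(exp(take(n)), take(ndep))
  )
}
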