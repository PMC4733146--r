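# S3 methods for fitted mtam objects.

#' @export
print.mtam <- function(x, digits = 3, ...) {
  cat("Multi-trait animal model fit (engine: ", x$engine, ")\n", sep = "")
  cat(x$data$n_ind, "individuals,", x$data$n_traits, "traits:",
      paste(x$data$trait_names, collapse = ", "), "\n\n")
  cat("Genetic covariance (G0):\n")
  print(round(x$g0_hat, digits))
  cat("Residual covariance (R0):\n")
  print(round(x$r0_hat, digits))
  h2 <- implied_heritability(x$g0_hat, x$r0_hat)
  cat("Heritabilities:",
      paste(format(round(h2, digits)), collapse = " "), "\n")
  if (isFALSE(x$diagnostics$converged))
    cat("WARNING: engine flagged non-convergence; see $diagnostics\n")
  invisible(x)
}

#' Summarize a fitted multi-trait animal model
#'
#' @param object an `mtam` fit.
#' @param ... unused.
#' @return A `summary.mtam` object: the per-parameter table (estimate,
#'   kernel mode, equal-tail 95% interval for sampling engines) plus
#'   diagnostics.
#' @export
summary.mtam <- function(object, ...) {
  structure(list(engine = object$engine,
                 table = object$summary,
                 loglik = object$loglik,
                 diagnostics = object$diagnostics,
                 n_ind = object$data$n_ind,
                 trait_names = object$data$trait_names),
            class = "summary.mtam")
}

#' @export
print.summary.mtam <- function(x, digits = 3, ...) {
  cat("Engine:", x$engine, "|", x$n_ind, "individuals |",
      length(x$trait_names), "traits\n")
  cat("Restricted log-likelihood at the point estimate:",
      format(x$loglik, digits = 8), "\n\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  dg <- x$diagnostics
  if (!is.null(dg$gradient_norm))
    cat("\ngradient norm at optimum:", format(dg$gradient_norm), "\n")
  if (!is.null(dg$acceptance_rate))
    cat("\nMetropolis acceptance rate:", round(dg$acceptance_rate, 3), "\n")
  invisible(x)
}

#' @export
coef.mtam <- function(object, type = c("fixed", "hyper"), ...) {
  type <- match.arg(type)
  if (type == "fixed") {
    b <- object$beta_hat
    nm <- unlist(lapply(seq_along(object$data$X), function(i)
      paste0(object$data$trait_names[i], ":",
             colnames(object$data$X[[i]]) %||%
               paste0("b", seq_len(object$data$p[i])))))
    stats::setNames(b, nm)
  } else {
    stats::setNames(object$summary$estimate, object$summary$parameter)
  }
}

#' @export
logLik.mtam <- function(object, ...) {
  structure(object$loglik, df = length(object$theta_vec), class = "logLik")
}

#' @export
vcov.mtam <- function(object, ...) {
  if (is.null(object$laplace_covariance))
    stop("transformed-scale covariance is only available for the laplace engine")
  object$laplace_covariance
}

#' Breeding values from a fitted model
#'
#' Plugs the fitted G0/R0 into Henderson's mixed model equations
#' ([solve_mme()]) and returns estimated breeding values.
#'
#' @param object an `mtam` fit.
#' @param truth optional `sim_truth` for accuracy scoring.
#' @param ... unused.
#' @return an `mtam_blup` object (see [solve_mme()]).
#' @export
predict.mtam <- function(object, truth = NULL, ...) {
  solve_mme(object$data, object$g0_hat, object$r0_hat, truth = truth)
}

#' @export
fitted.mtam <- function(object, ...) {
  bl <- predict.mtam(object)
  xb <- vapply(seq_len(object$data$n_traits), function(i) {
    idx <- sum(object$data$p[seq_len(i - 1L)]) + seq_len(object$data$p[i])
    as.vector(object$data$X[[i]] %*% object$beta_hat[idx])
  }, numeric(object$data$n_ind))
  out <- xb + bl$u_hat
  dimnames(out) <- dimnames(object$data$Y)
  out
}

#' @export
residuals.mtam <- function(object, ...) {
  object$data$Y - fitted.mtam(object)
}

#' @export
simulate.mtam <- function(object, nsim = 1, seed = 1, ...) {
  lapply(seq_len(nsim), function(s)
    simulate_traits(object$data$K, object$g0_hat, object$r0_hat,
                    seed = as.integer(seed) + s - 1L))
}

#' @export
plot.mtam <- function(x, ...) {
  h2_cols <- grep("^h2_", x$summary$parameter)
  if (is.null(x$samples)) {
    graphics::barplot(stats::setNames(x$summary$estimate[h2_cols],
                                      x$data$trait_names),
                      ylim = c(0, 1), ylab = "heritability",
                      main = paste("Point estimates (", x$engine, ")"))
  } else {
    nm <- x$summary$parameter[h2_cols]
    old <- graphics::par(mfrow = c(1, length(nm)))
    on.exit(graphics::par(old))
    for (j in seq_along(nm)) {
      graphics::plot(stats::density(x$samples[, nm[j]]),
                     main = x$data$trait_names[j], xlab = "heritability")
    }
  }
  invisible(x)
}

#' Serialize a fit to JSON (+ optional raw sample CSV)
#'
#' @param fit an `mtam` fit.
#' @param path output JSON path.
#' @param samples_path optional CSV path for the raw transformed-scale draws.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, samples_path = NULL) {
  out <- list(engine = fit$engine,
              g0_hat = unclass(fit$g0_hat),
              r0_hat = unclass(fit$r0_hat),
              beta_hat = fit$beta_hat,
              summary = fit$summary,
              loglik = fit$loglik,
              diagnostics = fit$diagnostics)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(samples_path) && !is.null(fit$theta_samples))
    utils::write.csv(as.data.frame(fit$theta_samples), samples_path,
                     row.names = FALSE)
  invisible(path)
}
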