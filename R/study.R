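#' Run a replicate simulation study
#'
#' Simulates `n_replicates` datasets from a scenario (factorial pedigree +
#' G0/R0), fits each with the requested engines, and aggregates original-
#' scale (co)variance estimates, estimation errors (estimate - truth),
#' implied correlations and heritabilities with empirical 95% intervals
#' across replicates (2.5/97.5 percentiles of the per-replicate point
#' estimates), and EBV accuracies scored against the simulated truth.
#' Replicate `r` uses seed `base_seed + r`; the whole study is deterministic
#' given `(scenario, engines, n_replicates, base_seed)`. A failing engine on
#' one replicate is recorded and the study continues.
#'
#' @param scenario a scenario list (see [scenario_high_h2()] /
#'   [read_scenario()]).
#' @param engines character subset of `c("reml", "laplace", "mcmc")`.
#' @param n_replicates number of simulation replicates.
#' @param base_seed integer base seed.
#' @param blup if `TRUE` (default) compute EBV accuracies per replicate via
#'   [solve_mme()] with each engine's estimated covariance matrices.
#' @param engine_args named list of extra argument lists per engine, e.g.
#'   `list(laplace = list(n_samples = 1000))`.
#' @param verbose print per-replicate progress.
#' @return An object of class `mtam_study`: `estimates` (long data frame:
#'   replicate, engine, parameter, estimate, truth, error), `correlations`
#'   and `heritability` summary tables (mean and empirical 95% interval per
#'   engine), `accuracy` (per engine: per-trait and mean EBV accuracy
#'   averaged over replicates), `failures`, and the inputs.
#' @export
run_replicate_study <- function(scenario, engines = c("reml", "laplace"),
                                n_replicates = 10, base_seed = 1,
                                blup = TRUE, engine_args = list(),
                                verbose = FALSE) {
  engines <- match.arg(engines, c("reml", "laplace", "mcmc"),
                       several.ok = TRUE)
  ped <- make_factorial_pedigree(scenario$n_seed, scenario$n_pollen)
  A <- build_a_matrix(ped)
  truth_vals <- .derived_scalars(
    hyper_params(decompose_cov(scenario$g0), decompose_cov(scenario$r0)))

  rows <- list()
  acc_rows <- list()
  failures <- data.frame(replicate = integer(0), engine = character(0),
                         message = character(0))
  for (r in seq_len(n_replicates)) {
    sim <- simulate_traits(A, scenario$g0, scenario$r0,
                           seed = as.integer(base_seed) + r)
    data <- mt_data(sim$phenotypes, A)
    for (eng in engines) {
      args <- c(list(data), engine_args[[eng]])
      if (eng != "reml" && is.null(args$seed))
        args$seed <- as.integer(base_seed) + r
      fit <- tryCatch(do.call(paste0("fit_", eng), args),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        failures <- rbind(failures,
                          data.frame(replicate = r, engine = eng,
                                     message = conditionMessage(fit)))
        next
      }
      est <- stats::setNames(fit$summary$estimate, fit$summary$parameter)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, engine = eng,
        parameter = names(est), estimate = unname(est),
        truth = unname(truth_vals[names(est)]),
        error = unname(est - truth_vals[names(est)]))
      if (blup) {
        bl <- solve_mme(data, fit$g0_hat, fit$r0_hat, truth = sim$truth)
        acc_rows[[length(acc_rows) + 1L]] <- data.frame(
          replicate = r, engine = eng,
          trait = c(data$trait_names, "mean"),
          accuracy = c(bl$accuracy$per_trait, bl$accuracy$mean))
      }
      if (verbose)
        message("replicate ", r, " engine ", eng, " done")
    }
  }
  estimates <- do.call(rbind, rows)
  accuracy_long <- if (length(acc_rows)) do.call(rbind, acc_rows) else NULL
  if (is.null(estimates)) {
    warning("every engine run failed; returning failure log only")
    return(structure(list(scenario = scenario, engines = engines,
                          n_replicates = n_replicates,
                          base_seed = base_seed, estimates = NULL,
                          correlations = NULL, heritability = NULL,
                          accuracy = NULL, accuracy_long = NULL,
                          failures = failures, truth = truth_vals),
                     class = "mtam_study"))
  }

  summarize <- function(params) {
    sub <- estimates[estimates$parameter %in% params, ]
    out <- do.call(rbind, lapply(split(sub, sub[c("engine", "parameter")]),
      function(g) data.frame(
        engine = g$engine[1], parameter = g$parameter[1],
        truth = g$truth[1], mean = mean(g$estimate),
        lower = unname(stats::quantile(g$estimate, 0.025)),
        upper = unname(stats::quantile(g$estimate, 0.975)))))
    rownames(out) <- NULL
    out[order(out$parameter, out$engine), ]
  }
  pnames <- unique(estimates$parameter)
  correlations <- summarize(grep("^r_[ge]_", pnames, value = TRUE))
  heritability <- summarize(grep("^h2_", pnames, value = TRUE))

  accuracy <- NULL
  if (!is.null(accuracy_long)) {
    accuracy <- do.call(rbind, lapply(
      split(accuracy_long, accuracy_long[c("engine", "trait")]),
      function(g) data.frame(engine = g$engine[1], trait = g$trait[1],
                             accuracy = mean(g$accuracy))))
    rownames(accuracy) <- NULL
  }

  structure(list(scenario = scenario, engines = engines,
                 n_replicates = n_replicates, base_seed = base_seed,
                 estimates = estimates, correlations = correlations,
                 heritability = heritability, accuracy = accuracy,
                 accuracy_long = accuracy_long,
                 failures = failures, truth = truth_vals),
            class = "mtam_study")
}

#' @export
print.mtam_study <- function(x, digits = 3, ...) {
  cat("Replicate study '", x$scenario$name, "': ", x$n_replicates,
      " replicates, engines: ", paste(x$engines, collapse = ", "), "\n",
      sep = "")
  if (nrow(x$failures))
    cat(nrow(x$failures), "engine failures recorded\n")
  cat("\nHeritability (replicate means, empirical 95% intervals):\n")
  tab <- x$heritability
  tab[c("truth", "mean", "lower", "upper")] <-
    lapply(tab[c("truth", "mean", "lower", "upper")], round, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$accuracy)) {
    cat("\nMean EBV accuracy:\n")
    acc <- x$accuracy
    acc$accuracy <- round(acc$accuracy, digits)
    print(acc, row.names = FALSE)
  }
  invisible(x)
}

#' Write the study tables as CSV
#'
#' Writes `<stem>_estimates.csv` (long format),
#' `<stem>_correlations.csv`, `<stem>_heritability.csv` and, when present,
#' `<stem>_accuracy.csv`.
#'
#' @param study an `mtam_study`.
#' @param stem output path stem.
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, stem) {
  paths <- character(0)
  w <- function(df, suffix) {
    p <- paste0(stem, "_", suffix, ".csv")
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(study$estimates, "estimates")
  w(study$correlations, "correlations")
  w(study$heritability, "heritability")
  if (!is.null(study$accuracy)) w(study$accuracy, "accuracy")
  invisible(paths)
}

#' Plot estimation-error box plots for a study
#'
#' One box per engine for each (co)variance component, with a horizontal
#' reference line at zero error.
#'
#' @param x an `mtam_study`.
#' @param which regular expression selecting parameters (default the
#'   variance components).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.mtam_study <- function(x, which = "^v[ae]", ...) {
  sub <- x$estimates[grepl(which, x$estimates$parameter), ]
  graphics::boxplot(error ~ engine + parameter, data = sub,
                    las = 2, ylab = "estimation error (estimate - truth)",
                    ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Standardize traits and build the covariance rescaling rule
#'
#' Z-scores every trait (zero mean, unit variance) and returns the rule that
#' maps covariance estimates from the standardized scale back to the
#' original scale: entry (i, j) is multiplied by `s_i * s_j`, the product of
#' the sample standard deviations.
#'
#' @param data an [mt_data] object.
#' @return list with `data` (standardized [mt_data]), `center`, `scale`, and
#'   `rescale_cov(cov)` applying the back-mapping.
#' @export
standardize_and_rescale <- function(data) {
  stopifnot(inherits(data, "mt_data"))
  s <- apply(data$Y, 2L, stats::sd)
  m <- colMeans(data$Y)
  if (any(s == 0)) stop("constant trait: cannot standardize")
  Ys <- sweep(sweep(data$Y, 2L, m), 2L, s, `/`)
  sdata <- mt_data(Ys, data$K, data$X, trait_names = data$trait_names)
  list(data = sdata, center = m, scale = s,
       rescale_cov = function(cov) {
         cov <- as.matrix(cov)
         cov * tcrossprod(s)
       })
}
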