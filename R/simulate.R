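#' Simulate correlated traits from an animal model
#'
#' Draws breeding values `a` with covariance `g0 (x) K` and residuals `e`
#' with covariance `r0 (x) I` via Cholesky factors (`a = P z_a`,
#' `e = T z_e`, `z` standard normal) and returns phenotypes `y = a + e`.
#' The Kronecker factor is never formed: with lower-triangular factors
#' `P0 P0' = g0` and `Lk Lk' = K`, the `n x t` matrix of breeding values is
#' `Lk Z P0'`, which has the required distribution.
#'
#' @param K relationship matrix (PSD), e.g. from [build_a_matrix()].
#' @param g0 genetic trait covariance matrix (PD).
#' @param r0 residual trait covariance matrix (PD), same dimension.
#' @param seed integer seed; the draw is fully reproducible given the seed.
#' @param mu optional per-trait intercepts added to the phenotypes
#'   (default none: `y = a + e`).
#' @return An object of class `sim_data`: list with `phenotypes`
#'   (`n x t` matrix, rownames = ids) and `truth` (class `sim_truth`:
#'   `true_breeding_values`, `true_residuals`, `g0`, `r0`, `seed`).
#' @export
simulate_traits <- function(K, g0, r0, seed, mu = NULL) {
  g0 <- as.matrix(g0); r0 <- as.matrix(r0)
  t_ <- nrow(g0)
  stopifnot(nrow(r0) == t_, ncol(g0) == t_, ncol(r0) == t_)
  n <- nrow(K)
  ids <- rownames(K) %||% as.character(seq_len(n))
  Lk <- .psd_factor(unclass(K))
  P0 <- t(chol(g0))
  T0 <- t(chol(r0))

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  Za <- matrix(stats::rnorm(n * t_), n, t_)
  Ze <- matrix(stats::rnorm(n * t_), n, t_)
  a <- Lk %*% Za %*% t(P0)
  e <- Ze %*% t(T0)
  y <- a + e
  if (!is.null(mu)) y <- sweep(y, 2L, mu, `+`)
  dimnames(a) <- dimnames(e) <- dimnames(y) <-
    list(ids, colnames(g0) %||% paste0("trait", seq_len(t_)))
  structure(list(
    phenotypes = y,
    truth = structure(list(true_breeding_values = a, true_residuals = e,
                           g0 = g0, r0 = r0, seed = as.integer(seed)),
                      class = "sim_truth")),
    class = "sim_data")
}

# lower-triangular-ish factor F with F F' = S for a PSD matrix; plain
# Cholesky when PD, eigen factor (negative eigenvalues beyond -1e-8 rejected,
# small ones clipped to 0) otherwise.
.psd_factor <- function(S) {
  f <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (!is.null(f)) return(f)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(es$values) < -1e-8 * max(1, max(es$values)))
    stop("matrix is not positive semi-definite")
  es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
}

#' @export
print.sim_data <- function(x, ...) {
  cat("Simulated multi-trait data:", nrow(x$phenotypes), "individuals x",
      ncol(x$phenotypes), "traits (seed", x$truth$seed, ")\n")
  invisible(x)
}

#' Built-in simulation scenarios
#'
#' The two trivariate scenarios of the package's simulation study, each a
#' 25 seed-parent x 25 pollen-donor factorial pedigree (675 individuals).
#' `scenario_high_h2()` uses
#' `G0 = [1.0 0.4 0.6; 0.4 1.5 0.9; 0.6 0.9 2.5]` and a residual matrix with
#' unit variances and all covariances 0.5 (heritabilities 0.50/0.60/0.71);
#' `scenario_low_h2()` uses `G0 = [5 -2 3; -2 7 4; 3 4 10]`,
#' `R0 = [20 -5 1; -5 28 3; 1 3 35]` (heritabilities 0.20/0.20/0.22 with a
#' negative genetic correlation between traits 1 and 2).
#'
#' @return list with elements `name`, `g0`, `r0`, `n_seed`, `n_pollen`.
#' @export
scenario_high_h2 <- function() {
  list(name = "high_h2",
       g0 = matrix(c(1.0, 0.4, 0.6,
                     0.4, 1.5, 0.9,
                     0.6, 0.9, 2.5), 3, 3, byrow = TRUE),
       r0 = matrix(c(1.0, 0.5, 0.5,
                     0.5, 1.0, 0.5,
                     0.5, 0.5, 1.0), 3, 3, byrow = TRUE),
       n_seed = 25L, n_pollen = 25L)
}

#' @rdname scenario_high_h2
#' @export
scenario_low_h2 <- function() {
  list(name = "low_h2",
       g0 = matrix(c( 5, -2,  3,
                     -2,  7,  4,
                      3,  4, 10), 3, 3, byrow = TRUE),
       r0 = matrix(c(20, -5,  1,
                     -5, 28,  3,
                      1,  3, 35), 3, 3, byrow = TRUE),
       n_seed = 25L, n_pollen = 25L)
}

#' Read / write a scenario configuration (YAML)
#'
#' The YAML file holds `name`, `g0` and `r0` as lists of rows, pedigree
#' parameters `n_seed`/`n_pollen`, and optionally `n_replicates` and
#' `base_seed`.
#'
#' @param path file path.
#' @param scenario a scenario list as returned by [scenario_high_h2()].
#' @return `read_scenario` returns the scenario list; `write_scenario`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("g0", "r0"))
    cfg[[f]] <- do.call(rbind, lapply(cfg[[f]], as.numeric))
  if (max(abs(cfg$g0 - t(cfg$g0))) > 0 || max(abs(cfg$r0 - t(cfg$r0))) > 0)
    stop("scenario covariance matrices must be symmetric")
  cfg$n_seed <- as.integer(cfg$n_seed)
  cfg$n_pollen <- as.integer(cfg$n_pollen)
  cfg
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  out <- scenario
  out$g0 <- lapply(seq_len(nrow(scenario$g0)),
                   function(i) as.numeric(scenario$g0[i, ]))
  out$r0 <- lapply(seq_len(nrow(scenario$r0)),
                   function(i) as.numeric(scenario$r0[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write simulated phenotypes (and truth) as CSV
#'
#' Phenotypes go to `<path>` with an `id` column plus one column per trait;
#' true breeding values and residuals go to `<stem>_truth.csv`.
#'
#' @param sim a `sim_data` object from [simulate_traits()].
#' @param path output CSV path for the phenotypes.
#' @return invisibly, the two paths written.
#' @export
write_sim_data <- function(sim, path) {
  stopifnot(inherits(sim, "sim_data"))
  ph <- data.frame(id = rownames(sim$phenotypes), sim$phenotypes,
                   check.names = FALSE)
  utils::write.csv(ph, path, row.names = FALSE)
  tr <- sim$truth
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  tdf <- data.frame(id = rownames(tr$true_breeding_values),
                    stats::setNames(as.data.frame(tr$true_breeding_values),
                                    paste0("a_", colnames(tr$true_breeding_values))),
                    stats::setNames(as.data.frame(tr$true_residuals),
                                    paste0("e_", colnames(tr$true_residuals))),
                    check.names = FALSE)
  utils::write.csv(tdf, truth_path, row.names = FALSE)
  invisible(c(path, truth_path))
}
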