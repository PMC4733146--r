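# Independent oracles used across the test files. These deliberately avoid
# the package's own computational paths.

# Monte-Carlo gene dropping: expected identity-by-descent relatedness.
# Unknown parents contribute unique founder alleles.
gene_drop_A <- function(ped, ndrop = 2e5) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  a1 <- matrix(0L, ndrop, n)
  a2 <- matrix(0L, ndrop, n)
  next_allele <- 1L
  new_allele <- function() {
    out <- next_allele
    next_allele <<- next_allele + 1L
    out
  }
  for (i in seq_len(n)) {
    a1[, i] <- if (si[i] == 0L) new_allele() else
      ifelse(stats::runif(ndrop) < 0.5, a1[, si[i]], a2[, si[i]])
    a2[, i] <- if (di[i] == 0L) new_allele() else
      ifelse(stats::runif(ndrop) < 0.5, a1[, di[i]], a2[, di[i]])
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    f <- ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
          (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
    A[i, j] <- A[j, i] <- 2 * mean(f)
  }
  A
}

# random valid pedigree of n individuals, first n_founder founders
random_pedigree <- function(n, n_founder = max(2L, n %/% 3L)) {
  id <- paste0("i", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= n_founder) next
    pool <- id[seq_len(i - 1L)]
    pick <- sample(pool, 2L)
    if (stats::runif(1) < 0.15) {            # one unknown parent sometimes
      sire[i] <- pick[1]
    } else {
      sire[i] <- pick[1]; dam[i] <- pick[2]
    }
  }
  pedigree(id, sire, dam)
}

# random symmetric positive-definite matrix
random_pd <- function(n) {
  L <- matrix(stats::rnorm(n * n), n)
  crossprod(L) + diag(0.5, n)
}

# dense restricted log-likelihood: brute-force V = G0 (x) K + R0 (x) I and
# the Gaussian integral over beta (exact GLS collapse)
dense_reml <- function(Y, K, Xlist, G0, R0) {
  n <- nrow(Y); t_ <- ncol(Y)
  V <- kronecker(G0, K) + kronecker(R0, diag(n))
  X <- matrix(0, n * t_, sum(vapply(Xlist, ncol, 1L)))
  off <- 0L
  for (i in seq_len(t_)) {
    X[(i - 1L) * n + seq_len(n), off + seq_len(ncol(Xlist[[i]]))] <- Xlist[[i]]
    off <- off + ncol(Xlist[[i]])
  }
  y <- as.vector(Y)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  b <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  p <- ncol(X)
  as.numeric(-0.5 * ((length(y) - p) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XVX)$modulus +
                       t(r) %*% Vi %*% r))
}

# joint-Gaussian conditional mean of (beta, u) with flat beta prior:
# beta = GLS, u = Cov(u, y) V^{-1} (y - X beta)
dense_blup <- function(Y, K, Xlist, G0, R0) {
  n <- nrow(Y); t_ <- ncol(Y)
  V <- kronecker(G0, K) + kronecker(R0, diag(n))
  X <- matrix(0, n * t_, sum(vapply(Xlist, ncol, 1L)))
  off <- 0L
  for (i in seq_len(t_)) {
    X[(i - 1L) * n + seq_len(n), off + seq_len(ncol(Xlist[[i]]))] <- Xlist[[i]]
    off <- off + ncol(Xlist[[i]])
  }
  y <- as.vector(Y)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- kronecker(G0, K) %*% Vi %*% (y - X %*% b)
  list(beta = as.vector(b), u = matrix(u, n, t_))
}

# Monte-Carlo standard error of a (possibly autocorrelated) chain mean,
# using the integrated autocorrelation time with Geyer-style truncation
mcse_chain <- function(x) {
  n <- length(x)
  ac <- stats::acf(x, lag.max = min(1000L, n - 1L), plot = FALSE)$acf[, 1, 1]
  tau <- 1
  for (l in 2:length(ac)) {
    if (ac[l] <= 0) break
    tau <- tau + 2 * ac[l]
  }
  stats::sd(x) * sqrt(tau / n)
}
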