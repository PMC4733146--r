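#' Construct a pedigree
#'
#' A pedigree is an ordered table of individual/sire/dam records. Parents must
#' be listed before their offspring; records are topologically sorted on
#' construction if they are not already in such an order.
#'
#' @param id character vector of unique individual identifiers.
#' @param sire,dam character vectors of parent identifiers; `NA`, `""` or
#'   `"0"` denote an unknown parent.
#' @return An object of class `pedigree`: a `data.frame` with columns
#'   `id`, `sire`, `dam` (character, `NA` = unknown parent), ordered so that
#'   every parent precedes its offspring.
#' @examples
#' pedigree(c("F1", "F2", "O"), c(NA, NA, "F1"), c(NA, NA, "F2"))
#' @export
pedigree <- function(id, sire, dam) {
  id   <- as.character(id)
  sire <- .clean_parent(sire)
  dam  <- .clean_parent(dam)
  if (length(sire) != length(id) || length(dam) != length(id))
    stop("id, sire and dam must have the same length")
  if (anyDuplicated(id))
    stop("duplicated individual ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  unknown <- setdiff(c(sire, dam), c(id, NA))
  if (length(unknown))
    stop("parent id(s) not present as individuals: ",
         paste(unknown, collapse = ", "))
  ord <- .topo_order(id, sire, dam)
  out <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("pedigree", "data.frame")
  out
}

.clean_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

# Kahn's algorithm; stable with respect to input order. Errors on cycles.
.topo_order <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam),  0L, idx[dam])
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                   (si == 0L | placed[pmax(si, 1L)]) &
                   (di == 0L | placed[pmax(di, 1L)]))
    if (!length(ready)) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (length(ord) < n)
    stop("pedigree contains a cycle involving: ",
         paste(id[!placed], collapse = ", "))
  ord
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat("Pedigree with", nrow(x), "individuals (", nf, "founders )\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Read a pedigree from CSV
#'
#' Expects a header row with columns `id`, `sire`, `dam`; `0` or an empty
#' field denotes an unknown parent.
#'
#' @param path file path.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns id, sire, dam")
  pedigree(df$id, df$sire, df$dam)
}

#' Factorial-mating pedigree
#'
#' Builds the one-generation factorial design used throughout the simulation
#' study: `n_seed + n_pollen` unrelated founders, and one offspring for every
#' (seed parent, pollen donor) pair. With 25 seed parents and 25 pollen
#' donors this gives 675 individuals in total.
#'
#' @param n_seed number of seed parents.
#' @param n_pollen number of pollen donors.
#' @return A [pedigree] with founders first (seed parents `S1..`, pollen
#'   donors `P1..`), then offspring `S<i>xP<j>` in seed-major order.
#' @export
make_factorial_pedigree <- function(n_seed, n_pollen) {
  stopifnot(n_seed >= 1, n_pollen >= 1)
  seeds  <- paste0("S", seq_len(n_seed))
  pollen <- paste0("P", seq_len(n_pollen))
  cross  <- expand.grid(p = pollen, s = seeds, stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reorder to seed-major
  off_sire <- cross$s
  off_dam  <- cross$p
  pedigree(id   = c(seeds, pollen, paste0(off_sire, "x", off_dam)),
           sire = c(rep(NA, n_seed + n_pollen), off_sire),
           dam  = c(rep(NA, n_seed + n_pollen), off_dam))
}

#' Additive relationship matrix from a pedigree
#'
#' Computes the numerator relationship matrix A by the tabular method:
#' founders are unrelated and non-inbred, `A[i,i] = 1 + 0.5 * A[sire, dam]`
#' and `A[i,j] = 0.5 * (A[j, sire] + A[j, dam])`, with terms for unknown
#' parents contributing zero.
#'
#' @param ped a [pedigree].
#' @return A [relationship_matrix] of kind `"pedigree"`.
#' @export
build_a_matrix <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped$id, ped$sire, ped$dam)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam),  0L, idx[ped$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s) A[j, s] else 0) + (if (d) A[j, d] else 0))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + 0.5 * (if (s && d) A[s, d] else 0)
  }
  relationship_matrix(A, ids = ped$id, kind = "pedigree")
}
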