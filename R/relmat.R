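#' Relationship matrix container
#'
#' Wraps a symmetric positive semi-definite relatedness matrix (pedigree A or
#' genomic M) together with individual labels.
#'
#' @param values symmetric numeric matrix.
#' @param ids individual labels (defaults to existing dimnames).
#' @param kind `"pedigree"` or `"genomic"`.
#' @param check if `TRUE` (default) verify symmetry, positive
#'   semi-definiteness (smallest eigenvalue >= -1e-8) and, for pedigree
#'   matrices, diagonal entries >= 1.
#' @return An object of class `relmat`: the matrix with `ids` as dimnames and
#'   attribute `kind`.
#' @export
relationship_matrix <- function(values, ids = rownames(values),
                                kind = c("pedigree", "genomic"),
                                check = TRUE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  ids <- as.character(ids)
  if (nrow(values) != ncol(values) || nrow(values) != length(ids))
    stop("relationship matrix must be square with one id per row")
  if (check) {
    if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values))))
      stop("relationship matrix is not symmetric")
    values <- (values + t(values)) / 2
    ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(1, max(ev)))
      stop("relationship matrix is not positive semi-definite (min eigenvalue ",
           format(min(ev)), ")")
    if (kind == "pedigree" && any(diag(values) < 1 - 1e-8))
      stop("pedigree relationship matrix has diagonal entries < 1")
  }
  dimnames(values) <- list(ids, ids)
  structure(values, kind = kind, class = c("relmat", "matrix", "array"))
}

#' @export
print.relmat <- function(x, ...) {
  cat(attr(x, "kind"), "relationship matrix,", nrow(x), "individuals\n")
  k <- min(6L, nrow(x))
  print(round(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], 3))
  if (nrow(x) > k) cat("...\n")
  invisible(x)
}

#' Genomic relationship matrix from biallelic markers
#'
#' VanRaden's first method: with genotypes coded -1/0/1 (copies of the
#' counted allele minus one), columns are centered at twice the sample allele
#' frequency minus one and `M = C C' / d`, where
#' `d = 2 * sum(p_k * (1 - p_k))`. Missing genotypes are mean-imputed per
#' marker before centering; allele frequencies are estimated from the sample.
#'
#' @param markers numeric matrix of codes in \{-1, 0, 1\} (`NA` = missing),
#'   individuals in rows; row names are used as ids.
#' @param jitter optional non-negative value added to the diagonal (default 0,
#'   no regularization) for near-singular matrices.
#' @return A [relationship_matrix] of kind `"genomic"`.
#' @export
build_grm <- function(markers, jitter = 0) {
  markers <- as.matrix(markers)
  if (nrow(markers) < 2) stop("need at least 2 individuals")
  ok <- markers %in% c(-1, 0, 1) | is.na(markers)
  if (!all(ok)) stop("marker codes must be -1, 0, 1 or missing")
  if (any(colSums(!is.na(markers)) == 0)) stop("all-missing marker column")
  cm <- colMeans(markers, na.rm = TRUE)
  for (k in which(colSums(is.na(markers)) > 0))
    markers[is.na(markers[, k]), k] <- cm[k]
  p <- (cm + 1) / 2                       # counted-allele frequency
  d <- 2 * sum(p * (1 - p))
  if (d <= 0) stop("all markers are monomorphic; GRM denominator is zero")
  C <- sweep(markers, 2L, cm)
  M <- tcrossprod(C) / d
  if (jitter > 0) M <- M + diag(jitter, nrow(M))
  relationship_matrix(M, ids = rownames(markers) %||%
                        as.character(seq_len(nrow(M))),
                      kind = "genomic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a marker matrix from CSV
#'
#' First column `id`, remaining columns integer codes in \{-1, 0, 1\};
#' blank fields are treated as missing.
#'
#' @param path file path.
#' @return numeric matrix with individual ids as row names.
#' @export
read_markers <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write / read a relationship matrix as CSV
#'
#' The CSV carries ids as the header row and first column.
#'
#' @param x a [relationship_matrix].
#' @param path file path.
#' @param kind matrix kind used when reading back.
#' @return `read_relmat` returns a [relationship_matrix]; `write_relmat`
#'   returns `path` invisibly.
#' @export
write_relmat <- function(x, path) {
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path, kind = c("pedigree", "genomic")) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  relationship_matrix(m, ids = as.character(df[[1]]), kind = match.arg(kind))
}
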