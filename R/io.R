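#' Read phenotypes from CSV
#'
#' Expects an `id` column plus one numeric column per trait.
#'
#' @param path file path.
#' @return numeric matrix with ids as row names.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"id" %in% names(df)) stop("phenotype file must have an id column")
  m <- as.matrix(df[setdiff(names(df), "id")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$id)
  m
}

#' Serialize hyperparameters to a flat named-value table
#'
#' Writes the [flatten_params()] representation
#' (`a1_var, ..., dep_g_1_2, ..., e1_var, ..., dep_e_1_2, ...`) as two-column
#' CSV (`name,value`) or as JSON, chosen by the file extension.
#'
#' @param hp a [hyper_params] object.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_params <- function(hp, path) {
  flat <- flatten_params(hp)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(flat), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(name = names(flat), value = unname(flat)),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @param n_traits number of traits encoded in the file.
#' @return `read_params` returns a [hyper_params] object.
#' @export
read_params <- function(path, n_traits) {
  flat <- if (grepl("\\.json$", path)) {
    unlist(jsonlite::read_json(path))
  } else {
    df <- utils::read.csv(path)
    stats::setNames(df$value, df$name)
  }
  n <- n_traits
  ndep <- n * (n - 1L) / 2L
  pr <- .dep_pairs(n)
  gv <- flat[paste0("a", seq_len(n), "_var")]
  gd <- if (ndep) flat[sprintf("dep_g_%d_%d", pr[, 1], pr[, 2])] else numeric(0)
  ev <- flat[paste0("e", seq_len(n), "_var")]
  ed <- if (ndep) flat[sprintf("dep_e_%d_%d", pr[, 1], pr[, 2])] else numeric(0)
  if (anyNA(c(gv, gd, ev, ed))) stop("parameter table is missing entries")
  hyper_params(chol_params(unname(gv), unname(gd)),
               chol_params(unname(ev), unname(ed)))
}
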