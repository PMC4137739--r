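#' Construct a descriptor table
#'
#' A descriptor table is a compounds-by-descriptors numeric matrix with
#' unique compound identifiers as row names and unique descriptor names as
#' column names. Entries may be `NA` for descriptors a compound does not
#' possess; such columns are normally removed by [pretreat()] rule 1.
#'
#' @param values numeric matrix (compounds in rows, descriptors in columns).
#' @param compound_ids character vector of unique compound identifiers;
#'   defaults to existing row names or `C1..Cn`.
#' @param descriptor_names character vector of unique descriptor names;
#'   defaults to existing column names or `D1..Dp`.
#' @param kind optional per-column annotation of descriptor class
#'   (composition, topological, geometric, electrostatic, quantum-chemical).
#' @return a numeric matrix of class `descriptor_table`.
#' @seealso [read_descriptor_table()], [pretreat()]
#' @export
descriptor_table <- function(values, compound_ids = rownames(values),
                             descriptor_names = colnames(values),
                             kind = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); p <- ncol(values)
  if (is.null(compound_ids)) compound_ids <- paste0("C", seq_len(n))
  if (is.null(descriptor_names)) descriptor_names <- paste0("D", seq_len(p))
  compound_ids <- as.character(compound_ids)
  descriptor_names <- as.character(descriptor_names)
  if (length(compound_ids) != n)
    stop("length of 'compound_ids' does not match the number of rows")
  if (length(descriptor_names) != p)
    stop("length of 'descriptor_names' does not match the number of columns")
  if (anyDuplicated(compound_ids))
    stop("duplicate compound ids: ",
         paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "))
  if (anyDuplicated(descriptor_names))
    stop("duplicate descriptor names: ",
         paste(unique(descriptor_names[duplicated(descriptor_names)]),
               collapse = ", "))
  dimnames(values) <- list(compound_ids, descriptor_names)
  if (!is.null(kind)) {
    if (length(kind) != p)
      stop("'kind' must have one entry per descriptor")
    attr(values, "kind") <- as.character(kind)
  }
  class(values) <- c("descriptor_table", class(values))
  values
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("Descriptor table: %d compounds x %d descriptors (%d missing entries)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE]), ...)
  if (ncol(x) > 6L) cat("... (", ncol(x) - 6L, " more descriptors)\n", sep = "")
  invisible(x)
}

# coerce input to a bare numeric matrix with dimnames
as_descriptor_matrix <- function(x) {
  if (inherits(x, "descriptor_table")) return(unclass(x))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("D", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("C", seq_len(nrow(x)))
  x
}

#' Read a descriptor table from CSV
#'
#' The expected layout is one header row of descriptor names, a first column
#' of compound identifiers, and a numeric body. Missing descriptor values are
#' written as the `na` token.
#'
#' @param path path to a CSV file.
#' @param na the missing-value token (default `"NA"`).
#' @return a [descriptor_table()].
#' @export
read_descriptor_table <- function(path, na = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = character())
  if (ncol(raw) < 2L)
    stop("descriptor CSV needs an id column plus at least one descriptor")
  ids <- raw[[1L]]
  dn <- colnames(raw)[-1L]
  if (anyDuplicated(dn))
    stop("format error: duplicate descriptor names in ", path, ": ",
         paste(unique(dn[duplicated(dn)]), collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals) & !(body == na | body == ""), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("parse error in %s: non-numeric value '%s' at row %d, column '%s'",
                 path, body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], dn[bad[1L, 2L]]))
  vals[is.na(vals)] <- NA_real_
  descriptor_table(vals, compound_ids = ids, descriptor_names = dn)
}

#' Write a descriptor table to CSV
#'
#' Inverse of [read_descriptor_table()]; round-trips finite values at full
#' double precision.
#'
#' @param x a descriptor table or numeric matrix.
#' @param path output path.
#' @param na token used for missing entries.
#' @export
write_descriptor_table <- function(x, path, na = "NA") {
  x <- as_descriptor_matrix(x)
  df <- data.frame(compound = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = na)
  invisible(path)
}

#' Construct a BRPP response vector
#'
#' Holds the observed binding rate of plasma protein (percent) per compound,
#' together with an optional train/test split flag.
#'
#' @param compound_ids character identifiers, aligned to a descriptor table.
#' @param brpp observed BRPP in percent; must lie in \[0, 100\].
#' @param split optional per-compound flag, `"train"` or `"test"`.
#' @param check_range enforce the \[0, 100\] range of observed BRPP
#'   (default `TRUE`; synthetic unclipped responses may disable it).
#' @return a data frame of class `response_vector` with columns `compound`,
#'   `brpp` and `split`.
#' @export
response_vector <- function(compound_ids, brpp, split = NULL,
                            check_range = TRUE) {
  compound_ids <- as.character(compound_ids)
  brpp <- as.numeric(brpp)
  if (length(compound_ids) != length(brpp))
    stop("'compound_ids' and 'brpp' must have equal length")
  if (anyDuplicated(compound_ids)) stop("duplicate compound ids")
  if (anyNA(brpp)) stop("missing BRPP values are not allowed")
  if (check_range && any(brpp < 0 | brpp > 100))
    stop("observed BRPP must lie in [0, 100] percent")
  if (is.null(split)) split <- rep("train", length(brpp))
  split <- as.character(split)
  if (length(split) != length(brpp) || !all(split %in% c("train", "test")))
    stop("'split' must be 'train' or 'test' for every compound")
  structure(data.frame(compound = compound_ids, brpp = brpp, split = split,
                       stringsAsFactors = FALSE),
            class = c("response_vector", "data.frame"))
}

#' Read a response vector from CSV
#'
#' Expects columns `compound` and `brpp` (percent), plus an optional `split`
#' column with values `train`/`test`.
#'
#' @param path path to a CSV file.
#' @return a [response_vector()].
#' @export
read_response_vector <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("compound", "brpp")
  if (!all(need %in% colnames(df)))
    stop("response CSV must contain columns 'compound' and 'brpp'")
  response_vector(df$compound, df$brpp,
                  split = if ("split" %in% colnames(df)) df$split else NULL)
}

#' Randomly assign a train/test split
#'
#' Flags `n_test` compounds as the test set (the study design holds out 14
#' of 70 compounds) and the rest as training, reproducibly for a fixed seed.
#'
#' @param response a [response_vector()].
#' @param n_test number of test compounds, `0 < n_test < n`.
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @return the response with a new `split` column.
#' @export
split_train_test <- function(response, n_test, seed = NULL) {
  stopifnot(inherits(response, "response_vector"))
  n <- nrow(response)
  if (!is.numeric(n_test) || length(n_test) != 1L || n_test <= 0 || n_test >= n)
    stop("'n_test' must satisfy 0 < n_test < ", n)
  idx <- with_seed(seed, sample.int(n, n_test))
  response$split <- "train"
  response$split[idx] <- "test"
  response
}
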