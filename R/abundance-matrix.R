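#' Samples-by-entities abundance matrix
#'
#' Container for non-negative abundance values of entities (genes, taxa or
#' MAGs) across samples, together with a declared normalization state.
#' Entities are rows and samples are columns (entity count usually far
#' exceeds the 18-sample scale of a pond survey, so files and matrices are
#' entity-major).
#'
#' The three normalization states are:
#' \describe{
#'   \item{`raw`}{values on an arbitrary non-negative scale (e.g. mean
#'     read coverage).}
#'   \item{`fraction`}{each sample column sums to 1 (all-zero columns are
#'     permitted and stay zero).}
#'   \item{`max100`}{each sample column is scaled so its maximum is 100
#'     (all-zero columns permitted).}
#' }
#'
#' @param values Numeric matrix, entities in rows (rownames required),
#'   samples in columns (colnames required); all values finite and >= 0.
#' @param normalization One of `"raw"`, `"fraction"`, `"max100"`.
#' @return An `abund_matrix`: a numeric matrix with a `normalization`
#'   attribute, validated against the state's invariant.
#' @examples
#' m <- abundance_matrix(
#'   matrix(c(0.6, 0.4, 0.5, 0.5), nrow = 2,
#'          dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'   normalization = "fraction")
#' normalization_state(m)
#' @export
abundance_matrix <- function(values,
                             normalization = c("raw", "fraction", "max100")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_sodamag("values must be a numeric matrix",
                 class = "sodamag_validation_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_sodamag("values must have entity rownames and sample colnames",
                 class = "sodamag_validation_error")
  }
  x <- structure(values, normalization = normalization,
                 class = c("abund_matrix", "matrix", "array"))
  validate_abund_matrix(x)
}

#' @rdname abundance_matrix
#' @param x An `abund_matrix`.
#' @export
normalization_state <- function(x) {
  attr(x, "normalization")
}

validate_abund_matrix <- function(x, tol = 1e-9) {
  if (anyDuplicated(rownames(x))) {
    stop_sodamag("duplicate entity ids: ",
                 paste(unique(rownames(x)[duplicated(rownames(x))]),
                       collapse = ", "),
                 class = "sodamag_validation_error")
  }
  if (anyDuplicated(colnames(x))) {
    stop_sodamag("duplicate sample ids",
                 class = "sodamag_validation_error")
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_sodamag("abundance values must be finite and non-negative",
                 class = "sodamag_validation_error")
  }
  state <- normalization_state(x)
  if (state == "fraction" && ncol(x) > 0 && nrow(x) > 0) {
    cs <- colSums(x)
    bad <- abs(cs - 1) > tol & cs > tol
    if (any(bad)) {
      stop_sodamag("fraction matrix columns must sum to 1 (or be all ",
                   "zero); offending samples: ",
                   paste(colnames(x)[bad], collapse = ", "),
                   class = "sodamag_validation_error")
    }
  }
  if (state == "max100" && ncol(x) > 0 && nrow(x) > 0) {
    mx <- apply(x, 2, max)
    bad <- abs(mx - 100) > tol & mx > tol
    if (any(bad)) {
      stop_sodamag("max100 matrix columns must peak at 100 (or be all ",
                   "zero); offending samples: ",
                   paste(colnames(x)[bad], collapse = ", "),
                   class = "sodamag_validation_error")
    }
  }
  x
}

#' @export
print.abund_matrix <- function(x, ...) {
  cat(sprintf("abundance matrix: %d entities x %d samples [%s]\n",
              nrow(x), ncol(x), normalization_state(x)))
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more entities\n", nrow(x) - 6L))
  invisible(x)
}

#' Renormalize an abundance matrix
#'
#' `normalize_fraction()` rescales each sample column to sum to 1;
#' `scale_max100()` rescales each sample column so its maximum is 100.
#' All-zero columns are left untouched in both cases.
#'
#' @param x An `abund_matrix` (or plain non-negative matrix with dimnames).
#' @return An `abund_matrix` in the corresponding normalization state.
#' @export
normalize_fraction <- function(x) {
  v <- as_plain_matrix(x)
  cs <- colSums(v)
  nz <- cs > 0
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2, cs[nz], "/")
  abundance_matrix(v, "fraction")
}

#' @rdname normalize_fraction
#' @export
scale_max100 <- function(x) {
  v <- as_plain_matrix(x)
  mx <- apply(v, 2, max)
  nz <- mx > 0
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2, mx[nz] / 100, "/")
  abundance_matrix(v, "max100")
}

as_plain_matrix <- function(x) {
  v <- unclass(x)
  attr(v, "normalization") <- NULL
  v
}

# TSV round trip --------------------------------------------------------------

#' Write / read an abundance matrix as TSV
#'
#' Entity-major TSV with a header row of sample ids and a leading comment
#' line `#normalization=<state>` recording the normalization state.  UTF-8,
#' `.` decimal point, no thousands separators; values are written with
#' enough digits that a round trip is exact to below 1e-12.
#'
#' @param m An `abund_matrix` (validated before writing).
#' @param path Output file path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()`
#'   returns the reconstructed `abund_matrix`.
#' @export
write_matrix <- function(m, path) {
  if (!inherits(m, "abund_matrix")) {
    stop_sodamag("m must be an abund_matrix",
                 class = "sodamag_validation_error")
  }
  validate_abund_matrix(m)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#normalization=", normalization_state(m)), con)
  writeLines(paste(c("entity_id", colnames(m)), collapse = "\t"), con)
  if (nrow(m) > 0) {
    body <- apply(unclass(m), 1, function(row) {
      paste(sprintf("%.17g", row), collapse = "\t")
    })
    writeLines(paste(rownames(m), body, sep = if (ncol(m)) "\t" else ""),
               con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) {
    stop_sodamag("no such file: ", path, class = "sodamag_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L || !startsWith(lines[[1L]], "#normalization=")) {
    stop_sodamag("matrix file must start with a #normalization= comment",
                 class = "sodamag_format_error")
  }
  state <- sub("^#normalization=", "", lines[[1L]])
  header <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
  samples <- header[-1L]
  body <- lines[-(1:2)]
  entities <- character(length(body))
  values <- matrix(0, nrow = length(body), ncol = length(samples))
  for (i in seq_along(body)) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != length(samples) + 1L) {
      stop_sodamag("line ", i + 2L, ": expected ", length(samples) + 1L,
                   " fields, found ", length(fields),
                   class = "sodamag_format_error")
    }
    entities[[i]] <- fields[[1L]]
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals)) {
      stop_sodamag("line ", i + 2L, ": non-numeric abundance value",
                   class = "sodamag_format_error")
    }
    values[i, ] <- vals
  }
  dimnames(values) <- list(entities, samples)
  abundance_matrix(values, state)
}
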