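#' Construct a community matrix
#'
#' A community matrix is a sites-by-species numeric matrix with a declared
#' `mode`: `"presence"` (all entries 0/1) or `"abundance"` (any non-negative
#' values).  Relative abundances used by diversity indices derive from the
#' rows of an abundance-mode matrix; presence mode implies equal weights
#' across the species present at a site.
#'
#' @param values numeric matrix, sites in rows, species in columns, with
#'   unique dimnames.
#' @param mode `"presence"` or `"abundance"`.
#' @param drop_empty_sites drop rows with zero total (diversity is undefined
#'   for empty sites); dropped rows are counted and reported via a warning.
#' @return a `community_matrix`: the numeric matrix with attributes `mode`,
#'   `n_coerced` (cells coerced to 1 in presence mode) and
#'   `dropped_sites` (labels of empty rows removed).
#' @export
community_matrix <- function(values, mode = c("presence", "abundance"),
                             drop_empty_sites = TRUE) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("community matrix requires site and species labels")
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate site label")
  if (anyDuplicated(colnames(values)))
    stop("duplicate species label")
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("community matrix contains missing values")
  if (any(values < 0)) stop("negative abundance")
  n_coerced <- 0L
  if (mode == "presence") {
    coerce <- values > 0 & values != 1
    n_coerced <- sum(coerce)
    values[values > 0] <- 1
  }
  dropped <- character(0)
  empty <- rowSums(values) == 0
  if (any(empty) && drop_empty_sites) {
    dropped <- rownames(values)[empty]
    warning(sprintf("dropped %d empty site(s): %s", length(dropped),
                    paste(dropped, collapse = ", ")))
    values <- values[!empty, , drop = FALSE]
  }
  if (nrow(values) == 0) stop("no non-empty sites")
  structure(values, mode_flag = mode, n_coerced = n_coerced,
            dropped_sites = dropped, class = c("community_matrix", "matrix", "array"))
}

#' Read a community matrix from delimited text
#'
#' First column is the site id; remaining columns are species.  The
#' delimiter is inferred from the file extension (`.tsv`/`.txt` = tab,
#' otherwise comma).
#'
#' @inheritParams community_matrix
#' @param path file path.
#' @return a [community_matrix()].
#' @export
read_community <- function(path, mode = c("presence", "abundance")) {
  mode <- match.arg(mode)
  tab <- read_id_table(path)
  community_matrix(as.matrix(tab), mode = mode)
}

# Shared reader: delimited text, first column = id -> data.frame with rownames
read_id_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- trimws(as.character(tab[[1]]))
  if (anyDuplicated(ids)) stop("duplicate id in first column of ", path)
  if (anyDuplicated(trimws(colnames(tab)[-1])))
    stop("duplicate species label in ", path)
  tab <- tab[, -1, drop = FALSE]
  colnames(tab) <- trimws(colnames(tab))
  rownames(tab) <- ids
  tab
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community matrix: %d sites x %d species (%s mode)\n",
              nrow(x), ncol(x), attr(x, "mode_flag")))
  if (attr(x, "n_coerced") > 0)
    cat(sprintf("  %d cell(s) coerced to presence\n", attr(x, "n_coerced")))
  invisible(x)
}

#' Validate a square distance matrix
#'
#' Checks symmetry, zero diagonal, non-negativity and labelling; returns the
#' matrix with labels trimmed.  All site-by-site and species-by-species
#' distances in the package flow through this check.
#'
#' @param d square numeric matrix with dimnames.
#' @param tol symmetry tolerance.
#' @return the validated matrix.
#' @export
as_dist_matrix <- function(d, tol = 1e-8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix requires labels")
  rownames(d) <- colnames(d) <- trimws(rownames(d))
  if (anyNA(d)) stop("distance matrix contains missing values")
  if (any(d < 0)) stop("negative distance")
  if (max(abs(d - t(d))) > tol) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > tol)) stop("distance matrix diagonal is not zero")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Write a tabular result to CSV
#'
#' Deterministic column order (as stored), full precision (15 significant
#' digits, enough to round-trip doubles for all practical purposes).
#' Matrices (e.g. distance matrices) are written as square tables with a
#' leading id column.
#'
#' @param x data.frame or matrix.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_table <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), as.data.frame(x), check.names = FALSE)
  }
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a square distance matrix written by [write_table()]
#' @param path CSV path (first column labels).
#' @return validated distance matrix.
#' @export
read_dist_matrix <- function(path) {
  tab <- read_id_table(path)
  m <- as.matrix(tab)
  as_dist_matrix(m)
}
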