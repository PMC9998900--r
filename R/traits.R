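#' Construct a trait table with declared trait kinds
#'
#' Trait kinds are declared, never inferred from the values (a column of
#' 1/2/3 codes is ambiguous between ordinal and categorical).  The five
#' riparian traits of the default analysis are dispersal type, growth form
#' and life cycle (categorical), flowering phenology (ordinal months) and
#' shoot height (continuous, metres).
#'
#' @param df data.frame with species as rownames (or a first column `species`).
#' @param kinds named character vector mapping trait name to one of
#'   `"categorical"`, `"ordinal"`, `"continuous"`.
#' @return a `trait_table` (data.frame with attribute `kinds`).
#' @export
trait_table <- function(df, kinds) {
  if ("species" %in% names(df) && is.null(rownames(df))) {
    rownames(df) <- trimws(df$species)
    df$species <- NULL
  }
  rownames(df) <- trimws(rownames(df))
  if (anyDuplicated(rownames(df))) stop("duplicate species label")
  kinds <- unlist(kinds)
  if (!all(names(kinds) %in% names(df)))
    stop("trait schema names traits absent from the table: ",
         paste(setdiff(names(kinds), names(df)), collapse = ", "))
  if (!all(names(df) %in% names(kinds)))
    stop("traits without a declared kind: ",
         paste(setdiff(names(df), names(kinds)), collapse = ", "))
  bad <- !kinds %in% c("categorical", "ordinal", "continuous")
  if (any(bad)) stop("unknown trait kind: ", paste(kinds[bad], collapse = ", "))
  kinds <- kinds[names(df)]
  for (j in names(df)) {
    if (kinds[[j]] %in% c("ordinal", "continuous") && !is.numeric(df[[j]]))
      stop("trait '", j, "' declared ", kinds[[j]], " but is not numeric")
    if (kinds[[j]] == "continuous" && any(!is.finite(df[[j]][!is.na(df[[j]])])))
      stop("non-finite values in continuous trait '", j, "'")
  }
  all_missing <- apply(df, 1, function(r) all(is.na(r)))
  if (any(all_missing))
    stop("species with no non-missing trait: ",
         paste(rownames(df)[all_missing], collapse = ", "))
  structure(df, kinds = kinds, class = c("trait_table", "data.frame"))
}

#' Read a trait table and its schema sidecar
#'
#' @param path CSV/TSV path, first column species id.
#' @param schema either a named vector/list of kinds or the path to a YAML
#'   sidecar mapping trait name to kind.
#' @return a [trait_table()].
#' @export
read_traits <- function(path, schema) {
  df <- read_id_table(path)
  if (is.character(schema) && length(schema) == 1 && file.exists(schema))
    schema <- yaml::read_yaml(schema)
  trait_table(df, unlist(schema))
}

#' Trait kinds of a trait table
#' @param traits a `trait_table`.
#' @return named character vector.
#' @export
trait_kinds <- function(traits) attr(traits, "kinds")

#' Read a site environment table
#'
#' Expects one row per site; columns may include the inundation zone
#' (`zone`, levels I-IV) and/or `inundation_days`, soil variables, climate
#' variables (MAT, MAP) and topography.  All non-id columns other than
#' `zone` must be numeric and finite.
#'
#' @param path CSV/TSV path, first column site id.
#' @return data.frame with site rownames.
#' @export
read_env <- function(path) {
  tab <- read_id_table(path)
  for (j in setdiff(names(tab), c("zone", "aspect_class"))) {
    if (!is.numeric(tab[[j]]))
      stop("environment column '", j, "' is not numeric")
    if (any(!is.finite(tab[[j]])))
      stop("non-finite values in environment column '", j, "'")
  }
  tab
}

#' Read site coordinates
#'
#' @param path CSV/TSV, first column site id, then x and y columns
#'   (lon/lat when geographic).
#' @param crs `"geographic"` (degrees) or `"planar"`.
#' @return data.frame with columns `x`, `y` and attribute `crs_flag`.
#' @export
read_coords <- function(path, crs = c("geographic", "planar")) {
  crs <- match.arg(crs)
  tab <- read_id_table(path)
  if (ncol(tab) < 2) stop("coordinates need two columns")
  tab <- tab[, 1:2]
  names(tab) <- c("x", "y")
  if (crs == "geographic" && any(abs(tab$y) > 90))
    stop("latitude outside [-90, 90]")
  attr(tab, "crs_flag") <- crs
  tab
}
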