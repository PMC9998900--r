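#' Gower distance over mixed trait types
#'
#' Per-trait dissimilarity is a 0/1 mismatch for categorical traits, a
#' range-normalized absolute difference for continuous traits, and a
#' range-normalized absolute difference of average ranks for ordinal traits
#' (rank scaling; ties get mean rank).  The pairwise distance is the
#' weighted mean over traits non-missing in both species (pairwise deletion
#' with weight renormalization); a pair sharing no trait is an error.
#' Continuous/ordinal normalization uses the pool-wide range of the table
#' as given, so distances are stable for a reconciled bundle.
#'
#' @param traits a [trait_table()].
#' @param weights optional named per-trait weights (default equal).
#' @return species-by-species distance matrix in \[0, 1\].
#' @export
gower_distance <- function(traits, weights = NULL) {
  kinds <- trait_kinds(traits)
  df <- as.data.frame(traits)
  sp <- rownames(df)
  n <- length(sp)
  if (is.null(weights)) {
    weights <- rep(1, ncol(df))
    names(weights) <- names(df)
  }
  if (!all(names(df) %in% names(weights)))
    stop("weights must cover every trait")
  weights <- weights[names(df)]
  if (any(weights < 0)) stop("negative trait weight")

  # per-trait scaled value columns; categorical kept as character
  cols <- list()
  keep <- character(0)
  for (j in names(df)) {
    v <- df[[j]]
    if (kinds[[j]] == "categorical") {
      cols[[j]] <- as.character(v)
      keep <- c(keep, j)
    } else {
      if (kinds[[j]] == "ordinal") {
        r <- rep(NA_real_, n)
        r[!is.na(v)] <- rank(v[!is.na(v)], ties.method = "average")
        v <- r
      }
      rng <- diff(range(v, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) {
        warning("trait '", j, "' has zero range over the pool; dropped")
        next
      }
      cols[[j]] <- (v - min(v, na.rm = TRUE)) / rng
      keep <- c(keep, j)
    }
  }
  if (length(keep) == 0) stop("no usable traits")
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  wsum <- matrix(0, n, n)
  for (j in keep) {
    v <- cols[[j]]
    ok <- !is.na(v)
    share <- outer(ok, ok, "&")
    contrib <- matrix(0, n, n)
    if (kinds[[j]] == "categorical") {
      contrib[share] <- outer(v, v, "!=")[share]
    } else {
      contrib[share] <- abs(outer(v, v, "-"))[share]
    }
    d <- d + weights[[j]] * contrib * share
    wsum <- wsum + weights[[j]] * share
  }
  if (any(wsum[upper.tri(wsum)] == 0))
    stop("species pair with no shared non-missing trait")
  d <- d / wsum
  diag(d) <- 0
  as_dist_matrix(d)
}
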