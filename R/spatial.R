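#' Pairwise geographic distances among sites
#'
#' @param coords data.frame with columns `x`, `y` (lon/lat when
#'   geographic) and attribute `crs_flag`, as from [read_coords()], or any
#'   two-column table (then `method` decides the interpretation).
#' @param method `"haversine"` (great-circle, km, Earth radius 6371 km)
#'   or `"euclidean"` (planar units).  Haversine on planar-flagged
#'   coordinates is an error.
#' @return site-by-site distance matrix.
#' @export
geo_distance <- function(coords, method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  crs <- attr(coords, "crs_flag")
  if (!is.null(crs)) {
    if (method == "haversine" && crs == "planar")
      stop("haversine distance requires geographic coordinates")
    if (method == "euclidean" && crs == "geographic")
      warning("euclidean distance on geographic coordinates")
  }
  m <- as.matrix(coords[, c("x", "y")])
  if (method == "haversine") {
    d <- geosphere::distm(m, fun = function(p, q)
      geosphere::distHaversine(p, q, r = 6371000)) / 1000
  } else {
    d <- as.matrix(stats::dist(m))
  }
  dimnames(d) <- list(rownames(coords), rownames(coords))
  as_dist_matrix(d)
}

# largest edge of the minimum spanning tree (Prim)
mst_max_edge <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  maxe <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    maxe <- max(maxe, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  maxe
}

#' Principal coordinates of neighbour matrices (spatial eigenvectors)
#'
#' PCNM construction: geographic distances above the truncation threshold
#' `t` (default: the largest edge of the minimum spanning tree, which
#' keeps the site graph connected) are replaced by `4t`; the modified
#' matrix is double-centered as in PCoA and eigendecomposed.  Retained
#' axes are those with positive eigenvalues (positively autocorrelated
#' spatial patterns); negative-eigenvalue axes are available via
#' `positive_only = FALSE`.
#'
#' @param geo_dist site distance matrix.
#' @param truncation threshold `t`, or `NULL` for the MST default.
#' @param positive_only keep only positive-eigenvalue axes.
#' @param tol relative eigenvalue tolerance.
#' @return an `eigen_basis` list: `vectors` (sites x axes, unit norm),
#'   `values`, `truncation`, `n_retained`, `site_ids`.
#' @export
pcnm_axes <- function(geo_dist, truncation = NULL, positive_only = TRUE,
                      tol = 1e-8) {
  d <- as_dist_matrix(geo_dist)
  n <- nrow(d)
  if (n < 3) stop("PCNM needs at least 3 sites")
  t0 <- if (is.null(truncation)) mst_max_edge(d) else truncation
  dm <- d
  dm[dm > t0] <- 4 * t0
  diag(dm) <- 0
  a <- -0.5 * dm^2
  rc <- rowMeans(a)
  g <- a - outer(rc, rep(1, n)) - outer(rep(1, n), rc) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  thresh <- tol * max(abs(e$values))
  keep <- if (positive_only) e$values > thresh else abs(e$values) > thresh
  vec <- e$vectors[, keep, drop = FALSE]
  colnames(vec) <- paste0("PCNM", seq_len(ncol(vec)))
  rownames(vec) <- rownames(d)
  structure(list(vectors = vec, values = e$values[keep],
                 all_values = e$values, truncation = t0,
                 n_retained = ncol(vec), site_ids = rownames(d)),
            class = "eigen_basis")
}

#' Center and scale numeric columns
#'
#' Each column is centered to mean 0 and scaled to SD 1 using the
#' population SD convention (divide by n).  Constant columns are dropped
#' with a warning.  Idempotent at the stated tolerance.
#'
#' @param env numeric data.frame or matrix.
#' @return standardized data.frame with attribute
#'   `sd_convention = "population"`.
#' @export
standardize <- function(env) {
  env <- as.data.frame(env)
  num <- vapply(env, is.numeric, logical(1))
  out <- env[, num, drop = FALSE]
  n <- nrow(out)
  keep <- rep(TRUE, ncol(out))
  for (j in seq_along(out)) {
    v <- out[[j]]
    s <- sqrt(mean((v - mean(v))^2))
    if (s < 1e-12) {
      warning("constant column '", names(out)[j], "' dropped")
      keep[j] <- FALSE
    } else {
      out[[j]] <- (v - mean(v)) / s
    }
  }
  out <- out[, keep, drop = FALSE]
  attr(out, "sd_convention") <- "population"
  out
}

#' PCA reduction of one environmental variable family
#'
#' Correlation-matrix PCA (variables standardized first); axes explaining
#' more than `retain_threshold` of the variance are retained.  Axis signs
#' are fixed so that the largest-magnitude loading on each axis is
#' positive, making results deterministic.  With fewer than two variables
#' the input passes through unreduced (with a note attribute).
#'
#' @param env_subset numeric table (one family, e.g. the soil variables).
#' @param retain_threshold variance-proportion retention threshold
#'   (default 0.10).
#' @param prefix axis label prefix, e.g. `"Soil_PC"`.
#' @return a `reduced_env` list: `scores` (retained axes), `loadings`,
#'   `proportion` (all axes), `retained`, `prefix`.
#' @export
env_pca <- function(env_subset, retain_threshold = 0.10, prefix = "PC") {
  x <- standardize(env_subset)
  if (ncol(x) < 2) {
    sc <- as.matrix(x)
    colnames(sc) <- paste0(prefix, seq_len(ncol(sc)))
    return(structure(list(scores = sc, loadings = diag(ncol(sc)),
                          proportion = rep(1, ncol(sc)),
                          retained = seq_len(ncol(sc)), prefix = prefix,
                          note = "fewer than 2 variables; passed through"),
                     class = "reduced_env"))
  }
  xm <- as.matrix(x)
  e <- eigen(stats::cov(xm) * (nrow(xm) - 1) / nrow(xm), symmetric = TRUE)
  prop <- e$values / sum(e$values)
  rot <- e$vectors
  # sign convention: largest |loading| positive per axis
  for (j in seq_len(ncol(rot))) {
    m <- which.max(abs(rot[, j]))
    if (rot[m, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- xm %*% rot
  retained <- which(prop > retain_threshold)
  scores <- scores[, retained, drop = FALSE]
  colnames(scores) <- paste0(prefix, retained)
  rownames(rot) <- colnames(xm)
  colnames(rot) <- paste0(prefix, seq_len(ncol(rot)))
  structure(list(scores = scores, loadings = rot, proportion = prop,
                 retained = retained, prefix = prefix),
            class = "reduced_env")
}

#' Euclidean environmental distance between sites
#'
#' @param table standardized numeric site table (rows = sites).
#' @return site-by-site Euclidean distance matrix.
#' @export
env_distance <- function(table) {
  m <- as.matrix(as.data.frame(table))
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- list(rownames(m), rownames(m))
  as_dist_matrix(d)
}
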