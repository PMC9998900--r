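#' Mantel permutation test
#'
#' Pearson correlation between the lower-triangular elements of two
#' aligned distance matrices; the null distribution comes from jointly
#' permuting rows and columns of `dy`.  One-tailed p for positive
#' association with the (r+1)/(n+1) convention.
#'
#' @param dx,dy distance matrices with identical labels.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return a `mantel_result` data.frame row: `r`, `p`, `n_perm`,
#'   `partial`, `seed`.
#' @export
mantel_test <- function(dx, dy, n_perm = 999, seed = NULL) {
  dx <- as_dist_matrix(dx)
  dy <- as_dist_matrix(dy)
  check_labels(dx, dy)
  if (n_perm < 99) stop("n_perm must be at least 99")
  n <- nrow(dx)
  lt <- lower.tri(dx)
  vx <- dx[lt]
  if (stats::sd(vx) < 1e-14 || stats::sd(dy[lt]) < 1e-14) {
    warning("constant distance matrix: Mantel r undefined")
    return(structure(data.frame(r = NA_real_, p = NA_real_, n_perm = n_perm,
                                partial = NA_character_,
                                seed = if (is.null(seed)) NA_integer_ else seed),
                     class = c("mantel_result", "data.frame")))
  }
  r_obs <- stats::cor(vx, dy[lt])
  if (!is.null(seed)) set.seed(seed)
  r_null <- vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    stats::cor(vx, dy[p, p][lt])
  }, 0)
  p <- (sum(r_null >= r_obs) + 1) / (n_perm + 1)
  structure(data.frame(r = r_obs, p = p, n_perm = n_perm,
                       partial = NA_character_,
                       seed = if (is.null(seed)) NA_integer_ else seed),
            class = c("mantel_result", "data.frame"))
}

#' Partial Mantel test
#'
#' Correlation of the residuals of `dx` and `dy` after regressing their
#' off-diagonal elements on those of `dz`.  The null permutes one raw
#' matrix (`dy`) and recomputes its residuals against the fixed `dz`
#' (residual-correlation method with raw-matrix permutation).
#'
#' @param dx,dy,dz aligned distance matrices; the association of `dx` and
#'   `dy` is tested controlling for `dz`.
#' @inheritParams mantel_test
#' @return a `mantel_result` row with `partial` naming the controlled
#'   matrix.
#' @export
partial_mantel <- function(dx, dy, dz, n_perm = 999, seed = NULL,
                           partial_label = "dz") {
  dx <- as_dist_matrix(dx); dy <- as_dist_matrix(dy); dz <- as_dist_matrix(dz)
  check_labels(dx, dy); check_labels(dx, dz)
  if (n_perm < 99) stop("n_perm must be at least 99")
  n <- nrow(dx)
  lt <- lower.tri(dx)
  vz <- dz[lt]
  resid_on <- function(v) {
    if (stats::sd(vz) < 1e-14) return(v - mean(v))
    stats::residuals(stats::lm.fit(cbind(1, vz), v))
  }
  rx <- resid_on(dx[lt])
  ry <- resid_on(dy[lt])
  if (stats::sd(rx) < 1e-14 || stats::sd(ry) < 1e-14) {
    warning("constant residual distances: partial Mantel r undefined")
    return(structure(data.frame(r = NA_real_, p = NA_real_, n_perm = n_perm,
                                partial = partial_label,
                                seed = if (is.null(seed)) NA_integer_ else seed),
                     class = c("mantel_result", "data.frame")))
  }
  r_obs <- stats::cor(rx, ry)
  if (!is.null(seed)) set.seed(seed)
  r_null <- vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    stats::cor(rx, resid_on(dy[p, p][lt]))
  }, 0)
  p <- (sum(r_null >= r_obs) + 1) / (n_perm + 1)
  structure(data.frame(r = r_obs, p = p, n_perm = n_perm,
                       partial = partial_label,
                       seed = if (is.null(seed)) NA_integer_ else seed),
            class = c("mantel_result", "data.frame"))
}

check_labels <- function(a, b) {
  if (!identical(rownames(a), rownames(b)))
    stop("distance matrices have mismatched labels")
}

#' Adjusted R-squared of a multivariate linear fit (RDA-style)
#'
#' Multivariate least squares of the (column-centered) response on the
#' predictors; `R2` is the explained proportion of the total trace and the
#' Ezekiel adjustment is `1 - (1 - R2)(n - 1)/(n - m - 1)` with `m` the
#' number of predictor columns.
#'
#' @param response site x axis score matrix (e.g. PCoA axes of a beta
#'   matrix).
#' @param predictors site x m numeric table.
#' @return list `r2`, `adj_r2`, `n`, `m`.
#' @export
rda_adj_r2 <- function(response, predictors) {
  Y <- scale(as.matrix(response), center = TRUE, scale = FALSE)
  X <- as.matrix(as.data.frame(predictors))
  n <- nrow(Y)
  m <- ncol(X)
  if (nrow(X) != n) stop("response and predictors disagree on sites")
  if (n - m - 1 <= 0) stop("saturated model: n - m - 1 <= 0")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), Y)
  fitted <- Y - fit$residuals
  r2 <- sum(fitted^2) / sum(Y^2)
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - m - 1), n = n, m = m)
}

#' Forward selection of predictors by adjusted R-squared
#'
#' Greedy addition of the candidate giving the largest adjusted-R2 gain,
#' with the double stopping rule: the added term must pass a permutation
#' test at `alpha` (Freedman-Lane residual permutation under the current
#' model), and the cumulative adjusted R2 may not exceed the global
#' (all-candidate) adjusted R2.
#'
#' @param response site x axis score matrix.
#' @param candidates data.frame of candidate predictor columns.
#' @param alpha significance level for entry.
#' @param n_perm permutations for the entry test.
#' @param seed RNG seed.
#' @return list `selected` (column names, possibly empty), `adj_r2`
#'   (cumulative after each addition), `p` (entry p-values),
#'   `global_adj_r2`.
#' @export
forward_select <- function(response, candidates, alpha = 0.05,
                           n_perm = 999, seed = NULL) {
  Y <- as.matrix(response)
  X <- as.data.frame(candidates)
  if (!is.null(seed)) set.seed(seed)
  global <- rda_adj_r2(Y, X)$adj_r2
  selected <- character(0)
  adj_path <- numeric(0)
  p_path <- numeric(0)
  current_adj <- 0
  repeat {
    # second stopping criterion: once the selected model explains as much
    # (adjusted) as the global model there is nothing non-redundant left
    if (current_adj >= global - 1e-12) break
    remaining <- setdiff(names(X), selected)
    if (length(remaining) == 0) break
    gains <- vapply(remaining, function(v) {
      rda_adj_r2(Y, X[, c(selected, v), drop = FALSE])$adj_r2
    }, 0)
    best <- names(gains)[which.max(gains)]
    best_adj <- gains[[best]]
    if (best_adj <= current_adj) break
    # Freedman-Lane: permute residuals of the current (reduced) model
    if (length(selected) > 0) {
      red <- stats::lm.fit(cbind(1, as.matrix(X[, selected, drop = FALSE])),
                           scale(Y, center = TRUE, scale = FALSE))
      res <- as.matrix(red$residuals)
      base_fit <- scale(Y, center = TRUE, scale = FALSE) - res
    } else {
      base_fit <- matrix(0, nrow(Y), ncol(Y))
      res <- scale(Y, center = TRUE, scale = FALSE)
    }
    stat_obs <- best_adj - current_adj
    stat_null <- vapply(seq_len(n_perm), function(b) {
      Yp <- base_fit + res[sample.int(nrow(Y)), , drop = FALSE]
      full <- rda_adj_r2(Yp, X[, c(selected, best), drop = FALSE])$adj_r2
      redr <- if (length(selected) > 0)
        rda_adj_r2(Yp, X[, selected, drop = FALSE])$adj_r2 else 0
      full - redr
    }, 0)
    p <- (sum(stat_null >= stat_obs) + 1) / (n_perm + 1)
    if (p > alpha) break
    selected <- c(selected, best)
    adj_path <- c(adj_path, best_adj)
    p_path <- c(p_path, p)
    current_adj <- best_adj
  }
  list(selected = selected, adj_r2 = adj_path, p = p_path,
       global_adj_r2 = global)
}

#' Variance partitioning of beta diversity over four predictor sets
#'
#' db-RDA-style partitioning: the response is the positive-eigenvalue
#' PCoA axes of the beta-dissimilarity matrix; adjusted R2 is computed
#' for all 15 non-empty unions of the predictor sets and the 15 Venn
#' fractions (unique, pairwise ... four-way joint) recovered by solving
#' the inclusion-exclusion system exactly.  Fractions may be slightly
#' negative (an adjusted-R2 artifact) and are reported as-is; the
#' residual is `1 - adjR2(all sets)`.
#'
#' @param beta_dist site-by-site beta dissimilarity matrix, or a
#'   precomputed score matrix (see `response_is_scores`).
#' @param sets named list of predictor tables (canonically `IGs`,
#'   `climate`, `soil`, `spatial`); empty/NULL sets are dropped with a
#'   warning.
#' @param response_is_scores set TRUE when `beta_dist` is already a
#'   site x axis score matrix.
#' @return a `varpart_result` list: `fractions` (data.frame with the
#'   Venn fraction per set combination), `unions` (adjusted R2 per
#'   union), `residual`, `set_labels`, `n_axes`.
#' @export
variance_partition <- function(beta_dist, sets, response_is_scores = FALSE) {
  sets <- Filter(function(s) !is.null(s) && NCOL(s) > 0, sets)
  if (length(sets) < 2) stop("need at least 2 non-empty predictor sets")
  if (length(sets) > 4) stop("at most 4 predictor sets supported")
  if (response_is_scores) {
    Y <- as.matrix(beta_dist)
  } else {
    ord <- pcoa_axes(beta_dist)
    Y <- ord$scores
  }
  labels <- names(sets)
  K <- length(sets)
  subsets <- lapply(seq_len(2^K - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
  })
  union_r2 <- vapply(subsets, function(ix) {
    X <- do.call(cbind, lapply(sets[ix], function(s) as.matrix(as.data.frame(s))))
    rda_adj_r2(Y, X)$adj_r2
  }, 0)
  union_names <- vapply(subsets, function(ix) paste(labels[ix], collapse = "+"), "")
  # region V (nonempty subset) contributes to union U iff V and U intersect
  M <- outer(seq_along(subsets), seq_along(subsets),
             Vectorize(function(u, v) {
               as.numeric(length(intersect(subsets[[u]], subsets[[v]])) > 0)
             }))
  fractions <- solve(M, union_r2)
  frac_names <- vapply(subsets, function(ix) paste(labels[ix], collapse = "&"), "")
  structure(list(
    fractions = data.frame(sets = frac_names,
                           n_sets = lengths(subsets),
                           fraction = fractions, stringsAsFactors = FALSE),
    unions = data.frame(union = union_names, adj_r2 = union_r2,
                        stringsAsFactors = FALSE),
    residual = 1 - union_r2[length(union_r2)],
    set_labels = labels,
    n_axes = ncol(Y)),
    class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("variance partitioning over", length(x$set_labels), "sets (",
      paste(x$set_labels, collapse = ", "), ")\n")
  uq <- x$fractions[x$fractions$n_sets == 1, ]
  for (i in seq_len(nrow(uq)))
    cat(sprintf("  unique %-10s %7.4f\n", uq$sets[i], uq$fraction[i]))
  cat(sprintf("  all joint fractions sum to %.4f; residual %.4f\n",
              sum(x$fractions$fraction), x$residual))
  invisible(x)
}
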