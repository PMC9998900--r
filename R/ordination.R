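#' Principal coordinates analysis of a distance matrix
#'
#' Classical PCoA: eigendecomposition of the double-centered matrix
#' \eqn{-\tfrac12 D^2}.  With `correction = "none"`, axes with eigenvalue
#' below tolerance are dropped and the count of negative eigenvalues is
#' reported; the Lingoes and Cailliez corrections (via [ape::pcoa()]) make
#' the matrix fully Euclidean first.
#'
#' @param d distance matrix (square, labelled).
#' @param correction `"none"`, `"lingoes"` or `"cailliez"`.
#' @param tol eigenvalue tolerance relative to the largest eigenvalue.
#' @return an `ordination` list: `scores` (objects x axes, scaled by
#'   sqrt(eigenvalue)), `eigenvalues` (all, decreasing), `proportion`
#'   (of the positive eigenvalue total), `n_negative`, `method = "pcoa"`.
#' @export
pcoa_axes <- function(d, correction = c("none", "lingoes", "cailliez"),
                      tol = 1e-8) {
  correction <- match.arg(correction)
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (n < 2) stop("PCoA needs at least 2 objects")
  if (correction != "none") {
    res <- ape::pcoa(stats::as.dist(d), correction = correction)
    vec <- if (!is.null(res$vectors.cor)) res$vectors.cor else res$vectors
    val <- if (!is.null(res$values$Corr_eig)) res$values$Corr_eig else res$values$Eigenvalues
    scores <- vec
    rownames(scores) <- rownames(d)
    eig <- val
  } else {
    a <- -0.5 * d^2
    rc <- rowMeans(a)
    g <- a - outer(rc, rep(1, n)) - outer(rep(1, n), rc) + mean(a)
    e <- eigen(g, symmetric = TRUE)
    eig <- e$values
    pos <- eig > tol * max(abs(eig))
    scores <- e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(eig[pos]), sum(pos))
    rownames(scores) <- rownames(d)
  }
  keep <- seq_len(ncol(scores))
  colnames(scores) <- paste0("PCo", keep)
  pos_eig <- eig[eig > 0]
  structure(list(scores = scores,
                 eigenvalues = eig,
                 proportion = if (length(pos_eig)) eig[keep] / sum(pos_eig) else numeric(0),
                 n_negative = sum(eig < -tol * max(abs(eig))),
                 method = "pcoa", correction = correction),
            class = "ordination")
}

#' UPGMA dendrogram of a species distance matrix
#'
#' Average-linkage agglomeration with a deterministic tie-break: when two
#' merges have equal (within 1e-12) minimum distance, the pair whose
#' smallest member labels sort first lexicographically is merged.  The
#' result is an ultrametric rooted tree whose cophenetic distances equal
#' the merge heights; it serves as the functional dendrogram for
#' branch-length-based functional beta diversity.
#'
#' @param d species distance matrix.
#' @return an ultrametric `phylo`.
#' @export
upgma_dendrogram <- function(d) {
  d <- as_dist_matrix(d)
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 species")
  # active clusters: newick fragment, size, height, min member label
  frag <- labels
  size <- rep(1, n)
  height <- rep(0, n)
  minlab <- labels
  dm <- d
  active <- seq_len(n)
  while (length(active) > 1) {
    sub <- dm[active, active, drop = FALSE]
    ut <- upper.tri(sub)
    best <- min(sub[ut])
    cand <- which(ut & sub <= best + 1e-12, arr.ind = TRUE)
    # tie-break: lexicographically smallest (sorted) pair of min member labels
    key <- apply(cand, 1, function(rc) {
      paste(sort(c(minlab[active[rc[1]]], minlab[active[rc[2]]])),
            collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    bi <- active[pick[1]]; bj <- active[pick[2]]
    h <- best / 2
    # order children lexicographically for a canonical newick
    ch <- c(bi, bj)[order(c(minlab[bi], minlab[bj]))]
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)",
                       frag[ch[1]], h - height[ch[1]],
                       frag[ch[2]], h - height[ch[2]])
    # UPGMA update: average weighted by cluster size
    rest <- setdiff(active, c(bi, bj))
    newrow <- (size[bi] * dm[bi, rest] + size[bj] * dm[bj, rest]) /
      (size[bi] + size[bj])
    k <- bi  # reuse slot bi for the merged cluster
    dm[k, rest] <- newrow
    dm[rest, k] <- newrow
    frag[k] <- newfrag
    size[k] <- size[bi] + size[bj]
    height[k] <- h
    minlab[k] <- min(minlab[bi], minlab[bj])
    active <- c(rest, k)
  }
  tr <- ape::read.tree(text = paste0(frag[active], ";"))
  validate_tree(tr)
}
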