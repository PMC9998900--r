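#' Shared/unique species counts for a site pair
#'
#' @param site_i,site_j logical or 0/1 presence vectors over the same
#'   species set.
#' @return numeric triple `(a, b, c)`: shared, unique to i, unique to j.
#' @export
abc_counts <- function(site_i, site_j) {
  pi <- site_i > 0
  pj <- site_j > 0
  c(a = sum(pi & pj), b = sum(pi & !pj), c = sum(!pi & pj))
}

#' Sorensen-family pairwise partition into turnover and nestedness
#'
#' Baselga decomposition on a shared/unique triple (counts, branch lengths
#' or functional units): total dissimilarity
#' `sor = (b+c)/(2a+b+c)`, turnover `sim = min(b,c)/(a+min(b,c))`,
#' nestedness-resultant `sne = sor - sim`.
#'
#' @param a,b,c shared and unique components (non-negative; `a+b+c > 0`).
#' @return named vector `(sor, sim, sne)`.
#' @export
pairwise_partition <- function(a, b, c) {
  a <- unname(a); b <- unname(b); c <- unname(c)
  if (a + b + c <= 0) stop("undefined partition: both sites empty")
  sor <- (b + c) / (2 * a + b + c)
  m <- min(b, c)
  sim <- if (a + m > 0) m / (a + m) else 0
  c(sor = sor, sim = sim, sne = sor - sim)
}

# Site x edge weighted presence: P[s, e] = TRUE if site s has a tip below
# edge e.  Shared branch length between two sites is then a sum over edges.
site_edge_presence <- function(tree, comm) {
  inc <- edge_tip_incidence(tree)            # edges x tips
  C <- (unclass(comm) > 0) * 1
  sp <- colnames(C)
  P <- tcrossprod(C, inc[, sp, drop = FALSE] * 1) > 0   # sites x edges
  P
}

#' Shared and unique branch lengths for a site pair
#'
#' Branch-length analogue of [abc_counts()]: `a` is the branch length
#' common to both communities' root-inclusive spanning subtrees, `b`/`c`
#' the length unique to each, so `a + b` equals Faith's PD of site i.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param site_i,site_j presence vectors named by species, or character
#'   vectors of species present.
#' @return named triple `(a, b, c)` in branch-length units.
#' @export
shared_branch_abc <- function(tree, site_i, site_j) {
  as_species <- function(s) {
    if (is.character(s)) s else names(s)[s > 0]
  }
  inc <- edge_tip_incidence(tree)
  pi <- rowSums(inc[, as_species(site_i), drop = FALSE]) > 0
  pj <- rowSums(inc[, as_species(site_j), drop = FALSE]) > 0
  len <- tree$edge.length
  c(a = sum(len[pi & pj]), b = sum(len[pi & !pj]), c = sum(len[!pi & pj]))
}

#' Functional shared/unique components for a site pair
#'
#' Dendrogram mode (default) measures shared vs unique branch length on a
#' functional dendrogram (UPGMA of Gower distances) exactly as
#' [shared_branch_abc()].  Hull mode measures shared vs unique convex-hull
#' area of the two communities in the first `k = 2` PCoA axes of the trait
#' space; each site then needs at least `k + 1` species.
#'
#' @param x in dendrogram mode the functional dendrogram (`phylo`); in
#'   hull mode the species scores matrix (species x >= k axes).
#' @param site_i,site_j species presence (see [shared_branch_abc()]).
#' @param mode `"dendrogram"` or `"hull"`.
#' @param k hull dimensionality (only 2 supported).
#' @return named triple `(a, b, c)`.
#' @export
functional_abc <- function(x, site_i, site_j,
                           mode = c("dendrogram", "hull"), k = 2) {
  mode <- match.arg(mode)
  if (mode == "dendrogram") return(shared_branch_abc(x, site_i, site_j))
  if (k != 2)
    stop("hull mode supports k = 2 axes; use dendrogram mode for ",
         "higher-dimensional trait spaces")
  as_species <- function(s) if (is.character(s)) s else names(s)[s > 0]
  si <- as_species(site_i); sj <- as_species(site_j)
  if (length(si) < k + 1 || length(sj) < k + 1)
    stop("hull mode needs at least k+1 = ", k + 1, " species per site; ",
         "use dendrogram mode")
  hull_i <- x[si, 1:k, drop = FALSE][grDevices::chull(x[si, 1:k]), , drop = FALSE]
  hull_j <- x[sj, 1:k, drop = FALSE][grDevices::chull(x[sj, 1:k]), , drop = FALSE]
  ai <- polygon_area(hull_i)
  aj <- polygon_area(hull_j)
  ax <- polygon_area(convex_clip(hull_i, hull_j))
  c(a = ax, b = ai - ax, c = aj - ax)
}

# Shoelace area of a polygon given as vertex matrix (counter-ordered ok).
polygon_area <- function(v) {
  if (is.null(v) || nrow(v) < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clipping of convex polygon `subject` by convex `clip`.
# Both as vertex matrices in hull (counterclockwise or clockwise) order.
convex_clip <- function(subject, clip) {
  # ensure counterclockwise order for the clip polygon
  orient <- function(v) {
    s <- sum(v[, 1] * c(v[-1, 2], v[1, 2]) - c(v[-1, 1], v[1, 1]) * v[, 2])
    if (s < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v
  }
  clip <- orient(clip)
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    A <- clip[i, ]; B <- clip[if (i == nc) 1 else i + 1, ]
    inside <- function(p) {
      (B[1] - A[1]) * (p[2] - A[2]) - (B[2] - A[2]) * (p[1] - A[1]) >= -1e-12
    }
    isect <- function(p, q) {
      dc <- A - B; dp <- p - q
      n1 <- A[1] * B[2] - A[2] * B[1]
      n2 <- p[1] * q[2] - p[2] * q[1]
      den <- dc[1] * dp[2] - dc[2] * dp[1]
      c(n1 * dp[1] - n2 * dc[1], n1 * dp[2] - n2 * dc[2]) / den
    }
    res <- NULL
    n <- nrow(out)
    for (j in seq_len(n)) {
      p <- out[j, ]; q <- out[if (j == n) 1 else j + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (qin) {
        if (!pin) res <- rbind(res, isect(p, q))
        res <- rbind(res, q)
      } else if (pin) {
        res <- rbind(res, isect(p, q))
      }
    }
    out <- res
  }
  out
}

#' Pairwise beta-diversity partition over all site pairs
#'
#' Computes the Sorensen-family `sor`/`sim`/`sne` matrices in one of the
#' three dimensions.  Taxonomic uses species counts; phylogenetic uses
#' shared branch lengths on the phylogeny; functional uses the functional
#' dendrogram (or convex hulls, see [functional_abc()]).
#'
#' @param comm a `community_matrix` (presence; abundance is reduced to
#'   presence).
#' @param dimension `"taxonomic"`, `"phylogenetic"` or `"functional"`.
#' @param tree phylogeny (phylogenetic) or functional dendrogram
#'   (functional, dendrogram mode).
#' @param scores species PCoA scores (functional hull mode).
#' @param mode functional mode, `"dendrogram"` or `"hull"`.
#' @return a `beta_pairwise` list with `sor`, `sim`, `sne` site-by-site
#'   matrices, the `dimension` and the functional `mode` used.
#' @export
beta_pairwise <- function(comm, dimension = c("taxonomic", "phylogenetic",
                                              "functional"),
                          tree = NULL, scores = NULL,
                          mode = c("dendrogram", "hull")) {
  dimension <- match.arg(dimension)
  mode <- match.arg(mode)
  C <- (unclass(comm) > 0) * 1
  if (any(rowSums(C) == 0)) stop("empty site in community matrix")
  n <- nrow(C)
  sites <- rownames(C)
  tri <- abc_pair_table(C, dimension, tree, scores, mode)
  sor <- sim <- sne <- matrix(0, n, n, dimnames = list(sites, sites))
  for (r in seq_len(nrow(tri$pairs))) {
    i <- tri$pairs[r, 1]; j <- tri$pairs[r, 2]
    p <- pairwise_partition(tri$a[r], tri$b[r], tri$c[r])
    sor[i, j] <- sor[j, i] <- p["sor"]
    sim[i, j] <- sim[j, i] <- p["sim"]
    sne[i, j] <- sne[j, i] <- p["sne"]
  }
  structure(list(sor = sor, sim = sim, sne = sne, dimension = dimension,
                 mode = if (dimension == "functional") mode else NA),
            class = "beta_pairwise")
}

# All-pairs (a, b, c) triples for one dimension; vectorized via the
# site x unit presence matrix (units = species, edges, or hull handled
# pairwise).
abc_pair_table <- function(C, dimension, tree, scores, mode) {
  n <- nrow(C)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (dimension == "taxonomic") {
    P <- C
    w <- rep(1, ncol(C))
  } else if (dimension == "phylogenetic" ||
             (dimension == "functional" && mode == "dendrogram")) {
    if (is.null(tree)) stop(dimension, " partition requires a tree")
    if (!all(colnames(C) %in% tree$tip.label))
      stop("species absent from tree")
    P <- site_edge_presence(tree, C)
    w <- tree$edge.length
  } else {
    if (is.null(scores)) stop("hull mode requires species scores")
    a <- b <- cc <- numeric(nrow(pairs))
    pres <- lapply(seq_len(n), function(i) colnames(C)[C[i, ] > 0])
    for (r in seq_len(nrow(pairs))) {
      t3 <- functional_abc(scores, pres[[pairs[r, 1]]], pres[[pairs[r, 2]]],
                           mode = "hull")
      a[r] <- t3["a"]; b[r] <- t3["b"]; cc[r] <- t3["c"]
    }
    return(list(pairs = pairs, a = a, b = b, c = cc))
  }
  Pw <- P * rep(w, each = n)        # weighted presence (site x unit)
  tot <- rowSums(Pw)                # PD / richness per site
  Ash <- Pw %*% t(P > 0)            # shared weight, asymmetric-safe:
  # for binary weights P coincide; for edges both sites' presence patterns
  # are 0/1 over the same units so shared = sum w over jointly present
  a <- Ash[pairs]
  b <- tot[pairs[, 1]] - a
  cc <- tot[pairs[, 2]] - a
  list(pairs = pairs, a = a, b = b, c = cc)
}

#' Multiple-site beta-diversity partition
#'
#' Baselga's multiple-site Sorensen-family decomposition.  With per-site
#' totals \eqn{S_i} (species counts, Faith's PD, or functional units),
#' pooled total \eqn{S_T} and unique components \eqn{b_{ij}} of site i
#' relative to j:
#' \deqn{SIM = \frac{\sum \min(b_{ij}, b_{ji})}{\sum \min + (\sum S_i - S_T)}}
#' \deqn{SOR = \frac{\sum \min + \sum \max}{2(\sum S_i - S_T) + \sum \min + \sum \max}}
#' and `SNE = SOR - SIM`.  Also reports turnover and nestedness
#' percentages of SOR, plus the mean of the pairwise `sor` values
#' (an alternative "overall beta" convention).
#'
#' @inheritParams beta_pairwise
#' @return a `beta_multisite` list: `SOR`, `SIM`, `SNE`, `turnover_pct`,
#'   `nestedness_pct`, `mean_pairwise_sor`, `n_sites`, `dimension`.
#' @export
beta_multisite <- function(comm, dimension = c("taxonomic", "phylogenetic",
                                               "functional"),
                           tree = NULL, scores = NULL,
                           mode = c("dendrogram", "hull")) {
  dimension <- match.arg(dimension)
  mode <- match.arg(mode)
  C <- (unclass(comm) > 0) * 1
  if (nrow(C) < 2) stop("multi-site partition needs at least 2 sites")
  if (any(rowSums(C) == 0)) stop("empty site in community matrix")
  if (dimension == "functional" && mode == "hull")
    stop("multi-site partition is defined for dendrogram mode only")
  n <- nrow(C)
  if (dimension == "taxonomic") {
    P <- C
    w <- rep(1, ncol(C))
  } else {
    if (is.null(tree)) stop(dimension, " partition requires a tree")
    P <- site_edge_presence(tree, C)
    w <- tree$edge.length
  }
  Pw <- (P > 0) * rep(w, each = n)
  tot <- rowSums(Pw)                      # S_i (or PD_i)
  ST <- sum(w[colSums(P > 0) > 0])        # pooled total
  Ash <- Pw %*% t(P > 0)                  # shared weight per pair
  pairs <- which(upper.tri(Ash), arr.ind = TRUE)
  bij <- tot[pairs[, 1]] - Ash[pairs]
  bji <- tot[pairs[, 2]] - Ash[pairs]
  smin <- sum(pmin(bij, bji))
  smax <- sum(pmax(bij, bji))
  core <- sum(tot) - ST
  SIM <- if (smin + core > 0) smin / (smin + core) else 0
  SOR <- if (smin + smax + 2 * core > 0)
    (smin + smax) / (2 * core + smin + smax) else 0
  SNE <- SOR - SIM
  pair_sor <- (bij + bji) / (2 * Ash[pairs] + bij + bji)
  structure(list(SOR = SOR, SIM = SIM, SNE = SNE,
                 turnover_pct = if (SOR > 0) 100 * SIM / SOR else NA_real_,
                 nestedness_pct = if (SOR > 0) 100 * SNE / SOR else NA_real_,
                 mean_pairwise_sor = mean(pair_sor),
                 n_sites = n, dimension = dimension),
            class = "beta_multisite")
}

#' @export
print.beta_multisite <- function(x, ...) {
  cat(sprintf("%s multi-site beta: SOR %.4f = SIM %.4f + SNE %.4f\n",
              x$dimension, x$SOR, x$SIM, x$SNE))
  cat(sprintf("  turnover %.2f%%, nestedness %.2f%% (n = %d sites); ",
              x$turnover_pct, x$nestedness_pct, x$n_sites))
  cat(sprintf("mean pairwise sor %.4f\n", x$mean_pairwise_sor))
  invisible(x)
}

#' Beta diversity in all three dimensions for a bundle
#'
#' Pairwise and multi-site partitions in the taxonomic, phylogenetic and
#' functional dimensions.  Functional structure uses the UPGMA dendrogram
#' of the Gower trait distances by default.
#'
#' @param bundle a `div_bundle` with traits and tree.
#' @param functional_mode `"dendrogram"` or `"hull"` (pairwise only).
#' @param k hull axes (see [functional_abc()]).
#' @return list with elements `taxonomic`, `phylogenetic`, `functional`,
#'   each containing `pairwise` ([beta_pairwise()]) and `multisite`
#'   ([beta_multisite()]; for hull mode the multisite entry uses the
#'   dendrogram).
#' @export
beta_pipeline <- function(bundle, functional_mode = c("dendrogram", "hull"),
                          k = 2) {
  functional_mode <- match.arg(functional_mode)
  stopifnot(inherits(bundle, "div_bundle"))
  comm <- bundle$community
  dendro <- upgma_dendrogram(gower_distance(bundle$traits))
  out <- list(
    taxonomic = list(
      pairwise = beta_pairwise(comm, "taxonomic"),
      multisite = beta_multisite(comm, "taxonomic")),
    phylogenetic = list(
      pairwise = beta_pairwise(comm, "phylogenetic", tree = bundle$tree),
      multisite = beta_multisite(comm, "phylogenetic", tree = bundle$tree))
  )
  if (functional_mode == "hull") {
    sc <- pcoa_axes(gower_distance(bundle$traits))$scores
    out$functional <- list(
      pairwise = beta_pairwise(comm, "functional", scores = sc, mode = "hull"),
      multisite = beta_multisite(comm, "functional", tree = dendro))
  } else {
    out$functional <- list(
      pairwise = beta_pairwise(comm, "functional", tree = dendro),
      multisite = beta_multisite(comm, "functional", tree = dendro))
  }
  out
}
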