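#' Rao quadratic entropy
#'
#' \eqn{Q = \sum_i \sum_j d_{ij} p_i p_j} over all ordered species pairs,
#' with \eqn{p} the relative abundances (the input vector is renormalized
#' to sum to 1, so Q is invariant to abundance rescaling).  In taxonomic
#' mode every between-species distance is 1, which makes Q the
#' Gini-Simpson index \eqn{1 - \sum_i p_i^2}.
#'
#' @param abundances named non-negative abundance vector over the species
#'   present.
#' @param dist species distance matrix covering those species; `NULL`
#'   selects taxonomic mode (`d_ij = 1` for `i != j`).
#' @return Rao's Q (scalar).
#' @export
rao_q <- function(abundances, dist = NULL) {
  if (all(abundances == 0)) stop("all-zero abundance vector")
  if (any(abundances < 0)) stop("negative abundance")
  p <- abundances / sum(abundances)
  if (is.null(dist)) return(1 - sum(p^2))
  d <- as_dist_matrix(dist)
  if (!is.null(names(p))) {
    if (!all(names(p) %in% rownames(d)))
      stop("species missing from distance matrix")
    d <- d[names(p), names(p), drop = FALSE]
  } else if (length(p) != nrow(d)) {
    stop("abundance vector and distance matrix disagree")
  }
  drop(crossprod(p, d %*% p))
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the subtree spanning the species present.
#' By default the path to the root is included (the common default in
#' community-phylogenetics software); `include_root = FALSE` restricts to
#' the subtree below the most recent common ancestor, in which case a
#' single-species community has PD 0.
#'
#' @param species character vector of species present (tip labels).
#' @param tree a `phylo` with branch lengths.
#' @param include_root include the root path (default TRUE).
#' @param incidence optional precomputed [edge x tip] incidence
#'   (internal use; must match `tree`).
#' @return Faith's PD.
#' @export
faith_pd <- function(species, tree, include_root = TRUE, incidence = NULL) {
  if (length(species) == 0) stop("at least one species required")
  if (!all(species %in% tree$tip.label))
    stop("species absent from tree: ",
         paste(setdiff(species, tree$tip.label), collapse = ", "))
  if (is.null(incidence)) incidence <- edge_tip_incidence(tree)
  counts <- rowSums(incidence[, species, drop = FALSE])
  if (include_root) {
    sum(tree$edge.length[counts > 0])
  } else {
    k <- length(species)
    sum(tree$edge.length[counts > 0 & counts < k])
  }
}

#' Mean pairwise distance among co-occurring species
#'
#' Unweighted (presence-based): the mean of the distinct pairwise
#' distances.  Returns `NA` for fewer than 2 species.
#'
#' @param species species present.
#' @param dist species distance matrix (cophenetic or trait-based).
#' @return MPD, or `NA_real_` if fewer than two species.
#' @export
mpd <- function(species, dist) {
  if (length(species) < 2) return(NA_real_)
  d <- dist[species, species, drop = FALSE]
  mean(d[upper.tri(d)])
}

#' Mean nearest taxon distance among co-occurring species
#'
#' Mean over species of the distance to their nearest co-occurring
#' neighbour.  Returns `NA` for fewer than 2 species.
#'
#' @inheritParams mpd
#' @return MNTD, or `NA_real_` if fewer than two species.
#' @export
mntd <- function(species, dist) {
  if (length(species) < 2) return(NA_real_)
  d <- dist[species, species, drop = FALSE]
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Per-site alpha diversity in three dimensions
#'
#' One row per site: taxonomic Rao Q (`raoq_td`), functional Rao Q on
#' Gower distances (`raoq_fd`), Faith's PD, and MPD/MNTD on the
#' phylogenetic (cophenetic) and functional (Gower) distances.  Abundance
#' mode uses the row abundances as weights for Rao Q; presence mode
#' implies equal weights.  MPD/MNTD are unweighted in both modes.
#'
#' @param bundle a [validate_bundle()] result with traits and tree.
#' @param include_root Faith's PD root convention (see [faith_pd()]).
#' @return data.frame (`alpha_table`) with columns `site`, `richness`,
#'   `raoq_td`, `raoq_fd`, `faith_pd`, `mpd_phylo`, `mntd_phylo`,
#'   `mpd_func`, `mntd_func`.
#' @export
alpha_pipeline <- function(bundle, include_root = TRUE) {
  stopifnot(inherits(bundle, "div_bundle"))
  if (is.null(bundle$traits) || is.null(bundle$tree))
    stop("bundle must carry traits and a tree")
  comm <- bundle$community
  gd <- gower_distance(bundle$traits)
  pdist <- as_dist_matrix(stats::cophenetic(bundle$tree))
  ord <- colnames(comm)
  gd <- gd[ord, ord]
  pdist <- pdist[ord, ord]
  inc <- edge_tip_incidence(bundle$tree)
  res <- lapply(rownames(comm), function(s) {
    row <- comm[s, ]
    sp <- names(row)[row > 0]
    ab <- row[row > 0]
    if (attr(comm, "mode_flag") == "presence") ab <- rep(1, length(sp))
    data.frame(site = s, richness = length(sp),
               raoq_td = rao_q(ab),
               raoq_fd = rao_q(stats::setNames(ab, sp), gd),
               faith_pd = faith_pd(sp, bundle$tree, include_root, inc),
               mpd_phylo = mpd(sp, pdist), mntd_phylo = mntd(sp, pdist),
               mpd_func = mpd(sp, gd), mntd_func = mntd(sp, gd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "abundance_mode") <- attr(comm, "mode_flag")
  attr(out, "include_root") <- include_root
  class(out) <- c("alpha_table", "data.frame")
  out
}
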