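#' Read a rooted phylogeny with branch lengths
#'
#' Wraps [ape::read.tree()] and enforces the invariants the diversity
#' metrics need: branch lengths on every edge, all lengths non-negative,
#' unique tip labels.  Unrooted or root-multifurcating trees are accepted
#' but flagged (attribute `rooted_flag`), since shared-branch beta metrics
#' and Faith's PD use a root convention.
#'
#' @param path Newick file path.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick tree from ", path)
  validate_tree(tr)
}

#' Validate a phylo object for use in diversity metrics
#' @param tr a `phylo` object.
#' @return the tree, with attribute `rooted_flag`.
#' @export
validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (is.null(tr$edge.length))
    stop("branch lengths required")
  if (anyNA(tr$edge.length)) stop("branch lengths required on every edge")
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr$tip.label <- trimws(tr$tip.label)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip label")
  attr(tr, "rooted_flag") <- ape::is.rooted(tr)
  tr
}

#' Total branch length of a tree
#' @param tr a `phylo` object.
#' @return sum of all edge lengths.
#' @export
total_branch_length <- function(tr) sum(tr$edge.length)

# Edge x tip incidence: inc[e, s] is TRUE when tip s descends from edge e.
# Single post-order pass; the root path above any present tip is exactly the
# set of edges whose incidence row covers it, so Faith's PD and shared-branch
# counts reduce to sums over this matrix.
edge_tip_incidence <- function(tr) {
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  inc <- matrix(FALSE, nrow = nrow(tr$edge), ncol = ntip,
                dimnames = list(NULL, tr$tip.label))
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  ord <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]
    child <- ord$edge[k, 2]
    if (is.null(below[[parent]])) below[[parent]] <- integer(0)
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  for (e in seq_len(nrow(tr$edge))) {
    inc[e, below[[tr$edge[e, 2]]]] <- TRUE
  }
  inc
}
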