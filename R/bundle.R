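#' Reconcile community, traits, tree, environment and coordinates
#'
#' Cross-dataset validation: the species sets of community/traits/tree and
#' the site sets of community/env/coords must agree.  Matching is by exact
#' label after whitespace trimming (no fuzzy matching).  With
#' `policy = "drop"` each dataset is restricted to the common species/site
#' intersection and the tree pruned accordingly; the reconciliation report
#' counts what was dropped from each source.  With `policy = "error"` any
#' mismatch is fatal.
#'
#' @param community a [community_matrix()].
#' @param traits a [trait_table()], or NULL.
#' @param tree a `phylo`, or NULL.
#' @param env site environment data.frame, or NULL.
#' @param coords site coordinates data.frame, or NULL.
#' @param policy `"error"` or `"drop"`.
#' @return a `div_bundle` list: `community`, `traits`, `tree`, `env`,
#'   `coords`, `species`, `sites`, `report` (drop counts per source).
#' @export
validate_bundle <- function(community, traits = NULL, tree = NULL,
                            env = NULL, coords = NULL,
                            policy = c("error", "drop")) {
  policy <- match.arg(policy)
  stopifnot(inherits(community, "community_matrix"))
  sp_sets <- list(community = colnames(community))
  if (!is.null(traits)) sp_sets$traits <- rownames(traits)
  if (!is.null(tree)) sp_sets$tree <- tree$tip.label
  species <- Reduce(intersect, sp_sets)
  if (length(species) == 0) stop("no common species")

  site_sets <- list(community = rownames(community))
  if (!is.null(env)) site_sets$env <- rownames(env)
  if (!is.null(coords)) site_sets$coords <- rownames(coords)
  sites <- Reduce(intersect, site_sets)
  if (length(sites) == 0) stop("no common sites")

  report <- list(
    species_dropped = vapply(sp_sets, function(s) length(setdiff(s, species)), 0L),
    sites_dropped = vapply(site_sets, function(s) length(setdiff(s, sites)), 0L)
  )
  if (policy == "error" &&
      (any(report$species_dropped > 0) || any(report$sites_dropped > 0)))
    stop("datasets disagree on species or sites (policy = 'error'); ",
         "species dropped: ",
         paste(names(report$species_dropped), report$species_dropped,
               sep = "=", collapse = " "),
         "; sites dropped: ",
         paste(names(report$sites_dropped), report$sites_dropped,
               sep = "=", collapse = " "))

  # keep original orderings for determinism
  species <- sp_sets$community[sp_sets$community %in% species]
  sites <- site_sets$community[site_sets$community %in% sites]

  comm <- community[sites, species, drop = FALSE]
  comm <- community_matrix(comm, mode = attr(community, "mode_flag"))
  if (!is.null(traits)) {
    kinds <- trait_kinds(traits)
    traits <- trait_table(as.data.frame(traits)[species, , drop = FALSE], kinds)
  }
  if (!is.null(tree) && length(setdiff(tree$tip.label, species)) > 0) {
    tree <- ape::keep.tip(tree, species)
    tree <- validate_tree(tree)
  }
  if (!is.null(env)) env <- env[rownames(comm), , drop = FALSE]
  if (!is.null(coords)) {
    crs <- attr(coords, "crs_flag")
    coords <- coords[rownames(comm), , drop = FALSE]
    attr(coords, "crs_flag") <- crs
  }
  structure(list(community = comm, traits = traits, tree = tree,
                 env = env, coords = coords,
                 species = colnames(comm), sites = rownames(comm),
                 report = report),
            class = "div_bundle")
}

#' @export
print.div_bundle <- function(x, ...) {
  cat(sprintf("diversity data bundle: %d sites, %d species\n",
              length(x$sites), length(x$species)))
  cat("  components:",
      paste(names(Filter(Negate(is.null),
                         x[c("traits", "tree", "env", "coords")])),
            collapse = ", "), "\n")
  drops <- c(x$report$species_dropped, x$report$sites_dropped)
  if (any(drops > 0)) cat("  reconciliation dropped:",
                          paste(names(drops)[drops > 0], drops[drops > 0],
                                sep = "=", collapse = " "), "\n")
  invisible(x)
}
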