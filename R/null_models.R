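#' Shuffle species identities on a distance matrix
#'
#' The taxa-label null model: one random permutation of the species labels
#' is applied jointly to rows and columns, so the multiset of off-diagonal
#' distances is conserved while species identities are randomized.  The
#' occurrence matrix stays fixed, which preserves observed richness at
#' every site.
#'
#' @param dist species distance matrix.
#' @param perm optional integer permutation (defaults to a random draw
#'   from the current RNG state).
#' @return permuted distance matrix with the original labels.
#' @export
shuffle_labels <- function(dist, perm = NULL) {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  if (is.null(perm)) perm <- sample.int(n)
  out <- d[perm, perm, drop = FALSE]
  dimnames(out) <- dimnames(d)
  out
}

# Vectorized per-site MPD for a binary occurrence matrix C (sites x species)
# against distance matrix D: sum over ordered pairs via (C D) * C.
mpd_all <- function(C, D, k = rowSums(C)) {
  s <- rowSums((C %*% D) * C)
  out <- s / (k * (k - 1))
  out[k < 2] <- NA_real_
  out
}

# Per-site MNTD; idx is a list of species index vectors per site.
mntd_all <- function(D, idx) {
  vapply(idx, function(i) {
    if (length(i) < 2) return(NA_real_)
    d <- D[i, i, drop = FALSE]
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }, 0)
}

#' Standardized effect sizes of MPD/MNTD under the taxa-label null
#'
#' For each site, `ses = (obs - mean_null) / sd_null` where the null
#' distribution comes from `n_null` shuffles of species identities on the
#' distance matrix ([shuffle_labels()]); richness is preserved because the
#' occurrence matrix never changes.  Negative SES indicates clustering
#' (co-occurring species closer than expected), positive SES
#' overdispersion.  By default a single shared permutation is used per
#' null replicate across all sites, so site SES values are comparable
#' within a replicate; `shared_null = FALSE` draws independent
#' permutations per site.
#'
#' @param bundle a `div_bundle` (with tree for `dimension = "phylo"`,
#'   traits for `"func"`), or a `community_matrix` when `dist` is given.
#' @param metric `"mpd"` or `"mntd"`.
#' @param dimension `"phylo"` (cophenetic distances) or `"func"` (Gower).
#' @param n_null number of null replicates (default 1000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param dist species distance matrix overriding `dimension`.
#' @param shared_null share one permutation per replicate across sites.
#' @return data.frame (`ses_table`): `site`, `metric`, `dimension`, `obs`,
#'   `null_mean`, `null_sd`, `ses`, `p_rank` ((r+1)/(n+1) proportion of
#'   null <= obs), `n_null`, `seed`, `degenerate`.  Sites with fewer than
#'   2 species are skipped.
#' @export
ses_diversity <- function(bundle, metric = c("mpd", "mntd"),
                          dimension = c("phylo", "func"),
                          n_null = 1000, seed = NULL, dist = NULL,
                          shared_null = TRUE) {
  metric <- match.arg(metric)
  dimension <- match.arg(dimension)
  if (inherits(bundle, "div_bundle")) {
    comm <- bundle$community
    if (is.null(dist)) {
      dist <- switch(dimension,
        phylo = as_dist_matrix(stats::cophenetic(bundle$tree)),
        func = gower_distance(bundle$traits))
    }
  } else {
    comm <- bundle
    if (is.null(dist)) stop("dist required when no bundle is given")
    dist <- as_dist_matrix(dist)
  }
  sp <- colnames(comm)
  D <- dist[sp, sp]
  C <- (unclass(comm) > 0) * 1
  k <- rowSums(C)
  keep <- k >= 2
  idx <- apply(C, 1, function(r) which(r > 0), simplify = FALSE)
  obs <- if (metric == "mpd") mpd_all(C, D, k) else mntd_all(D, idx)
  if (!is.null(seed)) set.seed(seed)
  n_site <- nrow(C)
  S <- ncol(C)
  nulls <- matrix(NA_real_, n_null, n_site)
  for (b in seq_len(n_null)) {
    if (shared_null) {
      Dp <- shuffle_labels_raw(D, sample.int(S))
      nulls[b, ] <- if (metric == "mpd") mpd_all(C, Dp, k) else mntd_all(Dp, idx)
    } else {
      nulls[b, ] <- vapply(seq_len(n_site), function(s) {
        if (k[s] < 2) return(NA_real_)
        Dp <- shuffle_labels_raw(D, sample.int(S))
        if (metric == "mpd") {
          d <- Dp[idx[[s]], idx[[s]]]
          mean(d[upper.tri(d)])
        } else {
          d <- Dp[idx[[s]], idx[[s]]]
          diag(d) <- Inf
          mean(apply(d, 1, min))
        }
      }, 0)
    }
  }
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, stats::sd)
  degenerate <- keep & (null_sd < 1e-12)
  ses <- (obs - null_mean) / null_sd
  ses[degenerate | !keep] <- NA_real_
  p_rank <- vapply(seq_len(n_site), function(s) {
    if (!keep[s]) return(NA_real_)
    (sum(nulls[, s] <= obs[s]) + 1) / (n_null + 1)
  }, 0)
  out <- data.frame(site = rownames(C), metric = metric,
                    dimension = dimension, obs = obs,
                    null_mean = null_mean, null_sd = null_sd, ses = ses,
                    p_rank = p_rank, n_null = n_null,
                    seed = if (is.null(seed)) NA_integer_ else seed,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- rownames(C)[!keep]
  attr(out, "shared_null") <- shared_null
  class(out) <- c("ses_table", "data.frame")
  out
}

# permutation without re-validation (hot loop)
shuffle_labels_raw <- function(D, perm) {
  out <- D[perm, perm, drop = FALSE]
  dimnames(out) <- dimnames(D)
  out
}

#' Classify community structure from SES values by zone
#'
#' Counts and proportions per zone and metric of clustered (`ses < 0`),
#' overdispersed (`ses > 0`), significantly clustered (`ses < -threshold`)
#' and significantly overdispersed (`ses > threshold`) communities.  The
#' default threshold 1.96 marks significant deviation from the null at
#' the two-sided 5% level.
#'
#' @param ses_table a `ses_table` (or rbind of several).
#' @param zones data.frame with columns `site` and `zone`, or a named
#'   vector of zone labels.
#' @param threshold significance threshold on |SES|.
#' @return data.frame with one row per zone x metric x dimension.
#' @export
classify_structure <- function(ses_table, zones, threshold = 1.96) {
  if (is.data.frame(zones)) {
    zv <- stats::setNames(as.character(zones$zone), zones$site)
  } else {
    zv <- stats::setNames(as.character(zones), names(zones))
  }
  missing <- setdiff(ses_table$site, names(zv))
  if (length(missing) > 0)
    stop("unknown zone for site(s): ", paste(missing, collapse = ", "))
  ses_table$zone <- zv[ses_table$site]
  parts <- split(ses_table,
                 list(ses_table$zone, ses_table$metric, ses_table$dimension),
                 drop = FALSE)
  out <- do.call(rbind, lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    key <- strsplit(nm, ".", fixed = TRUE)[[1]]
    s <- p$ses[!is.na(p$ses)]
    n <- length(s)
    data.frame(zone = key[1], metric = key[2], dimension = key[3], n = n,
               clustered = sum(s < 0), overdispersed = sum(s > 0),
               sig_clustered = sum(s < -threshold),
               sig_overdispersed = sum(s > threshold),
               prop_clustered = if (n) sum(s < 0) / n else NA_real_,
               prop_sig_clustered = if (n) sum(s < -threshold) / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out[order(out$dimension, out$metric, out$zone), ]
}
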