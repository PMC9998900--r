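#' Assembly scenario definition
#'
#' Bundles the parameters of the synthetic riparian community generator:
#' the regional pool size, site layout over four inundation zones, the
#' environmental-filtering niche breadth `sigma` (metres, on the
#' elevation axis), the dispersal decay scale `lambda` (km along the
#' channel) and per-site richness targets.
#'
#' @param name one of `"neutral"`, `"filtering"`, `"dispersal"`,
#'   `"nested_loss"`, `"turnover"`, `"mixed"`.
#' @param S regional pool size (>= 4).
#' @param N number of sites (>= 8; assigned to 4 zones).
#' @param richness per-site richness target: scalar or length-4 per-zone
#'   vector.
#' @param sigma niche breadth (m) on the elevation axis; scalar or
#'   length-4 per-zone vector.
#' @param lambda dispersal decay scale (km).
#' @param zone_days inundation days per zone (I-IV).
#' @param seed RNG seed for all stages.
#' @return a validated `scenario` list.
#' @export
scenario <- function(name = c("neutral", "filtering", "dispersal",
                              "nested_loss", "turnover", "mixed"),
                     S = 64, N = 32, richness = 10,
                     sigma = 6, lambda = 150,
                     zone_days = c(68, 112, 152, 204), seed = 1) {
  name <- match.arg(name)
  stopifnot(S >= 4, N >= 8, all(sigma > 0), lambda > 0,
            length(zone_days) == 4)
  if (!length(richness) %in% c(1, 4))
    stop("richness must be scalar or per-zone (length 4)")
  if (!length(sigma) %in% c(1, 4))
    stop("sigma must be scalar or per-zone (length 4)")
  if (max(richness) > S) stop("richness target exceeds pool size")
  structure(list(name = name, S = S, N = N, richness = richness,
                 sigma = sigma, lambda = lambda, zone_days = zone_days,
                 seed = seed),
            class = "scenario")
}

#' Named generator presets
#'
#' Frozen parameter sets, including `paperlike`: a 166-species pool over
#' 64 sites (16 locations x 4 elevation zones) with richness and niche
#' breadth decreasing with inundation, emulating a dam-regulated riparian
#' zone where flooding both removes species and filters them more
#' strongly downslope.
#'
#' @return named list of [scenario()] objects.
#' @export
scenario_presets <- function() {
  list(
    paperlike = scenario("mixed", S = 166, N = 64,
                         richness = c(26, 21, 16, 11),
                         sigma = c(12, 8, 5, 3), lambda = 150, seed = 1),
    neutral_small = scenario("neutral", S = 40, N = 32, richness = 8,
                             seed = 1),
    filtering_demo = scenario("filtering", S = 80, N = 32, richness = 12,
                              sigma = 4, seed = 1),
    dispersal_demo = scenario("dispersal", S = 80, N = 32, richness = 12,
                              lambda = 40, seed = 1),
    nested_demo = scenario("nested_loss", S = 80, N = 32,
                           richness = c(40, 30, 20, 10), seed = 1),
    turnover_demo = scenario("turnover", S = 80, N = 32, richness = 12,
                             seed = 1)
  )
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' @param S number of tips.
#' @param seed RNG seed.
#' @return ultrametric `phylo` with tips `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(S, seed = NULL) {
  stopifnot(S >= 2)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(S, birth = 1, death = 0)
  tr$tip.label <- sprintf("sp%03d", seq_len(S))
  validate_tree(tr)
}

#' Evolve traits on a phylogeny
#'
#' Generates the five riparian traits with phylogenetic signal: shoot
#' height from Brownian motion (exponentiated to stay positive, metres),
#' flowering phenology as a Brownian trait discretized into months 4-9
#' (ordinal), and dispersal type / growth form / life cycle from a
#' symmetric k-state Markov process.  Also evolves the latent elevation
#' optimum (Brownian, attribute `optimum`, scaled to \[145, 175\] m) used
#' by filtering scenarios, so optima are phylogenetically conserved.
#'
#' @param tree `phylo` with branch lengths.
#' @param seed RNG seed.
#' @param bm_rate Brownian rate (variance per unit branch length).
#' @param markov_rate transition rate of the categorical traits.
#' @param decouple_optima randomize optima across tips (breaks the
#'   phylogenetic conservatism of the filtering target).
#' @return a [trait_table()] with attribute `optimum` (named vector, m).
#' @export
evolve_traits <- function(tree, seed = NULL, bm_rate = 1, markov_rate = 0.3,
                          decouple_optima = FALSE) {
  if (sum(tree$edge.length) <= 0) stop("zero-length tree")
  if (!is.null(seed)) set.seed(seed)
  S <- length(tree$tip.label)
  bm <- function() ape::rTraitCont(tree, model = "BM", sigma = sqrt(bm_rate))
  mk <- function(states, rate) {
    as.character(ape::rTraitDisc(tree, model = "ER", k = length(states),
                                 rate = rate, states = states))
  }
  height <- exp(0.5 * bm())                      # log-normal heights, m
  phen_raw <- bm()
  phenology <- as.integer(cut(rank(phen_raw), breaks = 6, labels = FALSE)) + 3L
  df <- data.frame(
    dispersal_type = mk(c("anemochory", "hydrochory", "zoochory",
                          "autochory"), markov_rate),
    growth_form = mk(c("forb", "graminoid", "shrub", "vine"), markov_rate),
    life_cycle = mk(c("annual", "biennial", "perennial"), markov_rate),
    shoot_height = round(height, 3),
    flowering_phenology = phenology,
    row.names = tree$tip.label, stringsAsFactors = FALSE)
  tt <- trait_table(df, c(dispersal_type = "categorical",
                          growth_form = "categorical",
                          life_cycle = "categorical",
                          shoot_height = "continuous",
                          flowering_phenology = "ordinal"))
  opt_raw <- bm()
  if (decouple_optima) opt_raw <- sample(opt_raw)
  rng <- range(opt_raw)
  u <- (opt_raw - rng[1]) / diff(rng)
  # regional riparian floras are dominated by flood-intolerant species:
  # the sqrt skews optima toward the rarely inundated upper band, leaving
  # a small flood-tolerant tail reaching the low elevations
  opt <- 145 + 30 * sqrt(u)
  names(opt) <- tree$tip.label
  attr(tt, "optimum") <- opt
  tt
}

#' Simulate the riparian landscape
#'
#' `N` sites are laid out as N/4 cross-sectional locations along a 1-D
#' riverbank coordinate (600 km channel with jitter), each location
#' carrying one site per elevation zone; zone is therefore orthogonal to
#' the along-channel position, mirroring a transect design.  Elevation
#' bands are 170-175 m (zone I, 68 days inundation), 165-170 (II, 112),
#' 160-165 (III, 152) and 145-160 m (IV, 204).  The 11 soil variables
#' trend linearly with elevation (organic matter and nutrients increase
#' downslope) plus correlated noise; climate (MAT, MAP) follows a smooth
#' spatial gradient around 18.22 degC / 1110 mm plus noise.
#'
#' @param N number of sites (rounded up to a multiple of 4).
#' @param seed RNG seed.
#' @param zone_days inundation days per zone.
#' @param channel_km channel length spanned by the locations.
#' @return list with `env` (data.frame incl. `zone`, `inundation_days`,
#'   `elevation`, soils, climate, topography) and `coords` (planar km;
#'   `x` along channel, `y` across).
#' @export
build_landscape <- function(N, seed = NULL, zone_days = c(68, 112, 152, 204),
                            channel_km = 600) {
  if (!is.null(seed)) set.seed(seed)
  n_loc <- ceiling(N / 4)
  N <- n_loc * 4
  loc_x <- sort(stats::runif(n_loc, 0, channel_km))
  zone <- rep(c("I", "II", "III", "IV"), times = n_loc)
  loc <- rep(seq_len(n_loc), each = 4)
  bands <- list(I = c(170, 175), II = c(165, 170),
                III = c(160, 165), IV = c(145, 160))
  elev <- vapply(zone, function(z) stats::runif(1, bands[[z]][1], bands[[z]][2]), 0)
  days <- zone_days[match(zone, c("I", "II", "III", "IV"))]
  x <- loc_x[loc] + stats::rnorm(N, 0, 0.5)
  y <- stats::rnorm(N, 0, 0.2)
  site <- sprintf("site%03d", seq_len(N))
  # soils: linear trend in (negative) elevation + shared + own noise;
  # higher inundation (lower elevation) enriches nutrients and moisture
  e_std <- (elev - mean(elev)) / stats::sd(elev)
  shared <- stats::rnorm(N, 0, 0.5)
  soil_gen <- function(slope, base, sdv) {
    base * exp(0.2 * (slope * -e_std + shared * 0.4 +
                        stats::rnorm(N, 0, sdv)))
  }
  env <- data.frame(
    zone = zone, inundation_days = days, elevation = round(elev, 2),
    slope_deg = round(stats::runif(N, 2, 35), 1),
    aspect = round(stats::runif(N, 0, 360), 0),
    SM = soil_gen(1.0, 25, 0.5), pH = 7 - 0.15 * -e_std + stats::rnorm(N, 0, 0.2),
    BD = soil_gen(-0.4, 1.3, 0.3), OM = soil_gen(1.2, 18, 0.5),
    TN = soil_gen(1.0, 1.1, 0.5), TK = soil_gen(0.3, 14, 0.4),
    TP = soil_gen(0.6, 0.7, 0.4), NH4N = soil_gen(0.8, 6, 0.6),
    NO3N = soil_gen(0.8, 4, 0.6), AP = soil_gen(0.7, 9, 0.6),
    AK = soil_gen(0.5, 90, 0.5),
    MAT = 18.22 + 1.2 * sin(2 * pi * x / channel_km) +
      0.002 * (x - channel_km / 2) + stats::rnorm(N, 0, 0.15),
    MAP = 1110 + 180 * cos(2 * pi * x / channel_km) +
      0.15 * x + stats::rnorm(N, 0, 20),
    row.names = site, stringsAsFactors = FALSE)
  coords <- data.frame(x = x, y = y, row.names = site)
  attr(coords, "crs_flag") <- "planar"
  list(env = env, coords = coords)
}

#' Assemble communities under a named scenario
#'
#' Per site, species occurrence weight is the product of an environmental
#' filtering term `exp(-(opt_s - elev)^2 / (2 sigma^2))` and a dispersal
#' term `exp(-|x_site - center_s| / lambda)`; the scenario switches each
#' term on or off (`neutral` = both off).  A fixed per-site richness is
#' drawn without replacement with these weights, so the richness design
#' matches the richness-preserving null models.  `nested_loss` builds
#' strict subset chains (prefixes of one species ranking with richness
#' decreasing along the inundation gradient); `turnover` assigns disjoint
#' zone-specific pools.
#'
#' @param tree pool phylogeny.
#' @param traits [evolve_traits()] output (carries the optima).
#' @param landscape [build_landscape()] output.
#' @param scn a [scenario()].
#' @return presence-mode [community_matrix()] with attribute `truth`
#'   (list of generator internals: weights used, optima, centers).
#' @export
assemble_communities <- function(tree, traits, landscape, scn) {
  stopifnot(inherits(scn, "scenario"))
  set.seed(scn$seed + 7L)
  S <- length(tree$tip.label)
  env <- landscape$env
  coords <- landscape$coords
  N <- nrow(env)
  zone_idx <- match(env$zone, c("I", "II", "III", "IV"))
  rich <- if (length(scn$richness) == 1) rep(scn$richness, N) else
    scn$richness[zone_idx]
  sig <- if (length(scn$sigma) == 1) rep(scn$sigma, N) else
    scn$sigma[zone_idx]
  if (max(rich) > S) stop("richness target exceeds pool size")
  opt <- attr(traits, "optimum")[tree$tip.label]
  centers <- stats::runif(S, min(coords$x), max(coords$x))
  names(centers) <- tree$tip.label
  use_filter <- scn$name %in% c("filtering", "mixed")
  use_disp <- scn$name %in% c("dispersal", "mixed")
  C <- matrix(0, N, S, dimnames = list(rownames(env), tree$tip.label))
  if (scn$name == "nested_loss") {
    ranking <- sample(tree$tip.label)
    ord <- order(zone_idx, -env$elevation)
    k <- sort(rich, decreasing = TRUE)
    # strictly decreasing richness along the gradient so every later
    # community is a strict subset (a shorter prefix) of every earlier one
    k <- round(seq(max(rich), min(rich), length.out = N))
    for (i in seq_len(N)) C[ord[i], ranking[seq_len(k[i])]] <- 1
  } else if (scn$name == "turnover") {
    pools <- split(sample(tree$tip.label), rep(1:4, length.out = S))
    for (i in seq_len(N)) {
      pool <- pools[[zone_idx[i]]]
      C[i, sample(pool, min(rich[i], length(pool)))] <- 1
    }
  } else {
    for (i in seq_len(N)) {
      w <- rep(1, S)
      if (use_filter)
        w <- w * exp(-(opt - env$elevation[i])^2 / (2 * sig[i]^2))
      if (use_disp)
        w <- w * exp(-abs(coords$x[i] - centers) / scn$lambda)
      w <- pmax(w, 1e-12)
      C[i, sample.int(S, rich[i], prob = w)] <- 1
    }
  }
  out <- community_matrix(C, mode = "presence")
  attr(out, "truth") <- list(optima = opt, centers = centers,
                             sigma = sig, lambda = scn$lambda,
                             scenario = scn$name, seed = scn$seed)
  out
}

#' Simulate a complete synthetic dataset
#'
#' Runs the full generator (tree, traits, landscape, communities) for a
#' scenario and reconciles the pieces into a bundle.  Stage seeds are
#' derived deterministically from the scenario seed.
#'
#' @param scn a [scenario()] or a preset name from [scenario_presets()].
#' @param decouple_optima see [evolve_traits()].
#' @return a `div_bundle` with attribute `truth`.
#' @export
simulate_dataset <- function(scn, decouple_optima = FALSE) {
  if (is.character(scn)) {
    presets <- scenario_presets()
    if (!scn %in% names(presets)) stop("unknown preset: ", scn)
    scn <- presets[[scn]]
  }
  stopifnot(inherits(scn, "scenario"))
  tree <- simulate_tree(scn$S, seed = scn$seed)
  traits <- evolve_traits(tree, seed = scn$seed + 1L,
                          decouple_optima = decouple_optima)
  landscape <- build_landscape(scn$N, seed = scn$seed + 2L,
                               zone_days = scn$zone_days)
  comm <- assemble_communities(tree, traits, landscape, scn)
  bundle <- validate_bundle(comm, traits = traits, tree = tree,
                            env = landscape$env, coords = landscape$coords,
                            policy = "drop")
  attr(bundle, "truth") <- attr(comm, "truth")
  attr(bundle, "scenario") <- scn
  bundle
}

#' Write a simulated dataset to a directory
#'
#' Writes `community.csv`, `traits.csv`, `trait_schema.yaml`, `tree.nwk`,
#' `env.csv`, `coords.csv` and `truth.yaml` (generator parameters and
#' per-species optima).
#'
#' @param bundle a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(unclass(bundle$community), file.path(dir, "community.csv"))
  tdf <- data.frame(species = rownames(bundle$traits),
                    as.data.frame(bundle$traits), check.names = FALSE)
  write_table(tdf, file.path(dir, "traits.csv"))
  yaml::write_yaml(as.list(trait_kinds(bundle$traits)),
                   file.path(dir, "trait_schema.yaml"))
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  write_table(data.frame(site = rownames(bundle$env), bundle$env,
                         check.names = FALSE),
              file.path(dir, "env.csv"))
  write_table(data.frame(site = rownames(bundle$coords), bundle$coords),
              file.path(dir, "coords.csv"))
  truth <- attr(bundle, "truth")
  if (!is.null(truth))
    yaml::write_yaml(lapply(truth, function(v)
      if (is.numeric(v)) as.list(round(v, 6)) else v),
      file.path(dir, "truth.yaml"))
  invisible(dir)
}
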