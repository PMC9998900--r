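#' Run the full multifaceted-diversity analysis
#'
#' Orchestrates simulate-or-read, reconciliation, alpha diversity, null
#' model SES, zone classification, three-dimensional beta partitioning,
#' PCNM and environmental PCA, Mantel / partial Mantel tests and four-set
#' variance partitioning, writing one CSV per stage plus a
#' `manifest.yaml` recording every option and seed in effect.  The output
#' is a pure function of (inputs, config, seed): no timestamps are
#' written, so re-runs are byte-identical.
#'
#' @param config list (or path to a YAML file) with either
#'   `scenario = <preset name or scenario list>` or
#'   `inputs = list(community=, traits=, trait_schema=, tree=, env=,
#'   coords=, mode=, crs=)` (exactly one of the two), plus optional
#'   `n_null` (default 1000), `seed` (required), `functional_mode`,
#'   `include_root`, `retain_threshold`, `n_perm` (default 999),
#'   `out_dir` (required).
#' @return invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_scn <- !is.null(config$scenario)
  has_inp <- !is.null(config$inputs)
  if (has_scn == has_inp)
    stop("config error: exactly one of 'scenario' or 'inputs' must be set")
  if (is.null(config$seed)) stop("config error: seed is mandatory")
  if (is.null(config$out_dir)) stop("config error: out_dir is required")
  n_null <- config$n_null %||% 1000
  n_perm <- config$n_perm %||% 999
  fmode <- config$functional_mode %||% "dendrogram"
  include_root <- config$include_root %||% TRUE
  retain <- config$retain_threshold %||% 0.10
  seed <- config$seed
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  bundle <- stage("input", {
    if (has_scn) {
      scn <- config$scenario
      if (is.list(scn) && !inherits(scn, "scenario"))
        scn <- do.call(scenario, scn)
      if (is.character(scn) || inherits(scn, "scenario")) {
        b <- simulate_dataset(scn)
        if (is.character(scn)) scn <- attr(b, "scenario")
        b
      } else stop("unusable scenario specification")
    } else {
      inp <- config$inputs
      comm <- read_community(inp$community, mode = inp$mode %||% "presence")
      traits <- read_traits(inp$traits, inp$trait_schema)
      tree <- read_tree(inp$tree)
      env <- read_env(inp$env)
      coords <- read_coords(inp$coords, crs = inp$crs %||% "planar")
      validate_bundle(comm, traits, tree, env, coords, policy = "drop")
    }
  })

  alpha <- stage("alpha", alpha_pipeline(bundle, include_root = include_root))
  write_table(alpha, file.path(out_dir, "alpha.csv"))

  ses_tabs <- stage("ses", {
    combos <- expand.grid(metric = c("mpd", "mntd"),
                          dimension = c("phylo", "func"),
                          stringsAsFactors = FALSE)
    do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
      ses_diversity(bundle, metric = combos$metric[i],
                    dimension = combos$dimension[i],
                    n_null = n_null, seed = seed + i)))
  })
  write_table(ses_tabs, file.path(out_dir, "ses.csv"))

  zone_summary <- NULL
  if (!is.null(bundle$env$zone)) {
    zone_summary <- stage("zones", classify_structure(
      ses_tabs, stats::setNames(bundle$env$zone, rownames(bundle$env))))
    write_table(zone_summary, file.path(out_dir, "zone_summary.csv"))
  }

  beta <- stage("beta", beta_pipeline(bundle, functional_mode = fmode))
  tags <- c(taxonomic = "tax", phylogenetic = "phylo", functional = "func")
  for (dim in names(beta)) {
    for (comp in c("sor", "sim", "sne"))
      write_table(beta[[dim]]$pairwise[[comp]],
                  file.path(out_dir, sprintf("beta_%s_%s.csv",
                                             tags[[dim]], comp)))
  }
  multi <- do.call(rbind, lapply(names(beta), function(dim) {
    m <- beta[[dim]]$multisite
    data.frame(dimension = dim, SOR = m$SOR, SIM = m$SIM, SNE = m$SNE,
               turnover_pct = m$turnover_pct,
               nestedness_pct = m$nestedness_pct,
               mean_pairwise_sor = m$mean_pairwise_sor,
               stringsAsFactors = FALSE)
  }))
  write_table(multi, file.path(out_dir, "beta_multisite.csv"))

  spatial <- stage("spatial", {
    geo <- geo_distance(bundle$coords,
                        method = if (identical(attr(bundle$coords, "crs_flag"),
                                               "geographic"))
                          "haversine" else "euclidean")
    pcnm <- pcnm_axes(geo)
    list(geo = geo, pcnm = pcnm)
  })
  write_table(spatial$pcnm$vectors, file.path(out_dir, "pcnm.csv"))

  envred <- stage("envpca", {
    soil_vars <- intersect(c("SM", "pH", "BD", "OM", "TN", "TK", "TP",
                             "NH4N", "NO3N", "AP", "AK"),
                           colnames(bundle$env))
    clim_vars <- intersect(c("MAT", "MAP"), colnames(bundle$env))
    soil <- env_pca(bundle$env[, soil_vars, drop = FALSE],
                    retain_threshold = retain, prefix = "Soil_PC")
    clim <- env_pca(bundle$env[, clim_vars, drop = FALSE],
                    retain_threshold = retain, prefix = "Climate_PC")
    igs <- standardize(bundle$env[, "inundation_days", drop = FALSE])
    list(soil = soil, climate = clim, igs = igs)
  })
  envpca_tab <- data.frame(site = bundle$sites,
                           envred$igs,
                           as.data.frame(envred$climate$scores),
                           as.data.frame(envred$soil$scores),
                           check.names = FALSE)
  write_table(envpca_tab, file.path(out_dir, "envpca.csv"))

  mantel_tab <- stage("mantel", {
    envmat <- cbind(as.matrix(envred$igs), envred$climate$scores,
                    envred$soil$scores)
    env_d <- env_distance(envmat)
    geo_d <- spatial$geo
    rows <- list()
    i <- 0
    for (dim in names(beta)) {
      for (comp in c("sor", "sim", "sne")) {
        bmat <- beta[[dim]]$pairwise[[comp]]
        i <- i + 1
        r_env <- partial_mantel(bmat, env_d, geo_d, n_perm = n_perm,
                                seed = seed + 100 + i,
                                partial_label = "spatial")
        r_spa <- partial_mantel(bmat, geo_d, env_d, n_perm = n_perm,
                                seed = seed + 200 + i,
                                partial_label = "environment")
        rows[[length(rows) + 1]] <- data.frame(
          dimension = dim, component = comp, predictor = "environment",
          r = r_env$r, p = r_env$p, partial = r_env$partial)
        rows[[length(rows) + 1]] <- data.frame(
          dimension = dim, component = comp, predictor = "spatial",
          r = r_spa$r, p = r_spa$p, partial = r_spa$partial)
      }
    }
    do.call(rbind, rows)
  })
  write_table(mantel_tab, file.path(out_dir, "mantel.csv"))

  varpart_tab <- stage("varpart", {
    # keep residual degrees of freedom in the full model: truncate the
    # spatial axes (ordered by eigenvalue, broadest scales first) if the
    # site count is small relative to the predictor total
    n_sites <- length(bundle$sites)
    m_other <- ncol(envred$igs) + ncol(envred$climate$scores) +
      ncol(envred$soil$scores)
    max_spatial <- n_sites - 3 - m_other
    if (max_spatial < 1)
      stop("too few sites for variance partitioning")
    keep <- seq_len(min(ncol(spatial$pcnm$vectors), max_spatial))
    sets <- list(IGs = envred$igs,
                 climate = as.data.frame(envred$climate$scores),
                 soil = as.data.frame(envred$soil$scores),
                 spatial = as.data.frame(
                   spatial$pcnm$vectors[, keep, drop = FALSE]))
    rows <- list()
    vps <- list()
    for (dim in names(beta)) {
      vp <- variance_partition(beta[[dim]]$pairwise$sor, sets)
      vps[[dim]] <- vp
      rows[[dim]] <- data.frame(dimension = dim, vp$fractions,
                                residual = vp$residual,
                                stringsAsFactors = FALSE)
    }
    list(table = do.call(rbind, rows), results = vps)
  })
  write_table(varpart_tab$table, file.path(out_dir, "varpart.csv"))

  manifest <- list(
    package = "multidiv",
    version = as.character(utils::packageVersion("multidiv")),
    seed = seed, n_null = n_null, n_perm = n_perm,
    functional_mode = fmode,
    faith_pd_include_root = include_root,
    pca_retain_threshold = retain,
    null_model = "taxa-label shuffle, shared permutation per replicate",
    p_value_convention = "(r+1)/(n+1)",
    sd_convention = "population",
    pcnm_truncation = spatial$pcnm$truncation,
    pcnm_axes_retained = spatial$pcnm$n_retained,
    igs_coding = "inundation days (standardized)",
    varpart_response = "positive-eigenvalue PCoA axes of the sor matrix",
    scenario = if (has_scn) attr(bundle, "scenario")[
      c("name", "S", "N", "richness", "sigma", "lambda", "zone_days",
        "seed")] else NULL,
    inputs = if (has_inp) config$inputs else NULL)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(bundle = bundle, alpha = alpha, ses = ses_tabs,
                 zone_summary = zone_summary, beta = beta,
                 spatial = spatial, env = envred,
                 mantel = mantel_tab, varpart = varpart_tab$results,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
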