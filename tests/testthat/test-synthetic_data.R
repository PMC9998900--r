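test_that("simulated trees are binary, ultrametric and deterministic", {
  tr <- simulate_tree(20, seed = 1)
  expect_equal(nrow(tr$edge), 2 * 20 - 2)
  expect_equal(tr$Nnode, 19)
  depths <- ape::node.depth.edgelength(tr)[1:20]
  expect_lt(max(depths) - min(depths), 1e-8)
  expect_identical(ape::write.tree(simulate_tree(20, seed = 1)),
                   ape::write.tree(tr))
})

test_that("trait evolution shows Brownian scaling and Markov limits", {
  tr <- simulate_tree(60, seed = 2)
  # Brownian: mean squared tip difference grows linearly with path
  # length; average over replicate traits to beat the shared-tree noise
  set.seed(3)
  pd <- stats::cophenetic(tr)
  lt <- lower.tri(pd)
  msq <- rowMeans(replicate(60, {
    z <- ape::rTraitCont(tr, model = "BM", sigma = 1)
    outer(z, z, "-")[lt]^2
  }))
  fit <- stats::lm(msq ~ 0 + pd[lt])
  expect_equal(unname(stats::coef(fit)), 1, tolerance = 0.35)

  # Markov rate -> 0: all tips share the root state
  tt_slow <- evolve_traits(tr, seed = 4, markov_rate = 1e-8)
  expect_equal(length(unique(tt_slow$dispersal_type)), 1)

  # Markov rate -> large: approximately uniform states
  tt_fast <- evolve_traits(tr, seed = 5, markov_rate = 50)
  tab <- table(tt_fast$dispersal_type)
  chi <- sum((tab - 15)^2 / 15)
  expect_lt(chi, stats::qchisq(0.999, df = length(tab) - 1))

  # optima are attached, within the elevation band, phylo-conserved
  opt <- attr(evolve_traits(tr, seed = 6), "optimum")
  expect_true(all(opt >= 145 & opt <= 175))
  expect_error(evolve_traits(structure(list(tip.label = "a",
                                            edge.length = 0),
                                       class = "phylo")), "zero-length")
})

test_that("landscapes have balanced zones and soil-elevation trends", {
  l <- build_landscape(64, seed = 7)
  expect_equal(as.vector(table(l$env$zone)), rep(16L, 4))
  expect_equal(l$env$inundation_days[l$env$zone == "IV"][1], 204)
  # organic matter increases downslope (negative correlation w/ elevation)
  cors <- vapply(1:10, function(i)
    stats::cor(build_landscape(64, seed = i)$env$OM,
               build_landscape(64, seed = i)$env$elevation), 0)
  expect_lt(mean(cors), -0.3)
  l2 <- build_landscape(64, seed = 7)
  expect_identical(l, l2)
})

test_that("neutral assembly hits the richness target with uniform occupancy", {
  b <- simulate_dataset(scenario("neutral", S = 30, N = 24, richness = 7,
                                 seed = 8))
  expect_true(all(rowSums(b$community) == 7))
  # occupancy approximately uniform over the pool
  occ <- colSums(b$community)
  expect_lt(max(occ) , 24 * 0.8)
  chi <- sum((occ - mean(occ))^2 / mean(occ))
  expect_lt(chi, stats::qchisq(0.9999, df = 29))
})

test_that("nested_loss builds subset chains along the gradient", {
  b <- simulate_dataset(scenario("nested_loss", S = 40, N = 12,
                                 richness = c(30, 22, 14, 6), seed = 9))
  C <- unclass(b$community) > 0
  rich <- rowSums(C)
  ord <- order(rich, decreasing = TRUE)
  for (i in seq_along(ord)[-1]) {
    sub <- colnames(C)[C[ord[i], ]]
    sup <- colnames(C)[C[ord[i - 1], ]]
    expect_true(all(sub %in% sup))
  }
  # lower zones are poorer
  expect_gt(mean(rich[b$env$zone == "I"]), mean(rich[b$env$zone == "IV"]))
})

test_that("turnover scenario uses disjoint zone pools", {
  b <- simulate_dataset(scenario("turnover", S = 40, N = 16, richness = 6,
                                 seed = 10))
  C <- unclass(b$community) > 0
  zones <- b$env$zone
  pools <- lapply(split(seq_len(nrow(C)), zones), function(ix)
    colnames(C)[colSums(C[ix, , drop = FALSE]) > 0])
  for (z1 in seq_along(pools)) for (z2 in seq_len(z1 - 1))
    expect_equal(length(intersect(pools[[z1]], pools[[z2]])), 0)
})

test_that("scenario presets validate and are frozen", {
  p <- scenario_presets()
  expect_gt(length(p), 0)
  for (s in p) expect_s3_class(s, "scenario")
  expect_equal(p$paperlike$S, 166)
  expect_equal(p$paperlike$N, 64)
  expect_equal(p$paperlike$zone_days, c(68, 112, 152, 204))
  expect_identical(scenario_presets(), p)
})

test_that("the full generator is deterministic per seed", {
  b1 <- simulate_dataset(scenario("mixed", S = 20, N = 12, richness = 5,
                                  seed = 11))
  b2 <- simulate_dataset(scenario("mixed", S = 20, N = 12, richness = 5,
                                  seed = 11))
  expect_identical(unclass(b1$community), unclass(b2$community))
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  expect_identical(b1$env, b2$env)
  b3 <- simulate_dataset(scenario("mixed", S = 20, N = 12, richness = 5,
                                  seed = 12))
  expect_false(identical(unclass(b1$community), unclass(b3$community)))
})

test_that("scenario invariants are enforced", {
  expect_error(scenario("neutral", S = 3), "S >= 4")
  expect_error(scenario("neutral", S = 10, N = 4), "N >= 8")
  expect_error(scenario("neutral", S = 10, richness = 11), "exceeds pool")
  expect_error(scenario("neutral", sigma = c(1, 2)), "per-zone")
})

test_that("dataset export writes the expected files", {
  b <- simulate_dataset(scenario("neutral", S = 15, N = 8, richness = 4,
                                 seed = 13))
  d <- tempfile()
  write_dataset(b, d)
  expect_setequal(list.files(d),
                  c("community.csv", "traits.csv", "trait_schema.yaml",
                    "tree.nwk", "env.csv", "coords.csv", "truth.yaml"))
  # round trip through the readers
  cm <- read_community(file.path(d, "community.csv"))
  expect_equal(unclass(cm), unclass(b$community)[rownames(cm), colnames(cm)],
               ignore_attr = TRUE)
  tt <- read_traits(file.path(d, "traits.csv"),
                    file.path(d, "trait_schema.yaml"))
  expect_equal(trait_kinds(tt), trait_kinds(b$traits))
})
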