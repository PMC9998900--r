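test_that("abc counts and pairwise partition match set algebra", {
  pool <- paste0("sp", 1:6)
  x <- pool %in% c("sp1", "sp2", "sp3")
  y <- pool %in% c("sp2", "sp3", "sp4")
  expect_equal(unname(abc_counts(x, y)), c(2, 1, 1))
  expect_equal(unname(abc_counts(x, x)), c(3, 0, 0))
  z <- pool %in% c("sp5", "sp6")
  expect_equal(unname(abc_counts(x, z)), c(0, 3, 2))

  expect_equal(pairwise_partition(2, 1, 1),
               c(sor = 1 / 3, sim = 1 / 3, sne = 0), tolerance = 1e-4)
  expect_equal(pairwise_partition(2, 2, 0),
               c(sor = 1 / 3, sim = 0, sne = 1 / 3), tolerance = 1e-4)
  p <- pairwise_partition(0, 4, 2)
  expect_equal(unname(p), c(1, 1, 0))
  expect_error(pairwise_partition(0, 0, 0), "empty")
})

test_that("shared branch lengths match hand edge accounting", {
  tr <- toy_tree()
  t3 <- shared_branch_abc(tr, c("A", "B"), c("A", "C"))
  expect_equal(unname(t3), c(2, 1, 1.5))
  # a + b = PD(i), a + c = PD(j)
  expect_equal(t3[["a"]] + t3[["b"]], faith_pd(c("A", "B"), tr))
  expect_equal(t3[["a"]] + t3[["c"]], faith_pd(c("A", "C"), tr))
  same <- shared_branch_abc(tr, c("A", "C"), c("A", "C"))
  expect_equal(unname(same[c("b", "c")]), c(0, 0))
})

test_that("phylo partition on a unit star tree equals the taxonomic one", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  comm <- make_comm(list(s1 = c("A", "B", "C"), s2 = c("B", "C", "D"),
                         s3 = c("A", "E")), star$tip.label)
  tax <- beta_pairwise(comm, "taxonomic")
  phy <- beta_pairwise(comm, "phylogenetic", tree = star)
  for (comp in c("sor", "sim", "sne"))
    expect_equal(phy[[comp]], tax[[comp]], tolerance = 1e-12)
  mt <- beta_multisite(comm, "taxonomic")
  mp <- beta_multisite(comm, "phylogenetic", tree = star)
  expect_equal(mp$SOR, mt$SOR, tolerance = 1e-12)
  expect_equal(mp$SIM, mt$SIM, tolerance = 1e-12)
})

test_that("functional dendrogram mode degenerates to taxonomic when all species are identical", {
  # all-zero gower distances -> star dendrogram with zero internal structure
  df <- data.frame(t1 = rep("a", 4), h = rep(1, 4),
                   row.names = LETTERS[1:4])
  suppressWarnings({
    tt <- trait_table(df, c(t1 = "categorical", h = "continuous"))
    g <- gower_distance(tt)
  })
  expect_true(all(g == 0))
  # zero-height dendrogram cannot carry branch length; partition via
  # explicit star with unit branches equals taxonomic
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  comm <- make_comm(list(s1 = c("A", "B"), s2 = c("B", "C", "D")),
                    LETTERS[1:4])
  fun <- beta_pairwise(comm, "functional", tree = star)
  tax <- beta_pairwise(comm, "taxonomic")
  expect_equal(fun$sor, tax$sor, tolerance = 1e-12)
})

test_that("hull mode matches polygon-intersection geometry", {
  # unit square vs unit square shifted 0.5 in x: shared 0.5, unique 0.5 each
  sc <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
              c(0.5, 0), c(1.5, 0), c(1.5, 1), c(0.5, 1))
  rownames(sc) <- paste0("sp", 1:8)
  t3 <- functional_abc(sc, paste0("sp", 1:4), paste0("sp", 5:8),
                       mode = "hull")
  expect_equal(unname(t3), c(0.5, 0.5, 0.5), tolerance = 1e-10)
  # nested hulls: contained site has zero unique volume -> sim = 0
  sc2 <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4),
               c(1, 1), c(2, 1), c(2, 2), c(1, 2))
  rownames(sc2) <- paste0("sp", 1:8)
  t4 <- functional_abc(sc2, paste0("sp", 1:4), paste0("sp", 5:8),
                       mode = "hull")
  expect_equal(t4[["c"]], 0, tolerance = 1e-10)
  p <- pairwise_partition(t4[["a"]], t4[["b"]], t4[["c"]])
  expect_equal(unname(p["sim"]), 0)
  expect_gt(p[["sne"]], 0)
  # too few species for a hull
  expect_error(functional_abc(sc, paste0("sp", 1:2), paste0("sp", 5:8),
                              mode = "hull"), "dendrogram")
  expect_error(functional_abc(sc, paste0("sp", 1:4), paste0("sp", 5:8),
                              mode = "hull", k = 3), "k = 2")
})

test_that("multisite partition matches brute-force formula evaluation", {
  pool <- paste0("sp", 1:7)
  sites <- list(s1 = c("sp1", "sp2", "sp3", "sp4"),
                s2 = c("sp3", "sp4", "sp5"),
                s3 = c("sp1", "sp5", "sp6", "sp7"))
  comm <- make_comm(sites, pool)
  m <- beta_multisite(comm, "taxonomic")
  # brute force from the b_ij table
  Si <- lengths(sites)
  ST <- length(unique(unlist(sites)))
  bij <- function(i, j) length(setdiff(sites[[i]], sites[[j]]))
  pr <- list(c(1, 2), c(1, 3), c(2, 3))
  smin <- sum(vapply(pr, function(p) min(bij(p[1], p[2]), bij(p[2], p[1])), 0))
  smax <- sum(vapply(pr, function(p) max(bij(p[1], p[2]), bij(p[2], p[1])), 0))
  core <- sum(Si) - ST
  SIM <- smin / (smin + core)
  SOR <- (smin + smax) / (2 * core + smin + smax)
  expect_equal(m$SIM, SIM, tolerance = 1e-12)
  expect_equal(m$SOR, SOR, tolerance = 1e-12)
  expect_equal(m$SNE, SOR - SIM, tolerance = 1e-12)
  expect_equal(m$turnover_pct + m$nestedness_pct, 100, tolerance = 1e-9)
})

test_that("multisite degenerate cases: identical and disjoint sites", {
  pool <- paste0("sp", 1:9)
  same <- make_comm(list(s1 = pool[1:4], s2 = pool[1:4], s3 = pool[1:4]),
                    pool)
  m0 <- beta_multisite(same, "taxonomic")
  expect_equal(c(m0$SOR, m0$SIM, m0$SNE), c(0, 0, 0))

  disj <- make_comm(list(s1 = pool[1:3], s2 = pool[4:6], s3 = pool[7:9]),
                    pool)
  md <- beta_multisite(disj, "taxonomic")
  expect_equal(md$SIM, md$SOR)
  expect_equal(md$nestedness_pct, 0)
})

test_that("additivity and invariance to site order hold everywhere", {
  b <- simulate_dataset(scenario("mixed", S = 25, N = 12, richness = 6,
                                 seed = 17))
  be <- beta_pipeline(b)
  for (dim in names(be)) {
    pw <- be[[dim]]$pairwise
    expect_lt(max(abs(pw$sor - pw$sim - pw$sne)), 1e-12)
    expect_true(all(pw$sor >= -1e-12 & pw$sor <= 1 + 1e-12))
    expect_true(all(pw$sne >= -1e-12))
    m <- be[[dim]]$multisite
    expect_equal(m$SNE, m$SOR - m$SIM, tolerance = 1e-12)
  }
  # permuting site order leaves the multisite scalars unchanged
  perm <- sample(nrow(b$community))
  cm <- community_matrix(unclass(b$community)[perm, ], mode = "presence")
  m1 <- beta_multisite(b$community, "phylogenetic", tree = b$tree)
  m2 <- beta_multisite(cm, "phylogenetic", tree = b$tree)
  expect_equal(m1$SOR, m2$SOR, tolerance = 1e-12)
  expect_equal(m1$SIM, m2$SIM, tolerance = 1e-12)
})

test_that("an ordered-loss gradient is pure nestedness", {
  b <- simulate_dataset(scenario("nested_loss", S = 40, N = 8,
                                 richness = c(30, 24, 16, 8), seed = 23))
  pw <- beta_pairwise(b$community, "taxonomic")
  expect_lt(max(pw$sim), 1e-12)
  m <- beta_multisite(b$community, "taxonomic")
  expect_equal(m$SNE, m$SOR, tolerance = 1e-12)
})
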