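test_that("mantel r matches direct Pearson and is affine-invariant", {
  dx <- rand_dist(4, seed = 1)
  dy <- rand_dist(4, seed = 2, labels = rownames(dx))
  m <- mantel_test(dx, dy, n_perm = 99, seed = 1)
  lt <- lower.tri(dx)
  expect_equal(m$r, stats::cor(dx[lt], dy[lt]), tolerance = 1e-12)

  m2 <- mantel_test(dx, 2 * dx, n_perm = 99, seed = 1)
  expect_equal(m2$r, 1, tolerance = 1e-12)
  m3 <- mantel_test(dx, 0.5 + 2 * dx - diag(0.5, 4), n_perm = 99, seed = 1)
  expect_equal(m3$r, 1, tolerance = 1e-12)

  expect_error(mantel_test(dx, rand_dist(4, seed = 2,
                                         labels = letters[1:4])),
               "mismatch")
  expect_error(mantel_test(dx, dy, n_perm = 10), "at least 99")
})

test_that("mantel r agrees with vegan and is seed-deterministic", {
  skip_if_not_installed("vegan")
  dx <- rand_dist(10, seed = 3)
  dy <- rand_dist(10, seed = 4, labels = rownames(dx))
  m <- mantel_test(dx, dy, n_perm = 199, seed = 5)
  ref <- vegan::mantel(stats::as.dist(dx), stats::as.dist(dy),
                       permutations = 199)
  expect_equal(m$r, unname(ref$statistic), tolerance = 1e-12)
  expect_identical(m, mantel_test(dx, dy, n_perm = 199, seed = 5))
})

test_that("partial mantel behaves at its analytic limits", {
  dx <- rand_dist(8, seed = 6)
  dy <- rand_dist(8, seed = 7, labels = rownames(dx))
  # dy = dz: residuals of dy on dz vanish -> r undefined (constant)
  expect_warning(pz <- partial_mantel(dx, dy, dy, n_perm = 99, seed = 1),
                 "constant")
  expect_true(is.na(pz$r))
  # constant dz: partial reduces to plain mantel
  dz0 <- matrix(1, 8, 8) - diag(1, 8)
  dimnames(dz0) <- dimnames(dx)
  pp <- partial_mantel(dx, dy, dz0, n_perm = 99, seed = 1)
  mm <- mantel_test(dx, dy, n_perm = 99, seed = 1)
  expect_equal(pp$r, mm$r, tolerance = 1e-12)
  # closed form: r_xy.z = (r_xy - r_xz r_yz)/sqrt((1-r_xz^2)(1-r_yz^2))
  dz <- rand_dist(8, seed = 8, labels = rownames(dx))
  lt <- lower.tri(dx)
  rxy <- stats::cor(dx[lt], dy[lt]); rxz <- stats::cor(dx[lt], dz[lt])
  ryz <- stats::cor(dy[lt], dz[lt])
  expected <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  pr <- partial_mantel(dx, dy, dz, n_perm = 99, seed = 2)
  expect_equal(pr$r, expected, tolerance = 1e-10)
})

test_that("partial r is close to plain r when dz is unrelated", {
  set.seed(9)
  pts <- function() matrix(rnorm(40), 20, 2)
  lab <- paste0("s", 1:20)
  mk <- function() {
    d <- as.matrix(dist(pts())); dimnames(d) <- list(lab, lab); d
  }
  base <- mk()
  related <- as_dist_matrix(base + 0.3 * mk())
  unrelated <- mk()
  r_plain <- mantel_test(base, related, n_perm = 99, seed = 3)$r
  r_part <- partial_mantel(base, related, unrelated, n_perm = 99, seed = 3)$r
  expect_lt(abs(r_plain - r_part), 0.1)
})

test_that("adjusted R2 follows the Ezekiel formula", {
  # construct a response with known raw R2 = 0.5 at n=10, m=2 via the
  # formula directly
  expect_error(rda_adj_r2(matrix(rnorm(8), 4), matrix(rnorm(16), 4)),
               "saturated")
  set.seed(10)
  X <- matrix(rnorm(20), 10, 2)
  Y <- X %*% c(1, -1) + rnorm(10)
  fit <- rda_adj_r2(Y, X)
  expect_equal(fit$adj_r2, 1 - (1 - fit$r2) * 9 / 7, tolerance = 1e-12)
  # the reference point: R2 = 0.5, n = 10, m = 2 -> 0.357142857
  expect_equal(1 - (1 - 0.5) * 9 / 7, 0.357142857, tolerance = 1e-9)
  # exact linear response
  Yx <- X %*% c(2, 3)
  ex <- rda_adj_r2(Yx, X)
  expect_equal(ex$r2, 1, tolerance = 1e-12)
  expect_equal(ex$adj_r2, 1, tolerance = 1e-12)
})

test_that("pure-noise predictors have mean adjusted R2 near zero", {
  set.seed(11)
  n <- 20; m <- 3
  sims <- replicate(300, {
    r <- rda_adj_r2(matrix(rnorm(n), n, 1), matrix(rnorm(n * m), n, m))
    c(r$r2, r$adj_r2)
  })
  expect_lt(abs(mean(sims[2, ])), 0.03)
  expect_equal(mean(sims[1, ]), m / (n - 1), tolerance = 0.15)
})

test_that("forward selection finds the causal predictor and skips duplicates", {
  set.seed(12)
  n <- 40
  X <- data.frame(causal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  Y <- 2 * X$causal + rnorm(n, 0, 0.5)
  fs <- forward_select(matrix(Y), X, n_perm = 199, seed = 1)
  expect_equal(fs$selected[1], "causal")

  Xd <- cbind(X, dup = X$causal)
  fsd <- forward_select(matrix(Y), Xd, n_perm = 199, seed = 2)
  expect_false("dup" %in% fsd$selected[-1])

  # all-noise candidates select little or nothing
  set.seed(13)
  hits <- replicate(30, {
    Yn <- matrix(rnorm(n))
    length(forward_select(Yn, X, n_perm = 99, seed = NULL)$selected)
  })
  expect_lt(mean(hits > 0), 0.25)
})

test_that("variance partitioning fractions obey inclusion-exclusion exactly", {
  set.seed(14)
  n <- 30
  sets <- list(A = data.frame(a = rnorm(n)),
               B = data.frame(b1 = rnorm(n), b2 = rnorm(n)),
               C = data.frame(c1 = rnorm(n)),
               D = data.frame(d1 = rnorm(n)))
  Y <- matrix(rnorm(2 * n), n, 2)
  vp <- variance_partition(Y, sets, response_is_scores = TRUE)
  expect_equal(nrow(vp$fractions), 15)
  full <- vp$unions$adj_r2[nrow(vp$unions)]
  expect_lt(abs(sum(vp$fractions$fraction) - full), 1e-10)
  expect_equal(vp$residual, 1 - full, tolerance = 1e-12)
  # every union's adjusted R2 is reconstructed from the fractions
  for (i in seq_len(nrow(vp$unions))) {
    members <- strsplit(vp$unions$union[i], "+", fixed = TRUE)[[1]]
    covered <- vapply(strsplit(vp$fractions$sets, "&", fixed = TRUE),
                      function(v) length(intersect(v, members)) > 0, NA)
    expect_lt(abs(sum(vp$fractions$fraction[covered]) - vp$unions$adj_r2[i]),
              1e-10)
  }
})

test_that("signal lands in the generating set; duplicates share it", {
  set.seed(15)
  n <- 40
  a <- rnorm(n)
  Y <- matrix(2 * a + rnorm(n, 0, 0.3))
  sets <- list(A = data.frame(a = a), B = data.frame(b = rnorm(n)),
               C = data.frame(c = rnorm(n)))
  vp <- variance_partition(Y, sets, response_is_scores = TRUE)
  uq <- stats::setNames(vp$fractions$fraction[vp$fractions$n_sets == 1],
                        vp$fractions$sets[vp$fractions$n_sets == 1])
  expect_gt(uq["A"], 0.5)
  expect_lt(max(uq[c("B", "C")]), 0.1)

  sets2 <- list(A1 = data.frame(a = a), A2 = data.frame(a2 = a),
                B = data.frame(b = rnorm(n)))
  vp2 <- variance_partition(Y, sets2, response_is_scores = TRUE)
  f2 <- vp2$fractions
  joint <- f2$fraction[f2$sets == "A1&A2"]
  expect_gt(joint, 0.5)
  expect_lt(abs(f2$fraction[f2$sets == "A1"]), 0.05)
  expect_lt(abs(f2$fraction[f2$sets == "A2"]), 0.05)
})

test_that("mantel type-I error rate is near nominal", {
  set.seed(16)
  rej <- vapply(1:200, function(i) {
    p1 <- matrix(rnorm(24), 12); p2 <- matrix(rnorm(24), 12)
    rownames(p1) <- rownames(p2) <- paste0("s", 1:12)
    mantel_test(as.matrix(dist(p1)), as.matrix(dist(p2)),
                n_perm = 99)$p <= 0.05
  }, NA)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})
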