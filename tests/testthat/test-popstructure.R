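test_that("diversity matches hand arithmetic and flags excess hets", {
  # 5 individuals: (1,1) (1,2) (2,2) (1,2) (1,1)
  ds <- make_two_pop(list(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(1L, 2L),
                          c(1L, 1L)),
                     list(c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 2L),
                          c(1L, 2L)))
  dv <- diversity(ds, min_n = 5L, n_perms = 99, seed = 1)
  p1 <- dv$per_locus[dv$per_locus$locality == "p1", ]
  expect_lt(abs(p1$H_obs - 0.4), 1e-12)
  expect_lt(abs(p1$H_exp - (10 / 9) * (1 - 0.6^2 - 0.4^2)), 1e-12)
  expect_lt(abs(p1$G_is - (1 - 0.4 / ((10 / 9) * 0.48))), 1e-12)
  # all heterozygotes at p = 1/2: H_obs = 1 > H_exp, G_is < 0
  p2 <- dv$per_locus[dv$per_locus$locality == "p2", ]
  expect_equal(p2$H_obs, 1)
  expect_gt(p2$H_obs, p2$H_exp)
  expect_lt(p2$G_is, 0)
})

test_that("G_is permutation p-values are uniform under random mating", {
  set.seed(2)
  n <- 50L; L <- 150L
  ca <- matrix(sample(1:4, n * L, TRUE), n, L)
  cb <- matrix(sample(1:4, n * L, TRUE), n, L)
  colnames(ca) <- colnames(cb) <- paste0("L", 1:L)
  ds <- genotype_dataset(ca, cb,
                         data.frame(id = sprintf("i%03d", 1:n),
                                    locality = "hw"))
  dv <- diversity(ds, min_n = 20L, n_perms = 199, seed = 3)
  pv <- dv$per_locus$p_value
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pairwise Fst matches hand-derived variance components", {
  # pop1: (1,1) (1,2) (1,1); pop2: (2,2) (1,2); theta frozen from an
  # independent transcription of the variance-component arithmetic
  ds <- make_two_pop(list(c(1L, 1L), c(1L, 2L), c(1L, 1L)),
                     list(c(2L, 2L), c(1L, 2L)))
  theta <- unclass(pairwise_fst(ds, min_n = 2L))["p1", "p2"]
  expect_lt(abs(theta - 0.396600566572238), 1e-10)
})

test_that("Fst hits its limits under no and full differentiation", {
  set.seed(4)
  n <- 100L; L <- 10L
  draw <- function() matrix(sample(1:5, n * L, TRUE,
                                   prob = c(.4, .25, .2, .1, .05)),
                            n, L, dimnames = list(NULL, paste0("L", 1:L)))
  ds <- genotype_dataset(
    rbind(draw(), draw())[c(seq_len(n), n + seq_len(n)), ],
    rbind(draw(), draw())[c(seq_len(n), n + seq_len(n)), ],
    data.frame(id = sprintf("i%04d", 1:(2 * n)),
               locality = rep(c("p1", "p2"), each = n)))
  expect_lt(abs(unclass(pairwise_fst(ds))["p1", "p2"]), 0.02)
  # fixed alternative alleles at every locus
  n <- 50L
  ca <- matrix(1L, n, L, dimnames = list(NULL, paste0("L", 1:L)))
  cb2 <- matrix(2L, n, L, dimnames = list(NULL, paste0("L", 1:L)))
  ds2 <- genotype_dataset(rbind(ca, cb2), rbind(ca, cb2),
                          data.frame(id = sprintf("i%04d", 1:(2 * n)),
                                     locality = rep(c("p1", "p2"),
                                                    each = n)))
  expect_gte(unclass(pairwise_fst(ds2))["p1", "p2"], 0.97)
})

test_that("Fst and Rst are symmetric, zero-diagonal, order-invariant", {
  z <- small_zone(seed = 5, cap = 15L)
  ids <- z$dataset$individuals$id[
    z$dataset$individuals$locality %in% paste0("alloA_", 1:4)]
  sub <- subset_dataset(z$dataset, individuals = ids)
  set.seed(6)
  shuf <- subset_dataset(z$dataset, individuals = sample(ids))
  for (fn in list(pairwise_fst, pairwise_rst)) {
    m1 <- unclass(fn(sub)); m2 <- unclass(fn(shuf))
    expect_equal(m1, m2, tolerance = 1e-12)
    expect_equal(m1, t(m1))
    expect_equal(unname(diag(m1)), rep(0, nrow(m1)))
  }
})

test_that("Rst matches a brute-force squared-size-difference oracle", {
  ds <- make_two_pop(list(c(100L, 104L), c(100L, 100L), c(108L, 104L)),
                     list(c(120L, 116L), c(120L, 120L)))
  rst <- unclass(pairwise_rst(ds, min_n = 2L))["p1", "p2"]
  x1 <- c(100, 104, 100, 100, 108, 104); x2 <- c(120, 116, 120, 120)
  msd_loop <- function(x) {
    s <- 0; np <- 0
    for (i in seq_along(x)) for (j in seq_along(x)) if (i < j) {
      s <- s + (x[i] - x[j])^2; np <- np + 1
    }
    s / np
  }
  s_all <- msd_loop(c(x1, x2))
  np1 <- choose(6, 2); np2 <- choose(4, 2)
  s_w <- (msd_loop(x1) * np1 + msd_loop(x2) * np2) / (np1 + np2)
  expect_lt(abs(rst - (s_all - s_w) / s_all), 1e-10)
})

test_that("Rst is 1 for fixed distinct sizes and ~0 under exchange", {
  n <- 20L
  ca <- matrix(c(rep(100L, n), rep(120L, n)), ncol = 1,
               dimnames = list(NULL, "L1"))
  ds <- genotype_dataset(ca, ca,
                         data.frame(id = sprintf("i%03d", 1:(2 * n)),
                                    locality = rep(c("p1", "p2"),
                                                   each = n)))
  expect_equal(unclass(pairwise_rst(ds))["p1", "p2"], 1)
  # permuting individuals between localities removes structure
  set.seed(7)
  vals <- vapply(1:100, function(r) {
    ind <- ds$individuals
    ind$locality <- sample(ind$locality)
    ds2 <- genotype_dataset(ds$calls_a, ds$calls_b, ind)
    unclass(pairwise_rst(ds2))["p1", "p2"]
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("PCoA recovers Euclidean configurations exactly", {
  # two points at distance d -> one axis at +/- d/2
  D2 <- dist_matrix(matrix(c(0, 3, 3, 0), 2), labels = c("a", "b"))
  p2 <- pcoa(D2)
  expect_equal(sort(unname(p2$coordinates[, 1])), c(-1.5, 1.5))
  expect_equal(p2$percent_variance[1], 100)
  # known 2-D configuration: reconstructed distances match to 1e-9
  set.seed(8)
  pts <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(pts))
  p <- pcoa(D)
  rec <- as.matrix(dist(p$coordinates))
  expect_lt(max(abs(rec - D)), 1e-9)
  # cross-check coordinates against classical scaling in stats
  cs <- stats::cmdscale(D, k = 2)
  expect_lt(max(abs(as.matrix(dist(cs)) - rec)), 1e-8)
  # degenerate all-zero matrix
  p0 <- pcoa(matrix(0, 4, 4))
  expect_true(all(abs(p0$eigenvalues) < 1e-9))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("geographic distances honor both coordinate systems", {
  meta <- data.frame(locality_id = c("a", "b", "c"),
                     species = "A", sympatry = "allopatric",
                     lat = c(0, 0, 0), lon = c(0, 1, 1))
  g <- geographic_distances(meta, "lonlat")
  expect_equal(unclass(g)["a", "a"], 0)
  expect_lt(abs(unclass(g)["a", "b"] - 111.1951), 0.01)
  expect_equal(unclass(g)["b", "c"], 0)
  meta$lat <- c(0, 3, 0); meta$lon <- c(0, 0, 4)
  gp <- geographic_distances(meta, "planar")
  expect_equal(unclass(gp)["a", "b"], 3)
  expect_equal(unclass(gp)["b", "c"], 5)
  meta$lat[1] <- 95
  expect_error(geographic_distances(meta, "lonlat"), "latitude")
  # triangle inequality on random points
  set.seed(9)
  m2 <- data.frame(locality_id = paste0("l", 1:20), species = "A",
                   sympatry = "allopatric", lat = runif(20, -60, 60),
                   lon = runif(20, -170, 170))
  gm <- unclass(geographic_distances(m2, "lonlat"))
  for (r in 1:30) {
    ijk <- sample(20, 3)
    expect_lte(gm[ijk[1], ijk[3]],
               gm[ijk[1], ijk[2]] + gm[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("Mantel test is exact in its limits and under enumeration", {
  set.seed(10)
  pts <- matrix(rnorm(12), 6, 2)
  D1 <- as.matrix(dist(pts))
  r <- mantel_test(D1, 3 * D1, n_perms = 999, seed = 11)
  expect_equal(r$r, 1)
  # only permutations reproducing the configuration tie the observed r
  expect_lte(r$p_value, 5 / 1000)
  # n = 4: compare against exhaustive 4! relabelings
  D2 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  D3 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3),
    c(1,4,3,2), c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1),
    c(2,4,1,3), c(2,4,3,1), c(3,1,2,4), c(3,1,4,2), c(3,2,1,4),
    c(3,2,4,1), c(3,4,1,2), c(3,4,2,1), c(4,1,2,3), c(4,1,3,2),
    c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  u1 <- D2[upper.tri(D2)]
  robs <- cor(u1, D3[upper.tri(D3)])
  rnull <- apply(perms, 1, function(ix) {
    Dp <- D3[ix, ix]; cor(u1, Dp[upper.tri(Dp)])
  })
  p_exact <- mean(rnull >= robs - 1e-12)
  mt <- mantel_test(D2, D3, n_perms = 20000, seed = 12)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(mt$p_value - p_exact), 3 * se + 2 / 20001)
  expect_error(mantel_test(matrix(0, 4, 4), D3), "zero variance")
})

test_that("Mantel statistic agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(13)
  D1 <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  D2 <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  mine <- mantel_test(D1, D2, n_perms = 999, seed = 14)
  ref <- vegan::mantel(as.dist(D1), as.dist(D2), permutations = 999)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(mine$p_value - ref$signif), 0.07)
})

test_that("IBD residual statistic behaves at its fixed points", {
  set.seed(15)
  n <- 10L
  meta <- data.frame(locality_id = paste0("l", 1:n), species = "A",
                     sympatry = rep(c("sympatric", "allopatric"),
                                    each = n / 2),
                     lat = runif(n, 0, 100), lon = runif(n, 0, 500))
  geo <- geographic_distances(meta, "planar")
  # perfectly linear genetic distances -> all residuals zero
  gen <- dist_matrix(0.001 * unclass(geo), labels = meta$locality_id,
                     kind = "fst")
  ib <- ibd_residual_randomization(
    gen, geo, stats::setNames(meta$sympatry, meta$locality_id),
    n_reps = 99, n_perms_mantel = 99, seed = 16)
  expect_lt(abs(ib$sympatry_stat), 1e-12)
  expect_equal(ib$p_randomization, 1)
  expect_equal(ib$r_squared, 1)
  # adding a constant to all genetic distances leaves the statistic
  # unchanged (absorbed by the intercept)
  gen2 <- dist_matrix(unclass(gen) +
                        0.05 * (1 - diag(n)), labels = meta$locality_id,
                      kind = "fst")
  ib2 <- ibd_residual_randomization(
    gen2, geo, stats::setNames(meta$sympatry, meta$locality_id),
    n_reps = 99, n_perms_mantel = 99, seed = 16)
  expect_equal(ib2$sympatry_stat, ib$sympatry_stat, tolerance = 1e-10)
  expect_error(ibd_residual_randomization(
    gen, geo, rep("sympatric", n)), ">= 2")
})

test_that("hybrid filtering drops the union of both classifications", {
  res <- data.frame(individual = c("a", "b", "c", "d"),
                    locality = "x",
                    is_F1 = c(TRUE, FALSE, FALSE, FALSE),
                    is_hybrid_ci = c(TRUE, TRUE, FALSE, FALSE))
  ca <- matrix(1L, 4, 1, dimnames = list(NULL, "L1"))
  ds <- genotype_dataset(ca, ca, data.frame(id = c("a", "b", "c", "d"),
                                            locality = "x"))
  kept <- filter_hybrids(ds, res)
  expect_setequal(kept$individuals$id, c("c", "d"))
})
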