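test_that("PCA scores match a dense eigendecomposition oracle up to sign", {
  gm <- random_gm(6, 50, missing_rate = 0, seed = 60)
  pcs <- suppressWarnings(genotype_pca(gm, k = 3))  # few loci fix by chance
  # oracle: explicit centring/scaling then eigen of the cross-product
  d <- gm$dosages
  p <- colMeans(d) / 2
  use <- p > 0 & p < 1
  x <- sweep(d[, use], 2, 2 * p[use])
  x <- sweep(x, 2, sqrt(p[use] * (1 - p[use])), "/")
  ev <- eigen(tcrossprod(x), symmetric = TRUE)
  oracle <- ev$vectors[, 1:3] %*% diag(sqrt(ev$values[1:3]))
  for (j in 1:3) {
    expect_true(max(abs(pcs$coords[, j] - oracle[, j])) < 1e-8 ||
                max(abs(pcs$coords[, j] + oracle[, j])) < 1e-8)
  }
  expect_true(all(diff(pcs$eigenvalues) <= 1e-12))
})

test_that("duplicated samples land on identical PCA coordinates", {
  gm <- random_gm(8, 60, missing_rate = 0, seed = 61)
  dup <- genotype_matrix(rbind(gm$dosages, gm$dosages[1, , drop = FALSE]),
                         variants = gm$variants,
                         sample_ids = c(gm$sample_ids, "dup1"))
  pcs <- suppressWarnings(genotype_pca(dup, k = 2))
  expect_equal(pcs$coords["dup1", ], pcs$coords[gm$sample_ids[1], ],
               tolerance = 1e-8)
})

test_that("PC1 separates two diverged synthetic subpopulations", {
  panel <- generate_panel(synth_config(n_samples = 60, n_variants = 800,
                                       n_subpops = 2, fst = 0.3,
                                       selfing_gens = 0, missing_rate = 0,
                                       seed = 5))
  gm <- filter_variants(panel$gm, filter_spec(maf_min = 0.05, miss_max = 1))$gm
  pcs <- genotype_pca(gm, k = 2)
  lab <- panel$truth$samples$subpop
  # silhouette-style check on PC1: between-group gap exceeds within-group spread
  m1 <- mean(pcs$coords[lab == 1, 1])
  m2 <- mean(pcs$coords[lab == 2, 1])
  within <- max(stats::sd(pcs$coords[lab == 1, 1]),
                stats::sd(pcs$coords[lab == 2, 1]))
  expect_gt(abs(m1 - m2), 2 * within)
})

test_that("convex hull area matches known shapes and an independent hull", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(convex_hull_area(square), 1)
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(convex_hull_area(tri), 0.5)
  collinear <- cbind(1:5, 2 * (1:5))
  expect_equal(convex_hull_area(collinear), 0)
  expect_error(convex_hull_area(rbind(c(0, 0), c(1, 1))),
               class = "apd_domain_error")
  for (seed in 1:5) {
    set.seed(seed)
    pts <- matrix(stats::rnorm(200), ncol = 2)
    expect_equal(convex_hull_area(pts), hull_area_monotone_chain(pts),
                 tolerance = 1e-12)
  }
})

test_that("hap is 100 for the full set, 0 for collinear subsets, and exact on a constructed fixture", {
  # 10 x 10 square frame with interior points forming a known 2 x 2 square
  coords <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10),
                  c(4, 4), c(6, 4), c(6, 6), c(4, 6),
                  c(1, 1), c(2, 2), c(3, 3))
  ids <- sprintf("P%02d", seq_len(nrow(coords)))
  pcs <- structure(list(sample_ids = ids,
                        coords = `colnames<-`(coords, c("PC1", "PC2")),
                        eigenvalues = c(2, 1), n_variants_used = 0L),
                   class = "pca_coordinates")
  expect_equal(hap(pcs, ids)$hap, 100)
  inner <- hap(pcs, ids[5:8])
  expect_equal(inner$area_subset, 4)
  expect_equal(inner$area_full, 100)
  expect_equal(inner$hap, 4.0)
  expect_equal(hap(pcs, ids[9:11])$hap, 0)
  expect_error(hap(pcs, ids[1:2]), class = "apd_domain_error")
  expect_error(hap(pcs, c(ids[1:2], "nope")), class = "apd_lookup_error")
})

test_that("hap is monotone under subset nesting and invariant to rigid motion", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    coords <- matrix(stats::rnorm(2 * n), ncol = 2,
                     dimnames = list(NULL, c("PC1", "PC2")))
    ids <- sprintf("S%02d", 1:n)
    pcs <- structure(list(sample_ids = ids, coords = coords,
                          eigenvalues = c(2, 1), n_variants_used = 0L),
                     class = "pca_coordinates")
    small <- sample(ids, 5)
    big <- union(small, sample(ids, 15))
    expect_lte(hap(pcs, small)$hap, hap(pcs, big)$hap)
    # rotate + translate + scale the plane: the area ratio is unchanged
    theta <- stats::runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    moved <- 3.7 * coords %*% rot + matrix(c(5, -2), n, 2, byrow = TRUE)
    colnames(moved) <- c("PC1", "PC2")
    pcs2 <- structure(list(sample_ids = ids, coords = moved,
                           eigenvalues = c(2, 1), n_variants_used = 0L),
                      class = "pca_coordinates")
    h1 <- hap(pcs, small)
    h2 <- hap(pcs2, small)
    expect_equal(h2$area_subset / h2$area_full,
                 h1$area_subset / h1$area_full, tolerance = 1e-9)
  }
})

test_that("inbreeding estimator hits the analytic limits at p = 0.5", {
  # reference rows chosen so every locus has dosage total 3 over the 3
  # samples, i.e. estimated p exactly 0.5; the focal sample is fully
  # homozygous (alternating 0/2) or fully heterozygous
  l <- 40
  hom <- rep(c(0L, 2L), l / 2)
  gm_hom <- genotype_matrix(rbind(rep(1L, l), 2L - hom, hom),
                            sample_ids = c("r1", "r2", "focal"))
  gm_het <- genotype_matrix(rbind(hom, 2L - hom, rep(1L, l)),
                            sample_ids = c("r1", "r2", "focal"))
  expect_equal(individual_inbreeding(gm_hom)$fhat[3], 1)
  expect_equal(individual_inbreeding(gm_het)$fhat[3], -1)
})

test_that("inbreeding estimator recovers the selfing expectation on synthetic panels", {
  # one selfing level per panel; estimates averaged over samples
  for (s in c(0, 2)) {
    fh <- sapply(1:2, function(seed) {
      panel <- generate_panel(synth_config(n_samples = 100, n_variants = 2000,
                                           selfing_gens = rep(s, 100),
                                           seed = 500 + 10 * s + seed))
      gm <- filter_variants(panel$gm, filter_spec())$gm
      mean(individual_inbreeding(gm)$fhat)
    })
    expect_lt(max(abs(fh - (1 - 0.5^s))), 0.05)
  }
})

test_that("correlate reproduces exact lines and the textbook formula", {
  x <- c(1, 2, 3, 4, 5)
  exact <- correlate(x, 2 * x + 1)
  expect_equal(exact$r, 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(correlate(x, -x)$r, -1)
  set.seed(50)
  xs <- stats::rnorm(50)
  ys <- 0.5 * xs + stats::rnorm(50)
  rep <- correlate(xs, ys)
  expect_equal(rep$r, pearson_oracle(xs, ys), tolerance = 1e-12)
  expect_equal(rep$r_squared, rep$r^2)
  expect_equal(rep$n, 50)
  # p-value agrees with the t transform
  tstat <- rep$r * sqrt((50 - 2) / (1 - rep$r^2))
  expect_equal(rep$p_value, 2 * stats::pt(-abs(tstat), 48), tolerance = 1e-12)
  expect_error(correlate(x, rep(1, 5)), class = "apd_domain_error")
  expect_error(correlate(c(1, 2), c(1, 2)), class = "apd_domain_error")
  # NA pairs dropped
  expect_equal(correlate(c(xs, NA), c(ys, 1))$n, 50)
})

test_that("APD and inbreeding are negatively correlated on a selfing-gradient panel", {
  panel <- generate_panel(synth_config(n_samples = 120, n_variants = 3000,
                                       seed = 71))
  gm <- filter_variants(panel$gm, filter_spec())$gm
  res <- apd_all(gm, metric = "smc")
  ibc <- individual_inbreeding(gm)
  rep <- correlate(res$apd, ibc$fhat)
  expect_lt(rep$r, 0)
  expect_lt(rep$p_value, 0.01)
})
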