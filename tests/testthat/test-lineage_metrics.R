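# a 2-D space whose projection is the identity, for exact hand arithmetic
identity_space <- function() {
  structure(list(
    loadings = matrix(diag(2), 2, 2,
                      dimnames = list(c("t1", "t2"), c("PC1", "PC2"))),
    explained_variance = c(2, 1), ccr = c(2 / 3, 1),
    center = c(t1 = 0, t2 = 0), scale = NULL, n_components = 2L,
    scores = NULL), class = "pheno_space")
}

test_that("euclidean distance is the plain L2 norm", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_error(euclidean_distance(1:3, 1:4), class = "ml_schema_error")
})

test_that("distance in a full-rank component space equals Z-space distance", {
  set.seed(601)
  m <- matrix(rnorm(8 * 16), 8, 16, dimnames = list(NULL, paste0("t", 1:16)))
  sp <- build_pca(m)
  sc <- project(sp, m)
  for (i in c(1, 3)) for (j in c(5, 8))
    expect_equal(euclidean_distance(sc[i, ], sc[j, ]),
                 euclidean_distance(m[i, ], m[j, ]), tolerance = 1e-8)
})

test_that("replicate-pair distances enumerate the full Cartesian product", {
  sp <- identity_space()
  mk <- function(n, shift = 0) {
    m <- matrix(rnorm(2 * n, shift), n, 2)
    colnames(m) <- c("t1", "t2"); m
  }
  set.seed(602)
  d55 <- strain_pair_distances(sp, mk(5), mk(5, 3), ccr_threshold = 1)
  expect_equal(d55$n_pairs, 25L)
  expect_length(d55$distances, 25L)
  d34 <- strain_pair_distances(sp, mk(3), mk(4), ccr_threshold = 1)
  expect_equal(d34$n_pairs, 12L)
  # stored mean/sd agree with the multiset
  expect_equal(d55$mean, mean(d55$distances), tolerance = 1e-10)
  expect_equal(d55$sd, sd(d55$distances), tolerance = 1e-10)
  # identical point clouds collapse to zero
  pt <- matrix(c(1, 2), 1, 2, dimnames = list(NULL, c("t1", "t2")))
  d0 <- strain_pair_distances(sp, pt, pt, ccr_threshold = 1)
  expect_equal(d0$mean, 0); expect_equal(d0$sd, 0)
  # symmetry: multisets agree up to ordering
  X <- mk(3); Y <- mk(4, 1)
  dxy <- strain_pair_distances(sp, X, Y, ccr_threshold = 1)
  dyx <- strain_pair_distances(sp, Y, X, ccr_threshold = 1)
  expect_equal(sort(dxy$distances), sort(dyx$distances), tolerance = 1e-12)
})

test_that("mid-parent points average every replicate pair", {
  a <- matrix(rnorm(10), 5, 2); b <- matrix(rnorm(10), 5, 2)
  mp <- midparent_points(a, b)
  expect_equal(nrow(mp), 25L)
  one <- midparent_points(matrix(c(0, 0), 1), matrix(c(2, 2), 1))
  expect_equal(as.numeric(one), c(1, 1))
  same <- midparent_points(matrix(c(1, 5), 1), matrix(c(1, 5), 1))
  expect_equal(as.numeric(same), c(1, 5))
  h <- matrix(rnorm(10), 5, 2)
  expect_equal(hybrid_midparent_distances(h, mp)$n_pairs, 125L)
  expect_equal(hybrid_midparent_distances(h[1:2, ], mp[1:3, ])$n_pairs, 6L)
  # hybrid sitting exactly on a single shared midpoint
  hm <- hybrid_midparent_distances(matrix(c(1, 1), 1),
                                   matrix(c(1, 1), 1))
  expect_equal(hm$mean, 0)
})

test_that("cross-distance ratio reproduces hand geometry", {
  sp <- identity_space()
  A <- matrix(c(0, 0), 1, dimnames = list(NULL, c("t1", "t2")))
  B <- matrix(c(2, 0), 1, dimnames = list(NULL, c("t1", "t2")))
  at_mid <- matrix(c(1, 0), 1, dimnames = list(NULL, c("t1", "t2")))
  r0 <- cross_distance_ratio(A, B, at_mid, sp, ccr_threshold = 1)
  expect_equal(r0$mean, 0)
  r_half <- cross_distance_ratio(A, B, A, sp, ccr_threshold = 1)
  expect_equal(r_half$mean, 0.5)
  expect_equal(r_half$n, 1L)
  expect_error(cross_distance_ratio(A, A, at_mid, sp, ccr_threshold = 1),
               class = "ml_undefined_ratio_error")
  # the paired-denominator variant agrees in the single-replicate case
  r_paired <- cross_distance_ratio(A, B, A, sp, ccr_threshold = 1,
                                   denominator = "paired")
  expect_equal(r_paired$mean, 0.5)
})

test_that("mean cross ratio grows with isotropic deviation from mid-parent", {
  sp <- identity_space()
  A <- matrix(rep(c(0, 0), 5), 5, 2, byrow = TRUE,
              dimnames = list(NULL, c("t1", "t2")))
  B <- matrix(rep(c(4, 0), 5), 5, 2, byrow = TRUE,
              dimnames = list(NULL, c("t1", "t2")))
  means <- vapply(c(0.5, 1, 2), function(sig) {
    h <- generate_segregant_panel(c(0, 0), c(4, 0), 40, sig, seed = 603)
    colnames(h) <- c("t1", "t2")
    cross_distance_ratio(A, B, h, sp, ccr_threshold = 1)$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("distances scale equivariantly and ratios are scale-free", {
  set.seed(604)
  sp <- identity_space()
  A <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("t1", "t2")))
  B <- matrix(rnorm(10, 3), 5, 2, dimnames = list(NULL, c("t1", "t2")))
  H <- matrix(rnorm(10, 1.5), 5, 2, dimnames = list(NULL, c("t1", "t2")))
  lam <- 2.7
  d1 <- strain_pair_distances(sp, A, B, 1)
  d2 <- strain_pair_distances(sp, lam * A, lam * B, 1)
  expect_equal(d2$distances, lam * d1$distances, tolerance = 1e-10)
  r1 <- cross_distance_ratio(A, B, H, sp, 1)
  r2 <- cross_distance_ratio(lam * A, lam * B, lam * H, sp, 1)
  expect_equal(r2$ratios, r1$ratios, tolerance = 1e-10)
})

test_that("strain-mean score triples satisfy the triangle inequality", {
  set.seed(605)
  pts <- matrix(rnorm(30), 10, 3)
  for (tri in list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9), c(2, 5, 8))) {
    d12 <- euclidean_distance(pts[tri[1], ], pts[tri[2], ])
    d13 <- euclidean_distance(pts[tri[1], ], pts[tri[3], ])
    d23 <- euclidean_distance(pts[tri[2], ], pts[tri[3], ])
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("Mann-Whitney location test matches enumeration and has power", {
  # {1,2,3} vs {4,5,6}: U = 0; 2 of the C(6,3)=20 equally likely rank
  # assignments are as extreme, so the exact two-sided p is 0.1
  r <- group_location_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_true(r$exact)
  same <- group_location_test(c(1.5, 2.5, 3.5), c(1.5, 2.5, 3.5))
  expect_gt(same$p_value, 0.9)
  expect_error(group_location_test(numeric(), 1:3),
               class = "ml_insufficient_data_error")
  # shifted alternative: delta = 2 SD, n = 12 vs 15
  set.seed(606)
  rej <- mean(replicate(200, {
    group_location_test(rnorm(12), rnorm(15, 2))$p_value < 0.05
  }))
  expect_gt(rej, 0.9)
})

test_that("cell volume follows the three-halves power of projected area", {
  r <- 1.7
  expect_equal(cell_volume_from_area(pi * r^2), 4 / 3 * pi * r^3,
               tolerance = 1e-12)
  a <- 12.3
  expect_equal(cell_volume_from_area(2 * a) / cell_volume_from_area(a),
               2 * sqrt(2), tolerance = 1e-12)
  expect_lt(cell_volume_from_area(1e-12), 1e-15)
  expect_error(cell_volume_from_area(-1), class = "ml_domain_error")
  expect_error(cell_volume_from_area(0), class = "ml_domain_error")
})

test_that("the lineage distance table covers every measurable edge", {
  env <- cached_default_cohort()
  shared <- colnames(env$zs)
  dt <- lineage_distance_table(env$space, env$zr[, shared],
                               env$cohort$lineage, 0.9)
  e <- env$cohort$lineage$edges
  # one parent row per single parent plus parent rows + midparent per cross
  n_cross <- sum(e$breeding_type %in% c("cross", "cross_mutagen"))
  expect_equal(nrow(dt),
               sum(!e$breeding_type %in% c("cross", "cross_mutagen")) +
                 n_cross * 3L)
  expect_true(all(dt$n_pairs[dt$comparison == "parent"] == 25L))
  expect_true(all(dt$n_pairs[dt$comparison == "midparent"] == 125L))
  expect_true(all(dt$mean >= 0))
})
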