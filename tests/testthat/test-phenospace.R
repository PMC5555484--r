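test_that("explained-variance shares match an analytic covariance oracle", {
  set.seed(501)
  n <- 4000
  m <- cbind(rnorm(n, 0, 2), rnorm(n, 0, sqrt(3)), rnorm(n, 0, sqrt(2)),
             rnorm(n, 0, 1))
  colnames(m) <- paste0("t", 1:4)
  sp <- build_pca(m)
  shares <- sp$explained_variance / sum(sp$explained_variance)
  expect_equal(shares, c(0.4, 0.3, 0.2, 0.1), tolerance = 0.05)
  # smallest k at CCR 0.6 from the analytic shares: cumsums 0.4, 0.7
  expect_equal(components_for_ccr(sp, 0.6), 2L)
  expect_equal(components_for_ccr(sp, 1.0), sp$n_components)
  expect_equal(components_for_ccr(sp, 0.2), 1L)
})

test_that("rank and degeneracy are handled", {
  line <- outer(seq_len(10), c(1, 2, 3))   # rows on a line through 0
  colnames(line) <- paste0("t", 1:3)
  sp <- build_pca(line)
  expect_equal(sp$n_components, 1L)
  expect_equal(sp$ccr[sp$n_components], 1, tolerance = 1e-10)
  flat <- matrix(1, 5, 3, dimnames = list(NULL, paste0("t", 1:3)))
  expect_error(build_pca(flat), class = "ml_degenerate_space_error")
  expect_error(build_pca(matrix(c(1, NA, 2, 3), 2, 2,
                                dimnames = list(NULL, c("a", "b")))),
               class = "ml_domain_error")
})

test_that("the component space is an isometry of Z space", {
  set.seed(502)
  m <- matrix(rnorm(30 * 50), 30, 50,
              dimnames = list(NULL, paste0("t", 1:50)))
  sp <- build_pca(m)
  sc <- project(sp, m)
  dz <- as.matrix(dist(m))
  ds <- as.matrix(dist(sc))
  expect_lt(max(abs(dz - ds)), 1e-8)
})

test_that("projection is consistent, centered and complete", {
  set.seed(503)
  m <- matrix(rnorm(12 * 9), 12, 9, dimnames = list(NULL, paste0("t", 1:9)))
  sp <- build_pca(m)
  expect_equal(project(sp, m), sp$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(as.numeric(project(sp, sp$center)),
               rep(0, sp$n_components), tolerance = 1e-10)
  recon <- sp$scores %*% t(sp$loadings)
  recon <- sweep(recon, 2, sp$center, `+`)
  expect_equal(unname(recon), unname(m), tolerance = 1e-8)
  # trait mismatch is a schema error
  bad <- m[, 1:5]
  expect_error(project(sp, bad), class = "ml_schema_error")
})

test_that("loadings are orthonormal and the sign convention is
           deterministic", {
  set.seed(504)
  m <- matrix(rnorm(15 * 8), 15, 8, dimnames = list(NULL, paste0("t", 1:8)))
  sp1 <- build_pca(m)
  G <- crossprod(sp1$loadings)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_true(all(diff(sp1$explained_variance) <= 1e-12))
  expect_true(all(diff(sp1$ccr) >= -1e-12))
  sp2 <- build_pca(m)
  expect_identical(sp1$loadings, sp2$loadings)
  # per-component largest-|loading| entry is positive
  tops <- vapply(seq_len(sp1$n_components), function(k) {
    v <- sp1$loadings[, k]; v[which.max(abs(v))]
  }, numeric(1))
  expect_true(all(tops > 0))
})

test_that("components_for_ccr is monotone in the threshold", {
  set.seed(505)
  m <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(NULL, paste0("t", 1:10)))
  sp <- build_pca(m)
  ks <- vapply(seq(0.1, 1, by = 0.1), components_for_ccr, integer(1),
               space = sp)
  expect_true(all(diff(ks) >= 0))
})

test_that("variance ratios behave under identity, scaling and known truth", {
  set.seed(506)
  a <- matrix(rnorm(200 * 3), 200, 3)
  expect_equal(unname(variance_ratio(a, a)$per_component), rep(1, 3))
  expect_equal(variance_ratio(a, a)$cumulative, 1)
  vr <- variance_ratio(2 * a, a)
  expect_equal(unname(vr$per_component), rep(4, 3), tolerance = 1e-10)
  expect_equal(vr$cumulative, 4, tolerance = 1e-10)
  # simulated per-axis variances 4 and 1 against 1 and 1
  b <- cbind(rnorm(200, 0, 2), rnorm(200))
  c_ <- cbind(rnorm(200), rnorm(200))
  vr2 <- variance_ratio(b, c_, upto = 2)
  expect_lt(abs(vr2$per_component[1] - 4), 1.5)
  expect_lt(abs(vr2$per_component[2] - 1), 0.4)
  zerovar <- cbind(rep(1, 10), rnorm(10))
  expect_error(variance_ratio(a[, 1:2], zerovar),
               class = "ml_undefined_ratio_error")
})

test_that("reference-replicate PCA groups traits by shared components", {
  set.seed(507)
  # two orthogonal blocks: traits 1-3 driven by factor f1, 4-6 by f2
  n <- 40
  f1 <- rnorm(n); f2 <- rnorm(n)
  m <- cbind(f1, f1 * 1.1, f1 * 0.9, f2, f2 * 1.2, f2 * 0.8) +
    matrix(rnorm(n * 6, 0, 0.05), n, 6)
  colnames(m) <- paste0("t", 1:6)
  g <- group_traits_by_reference_pca(m, colnames(m))
  expect_equal(g$n_groups, 2L)
  grp_of <- g$assignment
  expect_length(unique(grp_of[1:3]), 1L)
  expect_length(unique(grp_of[4:6]), 1L)
  expect_false(grp_of[1] == grp_of[4])

  # perfectly correlated pair collapses to one group
  m2 <- cbind(t1 = f1, t2 = 2 * f1 + 1)
  expect_equal(group_traits_by_reference_pca(m2, c("t1", "t2"))$n_groups, 1L)
  # a single candidate is its own group
  expect_equal(group_traits_by_reference_pca(m, "t1")$n_groups, 1L)
  expect_error(group_traits_by_reference_pca(m[1:2, ], colnames(m)),
               class = "ml_insufficient_data_error")
})

test_that("a phenotypic space serializes to readable tables", {
  set.seed(508)
  m <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, paste0("t", 1:6)))
  sp <- build_pca(m)
  d <- withr::local_tempdir()
  write_pheno_space(sp, d)
  lo <- read.table(file.path(d, "loadings.tsv"), header = TRUE, sep = "\t",
                   check.names = FALSE)
  expect_equal(as.matrix(lo[-1]), sp$loadings, ignore_attr = TRUE,
               tolerance = 1e-12)
  va <- read.table(file.path(d, "variance.tsv"), header = TRUE, sep = "\t")
  expect_equal(va$ccr, sp$ccr, tolerance = 1e-12)
})
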