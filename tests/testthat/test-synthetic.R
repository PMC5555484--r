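test_that("the same seed reproduces the cohort byte for byte", {
  spec <- synthetic_spec(founders = c("A", "B"),
                         events = list(list(child = "AB", type = "cross",
                                            parents = c("A", "B"))),
                         seed = 77)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(as.data.frame(c1$table), as.data.frame(c2$table))
  expect_identical(unclass(c1$genotypes), unclass(c2$genotypes))
  expect_identical(c1$truth$effects, c2$truth$effects)
  c3 <- generate_cohort(synthetic_spec(founders = c("A", "B"),
                                       events = spec$events, seed = 78))
  expect_false(identical(as.data.frame(c1$table), as.data.frame(c3$table)))
})

test_that("record counts and value domains match the requested cohort geometry", {
  spec <- synthetic_spec(founders = c("A", "B"), events = list(), seed = 79)
  coh <- generate_cohort(spec)
  tab <- coh$table
  expect_equal(nrow(tab), spec$n_ref_replicates + 2 * spec$n_replicates)
  expect_equal(sum(tab$strain == "reference"), 11L)
  cat <- attr(tab, "catalog")
  vals <- as.matrix(as.data.frame(tab)[cat$trait_id])
  prop <- cat$trait_id[cat$family_class == "proportion"]
  pos <- cat$trait_id[cat$family_class == "positive"]
  expect_true(all(vals[, prop] >= 0 & vals[, prop] <= 1))
  expect_true(all(vals[, pos] > 0))
  expect_true(all(is.finite(vals)))
})

test_that("a fully null cohort passes the Bonferroni screen silently", {
  coh <- generate_cohort(null_cohort_spec(seed = 80, n_strains = 2))
  zs <- z_matrix(coh$table, mode = "strain")
  expect_lte(length(wald_screen(zs, alpha = 0.05)), 1L)
  # and strain Z values are centred near zero
  expect_lt(abs(mean(unclass(zs)[-1, ])), 0.1)
})

test_that("ground truth records every injected effect", {
  spec <- mutation_breeding_spec(seed = 81)
  coh <- generate_cohort(spec)
  tr <- coh$truth
  expect_length(tr$events$SP$traits, spec$k_spontaneous)
  expect_length(tr$events$MU$traits, spec$k_mutagen)
  expect_true(all(tr$effects["SP", tr$events$SP$traits] !=
                    tr$effects["K7", tr$events$SP$traits]))
  # children inherit the parent's founder deviations
  inherited <- tr$events$K7$traits
  expect_equal(tr$effects["SP", setdiff(inherited, tr$events$SP$traits)],
               tr$effects["K7", setdiff(inherited, tr$events$SP$traits)])
})

test_that("mutagen children move farther from the parent than spontaneous
           children in one cohort", {
  coh <- generate_cohort(mutation_breeding_spec(seed = 82))
  zs <- z_matrix(coh$table, mode = "strain")
  zr <- z_matrix(coh$table, mode = "replicate")
  shared <- intersect(colnames(zs), colnames(zr))
  sp <- build_pca(zs[, shared])
  dt <- lineage_distance_table(sp, zr[, shared], coh$lineage, 0.9)
  expect_gt(dt$mean[dt$child == "MU"], dt$mean[dt$child == "SP"])
})

test_that("genotypes mutate along the lineage so distance tracks descent", {
  coh <- cached_default_cohort()$cohort
  g <- coh$genotypes
  d <- function(a, b) snp_difference_proportion(g, c(a, b))
  expect_lt(d("K601", "K6"), d("K601", "K9"))
  expect_lt(d("K13", "K9"), d("K13", "K6"))
  expect_gt(d("K6", "K9"), 0)
})

test_that("segregant panels honour their size, seed and deviation", {
  a <- c(0, 0, 0); b <- c(4, 0, 0)
  s0 <- generate_segregant_panel(a, b, 10, 0, seed = 5)
  expect_equal(nrow(s0), 10L)
  mid <- (a + b) / 2
  expect_true(all(apply(s0, 1, function(r) all(r == mid))))
  s62 <- generate_segregant_panel(a, b, 62, 1, seed = 5)
  expect_equal(nrow(s62), 62L)
  expect_identical(generate_segregant_panel(a, b, 62, 1, seed = 5), s62)
  # ratio mean grows with the deviation
  ratio_mean <- vapply(c(0.5, 1, 2), function(sig) {
    s <- generate_segregant_panel(a, b, 62, sig, seed = 6)
    mean(apply(s, 1, function(r) euclidean_distance(r, mid))) /
      euclidean_distance(a, b)
  }, numeric(1))
  expect_true(all(diff(ratio_mean) > 0))
  expect_error(generate_segregant_panel(a, b, 0, 1),
               class = "ml_spec_error")
  # matrix parents are averaged
  am <- rbind(a + c(0.1, 0, 0), a - c(0.1, 0, 0))
  expect_equal(generate_segregant_panel(am, b, 3, 0, seed = 7)[1, ],
               mid, ignore_attr = TRUE)
})

test_that("spec validation rejects malformed scenarios", {
  expect_error(synthetic_spec(events = list(list(child = "X",
                                                 type = "cross",
                                                 parents = "A"))),
               class = "ml_spec_error")
  expect_error(synthetic_spec(sd_gaussian = 0), class = "ml_spec_error")
  expect_error(synthetic_spec(delta = -1), class = "ml_spec_error")
  expect_error(generate_cohort(synthetic_spec(
    founders = "A",
    events = list(list(child = "B", type = "spontaneous",
                       parents = "MISSING")), seed = 1)),
    class = "ml_spec_error")
})
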