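test_that("gaussian strain contrast equals the OLS closed form", {
  y0 <- c(1.2, 0.8, 1.1, 0.9, 1.0, 1.3, 0.7, 1.05, 0.95, 1.15, 1.0)
  y1 <- c(1.9, 2.2, 2.0, 2.1, 1.8)
  d <- data.frame(strain = rep(c("reference", "K7"), c(11, 5)))
  fit <- fit_trait_glm(c(y0, y1), d, design = "strain", family = "gaussian")
  expect_equal(unname(fit$coefficients[["strainK7"]]),
               mean(y1) - mean(y0), tolerance = 1e-12)
  expect_equal(wald_z(fit, "strainK7"), ols_wald_oracle(y0, y1),
               tolerance = 1e-8)
  # zero standard error request on a missing term errors
  expect_error(wald_z(fit, "strainK9"), class = "ml_design_error")
})

test_that("identical value sets across levels give zero contrast and zero Z", {
  y <- rep(c(1, 2, 3), 2)
  d <- data.frame(strain = rep(c("reference", "A"), each = 3))
  fit <- fit_trait_glm(y, d, design = "strain", family = "gaussian")
  expect_equal(unname(fit$coefficients[["strainA"]]), 0, tolerance = 1e-12)
  expect_equal(wald_z(fit, "strainA"), 0, tolerance = 1e-12)
})

test_that("gamma-log fit recovers a known multiplicative effect", {
  set.seed(401)
  n <- 200
  shape <- 25
  d <- data.frame(strain = rep(c("reference", "A"), each = n / 2))
  mu <- ifelse(d$strain == "A", 1.5, 1)   # exp(beta) = 1.5
  y <- rgamma(n, shape = shape, rate = shape / mu)
  fit <- fit_trait_glm(y, d, design = "strain", family = "gamma")
  b <- fit$coefficients[["strainA"]]
  se <- fit$standard_errors[["strainA"]]
  expect_lt(abs(b - log(1.5)), 3 * se)
  expect_gt(wald_z(fit, "strainA"), 3)
})

test_that("beta regression matches the mgcv beta-family oracle", {
  skip_if_not_installed("mgcv")
  set.seed(402)
  d <- data.frame(strain = rep(c("reference", "A", "B"), c(11, 5, 5)))
  eta <- c(A = 0.8, B = -0.5, reference = 0)[d$strain]
  mu <- plogis(qlogis(0.4) + eta)
  y <- rbeta(nrow(d), mu * 60, (1 - mu) * 60)
  fit <- fit_trait_glm(y, d, design = "strain", family = "beta")
  or <- mgcv::gam(y ~ strain,
                  data = transform(d, strain = relevel(factor(strain),
                                                       "reference")),
                  family = mgcv::betar(link = "logit"))
  expect_equal(unname(fit$coefficients),
               unname(coef(or)), tolerance = 0.03)
  expect_equal(unname(fit$standard_errors),
               unname(summary(or)$p.table[, "Std. Error"]), tolerance = 0.1)
  expect_equal(fit$log_likelihood, as.numeric(logLik(or)), tolerance = 0.02)
})

test_that("AIC model selection finds the generating design and is
           parsimonious under the null", {
  set.seed(403)
  cands <- list(list(terms = character()), list(terms = "strain"))
  pick <- function(y, d) {
    sel <- select_model_aic(y, d, cands, family = "gaussian")
    length(sel$design$terms)
  }
  d <- data.frame(strain = rep(c("reference", "A"), each = 50))
  # strong strain effect: strain design must win
  n_strain <- sum(replicate(30, {
    y <- rnorm(100, ifelse(d$strain == "A", 1.5, 0))
    pick(y, d) == 1
  }))
  expect_gte(n_strain, 28)
  # pure noise: intercept-only wins in the majority
  n_null <- sum(replicate(30, pick(rnorm(100), d) == 0))
  expect_gte(n_null, 16)
})

test_that("AIC ties break toward the smaller design", {
  set.seed(404)
  d <- data.frame(strain = rep(c("reference", "A"), each = 10))
  y <- rnorm(20, ifelse(d$strain == "A", 5, 0))
  cands <- list(list(terms = "strain"), list(terms = character()))
  sel <- select_model_aic(y, d, cands, family = "gaussian")
  expect_equal(sel$design$terms, "strain")
  # with an infinite tie window every candidate ties: fewest parameters wins
  sel_tie <- select_model_aic(y, d, cands, family = "gaussian", tol = Inf)
  expect_length(sel_tie$design$terms, 0)
})

test_that("AIC definition holds on every family", {
  set.seed(405)
  d <- data.frame(strain = rep(c("reference", "A"), c(11, 5)))
  for (fam in c("gaussian", "gamma", "beta")) {
    y <- switch(fam,
                gaussian = rnorm(16),
                gamma = rgamma(16, 20, 20),
                beta = rbeta(16, 30, 30))
    fit <- fit_trait_glm(y, d, design = "strain", family = fam)
    expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * fit$n_params,
                 tolerance = 1e-8)
    expect_true(all(fit$standard_errors > 0))
  }
})

test_that("Z matrices are invariant to replicate relabeling", {
  coh <- generate_cohort(synthetic_spec(founders = c("A", "B"),
                                        events = list(), seed = 31))
  tab <- coh$table
  sub <- attr(tab, "catalog")$trait_id[c(1:6, 100:105, 200:205, 300:305)]
  z1 <- z_matrix(tab, mode = "strain", traits = sub)
  df <- as.data.frame(tab)
  df$replicate <- ave(df$replicate, df$strain,
                      FUN = function(r) rev(r))   # relabel within strains
  z2 <- z_matrix(trait_table(df, attr(tab, "catalog")), mode = "strain",
                 traits = sub)
  expect_equal(unclass(z1), unclass(z2), tolerance = 1e-10)
})

test_that("medium adjustment removes a purely additive medium shift", {
  base <- synthetic_spec(founders = "A", events = list(),
                         strain_media = c(A = "SD"), medium_effect = 0,
                         seed = 55)
  cat <- base$catalog
  unb <- cat$trait_id[cat$family_class == "unbounded"][1:15]
  tab0 <- generate_cohort(base)$table
  # impose a purely additive medium shift on the gaussian traits
  df <- as.data.frame(tab0)
  df[df$medium == "SD", unb] <- df[df$medium == "SD", unb] + 3
  tab3 <- trait_table(df, cat)
  z0 <- medium_adjusted_z(tab0, traits = unb)
  z3 <- medium_adjusted_z(tab3, traits = unb)
  expect_equal(unclass(z0)["A", ], unclass(z3)["A", ], tolerance = 1e-8)
})

test_that("a zero medium effect leaves Z close to the one-way fit", {
  spec <- synthetic_spec(founders = c("A", "B"), events = list(),
                         strain_media = c(A = "SD", B = "YPD"),
                         medium_effect = 0, seed = 56)
  tab <- generate_cohort(spec)$table
  sub <- spec$catalog$trait_id[seq(1, 501, by = 25)]
  z_adj <- z_matrix(tab, mode = "strain", media_adjust = "always",
                    traits = sub)
  z_raw <- z_matrix(tab, mode = "strain", media_adjust = "never",
                    traits = sub)
  expect_gt(cor(unclass(z_adj)["A", ], unclass(z_raw)["A", ]), 0.9)
  expect_lt(mean(abs(unclass(z_adj)["A", ] - unclass(z_raw)["A", ])), 0.5)
})

test_that("a strain grown in a medium without reference observations is a
           design error", {
  spec <- synthetic_spec(founders = "A", events = list(), seed = 57)
  tab <- generate_cohort(spec)$table
  df <- as.data.frame(tab)
  df$medium[df$strain == "A"] <- "SD"   # reference never saw SD
  tab2 <- trait_table(df, attr(tab, "catalog"))
  expect_error(medium_adjusted_z(tab2), class = "ml_design_error")
})

test_that("likelihood-ratio screen keeps its boundary behavior", {
  set.seed(406)
  d <- data.frame(strain = rep(c("reference", "A"), each = 6))
  m <- 20
  fits_full <- fits_reduced <- stats::setNames(vector("list", m),
                                               paste0("t", seq_len(m)))
  for (i in seq_len(m)) {
    eff <- if (i == 7) 8 else 0     # one huge effect among nulls
    y <- rnorm(12, ifelse(d$strain == "A", eff, 0))
    fits_full[[i]] <- fit_trait_glm(y, d, "strain", family = "gaussian")
    fits_reduced[[i]] <- fit_trait_glm(y, d, character(),
                                       family = "gaussian")
  }
  hit <- lrt_screen(fits_full, fits_reduced, alpha = 0.05)
  expect_equal(as.character(hit), "t7")
  # alpha = 1 without correction returns every trait
  expect_length(lrt_screen(fits_full, fits_reduced, alpha = 1,
                           correction = "none"), m)
  # a fit pair with equal likelihoods contributes LR = 0, never flagged
  y_flat <- rep(c(1, 2, 3, 1, 2, 3), 2)[1:12]
  f_full <- fit_trait_glm(y_flat, d, "strain", family = "gaussian")
  f_red <- fit_trait_glm(y_flat, d, character(), family = "gaussian")
  expect_length(lrt_screen(list(t = f_full), list(t = f_red), alpha = 0.05),
                0)
  # non-nested (reversed) designs error
  expect_error(lrt_screen(list(t = f_red), list(t = f_full)),
               class = "ml_design_error")
})

test_that("the Bonferroni Wald screen never flags a trait whose unadjusted
           p exceeds alpha", {
  coh <- generate_cohort(synthetic_spec(founders = "A", events = list(),
                                        founder_delta = 4, seed = 58))
  zs <- z_matrix(coh$table, mode = "strain")
  alpha <- 0.05
  hit <- wald_screen(zs, alpha = alpha)
  expect_gt(length(hit), 0)
  p <- attr(hit, "p")
  expect_true(all(p[hit] <= alpha))
})
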