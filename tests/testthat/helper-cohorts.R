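# Shared fixtures, built in code at test time.

# a cohort with no injected effects anywhere: every strain is statistically
# identical to the reference
null_cohort_spec <- function(seed, n_strains = 1L) {
  synthetic_spec(founders = paste0("S", seq_len(n_strains)), events = list(),
                 founder_delta = 0, founder_k_traits = 0, seed = seed)
}

# parent with one spontaneous (few traits) and one mutagen (many traits)
# child, same per-trait effect size
mutation_breeding_spec <- function(seed, delta = 1) {
  synthetic_spec(
    founders = "K7",
    events = list(
      list(child = "SP", type = "spontaneous", parents = "K7", delta = delta),
      list(child = "MU", type = "mutagen", parents = "K7", delta = delta)),
    founder_delta = 1, seed = seed)
}

# small default cohort reused by expensive-ish module tests
cached_default_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      coh <- generate_cohort(synthetic_spec(seed = 20260901))
      zs <- z_matrix(coh$table, mode = "strain")
      zr <- z_matrix(coh$table, mode = "replicate")
      memo <<- list(cohort = coh, zs = zs, zr = zr,
                    space = build_pca(zs[, intersect(colnames(zs),
                                                     colnames(zr))]))
    }
    memo
  }
})

# hand OLS two-group Wald statistic: (m1 - m0) / (s_p sqrt(1/n0 + 1/n1))
ols_wald_oracle <- function(y0, y1) {
  n0 <- length(y0); n1 <- length(y1)
  sp2 <- (sum((y0 - mean(y0))^2) + sum((y1 - mean(y1))^2)) / (n0 + n1 - 2)
  (mean(y1) - mean(y0)) / sqrt(sp2 * (1 / n0 + 1 / n1))
}
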