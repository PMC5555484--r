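#' Pairwise SNP-difference proportion
#'
#' Genetic distance between two strains: the fraction of co-called
#' biallelic sites at which their diploid genotype codes (0/1/2
#' alternate-allele counts) differ. Sites missing in either strain are
#' excluded pairwise. An \code{"allele_sharing"} variant instead averages
#' \eqn{|g_1 - g_2|/2} over co-called sites.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param pair length-2 character vector of strain ids.
#' @param method \code{"code_difference"} (default) or
#'   \code{"allele_sharing"}.
#' @return distance in [0, 1].
#' @export
snp_difference_proportion <- function(genotypes, pair,
                                      method = c("code_difference",
                                                 "allele_sharing")) {
  method <- match.arg(method)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  miss <- setdiff(pair, rownames(genotypes))
  if (length(miss))
    ml_stop("ml_schema_error",
            paste0("strain(s) absent from genotypes: ",
                   paste(miss, collapse = ", ")))
  g1 <- genotypes[pair[1], ]
  g2 <- genotypes[pair[2], ]
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok))
    ml_stop("ml_undefined_distance_error",
            paste0("no co-called sites for pair ", pair[1], "/", pair[2]))
  if (method == "code_difference") mean(g1[ok] != g2[ok])
  else mean(abs(g1[ok] - g2[ok]) / 2)
}

#' Genotype-phenotype pairwise comparisons
#'
#' For every pair of strains present in both inputs, computes the
#' SNP-difference proportion and the phenotypic similarity — the Pearson
#' correlation of the two strains' component scores over the leading
#' components at the given CCR (conventionally 90\%).
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param space a \code{\link{build_pca}} result built from strain-level Z.
#' @param z strain-level Z matrix to project (defaults to the space's
#'   training scores via row names).
#' @param ccr_threshold CCR selecting the component count (default 0.90).
#' @param strains optional subset of strains to compare.
#' @param method genetic-distance coding, see
#'   \code{\link{snp_difference_proportion}}.
#' @return data.frame with columns \code{strain1}, \code{strain2},
#'   \code{genetic_distance}, \code{phenotypic_similarity}; one row per
#'   unordered pair (n strains give choose(n, 2) rows).
#' @export
pairwise_comparisons <- function(genotypes, space, z = NULL,
                                 ccr_threshold = 0.90, strains = NULL,
                                 method = "code_difference") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  k <- max(components_for_ccr(space, ccr_threshold), 2L)
  sc <- if (is.null(z)) space$scores[, seq_len(k), drop = FALSE]
  else project(space, z, components = k)
  strains <- strains %||% intersect(rownames(sc), rownames(genotypes))
  if (length(strains) < 3L)
    ml_stop("ml_insufficient_data_error",
            "need >= 3 strains shared between genotypes and scores")
  pairs <- utils::combn(sort(strains), 2)
  out <- data.frame(strain1 = pairs[1, ], strain2 = pairs[2, ])
  out$genetic_distance <- vapply(seq_len(ncol(pairs)), function(i)
    snp_difference_proportion(genotypes, pairs[, i], method = method),
    numeric(1))
  out$phenotypic_similarity <- vapply(seq_len(ncol(pairs)), function(i)
    stats::cor(sc[pairs[1, i], ], sc[pairs[2, i], ]), numeric(1))
  out
}

#' Rank correlation and regression of phenotypic similarity on genetic
#' distance
#'
#' Kendall's tau-b (tie-corrected, two-sided test) between genetic distance
#' and phenotypic similarity, plus the ordinary least-squares line of
#' similarity on distance.
#'
#' @param comparisons data.frame from \code{\link{pairwise_comparisons}}
#'   (needs \code{genetic_distance} and \code{phenotypic_similarity},
#'   >= 3 rows).
#' @return list with \code{tau}, \code{p_value}, \code{slope},
#'   \code{intercept}, \code{n_pairs}.
#' @export
geno_pheno_correlation <- function(comparisons) {
  req <- c("genetic_distance", "phenotypic_similarity")
  if (!all(req %in% names(comparisons)) || nrow(comparisons) < 3L)
    ml_stop("ml_insufficient_data_error",
            "need >= 3 pairwise comparisons with distance and similarity")
  x <- comparisons$genetic_distance
  y <- comparisons$phenotypic_similarity
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ml_stop("ml_undefined_correlation_error",
            "constant distance or similarity vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", alternative = "two.sided"))
  fit <- stats::lm(y ~ x)
  list(tau = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_pairs = nrow(comparisons))
}
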