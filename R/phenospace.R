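#' Build the orthogonal phenotypic space by PCA
#'
#' Principal component analysis of Z-profiles produces the "degenerated"
#' orthogonal phenotypic space in which all distance and clustering analyses
#' run: components are uncorrelated, so Euclidean distances are not biased
#' by correlation between morphological traits. The rows are centered but
#' not rescaled (the GLM stage already put every trait on the Wald-Z scale);
#' rescaling is available for inputs on heterogeneous scales.
#'
#' Components are ordered by explained variance; components beyond the
#' numerical rank (singular value below \code{1e-10} times the largest) are
#' dropped. A deterministic sign convention — the largest-magnitude loading
#' of each component is positive — makes the decomposition reproducible
#' across runs and platforms.
#'
#' @param z a \code{\link{z_matrix}} or plain numeric matrix (rows =
#'   strains or replicates, columns = traits).
#' @param rescale also divide each trait column by its standard deviation.
#' @return A \code{pheno_space}: list with \code{loadings} (traits x
#'   components, orthonormal columns), \code{explained_variance}
#'   (nonincreasing), \code{ccr} (cumulative contribution ratio, ending at
#'   1), \code{center}, \code{scale}, \code{n_components}, \code{scores}
#'   (the training rows' coordinates).
#' @export
build_pca <- function(z, rescale = FALSE) {
  m <- unclass(z)
  if (!is.matrix(m) || nrow(m) < 2L)
    ml_stop("ml_design_error", "PCA needs at least 2 rows")
  if (any(!is.finite(m)))
    ml_stop("ml_domain_error", "PCA input contains non-finite entries")
  pr <- stats::prcomp(m, center = TRUE, scale. = rescale)
  if (pr$sdev[1] <= 1e-12 * max(1, max(abs(m))))
    ml_stop("ml_degenerate_space_error", "all rows identical: rank-0 input")
  keep <- pr$sdev >= 1e-10 * pr$sdev[1]
  load <- pr$rotation[, keep, drop = FALSE]
  sdev <- pr$sdev[keep]
  # sign convention: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(ncol(load)), function(k) {
    v <- load[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  load <- sweep(load, 2, flip, `*`)
  ev <- sdev^2
  scores <- sweep(m, 2, pr$center)
  if (rescale) scores <- sweep(scores, 2, pr$scale, `/`)
  scores <- scores %*% load
  structure(list(loadings = load,
                 explained_variance = ev,
                 ccr = cumsum(ev) / sum(ev),
                 center = pr$center,
                 scale = if (rescale) pr$scale else NULL,
                 n_components = ncol(load),
                 scores = scores),
            class = "pheno_space")
}

#' @export
print.pheno_space <- function(x, ...) {
  cat(sprintf("<pheno_space> %d traits -> %d components\n",
              nrow(x$loadings), x$n_components))
  k <- min(6L, x$n_components)
  cat("  CCR:", paste(sprintf("PC%d=%.0f%%", seq_len(k), 100 * x$ccr[1:k]),
                      collapse = " "), "\n")
  invisible(x)
}

#' Number of components reaching a cumulative contribution ratio
#'
#' The smallest k such that the first k components explain at least
#' \code{threshold} of the total variance. The field's conventional
#' thresholds are 0.60 for clustering, 0.90 for distance analyses.
#'
#' @param space a \code{\link{build_pca}} result.
#' @param threshold CCR threshold in (0, 1].
#' @return integer k.
#' @export
components_for_ccr <- function(space, threshold) {
  stopifnot(inherits(space, "pheno_space"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    ml_stop("ml_domain_error", "threshold must be in (0, 1]")
  which(space$ccr >= threshold - 1e-12)[1]
}

#' Project Z-profiles onto the phenotypic space
#'
#' Scores are \code{(z - center) \%*\% loadings}, restricted to the
#' requested components. The projected rows must carry the same traits the
#' space was built from.
#'
#' @param space a \code{\link{build_pca}} result.
#' @param z matrix (or single row) of Z values over the space's traits.
#' @param components integer vector or count of leading components; default
#'   all.
#' @return numeric score matrix (rows x components).
#' @export
project <- function(space, z, components = NULL) {
  stopifnot(inherits(space, "pheno_space"))
  m <- unclass(z)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                   dimnames = list(NULL, names(z)))
  if (!is.null(colnames(m))) {
    if (!setequal(colnames(m), names(space$center)))
      ml_stop("ml_schema_error",
              "projected rows do not carry the space's trait set")
    m <- m[, names(space$center), drop = FALSE]
  } else if (ncol(m) != length(space$center)) {
    ml_stop("ml_schema_error",
            "projected rows do not match the space's trait count")
  }
  k <- if (is.null(components)) seq_len(space$n_components)
  else if (length(components) == 1L) seq_len(components)
  else components
  m <- sweep(m, 2, space$center)
  if (!is.null(space$scale)) m <- sweep(m, 2, space$scale, `/`)
  m %*% space$loadings[, k, drop = FALSE]
}

#' Per-component variance ratio between two populations
#'
#' Compares the spread of two populations in the shared phenotypic space:
#' component-wise \code{var(A)/var(B)} and the cumulative ratio
#' \code{sum(var(A))/sum(var(B))} over the first \code{upto} components.
#' Used to compare the morphological diversity of one strain collection
#' (e.g. sake strains) against a reference panel (e.g. natural isolates)
#' after a pooled PCA.
#'
#' @param scoresA,scoresB score matrices of the two populations (columns =
#'   components of one shared space).
#' @param upto number of leading components to compare.
#' @return list with \code{per_component} (length-\code{upto} ratios) and
#'   \code{cumulative} (scalar).
#' @export
variance_ratio <- function(scoresA, scoresB, upto = NULL) {
  a <- as.matrix(scoresA); b <- as.matrix(scoresB)
  if (nrow(a) < 2L || nrow(b) < 2L)
    ml_stop("ml_design_error", "each population needs >= 2 members")
  upto <- upto %||% min(ncol(a), ncol(b))
  if (upto > min(ncol(a), ncol(b)))
    ml_stop("ml_schema_error", "fewer components than requested")
  va <- apply(a[, seq_len(upto), drop = FALSE], 2, stats::var)
  vb <- apply(b[, seq_len(upto), drop = FALSE], 2, stats::var)
  if (any(vb <= 0))
    ml_stop("ml_undefined_ratio_error",
            sprintf("zero denominator variance in component %d",
                    which(vb <= 0)[1]))
  list(per_component = va / vb, cumulative = sum(va) / sum(vb))
}

#' Group traits by the component they load on, using reference replicates
#'
#' Runs PCA on the reference strain's replicate Z values restricted to a
#' candidate trait set and assigns each trait to the component, among the
#' leading components reaching \code{ccr_threshold}, on which it loads most
#' strongly (largest absolute loading). Trailing near-noise components are
#' excluded from the assignment so a trait cannot form a spurious singleton
#' group on a negligible axis. Traits grouped together co-vary across
#' reference replicates and are treated as reporting one underlying
#' morphological feature.
#'
#' @param z_reference_replicates matrix of reference replicate Z rows
#'   (>= 3 rows).
#' @param candidate_traits character vector of trait columns to group
#'   (>= 1; a single candidate forms its own group).
#' @param ccr_threshold CCR delimiting the assignable components (default
#'   0.90).
#' @return list with \code{groups} (named list: component -> trait ids),
#'   \code{n_groups}, and \code{assignment} (named integer vector).
#' @export
group_traits_by_reference_pca <- function(z_reference_replicates,
                                          candidate_traits,
                                          ccr_threshold = 0.90) {
  m <- unclass(z_reference_replicates)
  if (nrow(m) < 3L)
    ml_stop("ml_insufficient_data_error",
            "need >= 3 reference replicates to group traits")
  miss <- setdiff(candidate_traits, colnames(m))
  if (length(miss))
    ml_stop("ml_schema_error",
            paste0("candidate trait(s) absent: ", paste(miss, collapse = ", ")))
  if (length(candidate_traits) == 1L) {
    assignment <- stats::setNames(1L, candidate_traits)
    return(list(groups = list(PC1 = candidate_traits), n_groups = 1L,
                assignment = assignment))
  }
  space <- build_pca(m[, candidate_traits, drop = FALSE])
  k <- components_for_ccr(space, ccr_threshold)
  assignment <- apply(abs(space$loadings[, seq_len(k), drop = FALSE]), 1,
                      which.max)
  groups <- split(names(assignment), paste0("PC", assignment))
  groups <- groups[order(as.integer(sub("^PC", "", names(groups))))]
  list(groups = groups, n_groups = length(groups), assignment = assignment)
}

#' Serialize a phenotypic space
#'
#' Writes the loadings and the per-component variance table as TSV files in
#' a directory, plus JSON metadata.
#'
#' @param space a \code{\link{build_pca}} result.
#' @param dir output directory (created if absent).
#' @export
write_pheno_space <- function(space, dir) {
  stopifnot(inherits(space, "pheno_space"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(trait_id = rownames(space$loadings), space$loadings,
               check.names = FALSE),
    file.path(dir, "loadings.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(
    data.frame(component = seq_along(space$explained_variance),
               explained_variance = space$explained_variance,
               ccr = space$ccr),
    file.path(dir, "variance.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(
    data.frame(trait_id = names(space$center), center = space$center),
    file.path(dir, "center.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(list(n_components = space$n_components,
                            rescaled = !is.null(space$scale)),
                       file.path(dir, "space.json"), auto_unbox = TRUE)
  invisible(dir)
}
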