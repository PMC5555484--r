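#' Euclidean distance between two phenotype vectors
#'
#' \eqn{d(x,y) = \sqrt{\sum_i (x_i - y_i)^2}} over the coordinates of the
#' orthogonal phenotypic space; close to zero when two strains have similar
#' cell morphology.
#'
#' @param x,y numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y))
    ml_stop("ml_schema_error", "score vectors differ in length")
  sqrt(sum((x - y)^2))
}

new_distance_summary <- function(pair, distances, k, ccr) {
  structure(list(pair = pair, n_pairs = length(distances),
                 distances = distances,
                 mean = mean(distances),
                 sd = if (length(distances) > 1L) stats::sd(distances) else 0,
                 n_components_used = k, ccr_used = ccr),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("<distance_summary> %s: mean %.3f, sd %.3f over %d pair(s) (%d PCs)\n",
              paste(x$pair, collapse = " vs "), x$mean, x$sd, x$n_pairs,
              x$n_components_used))
  invisible(x)
}

#' Replicate-combinatoric distance between two strains
#'
#' Projects both strains' replicate Z-profiles onto the leading components
#' reaching the requested cumulative contribution ratio, then computes the
#' Euclidean distance for every pair in the Cartesian product of replicates
#' (5 x 5 replicates give 25 distances) and summarizes the multiset by its
#' mean and SD.
#'
#' @param space a \code{\link{build_pca}} result.
#' @param reps_x,reps_y matrices of replicate Z rows for the two strains.
#' @param ccr_threshold cumulative contribution ratio selecting the
#'   component count (default 0.90).
#' @param labels length-2 character vector naming the pair.
#' @return a \code{distance_summary}.
#' @export
strain_pair_distances <- function(space, reps_x, reps_y,
                                  ccr_threshold = 0.90,
                                  labels = c("x", "y")) {
  if (is.null(dim(reps_x))) reps_x <- matrix(reps_x, nrow = 1,
                                             dimnames = list(NULL, names(reps_x)))
  if (is.null(dim(reps_y))) reps_y <- matrix(reps_y, nrow = 1,
                                             dimnames = list(NULL, names(reps_y)))
  if (nrow(reps_x) < 1L || nrow(reps_y) < 1L)
    ml_stop("ml_insufficient_data_error", "empty replicate set")
  k <- components_for_ccr(space, ccr_threshold)
  sx <- project(space, reps_x, components = k)
  sy <- project(space, reps_y, components = k)
  d <- as.vector(cross_distances(sx, sy))
  new_distance_summary(labels, d, k, ccr_threshold)
}

# all pairwise distances between rows of a and rows of b (n_a x n_b matrix)
cross_distances <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Mid-parent points of a cross
#'
#' The expected hybrid position absent heterosis or inbreeding deviation:
#' the element-wise average \eqn{(a + b)/2} for every pair of one replicate
#' score from each parent (5 x 5 replicates give 25 mid-points).
#'
#' @param reps_a,reps_b parent score matrices (replicates x components).
#' @return matrix of \code{nrow(reps_a) * nrow(reps_b)} midpoint rows.
#' @export
midparent_points <- function(reps_a, reps_b) {
  a <- as.matrix(reps_a); b <- as.matrix(reps_b)
  if (nrow(a) < 1L || nrow(b) < 1L)
    ml_stop("ml_insufficient_data_error", "empty replicate set")
  if (ncol(a) != ncol(b))
    ml_stop("ml_schema_error", "parent score dimensions differ")
  idx <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  (a[idx$i, , drop = FALSE] + b[idx$j, , drop = FALSE]) / 2
}

#' Hybrid-to-midpoint distances
#'
#' Euclidean distances for every pair of one hybrid replicate score and one
#' mid-parent point (5 hybrid replicates x 25 midpoints give 125
#' distances), summarized by mean and SD.
#'
#' @param hybrid_reps hybrid score matrix (replicates x components).
#' @param midpoints matrix from \code{\link{midparent_points}}.
#' @param labels pair label carried in the summary.
#' @return a \code{distance_summary}.
#' @export
hybrid_midparent_distances <- function(hybrid_reps, midpoints,
                                       labels = c("hybrid", "midparent")) {
  h <- as.matrix(hybrid_reps); m <- as.matrix(midpoints)
  if (nrow(h) < 1L || nrow(m) < 1L)
    ml_stop("ml_insufficient_data_error", "empty input")
  if (ncol(h) != ncol(m))
    ml_stop("ml_schema_error", "score dimensions differ")
  d <- as.vector(cross_distances(h, m))
  new_distance_summary(labels, d, ncol(h), NA_real_)
}

#' Cross-distance ratio of a hybrid
#'
#' A scale-free measure of how far a hybrid departs from the additive
#' (mid-parent) expectation: each hybrid-to-midpoint distance divided by
#' the parent-parent distance. By default the denominator is the single
#' scalar mean of all replicate-pair parent distances, so the ratio count
#' equals the hybrid-to-midpoint count (5 replicates everywhere: 125
#' ratios). The \code{"paired"} variant instead divides the distance from
#' hybrid replicate to the midpoint of parent pair (i, j) by that same
#' pair's parent distance.
#'
#' @param parentA_reps,parentB_reps,hybrid_reps replicate Z rows of the two
#'   parents and the hybrid.
#' @param space a \code{\link{build_pca}} result.
#' @param ccr_threshold CCR selecting the component count (default 0.90).
#' @param denominator \code{"mean_parent"} (default) or \code{"paired"}.
#' @param labels length-3 character vector (parent A, parent B, hybrid).
#' @return a \code{ratio_summary}: list with \code{cross}, \code{ratios},
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
cross_distance_ratio <- function(parentA_reps, parentB_reps, hybrid_reps,
                                 space, ccr_threshold = 0.90,
                                 denominator = c("mean_parent", "paired"),
                                 labels = c("parentA", "parentB", "hybrid")) {
  denominator <- match.arg(denominator)
  k <- components_for_ccr(space, ccr_threshold)
  sa <- project(space, parentA_reps, components = k)
  sb <- project(space, parentB_reps, components = k)
  sh <- project(space, hybrid_reps, components = k)
  if (nrow(sa) < 1L || nrow(sb) < 1L || nrow(sh) < 1L)
    ml_stop("ml_insufficient_data_error", "empty replicate set")
  pp <- cross_distances(sa, sb)              # n_a x n_b parent distances
  if (all(pp == 0))
    ml_stop("ml_undefined_ratio_error", "parent-parent distance is zero")
  mid <- midparent_points(sa, sb)            # rows follow expand.grid(i, j)
  hm <- cross_distances(sh, mid)             # n_h x (n_a n_b)
  ratios <- if (denominator == "mean_parent") {
    as.vector(hm) / mean(pp)
  } else {
    pp_vec <- pp[cbind(expand.grid(i = seq_len(nrow(sa)),
                                   j = seq_len(nrow(sb)))$i,
                       expand.grid(i = seq_len(nrow(sa)),
                                   j = seq_len(nrow(sb)))$j)]
    if (any(pp_vec == 0))
      ml_stop("ml_undefined_ratio_error",
              "a parent replicate pair has zero distance")
    as.vector(sweep(hm, 2, pp_vec, `/`))
  }
  structure(list(cross = labels, ratios = ratios, mean = mean(ratios),
                 sd = if (length(ratios) > 1L) stats::sd(ratios) else 0,
                 n = length(ratios), n_components_used = k,
                 ccr_used = ccr_threshold, denominator = denominator),
            class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("<ratio_summary> %s x %s -> %s: mean %.3f, sd %.3f (n=%d, %s)\n",
              x$cross[1], x$cross[2], x$cross[3], x$mean, x$sd, x$n,
              x$denominator))
  invisible(x)
}

#' Wilcoxon-Mann-Whitney location test between two groups
#'
#' Two-sided Mann-Whitney U comparison of two value sets: exact when both
#' groups have at most 20 values and there are no ties, otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param values_group1,values_group2 numeric vectors.
#' @return list with \code{statistic} (U for group 1), \code{p_value},
#'   \code{exact}.
#' @export
group_location_test <- function(values_group1, values_group2) {
  if (length(values_group1) < 1L || length(values_group2) < 1L)
    ml_stop("ml_insufficient_data_error", "empty group")
  ties <- anyDuplicated(c(values_group1, values_group2)) > 0
  exact <- length(values_group1) <= 20L && length(values_group2) <= 20L &&
    !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_group1, values_group2, exact = exact,
                       correct = TRUE, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = exact)
}

#' Cell volume from projected area
#'
#' Converts a projected (2-D image) cell area to a volume under the
#' spherical-projection convention: a sphere of radius r projects to a disk
#' of area \eqn{A = \pi r^2} and has volume \eqn{V = (4/3)\pi r^3}, hence
#' \eqn{V = \frac{4}{3\sqrt{\pi}} A^{3/2}}. With A in square micrometers, V
#' is in cubic micrometers = femtoliters. Absolute values depend on this
#' convention; ratios between strains do not.
#'
#' @param area projected cell area (> 0), square micrometers.
#' @return volume in femtoliters.
#' @export
cell_volume_from_area <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0))
    ml_stop("ml_domain_error", "area must be positive")
  (4 / (3 * sqrt(pi))) * area^1.5
}

#' Distance statistics for every breeding edge of a lineage
#'
#' For each parent-child edge of the lineage graph, computes the
#' replicate-combinatoric distance summary between child and parent(s) in
#' the phenotypic space at the given CCR. For cross edges the child is
#' additionally compared with the mid-parent points
#' (\code{\link{hybrid_midparent_distances}}) and the cross-distance ratio
#' is reported; distances to each parent separately are always included.
#'
#' @param space a \code{\link{build_pca}} result.
#' @param z a replicate-mode \code{\link{z_matrix}} covering the lineage's
#'   strains.
#' @param lineage a \code{\link{lineage_graph}}.
#' @param ccr_threshold CCR selecting the component count (default 0.90).
#' @return data.frame with one row per edge-parent combination plus, for
#'   crosses, a \code{midparent} row: columns \code{child}, \code{parent},
#'   \code{breeding_type}, \code{comparison}, \code{mean}, \code{sd},
#'   \code{n_pairs}, \code{ratio_mean}, \code{ratio_sd}.
#' @export
lineage_distance_table <- function(space, z, lineage, ccr_threshold = 0.90) {
  stopifnot(inherits(lineage, "lineage_graph"))
  edges <- lineage$edges
  have <- unique(attr(z, "row_strain"))
  rows <- list()
  for (i in seq_len(nrow(edges))) {
    child <- edges$child[i]
    parents <- c(edges$parent1[i], edges$parent2[i])
    parents <- parents[!is.na(parents)]
    if (!child %in% have || !all(parents %in% have)) next
    ch <- z_rows_for(z, child)
    for (p in parents) {
      ds <- strain_pair_distances(space, ch, z_rows_for(z, p),
                                  ccr_threshold, labels = c(child, p))
      rows[[length(rows) + 1L]] <- data.frame(
        child = child, parent = p, breeding_type = edges$breeding_type[i],
        comparison = "parent", mean = ds$mean, sd = ds$sd,
        n_pairs = ds$n_pairs, ratio_mean = NA_real_, ratio_sd = NA_real_)
    }
    if (length(parents) == 2L) {
      k <- components_for_ccr(space, ccr_threshold)
      sa <- project(space, z_rows_for(z, parents[1]), components = k)
      sb <- project(space, z_rows_for(z, parents[2]), components = k)
      sh <- project(space, ch, components = k)
      hm <- hybrid_midparent_distances(sh, midparent_points(sa, sb),
                                       labels = c(child, "midparent"))
      rs <- cross_distance_ratio(z_rows_for(z, parents[1]),
                                 z_rows_for(z, parents[2]), ch, space,
                                 ccr_threshold,
                                 labels = c(parents, child))
      rows[[length(rows) + 1L]] <- data.frame(
        child = child, parent = paste(parents, collapse = "+"),
        breeding_type = edges$breeding_type[i],
        comparison = "midparent", mean = hm$mean, sd = hm$sd,
        n_pairs = hm$n_pairs, ratio_mean = rs$mean, ratio_sd = rs$sd)
    }
  }
  if (!length(rows))
    return(data.frame(child = character(), parent = character(),
                      breeding_type = character(), comparison = character(),
                      mean = numeric(), sd = numeric(), n_pairs = integer(),
                      ratio_mean = numeric(), ratio_sd = numeric()))
  do.call(rbind, rows)
}
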