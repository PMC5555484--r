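#' Correlation dissimilarity between strain score profiles
#'
#' Dissimilarity \eqn{D = 1 - R}, where R is the Pearson correlation
#' between two strains' component-score vectors (conventionally the
#' components reaching 60\% CCR). D ranges over [0, 2]: 0 for identical
#' profiles up to a positive affine transform, 2 for perfectly
#' anticorrelated profiles.
#'
#' @param scores matrix, strains x components (>= 2 components).
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
correlation_dissimilarity <- function(scores) {
  m <- as.matrix(scores)
  if (ncol(m) < 2L)
    ml_stop("ml_schema_error",
            "correlation dissimilarity needs >= 2 components")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    ml_stop("ml_undefined_correlation_error",
            paste0("zero-variance score vector for strain ",
                   rownames(m)[which(sds == 0)[1]]))
  D <- 1 - stats::cor(t(m))
  D[D < 0] <- 0   # clip numerical -epsilon
  diag(D) <- 0
  D
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' UPGMA merge sequence over a symmetric zero-diagonal dissimilarity
#' matrix. Leaves are ordered lexicographically before clustering so the
#' merge sequence (including tie-breaking, which \code{hclust} resolves by
#' input order) is deterministic.
#'
#' @param D symmetric dissimilarity matrix with labels.
#' @return A \code{morph_dendrogram}: list with \code{hclust} (the stats
#'   object), \code{labels}, and optional \code{support} filled in by
#'   \code{\link{bootstrap_support}}.
#' @export
average_linkage_hca <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    ml_stop("ml_format_error", "dissimilarity matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-8))
    ml_stop("ml_format_error", "dissimilarity diagonal must be zero")
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- paste0("S", seq_len(nrow(D)))
  ord <- order(rownames(D))
  D <- D[ord, ord]
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  structure(list(hclust = hc, labels = hc$labels, support = NULL),
            class = "morph_dendrogram")
}

#' @export
print.morph_dendrogram <- function(x, ...) {
  cat(sprintf("<morph_dendrogram> %d leaves, %d merges%s\n",
              length(x$labels), length(x$hclust$height),
              if (!is.null(x$support)) " (with bootstrap support)" else ""))
  invisible(x)
}

# leaf-label sets of every internal node of an hclust tree
clade_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    sets[[i]] <- sort(unlist(lapply(kids, function(k)
      if (k < 0) hc$labels[-k] else sets[[k]])))
  }
  sets
}

#' Bootstrap support for morphological clusters
#'
#' Ordinary bootstrap over traits: resamples the Z-matrix's trait columns
#' with replacement, rebuilds the phenotypic space, the correlation
#' dissimilarity (at the same CCR threshold) and the UPGMA tree, and
#' reports for each internal node of the original tree the proportion of
#' resampled trees containing the same leaf set.
#'
#' @param z strain-level Z matrix (strains x traits, one row per strain).
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed integer seed fixing the resampling stream.
#' @param ccr_threshold CCR selecting the component count (default 0.60).
#' @return A \code{morph_dendrogram} whose \code{support} is a numeric
#'   vector (one entry per merge of \code{hclust}, in merge order).
#' @export
bootstrap_support <- function(z, n_boot = 1000L, seed = 1L,
                              ccr_threshold = 0.60) {
  if (!is_count(n_boot))
    ml_stop("ml_parameter_error", "n_boot must be a positive integer")
  m <- as.matrix(unclass(z))
  if (nrow(m) < 2L)
    ml_stop("ml_insufficient_data_error", "need >= 2 strains")
  build <- function(mat) {
    sp <- build_pca(mat)
    k <- max(components_for_ccr(sp, ccr_threshold), 2L)
    sc <- sp$scores[, seq_len(min(k, ncol(sp$scores))), drop = FALSE]
    average_linkage_hca(correlation_dissimilarity(sc))
  }
  base <- build(m)
  base_sets <- clade_sets(base$hclust)
  keys <- vapply(base_sets, paste, character(1), collapse = "\r")
  hits <- numeric(length(keys))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      colnames(mb) <- paste0("t", seq_len(ncol(mb)))
      tb <- try(build(mb), silent = TRUE)
      if (inherits(tb, "try-error")) next
      bk <- vapply(clade_sets(tb$hclust), paste, character(1),
                   collapse = "\r")
      hits <- hits + as.numeric(keys %in% bk)
    }
  })
  base$support <- hits / n_boot
  base
}

#' Newick export of a morphological dendrogram
#'
#' Converts the UPGMA tree to \code{ape}'s phylo representation and writes
#' Newick text, with bootstrap support proportions (if present) as internal
#' node labels.
#'
#' @param dend a \code{\link{average_linkage_hca}} /
#'   \code{\link{bootstrap_support}} result.
#' @param path optional output file; omitted, the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "morph_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  if (!is.null(dend$support)) {
    # ape numbers internal nodes in its own order; map via clade leaf sets
    sets <- clade_sets(dend$hclust)
    keys <- vapply(sets, paste, character(1), collapse = "\r")
    lab <- rep("", phy$Nnode)
    for (node in seq_len(phy$Nnode)) {
      tips <- sort(ape::extract.clade(phy, node + ape::Ntip(phy))$tip.label)
      i <- match(paste(tips, collapse = "\r"), keys)
      if (!is.na(i)) lab[node] <- sprintf("%.3f", dend$support[i])
    }
    phy$node.label <- lab
  }
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
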