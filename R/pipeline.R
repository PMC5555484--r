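#' Pipeline configuration
#'
#' Bundles the thresholds and identifiers that drive an end-to-end run:
#' the reference strain, the CCR thresholds per analysis (distance 0.90,
#' clustering 0.60, genotype-phenotype 0.90 — the field's conventional
#' values), significance levels, the multiplicity correction, the Dunnett
#' control strain and the seed for the bootstrap.
#'
#' @param reference reference strain id.
#' @param ccr_distance,ccr_cluster,ccr_genopheno CCR thresholds in (0, 1].
#' @param alpha significance level in (0, 1).
#' @param correction multiplicity correction for trait screens.
#' @param control control strain for the Dunnett PP comparison; defaults to
#'   the reference strain.
#' @param n_boot bootstrap resamples for cluster support.
#' @param seed integer seed for all stochastic stages.
#' @return a \code{pipeline_config} (validated list).
#' @export
pipeline_config <- function(reference = "reference",
                            ccr_distance = 0.90, ccr_cluster = 0.60,
                            ccr_genopheno = 0.90, alpha = 0.05,
                            correction = "bonferroni",
                            control = NULL, n_boot = 200L, seed = 1L) {
  for (thr in c(ccr_distance, ccr_cluster, ccr_genopheno))
    if (!is.numeric(thr) || thr <= 0 || thr > 1)
      ml_stop("ml_parameter_error", "CCR thresholds must be in (0, 1]")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    ml_stop("ml_parameter_error", "alpha must be in (0, 1)")
  structure(list(reference = reference, ccr_distance = ccr_distance,
                 ccr_cluster = ccr_cluster, ccr_genopheno = ccr_genopheno,
                 alpha = alpha, correction = correction,
                 control = control %||% reference,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full phenotyping pipeline
#'
#' Orchestrates normalize, PCA, lineage distances, phenotypic potential,
#' clustering and (when genotypes are supplied) the genotype-phenotype
#' comparison, from in-memory objects or file paths. Deterministic given
#' inputs and the config seed. Any stage failure aborts with the stage
#' name.
#'
#' @param table a \code{\link{trait_table}} or path to one.
#' @param lineage a \code{\link{lineage_graph}} or path; optional.
#' @param genotypes a \code{\link{genotype_matrix}} or path; optional.
#' @param config a \code{\link{pipeline_config}}.
#' @param catalog catalog used when \code{table} is a path.
#' @param out optional output directory; when given, every result table is
#'   written there along with a machine-readable \code{manifest.json}.
#' @return list with \code{z_strain}, \code{z_replicate}, \code{space},
#'   \code{distances}, \code{pp}, \code{dunnett}, \code{tree} (Newick
#'   string), \code{genopheno}, \code{manifest}.
#' @export
run_pipeline <- function(table, lineage = NULL, genotypes = NULL,
                         config = pipeline_config(),
                         catalog = load_default_catalog(), out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      ml_stop("ml_pipeline_error",
              sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }
  if (is.character(table))
    table <- stage("read", read_trait_table(table, catalog))
  catalog <- attr(table, "catalog")
  if (is.character(lineage)) lineage <- stage("read", read_lineage(lineage))
  if (is.character(genotypes))
    genotypes <- stage("read", read_genotypes(genotypes))

  zs <- stage("normalize", z_matrix(table, reference = config$reference,
                                    mode = "strain"))
  zr <- stage("normalize", z_matrix(table, reference = config$reference,
                                    mode = "replicate"))
  shared <- intersect(colnames(zs), colnames(zr))
  space <- stage("pca", build_pca(zs[, shared]))

  distances <- if (!is.null(lineage))
    stage("distances",
          lineage_distance_table(space, zr[, shared], lineage,
                                 ccr_threshold = config$ccr_distance))
  else NULL

  pp <- stage("pp", pp_by_strain(zr, catalog))
  dunnett <- if (length(pp) >= 2L && config$control %in% names(pp) &&
                 all(lengths(pp) >= 2L))
    stage("pp", dunnett_vs_control(pp, control = config$control,
                                   alpha = config$alpha))
  else NULL

  tree <- stage("cluster", {
    dend <- bootstrap_support(zs[, shared], n_boot = config$n_boot,
                              seed = config$seed,
                              ccr_threshold = config$ccr_cluster)
    write_newick(dend)
  })

  genopheno <- if (!is.null(genotypes) &&
                   length(intersect(rownames(zs), rownames(genotypes))) >= 3L)
    stage("genopheno", {
      cmp <- pairwise_comparisons(genotypes, space, z = NULL,
                                  ccr_threshold = config$ccr_genopheno)
      list(pairs = cmp, correlation = geno_pheno_correlation(cmp))
    })
  else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("morphlineage")),
    reference = config$reference,
    n_strains = length(unique(table$strain)),
    n_traits = ncol(zs),
    failed_traits = attr(zs, "failed"),
    ccr = list(distance = config$ccr_distance, cluster = config$ccr_cluster,
               genopheno = config$ccr_genopheno),
    alpha = config$alpha, correction = config$correction,
    control = config$control, n_boot = config$n_boot, seed = config$seed,
    n_errors = 0L)

  res <- list(z_strain = zs, z_replicate = zr, space = space,
              distances = distances, pp = pp, dunnett = dunnett,
              tree = tree, genopheno = genopheno, manifest = manifest)

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_z_matrix(zs, file.path(out, "z_strain.tsv"))
    write_z_matrix(zr, file.path(out, "z_replicate.tsv"))
    write_pheno_space(space, file.path(out, "space"))
    if (!is.null(distances))
      utils::write.table(distances, file.path(out, "distances.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    pp_df <- data.frame(strain = rep(names(pp), lengths(pp)),
                        pp = unlist(pp, use.names = FALSE))
    utils::write.table(pp_df, file.path(out, "pp.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(dunnett))
      utils::write.table(dunnett, file.path(out, "pp_dunnett.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(tree, file.path(out, "tree.nwk"))
    if (!is.null(genopheno))
      utils::write.table(genopheno$pairs, file.path(out, "genopheno.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
  }
  res
}
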