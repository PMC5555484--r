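#' Reference noise envelope for phenotypic-potential scoring
#'
#' Estimates, per noise trait, the two-sided tolerance interval within which
#' a replicate of a reference-like (robust) strain is expected to fall: the
#' envelope is \code{mean +/- z_{(1+level)/2} * sd} of the reference
#' strain's own per-replicate Z values. Replicate-mode
#' \code{\link{z_matrix}} stores the reference replicates as leave-one-out
#' studentized deviations, which are already on the out-of-sample scale of
#' a test replicate's Wald statistic, so the empirical SD is used as is.
#'
#' @param z_reference_replicates replicate-mode Z rows of the reference
#'   strain (>= 10 rows recommended; < 2 is an error).
#' @param noise_traits character vector of noise trait ids (defaults to all
#'   columns).
#' @param level two-sided coverage (default 0.95).
#' @return A \code{noise_envelope}: data.frame with columns
#'   \code{trait_id}, \code{lower}, \code{upper}.
#' @export
reference_noise_envelope <- function(z_reference_replicates,
                                     noise_traits = NULL, level = 0.95) {
  m <- as.matrix(unclass(z_reference_replicates))
  noise_traits <- noise_traits %||% colnames(m)
  miss <- setdiff(noise_traits, colnames(m))
  if (length(miss))
    ml_stop("ml_schema_error",
            paste0("noise trait(s) absent from reference Z: ",
                   paste(utils::head(miss, 3), collapse = ", ")))
  m <- m[, noise_traits, drop = FALSE]
  n <- nrow(m)
  if (n < 2L)
    ml_stop("ml_insufficient_data_error",
            "need >= 2 reference replicates for the envelope")
  zq <- stats::qnorm((1 + level) / 2)
  mu <- colMeans(m, na.rm = TRUE)
  s <- apply(m, 2, stats::sd, na.rm = TRUE)
  structure(data.frame(trait_id = noise_traits, lower = mu - zq * s,
                       upper = mu + zq * s, row.names = NULL),
            level = level, n_reference = n,
            class = c("noise_envelope", "data.frame"))
}

#' Phenotypic potential of a replicate
#'
#' Phenotypic potential (PP) is a scalar robustness indicator computed from
#' the 220 cell-to-cell noise traits: higher PP means a more heterogeneous
#' (less buffered) cell population. The default definition is the fraction
#' of noise traits whose Z value falls outside the reference strain's
#' two-sided envelope (\code{\link{reference_noise_envelope}}); a
#' reference-calibrated replicate therefore scores near the nominal
#' exceedance (0.05 at the default 95\% envelope). The alternative
#' \code{"mean_abs_z"} definition returns the mean absolute noise-trait Z
#' rescaled to (0, 1) by \code{z/(1+z)}.
#'
#' @param replicate_z_noise numeric vector (or 1-row matrix) of one
#'   replicate's Z values over the noise traits, or a matrix of several
#'   replicates (one PP per row).
#' @param envelope a \code{\link{reference_noise_envelope}}.
#' @param method \code{"envelope"} (default) or \code{"mean_abs_z"}.
#' @param min_fraction minimum fraction of envelope traits that must be
#'   available (default 0.9).
#' @return numeric vector of PP values in [0, 1], one per replicate, with
#'   attribute \code{method}.
#' @export
phenotypic_potential <- function(replicate_z_noise, envelope,
                                 method = c("envelope", "mean_abs_z"),
                                 min_fraction = 0.9) {
  method <- match.arg(method)
  stopifnot(inherits(envelope, "noise_envelope"))
  m <- replicate_z_noise
  if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                   dimnames = list(NULL, names(replicate_z_noise)))
  m <- as.matrix(unclass(m))
  ids <- intersect(envelope$trait_id, colnames(m))
  if (length(ids) < min_fraction * nrow(envelope))
    ml_stop("ml_insufficient_data_error",
            sprintf("only %d of %d noise traits available (< %.0f%%)",
                    length(ids), nrow(envelope), 100 * min_fraction))
  m <- m[, ids, drop = FALSE]
  env <- envelope[match(ids, envelope$trait_id), ]
  pp <- if (method == "envelope") {
    outside <- sweep(m, 2, env$lower, `<`) | sweep(m, 2, env$upper, `>`)
    rowMeans(outside, na.rm = TRUE)
  } else {
    az <- rowMeans(abs(m), na.rm = TRUE)
    az / (1 + az)
  }
  structure(unname(pp), method = method)
}

#' Per-strain phenotypic potential from a replicate-mode Z matrix
#'
#' Convenience wrapper: builds the reference envelope from the reference
#' strain's replicate rows, then scores every strain's replicates.
#'
#' @param z a replicate-mode \code{\link{z_matrix}}.
#' @param catalog the \code{\link{trait_catalog}} (identifies noise traits).
#' @param level envelope coverage (default 0.95).
#' @param method PP definition, see \code{\link{phenotypic_potential}}.
#' @return named list: strain id -> numeric vector of per-replicate PPs;
#'   attributes \code{method}, \code{level}.
#' @export
pp_by_strain <- function(z, catalog, level = 0.95,
                         method = c("envelope", "mean_abs_z")) {
  method <- match.arg(method)
  stopifnot(inherits(z, "z_matrix"))
  if (attr(z, "mode") != "replicate")
    ml_stop("ml_design_error", "pp_by_strain needs a replicate-mode Z matrix")
  reference <- attr(z, "reference")
  noise <- intersect(noise_trait_ids(catalog), colnames(z))
  env <- reference_noise_envelope(z_rows_for(z, reference)[, noise,
                                                           drop = FALSE],
                                  noise_traits = noise, level = level)
  strains <- unique(attr(z, "row_strain"))
  out <- lapply(stats::setNames(strains, strains), function(s) {
    as.numeric(phenotypic_potential(
      z_rows_for(z, s)[, noise, drop = FALSE], env, method = method))
  })
  structure(out, method = method, level = level, reference = reference)
}

#' Dunnett many-to-one comparison of phenotypic potentials
#'
#' Compares every strain's replicate PP values against a designated control
#' strain under a common-variance one-way model, with multiplicity-adjusted
#' p-values from the multivariate-t reference distribution (the standard
#' many-to-one Dunnett procedure).
#'
#' @param pp_by_strain named list of per-replicate PP vectors (as returned
#'   by \code{\link{pp_by_strain}}), including the control.
#' @param control name of the control strain.
#' @param alpha flagging level (default 0.05).
#' @param alternative \code{"two.sided"} (default), \code{"greater"}
#'   (strain PP larger than control) or \code{"less"}.
#' @return data.frame with one row per non-control strain: \code{strain},
#'   \code{mean}, \code{sd}, \code{estimate} (difference vs control),
#'   \code{adjusted_p}, \code{flagged}.
#' @export
dunnett_vs_control <- function(pp_by_strain, control, alpha = 0.05,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  if (!control %in% names(pp_by_strain))
    ml_stop("ml_design_error", paste0("control strain absent: ", control))
  if (length(pp_by_strain) < 2L)
    ml_stop("ml_design_error",
            "need at least one non-control strain to compare")
  lens <- lengths(pp_by_strain)
  if (any(lens < 2L))
    ml_stop("ml_insufficient_data_error",
            paste0("strain(s) with < 2 replicates: ",
                   paste(names(pp_by_strain)[lens < 2L], collapse = ", ")))
  strains <- names(pp_by_strain)
  d <- data.frame(
    pp = unlist(pp_by_strain, use.names = FALSE),
    strain = factor(rep(strains, lens),
                    levels = c(control, sort(setdiff(strains, control)))))
  fit <- stats::aov(pp ~ strain, data = d)
  glht_alt <- switch(alternative, two.sided = "two.sided",
                     greater = "greater", less = "less")
  gl <- multcomp::glht(fit,
                       linfct = multcomp::mcp(strain = "Dunnett"),
                       alternative = glht_alt)
  sm <- summary(gl)
  cmp <- sub(" - .*$", "", rownames(sm$linfct))
  adj_p <- as.numeric(sm$test$pvalues)
  data.frame(strain = cmp,
             mean = vapply(pp_by_strain[cmp], mean, numeric(1)),
             sd = vapply(pp_by_strain[cmp], stats::sd, numeric(1)),
             estimate = as.numeric(sm$test$coefficients),
             adjusted_p = adj_p,
             flagged = adj_p < alpha,
             row.names = NULL)
}
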