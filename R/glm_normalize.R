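#' Fit a single-trait generalized linear model
#'
#' Fits the trait-normalization GLM for one trait: the linear predictor is an
#' intercept plus the requested explanatory terms (subset of \code{strain},
#' \code{medium}, and any further factor columns of \code{data}), optionally
#' with their interaction. The reference strain is made the baseline factor
#' level, so strain coefficients are contrasts against it. The model family
#' follows the trait's value domain:
#' \itemize{
#'   \item \code{"gaussian"}: identity link (unbounded traits);
#'   \item \code{"gamma"}: log link (strictly positive traits);
#'   \item \code{"beta"}: logit mean link, full-ML beta regression
#'     (proportion traits; boundary values are shrunk by
#'     \eqn{(y(n-1)+0.5)/n} using the record's cell count).
#' }
#'
#' @param values numeric response vector (one entry per record).
#' @param data data.frame of explanatory columns aligned with \code{values};
#'   must contain every term in \code{design}.
#' @param design character vector of term names; empty for intercept-only.
#' @param family one of \code{"gaussian"}, \code{"gamma"}, \code{"beta"}.
#' @param include_interaction add the pairwise interaction of the design
#'   terms.
#' @param reference baseline level for the \code{strain} term.
#' @param cell_count per-record cell counts, used only to shrink boundary
#'   proportion values for the beta family.
#' @param trait_id optional label carried in errors and the returned fit.
#' @return A \code{glm_fit}: list with \code{coefficients},
#'   \code{standard_errors}, \code{vcov}, \code{dispersion},
#'   \code{log_likelihood}, \code{aic}, \code{n_obs}, \code{n_params},
#'   \code{family}, \code{design}.
#' @export
fit_trait_glm <- function(values, data, design = "strain",
                          family = c("gaussian", "gamma", "beta"),
                          include_interaction = FALSE,
                          reference = "reference",
                          cell_count = NULL, trait_id = NULL) {
  family <- match.arg(family)
  keep <- is.finite(values)
  values <- values[keep]
  data <- data[keep, , drop = FALSE]
  if (!is.null(cell_count)) cell_count <- cell_count[keep]
  n <- length(values)
  if (n < 2L)
    ml_stop("ml_fit_error",
            paste0("fewer than 2 usable observations",
                   if (!is.null(trait_id)) paste0(" for trait ", trait_id)))
  miss <- setdiff(design, names(data))
  if (length(miss))
    ml_stop("ml_design_error",
            paste0("design term(s) absent from data: ",
                   paste(miss, collapse = ", ")))
  for (term in design) {
    f <- factor(as.character(data[[term]]))
    if (term == "strain" && reference %in% levels(f))
      f <- stats::relevel(f, ref = reference)
    data[[term]] <- f
  }
  rhs <- if (length(design) == 0L) "1"
  else if (include_interaction && length(design) >= 2L)
    paste(paste(design, collapse = " + "), "+",
          paste(utils::combn(design, 2, paste, collapse = ":"),
                collapse = " + "))
  else paste(design, collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))
  d <- cbind(data.frame(y = values), data)

  X <- stats::model.matrix(form, data = d)
  if (qr(X)$rank < ncol(X))
    ml_stop("ml_design_error",
            paste0("singular design",
                   if (!is.null(trait_id)) paste0(" for trait ", trait_id)))

  fit <- switch(family,
    gaussian = {
      m <- stats::glm(form, data = d, family = stats::gaussian())
      sm <- summary(m)
      list(coefficients = stats::coef(m),
           standard_errors = sm$coefficients[, "Std. Error"],
           vcov = stats::vcov(m),
           dispersion = sm$dispersion,
           log_likelihood = as.numeric(stats::logLik(m)),
           aic = stats::AIC(m),
           n_params = attr(stats::logLik(m), "df"))
    },
    gamma = {
      if (any(values <= 0))
        ml_stop("ml_domain_error",
                paste0("gamma family requires positive values",
                       if (!is.null(trait_id)) paste0(" (trait ", trait_id, ")")))
      m <- suppressWarnings(
        stats::glm(form, data = d, family = stats::Gamma(link = "log")))
      if (!m$converged)
        ml_stop("ml_fit_error",
                paste0("gamma GLM did not converge",
                       if (!is.null(trait_id)) paste0(" for trait ", trait_id)))
      sm <- summary(m)
      list(coefficients = stats::coef(m),
           standard_errors = sm$coefficients[, "Std. Error"],
           vcov = stats::vcov(m),
           dispersion = sm$dispersion,
           log_likelihood = as.numeric(stats::logLik(m)),
           aic = stats::AIC(m),
           n_params = attr(stats::logLik(m), "df"))
    },
    beta = {
      y <- values
      if (any(y < 0 | y > 1))
        ml_stop("ml_domain_error",
                paste0("beta family requires values in [0,1]",
                       if (!is.null(trait_id)) paste0(" (trait ", trait_id, ")")))
      if (any(y <= 0 | y >= 1)) {
        nn <- if (is.null(cell_count)) rep(200, length(y)) else cell_count
        y <- shrink_proportion(y, nn)
      }
      b <- fit_beta_ml(X, y)
      list(coefficients = b$coefficients,
           standard_errors = b$standard_errors,
           vcov = b$vcov,
           dispersion = 1 / (1 + b$phi),
           phi = b$phi,
           log_likelihood = b$log_likelihood,
           aic = -2 * b$log_likelihood + 2 * b$n_params,
           n_params = b$n_params)
    })

  if (anyNA(fit$coefficients))
    ml_stop("ml_design_error",
            paste0("inestimable coefficients",
                   if (!is.null(trait_id)) paste0(" for trait ", trait_id)))
  if (any(fit$standard_errors <= 0 | !is.finite(fit$standard_errors)))
    ml_stop("ml_fit_error",
            paste0("degenerate fit (zero or non-finite standard error)",
                   if (!is.null(trait_id)) paste0(" for trait ", trait_id)))

  structure(c(fit, list(family = family, design = design,
                        include_interaction = include_interaction,
                        reference = reference, n_obs = n,
                        trait_id = trait_id, formula = form)),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %s family, n=%d, AIC=%.2f, logLik=%.2f\n",
              x$family, x$n_obs, x$aic, x$log_likelihood))
  print(data.frame(estimate = x$coefficients, se = x$standard_errors))
  invisible(x)
}

#' Wald Z statistic for a fitted contrast
#'
#' The Wald statistic of one model term: its estimate divided by its
#' standard error. For a strain contrast against the reference strain the
#' sign is positive when the strain's linear predictor exceeds the
#' reference's.
#'
#' @param fit a \code{\link{fit_trait_glm}} result.
#' @param term coefficient name (e.g. \code{"strainK7"}).
#' @return The Z value (numeric scalar).
#' @export
wald_z <- function(fit, term) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!term %in% names(fit$coefficients))
    ml_stop("ml_design_error", paste0("term not in fit: ", term))
  se <- fit$standard_errors[[term]]
  if (!is.finite(se) || se <= 0)
    ml_stop("ml_fit_error", paste0("degenerate standard error for ", term))
  unname(fit$coefficients[[term]] / se)
}

#' Select a per-trait model by AIC
#'
#' Fits every candidate design and returns the one with the minimum AIC;
#' ties (to \code{tol}) are broken toward the design with fewer estimated
#' parameters.
#'
#' @param values,data,family,reference,cell_count,trait_id as in
#'   \code{\link{fit_trait_glm}}.
#' @param candidates list of candidate designs, each a list with elements
#'   \code{terms} (character vector, possibly empty) and optional
#'   \code{interaction} (logical).
#' @param tol AIC difference treated as a tie.
#' @return list with \code{design} (the winning candidate), \code{fit} (its
#'   \code{glm_fit}) and \code{aic_table} (data.frame of all candidates).
#' @export
select_model_aic <- function(values, data, candidates,
                             family = c("gaussian", "gamma", "beta"),
                             reference = "reference", cell_count = NULL,
                             trait_id = NULL, tol = 1e-9) {
  family <- match.arg(family)
  if (length(candidates) < 2L)
    ml_stop("ml_design_error", "need at least 2 candidate designs")
  fits <- lapply(candidates, function(cand) {
    tryCatch(
      fit_trait_glm(values, data, design = cand$terms %||% character(),
                    family = family,
                    include_interaction = isTRUE(cand$interaction),
                    reference = reference, cell_count = cell_count,
                    trait_id = trait_id),
      morphlineage_error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    ml_stop("ml_fit_error",
            paste0("no candidate design converged",
                   if (!is.null(trait_id)) paste0(" for trait ", trait_id)))
  aic <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, numeric(1))
  npar <- vapply(fits, function(f) if (is.null(f)) NA_integer_
                 else as.integer(f$n_params), integer(1))
  best_aic <- min(aic)
  tied <- which(aic <= best_aic + tol)
  winner <- tied[which.min(npar[tied])]
  list(design = candidates[[winner]], fit = fits[[winner]],
       aic_table = data.frame(
         candidate = seq_along(candidates),
         terms = vapply(candidates, function(cand)
           paste(cand$terms %||% "(intercept)", collapse = "+"), character(1)),
         interaction = vapply(candidates, function(cand)
           isTRUE(cand$interaction), logical(1)),
         aic = aic, n_params = npar, converged = ok))
}

#' Likelihood-ratio screen over traits with Bonferroni correction
#'
#' For each trait, compares a full fit against a nested reduced fit by the
#' likelihood-ratio test (statistic \eqn{2(\ell_{full} - \ell_{red})},
#' chi-squared with degrees of freedom equal to the difference in estimated
#' parameter counts, dispersion included where profiled) and returns the
#' traits significant at \code{alpha} after Bonferroni correction over the
#' number of traits tested.
#'
#' @param fits_full,fits_reduced named lists of \code{glm_fit}s (same trait
#'   ids); the reduced design must be nested in the full design.
#' @param alpha family-wise significance level.
#' @param correction only \code{"bonferroni"} (or \code{"none"}).
#' @return character vector of significant trait ids, with the per-trait
#'   statistics attached as attribute \code{table}.
#' @export
lrt_screen <- function(fits_full, fits_reduced, alpha = 0.05,
                       correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  ids <- names(fits_full)
  if (is.null(ids) || !setequal(ids, names(fits_reduced)))
    ml_stop("ml_design_error",
            "full and reduced fit lists must share the same trait ids")
  m <- length(ids)
  stat <- df <- p <- numeric(m)
  for (i in seq_len(m)) {
    f <- fits_full[[ids[i]]]; r <- fits_reduced[[ids[i]]]
    if (f$n_params <= r$n_params ||
        !all(r$design %in% c(f$design, character())))
      ml_stop("ml_design_error",
              paste0("reduced design not nested in full for trait ", ids[i]))
    stat[i] <- 2 * (f$log_likelihood - r$log_likelihood)
    df[i] <- f$n_params - r$n_params
    p[i] <- stats::pchisq(max(stat[i], 0), df = df[i], lower.tail = FALSE)
  }
  thr <- if (correction == "bonferroni") alpha / m else alpha
  hit <- ids[p < thr]
  attr(hit, "table") <- data.frame(trait_id = ids, statistic = stat,
                                   df = df, p = p, significant = p < thr)
  hit
}

#' Wald screen of a Z-matrix with Bonferroni correction
#'
#' Flags traits whose Wald Z (for any non-reference row, or for one named
#' strain) is significant at level \code{alpha} after Bonferroni correction
#' over traits. P-values use the Student-t reference with the Z-matrix's
#' residual degrees of freedom (exact for the gaussian family, a
#' small-sample approximation for the others); with large df this
#' converges to the standard-normal reference.
#'
#' @param z a \code{\link{z_matrix}}.
#' @param alpha family-wise significance level.
#' @param strain restrict to a single strain's row(s); default: all
#'   non-reference rows, using each trait's smallest p-value.
#' @param correction \code{"bonferroni"} or \code{"none"}.
#' @return character vector of significant trait ids, with p-values attached
#'   as attribute \code{p}.
#' @export
wald_screen <- function(z, alpha = 0.05, strain = NULL,
                        correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(z, "z_matrix"))
  rows <- if (is.null(strain)) {
    which(attr(z, "row_strain") != attr(z, "reference"))
  } else {
    which(attr(z, "row_strain") == strain)
  }
  if (!length(rows))
    ml_stop("ml_design_error", "no non-reference rows to screen")
  zz <- abs(unclass(z)[rows, , drop = FALSE])
  zmax <- apply(zz, 2, function(col) if (all(is.na(col))) NA_real_
                else max(col, na.rm = TRUE))
  df <- attr(z, "df_residual")
  p <- if (!is.null(df) && is.finite(df) && df > 0)
    2 * stats::pt(-zmax, df = df)
  else 2 * stats::pnorm(-zmax)
  m <- sum(!is.na(p))
  thr <- if (correction == "bonferroni") alpha / m else alpha
  hit <- colnames(z)[!is.na(p) & p < thr]
  attr(hit, "p") <- p
  hit
}
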