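#' Wald Z-profiles against the reference strain
#'
#' The normalization step of the pipeline: every trait is fitted with its
#' family's GLM (gaussian-identity, gamma-log or beta-logit, chosen by the
#' catalog's \code{family_class}) with the strain — or, in replicate mode,
#' each strain replicate — as a factor whose baseline level is the reference
#' strain, and each non-reference level's Wald statistic (coefficient /
#' standard error) becomes its Z value for that trait. The result is the
#' strain-by-trait (or replicate-by-trait) matrix of Z-profiles on which all
#' downstream analyses operate.
#'
#' Modes:
#' \describe{
#'   \item{\code{"strain"}}{one row per strain; all replicates of a strain
#'     inform its single contrast. The reference strain's row is identically
#'     zero by construction.}
#'   \item{\code{"replicate"}}{one row per strain x replicate; each
#'     non-reference replicate is its own factor level (a singleton), with
#'     residual information coming from the pooled reference replicates.
#'     Rows for the reference strain's own replicates hold leave-one-out
#'     studentized deviations on the trait's link scale,
#'     \eqn{(g(y_j) - \bar g_{-j}) / (s_{-j}\sqrt{1 + 1/(n-1)})}, so they
#'     are on the same out-of-sample scale as a singleton replicate's Wald
#'     statistic; these calibrate the noise envelope used by
#'     \code{\link{phenotypic_potential}}. With several media, the
#'     leave-one-out statistics are formed within each medium.}
#' }
#'
#' When the table spans several media and \code{media_adjust} is active, the
#' medium enters the linear predictor as an additive term (no interaction),
#' so the returned strain contrasts have the medium effect subtracted. This
#' requires the reference strain to be observed in every medium in which a
#' non-reference strain appears; otherwise a design error is raised.
#'
#' Traits whose fit fails (non-convergence, separation) are excluded from
#' the matrix and reported in the \code{failed} attribute, never imputed.
#'
#' @param table a \code{\link{trait_table}}.
#' @param reference reference strain id (default \code{"reference"}).
#' @param mode \code{"strain"} or \code{"replicate"} (see above).
#' @param media_adjust \code{"auto"} adjusts whenever the table has more
#'   than one medium; \code{"always"} requires it; \code{"never"} forbids it.
#' @param traits optional subset of trait ids to fit.
#' @return A \code{z_matrix}: numeric matrix (rows = strains or
#'   strain|replicate, columns = traits) with attributes \code{reference},
#'   \code{mode}, \code{row_strain}, \code{row_replicate}, \code{families},
#'   \code{failed}, \code{media_adjusted}.
#' @export
z_matrix <- function(table, reference = "reference",
                     mode = c("strain", "replicate"),
                     media_adjust = c("auto", "never", "always"),
                     traits = NULL) {
  stopifnot(inherits(table, "trait_table"))
  mode <- match.arg(mode)
  media_adjust <- match.arg(media_adjust)
  catalog <- attr(table, "catalog")
  if (!reference %in% table$strain)
    ml_stop("ml_design_error",
            paste0("reference strain not in table: ", reference))
  ids <- traits %||% catalog$trait_id
  fam <- trait_family(catalog)[ids]

  media <- unique(table$medium)
  adjust <- switch(media_adjust,
                   auto = length(media) > 1L,
                   always = TRUE,
                   never = FALSE)
  if (adjust) {
    ref_media <- unique(table$medium[table$strain == reference])
    other_media <- unique(table$medium[table$strain != reference])
    orphan <- setdiff(other_media, ref_media)
    if (length(orphan))
      ml_stop("ml_design_error",
              paste0("medium without reference observations: ",
                     paste(orphan, collapse = ", ")))
  }

  is_ref <- table$strain == reference
  unit <- if (mode == "strain") table$strain
  else ifelse(is_ref, reference,
              paste(table$strain, table$replicate, sep = "|"))
  unit <- stats::relevel(factor(unit), ref = reference)
  n_ref <- sum(is_ref)
  if (mode == "replicate" && n_ref < 2L)
    ml_stop("ml_design_error",
            "replicate mode needs at least 2 reference replicates")

  d <- data.frame(unit = unit)
  if (adjust) d$medium <- factor(table$medium)
  X <- stats::model.matrix(if (adjust) ~ unit + medium else ~ unit, d)
  if (qr(X)$rank < ncol(X))
    ml_stop("ml_design_error",
            "singular design (a strain level is confounded)")
  p <- ncol(X)
  n <- nrow(X)
  if (n - p < 1L && mode == "replicate")
    ml_stop("ml_design_error", "no residual degrees of freedom")
  xtx_inv <- chol2inv(chol(crossprod(X)))
  lev <- levels(unit)[-1L]
  coef_names <- paste0("unit", lev)
  cn_idx <- match(coef_names, colnames(X))

  vals <- as.matrix(as.data.frame(table)[ids])
  complete <- !apply(is.na(vals), 2, any)

  zmat <- matrix(NA_real_, nrow = length(lev), ncol = length(ids),
                 dimnames = list(lev, ids))
  ref_z <- if (mode == "replicate")
    matrix(NA_real_, nrow = n_ref, ncol = length(ids),
           dimnames = list(paste(reference, table$replicate[is_ref],
                                 sep = "|"), ids))
  else NULL
  failed <- character()

  # gaussian traits with complete data: one multi-response least-squares fit
  g_fast <- ids[fam == "unbounded" & complete]
  if (length(g_fast)) {
    qr_x <- qr(X)
    cf <- qr.coef(qr_x, vals[, g_fast, drop = FALSE])
    res <- vals[, g_fast, drop = FALSE] - X %*% cf
    sigma2 <- colSums(res^2) / (n - p)
    se_scale <- sqrt(diag(xtx_inv)[cn_idx])
    zmat[, g_fast] <- cf[cn_idx, , drop = FALSE] /
      outer(se_scale, sqrt(sigma2))
    degenerate <- sigma2 <= 0 | !is.finite(sigma2)
    if (any(degenerate)) {
      failed <- c(failed, g_fast[degenerate])
      zmat[, g_fast[degenerate]] <- NA_real_
    }
  }

  slow <- setdiff(ids, g_fast)
  for (id in slow) {
    y <- vals[, id]
    keep <- is.finite(y)
    res <- tryCatch({
      Xi <- if (all(keep)) X else X[keep, , drop = FALSE]
      if (!all(keep) && qr(Xi)$rank < ncol(Xi))
        ml_stop("ml_design_error", "rank-deficient after NA removal")
      fit_unit_glm(Xi, y[keep], fam[[id]],
                   cell_count = table$cell_count[keep])
    }, morphlineage_error = function(e) NULL,
       error = function(e) NULL)
    if (is.null(res)) { failed <- c(failed, id); next }
    zmat[, id] <- res$coefficients[cn_idx] / res$standard_errors[cn_idx]
  }

  # reference replicates: leave-one-out studentized link-scale deviations,
  # formed within medium so medium effects cancel
  if (mode == "replicate") {
    ref_med <- table$medium[is_ref]
    cc_ref <- table$cell_count[is_ref]
    groups <- split(seq_len(n_ref), ref_med)
    for (id in ids) {
      g_all <- link_scale_values(vals[is_ref, id], fam[[id]], cc_ref)
      for (grp in groups) {
        g <- g_all[grp]
        fin <- is.finite(g)
        nn <- sum(fin)
        if (nn < 3L) next
        gs <- g[fin]
        S <- sum(gs); SS <- sum(gs^2)
        m_loo <- (S - gs) / (nn - 1)
        v_loo <- pmax((SS - gs^2 - (nn - 1) * m_loo^2) / (nn - 2), 0)
        z <- rep(NA_real_, length(g))
        z[fin] <- ifelse(v_loo > 0,
                         (gs - m_loo) /
                           (sqrt(v_loo) * sqrt(1 + 1 / (nn - 1))),
                         NA_real_)
        ref_z[grp, id] <- z
      }
    }
  }

  if (any(!is.finite(zmat[, setdiff(ids, failed), drop = FALSE]))) {
    inf_traits <- ids[apply(!is.finite(zmat) &
                              !is.na(zmat), 2, any)]
    failed <- unique(c(failed, inf_traits))
  }
  ok_ids <- setdiff(ids, failed)
  zmat <- zmat[, ok_ids, drop = FALSE]

  if (mode == "strain") {
    out <- rbind(matrix(0, 1, length(ok_ids),
                        dimnames = list(reference, ok_ids)),
                 zmat)
    row_strain <- rownames(out)
    row_replicate <- rep(NA_character_, nrow(out))
  } else {
    ref_z <- ref_z[, ok_ids, drop = FALSE]
    out <- rbind(ref_z, zmat)
    split_rows <- strsplit(rownames(out), "|", fixed = TRUE)
    row_strain <- vapply(split_rows, `[`, character(1), 1L)
    row_replicate <- vapply(split_rows, `[`, character(1), 2L)
  }
  structure(out,
            reference = reference, mode = mode,
            row_strain = row_strain, row_replicate = row_replicate,
            families = fam[ok_ids], failed = failed,
            media_adjusted = adjust, df_residual = n - p,
            class = c("z_matrix", "matrix"))
}

# Fit one trait's GLM on a prebuilt model matrix; returns coefficients,
# standard errors and the link-scale residual SD used for reference
# pseudo-Z values.
fit_unit_glm <- function(X, y, family, cell_count = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (family == "unbounded") {
    f <- stats::lm.fit(X, y)
    sigma2 <- sum(f$residuals^2) / (n - p)
    if (!is.finite(sigma2) || sigma2 <= 0)
      ml_stop("ml_fit_error", "degenerate gaussian fit")
    V <- chol2inv(chol(crossprod(X))) * sigma2
    list(coefficients = stats::setNames(f$coefficients, colnames(X)),
         standard_errors = stats::setNames(sqrt(diag(V)), colnames(X)))
  } else if (family == "positive") {
    if (any(y <= 0)) ml_stop("ml_domain_error", "nonpositive value")
    f <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::Gamma(link = "log")))
    if (!f$converged) ml_stop("ml_fit_error", "gamma fit did not converge")
    mu <- f$fitted.values
    disp <- sum(((y - mu) / mu)^2) / (n - p)
    if (!is.finite(disp) || disp <= 0)
      ml_stop("ml_fit_error", "degenerate gamma fit")
    Qr <- f$qr
    V <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE]) * disp
    list(coefficients = stats::setNames(f$coefficients, colnames(X)),
         standard_errors = stats::setNames(sqrt(diag(V)), colnames(X)))
  } else {
    yb <- y
    if (any(yb <= 0 | yb >= 1)) {
      nn <- cell_count %||% rep(200, length(yb))
      yb <- shrink_proportion(yb, nn)
    }
    b <- fit_beta_ml(X, yb)
    list(coefficients = b$coefficients,
         standard_errors = b$standard_errors)
  }
}

link_scale_values <- function(y, family, cell_count = NULL) {
  switch(family,
         unbounded = y,
         positive = log(y),
         proportion = {
           yb <- y
           bad <- !is.na(yb) & (yb <= 0 | yb >= 1)
           if (any(bad)) {
             nn <- cell_count %||% rep(200, length(yb))
             yb <- shrink_proportion(yb, nn)
           }
           stats::qlogis(yb)
         })
}

#' @export
print.z_matrix <- function(x, ...) {
  cat(sprintf(
    "<z_matrix> %d row(s) x %d trait(s), mode=%s, reference=%s%s\n",
    nrow(x), ncol(x), attr(x, "mode"), attr(x, "reference"),
    if (length(attr(x, "failed")))
      sprintf(", %d trait(s) failed to fit", length(attr(x, "failed")))
    else ""))
  invisible(x)
}

#' @export
`[.z_matrix` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  out <- m[i, j, drop = FALSE]
  ii <- stats::setNames(seq_len(nrow(m)), rownames(m))[i]
  jj <- stats::setNames(seq_len(ncol(m)), colnames(m))[j]
  structure(out,
            reference = attr(x, "reference"), mode = attr(x, "mode"),
            row_strain = attr(x, "row_strain")[ii],
            row_replicate = attr(x, "row_replicate")[ii],
            families = attr(x, "families")[jj],
            failed = attr(x, "failed"),
            media_adjusted = attr(x, "media_adjusted"),
            df_residual = attr(x, "df_residual"),
            class = c("z_matrix", "matrix"))
}

#' Rows of a Z-matrix belonging to one strain
#'
#' @param z a \code{\link{z_matrix}}.
#' @param strain strain id.
#' @return plain numeric matrix of that strain's row(s).
#' @export
z_rows_for <- function(z, strain) {
  stopifnot(inherits(z, "z_matrix"))
  rows <- which(attr(z, "row_strain") == strain)
  if (!length(rows))
    ml_stop("ml_design_error", paste0("strain not in Z matrix: ", strain))
  unclass(z)[rows, , drop = FALSE]
}

#' Medium-adjusted Z-profiles
#'
#' Convenience wrapper around \code{\link{z_matrix}} that always includes
#' the medium as an additive covariate, returning strain contrasts with the
#' medium effect removed. Intended for tables where the reference strain was
#' grown in every medium while each test strain appears in a single medium.
#'
#' @inheritParams z_matrix
#' @return a \code{z_matrix}.
#' @export
medium_adjusted_z <- function(table, reference = "reference",
                              mode = c("strain", "replicate"),
                              traits = NULL) {
  z_matrix(table, reference = reference, mode = match.arg(mode),
           media_adjust = "always", traits = traits)
}

#' Serialize a Z-matrix
#'
#' Writes the numeric matrix as tab-separated text plus a JSON sidecar
#' (\code{<path>.json}) recording the reference strain, mode, per-trait
#' family and the traits whose fits failed.
#'
#' @param z a \code{\link{z_matrix}}.
#' @param path output TSV path.
#' @export
write_z_matrix <- function(z, path) {
  stopifnot(inherits(z, "z_matrix"))
  df <- data.frame(row = rownames(z), unclass(z), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(reference = attr(z, "reference"), mode = attr(z, "mode"),
               media_adjusted = attr(z, "media_adjusted"),
               df_residual = attr(z, "df_residual"),
               families = as.list(attr(z, "families")),
               failed = attr(z, "failed"),
               row_strain = attr(z, "row_strain"),
               row_replicate = attr(z, "row_replicate"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_z_matrix
#' @export
read_z_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(m,
            reference = meta$reference, mode = meta$mode,
            row_strain = as.character(meta$row_strain),
            row_replicate = as.character(meta$row_replicate),
            families = unlist(meta$families),
            failed = as.character(meta$failed %||% character()),
            media_adjusted = isTRUE(meta$media_adjusted),
            df_residual = meta$df_residual,
            class = c("z_matrix", "matrix"))
}
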