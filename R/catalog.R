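#' Trait catalogs
#'
#' A trait catalog enumerates the 501 morphological traits produced by
#' CalMorph-style image analysis of triple-stained yeast cells (cell wall,
#' actin, nuclear DNA), together with the information downstream stages key
#' on: the value-domain family of each trait and whether it is one of the 220
#' "noise" traits that quantify cell-to-cell variability (coefficients of
#' variation) within an isogenic culture.
#'
#' Three value-domain families are distinguished, because they determine the
#' generalized linear model used to normalize a trait:
#' \describe{
#'   \item{\code{unbounded}}{real-valued traits (shape/angle deviations);
#'     gaussian model with identity link.}
#'   \item{\code{positive}}{strictly positive traits (sizes, lengths,
#'     intensities, and all CV noise traits); gamma model with log link.}
#'   \item{\code{proportion}}{traits in \eqn{[0,1]} (ratios, fractions of
#'     cells); beta model with logit link.}
#' }
#'
#' The shipped default catalog (\code{load_default_catalog()}) carries
#' generated identifiers in the style of the yeast morphological database
#' (\code{C}/\code{A}/\code{D} prefixes for cell, actin and nuclear-DNA
#' traits, \code{_CV} suffix for noise traits) with family assignments by
#' value-domain heuristic. Downstream computation depends only on
#' \code{family_class} and \code{is_noise}, never on trait identity, so users
#' holding the true trait list can supply their own catalog via
#' \code{read_trait_catalog()}.
#'
#' @param entries data.frame with columns \code{trait_id},
#'   \code{family_class}, \code{is_noise}, \code{description}.
#' @param strict enforce the full-catalog invariants (exactly 501 traits, 220
#'   of them noise). Set \code{FALSE} only for deliberately subsetted
#'   analyses.
#' @return An object of class \code{trait_catalog}: a validated data.frame.
#' @export
trait_catalog <- function(entries, strict = TRUE) {
  req <- c("trait_id", "family_class", "is_noise", "description")
  if (!is.data.frame(entries) || !all(req %in% names(entries)))
    ml_stop("ml_format_error",
            "catalog needs columns trait_id, family_class, is_noise, description")
  entries <- as.data.frame(entries)[req]
  entries$trait_id <- as.character(entries$trait_id)
  entries$family_class <- as.character(entries$family_class)
  entries$is_noise <- as.logical(entries$is_noise)
  if (anyDuplicated(entries$trait_id))
    ml_stop("ml_format_error", "duplicate trait_id in catalog")
  bad <- setdiff(unique(entries$family_class),
                 c("unbounded", "positive", "proportion"))
  if (length(bad))
    ml_stop("ml_format_error",
            paste0("unknown family_class: ", paste(bad, collapse = ", ")))
  if (anyNA(entries$is_noise))
    ml_stop("ml_format_error", "is_noise must be TRUE/FALSE for every trait")
  if (strict) {
    if (nrow(entries) != 501L)
      ml_stop("ml_format_error",
              sprintf("catalog must list exactly 501 traits, got %d",
                      nrow(entries)))
    if (sum(entries$is_noise) != 220L)
      ml_stop("ml_format_error",
              sprintf("catalog must flag exactly 220 noise traits, got %d",
                      sum(entries$is_noise)))
  }
  rownames(entries) <- NULL
  structure(entries, class = c("trait_catalog", "data.frame"))
}

#' @rdname trait_catalog
#' @export
load_default_catalog <- function() {
  pos_stems  <- c("area", "perimeter", "length", "width", "diameter",
                  "intensity", "distance", "region_size")
  prop_stems <- c("axis_ratio", "roundness", "region_ratio",
                  "localization_ratio", "cell_fraction")
  unb_stems  <- c("angle_deviation", "shape_deviation", "skewness")

  # mean traits: per-compartment counts chosen so the family totals cover all
  # three model families; C = cell wall/shape, A = actin, D = nuclear DNA
  plan <- data.frame(
    comp = c("C", "A", "D"),
    n_pos = c(40L, 30L, 26L),
    n_prop = c(50L, 30L, 31L),
    n_unb = c(30L, 20L, 24L)
  )
  mk <- function(comp, n, stems, family, start) {
    if (n == 0L) return(NULL)
    stem <- rep_len(stems, n)
    data.frame(
      trait_id = sprintf("%s%d_%s", comp, start + seq_len(n) - 1L, stem),
      family_class = family,
      is_noise = FALSE,
      description = sprintf("%s trait %s (%s)", comp, stem, family),
      stringsAsFactors = FALSE
    )
  }
  mean_traits <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
    p <- plan[i, ]
    rbind(
      mk(p$comp, p$n_pos, pos_stems, "positive", 101L),
      mk(p$comp, p$n_prop, prop_stems, "proportion", 201L),
      mk(p$comp, p$n_unb, unb_stems, "unbounded", 301L)
    )
  }))

  # 220 cell-to-cell variability (CV) traits; CVs are strictly positive
  cv_plan <- c(C = 94L, A = 63L, D = 63L)
  cv_traits <- do.call(rbind, lapply(names(cv_plan), function(comp) {
    n <- cv_plan[[comp]]
    stem <- rep_len(pos_stems, n)
    data.frame(
      trait_id = sprintf("%s%d_%s_CV", comp, 401L + seq_len(n) - 1L, stem),
      family_class = "positive",
      is_noise = TRUE,
      description = sprintf("%s cell-to-cell CV of %s", comp, stem),
      stringsAsFactors = FALSE
    )
  }))

  trait_catalog(rbind(mean_traits, cv_traits))
}

#' @rdname trait_catalog
#' @param path delimited text file (comma or tab) with the catalog columns.
#' @export
read_trait_catalog <- function(path, strict = TRUE) {
  sep <- sniff_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  trait_catalog(df, strict = strict)
}

#' @rdname trait_catalog
#' @param catalog a \code{trait_catalog}.
#' @param sep field separator for the written file.
#' @export
write_trait_catalog <- function(catalog, path, sep = "\t") {
  stopifnot(inherits(catalog, "trait_catalog"))
  utils::write.table(as.data.frame(catalog), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.trait_catalog <- function(x, ...) {
  cat(sprintf("<trait_catalog> %d traits (%d noise)\n", nrow(x),
              sum(x$is_noise)))
  print(table(family = x$family_class))
  invisible(x)
}

noise_trait_ids <- function(catalog) catalog$trait_id[catalog$is_noise]

trait_family <- function(catalog) {
  stats::setNames(catalog$family_class, catalog$trait_id)
}
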