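#' Read and write replicate-level trait tables
#'
#' A trait table holds the raw input of the pipeline: one row per strain x
#' replicate (x medium) culture, with the number of cells measured and the
#' value of every catalog trait for that culture. The expected file layout is
#' delimited text (tab or comma, auto-detected) with header
#' \code{strain,replicate,medium,cell_count,<trait ids...>}.
#'
#' Validation enforced on read and on construction:
#' \itemize{
#'   \item proportion-family trait values lie in \eqn{[0,1]}, positive-family
#'     values are strictly positive (violations raise a domain error naming
#'     the trait and row);
#'   \item \code{(strain, replicate)} pairs are unique;
#'   \item the trait columns cover exactly the catalog's trait ids; missing
#'     values (\code{NA}) are allowed, but a record missing more than 10\% of
#'     traits is rejected.
#' }
#'
#' @param path file to read or write.
#' @param catalog a \code{\link{trait_catalog}} the table must conform to.
#' @return \code{read_trait_table()} returns a \code{trait_table}: a
#'   data.frame with metadata columns \code{strain}, \code{replicate},
#'   \code{medium}, \code{cell_count} followed by one column per trait, with
#'   the catalog attached as attribute \code{catalog}.
#' @export
read_trait_table <- function(path, catalog) {
  sep <- sniff_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  trait_table(df, catalog)
}

#' @rdname read_trait_table
#' @param df data.frame in the trait-table layout.
#' @export
trait_table <- function(df, catalog) {
  stopifnot(inherits(catalog, "trait_catalog"))
  meta_cols <- c("strain", "replicate", "medium", "cell_count")
  missing_meta <- setdiff(meta_cols, names(df))
  if (length(missing_meta))
    ml_stop("ml_format_error",
            paste0("trait table lacks mandatory column(s): ",
                   paste(missing_meta, collapse = ", ")))
  ids <- catalog$trait_id
  missing_traits <- setdiff(ids, names(df))
  extra <- setdiff(names(df), c(meta_cols, ids))
  if (length(missing_traits))
    ml_stop("ml_format_error",
            sprintf("trait table lacks %d catalog trait(s), e.g. %s",
                    length(missing_traits), missing_traits[1]))
  if (length(extra))
    ml_stop("ml_format_error",
            sprintf("trait table has %d column(s) not in the catalog, e.g. %s",
                    length(extra), extra[1]))
  df <- df[c(meta_cols, ids)]
  df$strain <- as.character(df$strain)
  df$replicate <- as.character(df$replicate)
  df$medium <- as.character(df$medium)
  df$cell_count <- as.integer(df$cell_count)
  if (any(!is.finite(df$cell_count)) || any(df$cell_count <= 0L))
    ml_stop("ml_domain_error", "cell_count must be a positive integer")

  key <- paste(df$strain, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    ml_stop("ml_format_error",
            paste0("duplicated (strain, replicate) pair: ",
                   gsub("\r", "/", d)))
  }

  fam <- trait_family(catalog)
  for (id in ids) df[[id]] <- as.numeric(df[[id]])
  vals <- as.matrix(df[ids])
  prop <- ids[fam[ids] == "proportion"]
  pos <- ids[fam[ids] == "positive"]
  if (length(prop)) {
    bad <- which(vals[, prop, drop = FALSE] < 0 |
                   vals[, prop, drop = FALSE] > 1, arr.ind = TRUE)
    if (nrow(bad))
      ml_stop("ml_domain_error",
              sprintf("proportion trait %s outside [0,1] in row %d",
                      prop[bad[1, 2]], bad[1, 1]))
  }
  if (length(pos)) {
    bad <- which(vals[, pos, drop = FALSE] <= 0, arr.ind = TRUE)
    if (nrow(bad))
      ml_stop("ml_domain_error",
              sprintf("positive trait %s not > 0 in row %d",
                      pos[bad[1, 2]], bad[1, 1]))
  }
  n_missing <- rowSums(is.na(vals))
  too_sparse <- which(n_missing > 0.10 * length(ids))
  if (length(too_sparse))
    ml_stop("ml_domain_error",
            sprintf("record %s/%s is missing %d of %d traits (>10%%)",
                    df$strain[too_sparse[1]], df$replicate[too_sparse[1]],
                    n_missing[too_sparse[1]], length(ids)))

  rownames(df) <- NULL
  structure(df, catalog = catalog, class = c("trait_table", "data.frame"))
}

#' @rdname read_trait_table
#' @param table a \code{trait_table}.
#' @param sep field separator for the written file.
#' @export
write_trait_table <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "trait_table"))
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("<trait_table> %d records, %d strains, %d traits, media: %s\n",
              nrow(x), length(unique(x$strain)),
              nrow(attr(x, "catalog")),
              paste(unique(x$medium), collapse = ", ")))
  invisible(x)
}

#' Read and write breeding lineage graphs
#'
#' A lineage graph records the breeding history of a strain collection: each
#' edge names a child strain, its breeding type, and one parent (spontaneous
#' or mutagen-induced mutant isolation) or two parents (a cross, optionally
#' followed by mutagenesis). The file format is a whitespace-delimited edge
#' list, one edge per line: \code{child breeding_type parent1 [parent2]}.
#' Lines starting with \code{#} are ignored.
#'
#' The graph must be acyclic; cross-type edges require exactly two parents
#' and mutant-isolation edges exactly one.
#'
#' @param path file to read or write.
#' @return \code{read_lineage()} returns a \code{lineage_graph}: a list with
#'   \code{nodes} (all strain ids) and \code{edges} (data.frame with columns
#'   \code{child}, \code{breeding_type}, \code{parent1}, \code{parent2};
#'   \code{parent2} is \code{NA} for single-parent edges).
#' @export
read_lineage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t,]+")
  edges <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 3L)
      ml_stop("ml_format_error",
              sprintf("lineage line %d needs child, type, parent(s): '%s'",
                      i, lines[i]))
    data.frame(child = p[1], breeding_type = p[2], parent1 = p[3],
               parent2 = if (length(p) >= 4L) p[4] else NA_character_,
               stringsAsFactors = FALSE)
  })
  lineage_graph(do.call(rbind, edges))
}

#' @rdname read_lineage
#' @param edges data.frame with columns \code{child}, \code{breeding_type},
#'   \code{parent1}, optionally \code{parent2}.
#' @export
lineage_graph <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L)
    return(structure(list(nodes = character(),
                          edges = data.frame(child = character(),
                                             breeding_type = character(),
                                             parent1 = character(),
                                             parent2 = character())),
                     class = "lineage_graph"))
  if (!"parent2" %in% names(edges)) edges$parent2 <- NA_character_
  edges <- edges[c("child", "breeding_type", "parent1", "parent2")]
  for (cl in names(edges)) edges[[cl]] <- as.character(edges[[cl]])
  ok_types <- c("spontaneous", "mutagen", "cross", "cross_mutagen")
  bad <- setdiff(unique(edges$breeding_type), ok_types)
  if (length(bad))
    ml_stop("ml_format_error",
            paste0("unknown breeding_type: ", paste(bad, collapse = ", ")))
  is_cross <- edges$breeding_type %in% c("cross", "cross_mutagen")
  if (any(is_cross & is.na(edges$parent2)))
    ml_stop("ml_format_error",
            paste0("cross edge with a single parent: child ",
                   edges$child[which(is_cross & is.na(edges$parent2))[1]]))
  if (any(!is_cross & !is.na(edges$parent2)))
    ml_stop("ml_format_error",
            paste0("non-cross edge with two parents: child ",
                   edges$child[which(!is_cross & !is.na(edges$parent2))[1]]))
  if (anyDuplicated(edges$child))
    ml_stop("ml_lineage_error",
            paste0("strain derived twice: ",
                   edges$child[duplicated(edges$child)][1]))

  nodes <- unique(c(edges$parent1, edges$parent2, edges$child))
  nodes <- nodes[!is.na(nodes)]
  # Kahn topological sort; leftovers indicate a cycle (incl. self-edges)
  parents_of <- function(i) {
    p <- c(edges$parent1[i], edges$parent2[i])
    p[!is.na(p)]
  }
  placed <- setdiff(nodes, edges$child)
  remaining <- seq_len(nrow(edges))
  repeat {
    ready <- remaining[vapply(remaining, function(i)
      all(parents_of(i) %in% placed), logical(1))]
    if (!length(ready)) break
    placed <- c(placed, edges$child[ready])
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining))
    ml_stop("ml_lineage_error",
            paste0("lineage contains a cycle involving: ",
                   paste(unique(edges$child[remaining]), collapse = ", ")))

  structure(list(nodes = sort(nodes), edges = edges),
            class = "lineage_graph")
}

#' @rdname read_lineage
#' @param graph a \code{lineage_graph}.
#' @export
write_lineage <- function(graph, path) {
  stopifnot(inherits(graph, "lineage_graph"))
  e <- graph$edges
  lines <- ifelse(is.na(e$parent2),
                  paste(e$child, e$breeding_type, e$parent1),
                  paste(e$child, e$breeding_type, e$parent1, e$parent2))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat(sprintf("<lineage_graph> %d strains, %d breeding edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) print(table(type = x$edges$breeding_type))
  invisible(x)
}

#' Read and write genotype matrices
#'
#' Diploid genotypes coded as alternate-allele counts (0/1/2, \code{NA} for
#' missing) at biallelic sites. Two on-disk layouts are accepted: a TSV
#' matrix of sites x strains (first column = site id, header = strain ids)
#' and a minimal VCF in which only the GT field is used. Sites with more
#' than two alleles are dropped with a message giving the count.
#'
#' @param path file to read or write.
#' @param format \code{"auto"} detects VCF by the \code{##fileformat} header
#'   line or a \code{.vcf} extension.
#' @return \code{read_genotypes()} returns a \code{genotype_matrix}: an
#'   integer matrix with strains as rows and sites as columns.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^##fileformat=VCF", first) ||
                  grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  sites <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  suppressWarnings(storage.mode(m) <- "integer")
  raw <- as.matrix(df[-1])
  bad <- !is.na(raw) & is.na(m)
  if (any(bad))
    ml_stop("ml_format_error",
            sprintf("non-numeric genotype token '%s' at site %s",
                    raw[which(bad)[1]], sites[which(bad, arr.ind = TRUE)[1, 1]]))
  if (any(!is.na(m) & !(m %in% 0:2)))
    ml_stop("ml_format_error", "genotype codes must be 0, 1, 2 or NA")
  genotype_matrix(t(m), strains = colnames(df)[-1], sites = sites)
}

read_genotypes_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"])
    gt <- vcfR::extract.gt(v, element = "GT")
  } else {
    lines <- readLines(path, warn = FALSE)
    body <- lines[!startsWith(lines, "##")]
    hdr <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
    rows <- strsplit(body[-1], "\t")
    fix <- do.call(rbind, lapply(rows, function(r) r[seq_len(8)]))
    colnames(fix) <- hdr[seq_len(8)]
    multi <- grepl(",", fix[, "ALT"])
    fmt_i <- which(hdr == "FORMAT")
    gt <- do.call(rbind, lapply(rows, function(r) {
      keys <- strsplit(r[fmt_i], ":")[[1]]
      gi <- which(keys == "GT")
      vapply(r[-seq_len(fmt_i)], function(cell)
        strsplit(cell, ":")[[1]][gi], character(1))
    }))
    colnames(gt) <- hdr[-seq_len(fmt_i)]
  }
  if (any(multi))
    message(sprintf("read_genotypes: dropped %d site(s) with >2 alleles",
                    sum(multi)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  sites <- paste(fix[, "CHROM"], fix[, "POS"], sep = ":")
  alleles <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(as.integer(a) > 0L)
  }
  calls <- apply(gt, c(1, 2), alleles)
  genotype_matrix(t(calls), strains = colnames(gt), sites = sites)
}

#' @rdname read_genotypes
#' @param calls integer matrix of 0/1/2/NA, strains x sites.
#' @param strains,sites row and column identifiers.
#' @export
genotype_matrix <- function(calls, strains = rownames(calls),
                            sites = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(strains) || is.null(sites))
    ml_stop("ml_format_error", "genotype matrix needs strain and site ids")
  if (length(strains) != nrow(calls) || length(sites) != ncol(calls))
    ml_stop("ml_format_error", "genotype matrix dimensions inconsistent")
  suppressWarnings(storage.mode(calls) <- "integer")
  if (any(!is.na(calls) & !(calls %in% 0:2)))
    ml_stop("ml_format_error", "genotype codes must be 0, 1, 2 or NA")
  dimnames(calls) <- list(strains, sites)
  structure(calls, class = c("genotype_matrix", "matrix"))
}

#' @rdname read_genotypes
#' @param genotypes a \code{genotype_matrix}.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  df <- data.frame(site = colnames(genotypes),
                   t(unclass(genotypes)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d strains x %d sites (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

# Detect tab vs comma separation from the header line.
sniff_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first))
    ml_stop("ml_format_error", paste0("empty file: ", path))
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com && n_tab > 0) "\t"
  else if (n_com > 0) ","
  else "\t"
}
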