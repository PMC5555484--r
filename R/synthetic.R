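#' Specification for a synthetic breeding cohort
#'
#' Defines the generative model used to emulate a morphological phenotyping
#' study of a breeding lineage: per-trait baselines for the reference
#' strain, founder strains deviating on a subset of traits, breeding events
#' (spontaneous or mutagen-induced mutant isolation shifting few or many
#' traits, crosses placing the child at the mid-parent with an optional
#' inbreeding-deviation term), an optional per-strain inflation of the
#' cell-to-cell noise traits, and family-appropriate within-replicate
#' sampling noise.
#'
#' All strain effects are injected on the linear-predictor (link) scale in
#' units of the within-replicate link-scale SD of the trait's family, so an
#' effect of size \code{delta} produces an expected per-replicate Wald Z of
#' about \code{delta} regardless of family.
#'
#' @param founders character vector of founder strain ids.
#' @param events list of breeding events, each a list with \code{child},
#'   \code{type} (\code{spontaneous}, \code{mutagen}, \code{cross},
#'   \code{cross_mutagen}), \code{parents} (one or two ids), and optional
#'   \code{k_traits}, \code{delta}, \code{sigma_dev},
#'   \code{noise_inflation}. \code{NULL} uses
#'   \code{\link{default_breeding_events}}.
#' @param n_replicates replicates per non-reference strain (default 5).
#' @param n_ref_replicates reference replicates per medium (default 11).
#' @param catalog a \code{\link{trait_catalog}} (default the shipped one).
#' @param reference reference strain id (default \code{"reference"}).
#' @param founder_k_traits,founder_delta number of traits on which each
#'   founder deviates from the reference, and the effect size (within-SD
#'   units).
#' @param k_spontaneous,k_mutagen default trait counts shifted by the two
#'   mutant-isolation modes (5 and 50).
#' @param delta default effect size of breeding events (within-SD units).
#' @param sigma_dev default inbreeding-deviation SD of crosses (within-SD
#'   units).
#' @param strain_media optional named character vector assigning each
#'   non-reference strain a medium; default: all in \code{"YPD"}. The
#'   reference is replicated in every medium used.
#' @param medium_effect link-scale shift (within-SD units) added to every
#'   trait in media other than the first (scalar, or per-trait vector).
#' @param sd_gaussian within-replicate SD of unbounded traits.
#' @param cv_positive within-replicate coefficient of variation of positive
#'   traits.
#' @param phi_proportion beta precision of proportion traits.
#' @param n_sites,founder_mutations,mutations_per_event genotype-simulation
#'   sizes: biallelic site count, Poisson mean of founder private SNPs, and
#'   Poisson mean of new SNPs per breeding event (mutagen events use four
#'   times the rate).
#' @param seed integer seed fixing the whole output stream.
#' @return a \code{synthetic_spec} (validated list).
#' @export
synthetic_spec <- function(founders = c("K6", "K7", "K9", "K10"),
                           events = NULL,
                           n_replicates = 5L, n_ref_replicates = 11L,
                           catalog = load_default_catalog(),
                           reference = "reference",
                           founder_k_traits = 30L, founder_delta = 1,
                           k_spontaneous = 5L, k_mutagen = 50L,
                           delta = 1, sigma_dev = 0.5,
                           strain_media = NULL, medium_effect = 0,
                           sd_gaussian = 1, cv_positive = 0.2,
                           phi_proportion = 100,
                           n_sites = 300L, founder_mutations = 40,
                           mutations_per_event = 12,
                           seed = 1L) {
  events <- events %||% default_breeding_events()
  stopifnot(inherits(catalog, "trait_catalog"))
  if (!is_count(n_replicates) || !is_count(n_ref_replicates) ||
      !is_count(n_sites) || !is_count(seed + 1))
    ml_stop("ml_spec_error", "counts and seed must be positive integers")
  for (nm in c("founder_delta", "delta", "sigma_dev", "sd_gaussian",
               "cv_positive", "phi_proportion")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      ml_stop("ml_spec_error", paste0(nm, " must be a nonnegative number"))
  }
  if (sd_gaussian <= 0 || cv_positive <= 0 || phi_proportion <= 0)
    ml_stop("ml_spec_error", "noise parameters must be positive")
  for (e in events) {
    if (is.null(e$child) || is.null(e$type) || is.null(e$parents))
      ml_stop("ml_spec_error", "every event needs child, type, parents")
    if (e$type %in% c("cross", "cross_mutagen") && length(e$parents) != 2L)
      ml_stop("ml_spec_error",
              paste0("cross event for ", e$child, " needs two parents"))
    if (!e$type %in% c("cross", "cross_mutagen") && length(e$parents) != 1L)
      ml_stop("ml_spec_error",
              paste0("event for ", e$child, " needs one parent"))
    infl <- e$noise_inflation %||% 1
    if (infl < 0) ml_stop("ml_spec_error", "noise_inflation must be >= 0")
  }
  structure(list(founders = founders, events = events,
                 n_replicates = as.integer(n_replicates),
                 n_ref_replicates = as.integer(n_ref_replicates),
                 catalog = catalog, reference = reference,
                 founder_k_traits = as.integer(founder_k_traits),
                 founder_delta = founder_delta,
                 k_spontaneous = as.integer(k_spontaneous),
                 k_mutagen = as.integer(k_mutagen),
                 delta = delta, sigma_dev = sigma_dev,
                 strain_media = strain_media,
                 medium_effect = medium_effect,
                 sd_gaussian = sd_gaussian, cv_positive = cv_positive,
                 phi_proportion = phi_proportion,
                 n_sites = as.integer(n_sites),
                 founder_mutations = founder_mutations,
                 mutations_per_event = mutations_per_event,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_breeding_events <- function() {
  list(
    list(child = "K601", type = "spontaneous", parents = "K6"),
    list(child = "K701", type = "spontaneous", parents = "K7"),
    list(child = "K901", type = "spontaneous", parents = "K9"),
    list(child = "K1001", type = "spontaneous", parents = "K10"),
    list(child = "K1701", type = "mutagen", parents = "K7"),
    list(child = "K13", type = "cross", parents = c("K9", "K10"))
  )
}

# within-replicate SD of each trait on its link scale, used to express
# injected effects in comparable units across families
link_sd_by_family <- function(spec, baseline_logit_mu = 0.5) {
  c(unbounded = spec$sd_gaussian,
    positive = spec$cv_positive,
    proportion = sqrt(1 / ((1 + spec$phi_proportion) *
                             baseline_logit_mu * (1 - baseline_logit_mu))))
}

#' Generate a synthetic cohort
#'
#' Draws a full study from a \code{\link{synthetic_spec}}: a replicate-level
#' trait table (reference strain included with its larger replicate
#' number), the breeding lineage graph, a genotype matrix whose pairwise
#' distances track lineage depth, and a ground-truth record of every
#' injected effect. The same seed yields byte-identical output.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{table} (\code{trait_table}), \code{lineage}
#'   (\code{lineage_graph}), \code{genotypes} (\code{genotype_matrix}) and
#'   \code{truth} (list: per-strain link-scale effect matrix, per-event
#'   shifted traits, noise inflations).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  catalog <- spec$catalog
  ids <- catalog$trait_id
  fam <- trait_family(catalog)
  p <- length(ids)
  with_seed(spec$seed, {
    # reference baselines on the link scale
    base <- numeric(p); names(base) <- ids
    unb <- fam == "unbounded"; pos <- fam == "positive"
    prop <- fam == "proportion"; noise <- catalog$is_noise
    base[unb] <- stats::rnorm(sum(unb), 0, 0.5)
    base[pos & !noise] <- stats::rnorm(sum(pos & !noise), log(10), 1)
    base[pos & noise] <- stats::rnorm(sum(pos & noise), log(0.15), 0.3)
    base[prop] <- stats::qlogis(stats::runif(sum(prop), 0.2, 0.8))

    mu_prop <- mean(stats::plogis(base[prop]))
    lsd_fam <- link_sd_by_family(spec, baseline_logit_mu = mu_prop)
    lsd <- lsd_fam[fam]; names(lsd) <- ids

    strains <- c(spec$founders, vapply(spec$events, `[[`, "", "child"))
    if (anyDuplicated(strains))
      ml_stop("ml_spec_error", "duplicated strain id in scenario")
    eff <- matrix(0, nrow = length(strains), ncol = p,
                  dimnames = list(strains, ids))
    truth_events <- list()

    for (f in spec$founders) {
      k <- min(spec$founder_k_traits, p)
      if (k > 0L && spec$founder_delta > 0) {
        sel <- sample(ids, k)
        sgn <- sample(c(-1, 1), k, replace = TRUE)
        eff[f, sel] <- sgn * spec$founder_delta * lsd[sel]
        truth_events[[f]] <- list(strain = f, type = "founder",
                                  traits = sel, delta = spec$founder_delta)
      }
    }

    edge_rows <- list()
    for (e in spec$events) {
      miss <- setdiff(e$parents, rownames(eff))
      if (length(miss))
        ml_stop("ml_spec_error",
                paste0("event parent(s) not yet defined: ",
                       paste(miss, collapse = ", ")))
      child_eff <- if (length(e$parents) == 2L)
        colMeans(eff[e$parents, , drop = FALSE])
      else eff[e$parents, ]
      shifted <- character()
      if (e$type %in% c("cross", "cross_mutagen")) {
        sdev <- e$sigma_dev %||% spec$sigma_dev
        if (sdev > 0)
          child_eff <- child_eff + stats::rnorm(p, 0, sdev) * lsd
      }
      if (e$type %in% c("spontaneous", "mutagen", "cross_mutagen")) {
        k <- e$k_traits %||%
          if (e$type == "spontaneous") spec$k_spontaneous else spec$k_mutagen
        k <- min(k, p)
        dlt <- e$delta %||% spec$delta
        if (k > 0L && dlt > 0) {
          shifted <- sample(ids, k)
          sgn <- sample(c(-1, 1), k, replace = TRUE)
          child_eff[shifted] <- child_eff[shifted] + sgn * dlt * lsd[shifted]
        }
      }
      infl <- e$noise_inflation %||% 1
      if (infl != 1)
        child_eff[noise] <- child_eff[noise] + log(infl)
      eff[e$child, ] <- child_eff
      truth_events[[e$child]] <- list(strain = e$child, type = e$type,
                                      parents = e$parents, traits = shifted,
                                      noise_inflation = infl)
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        child = e$child, breeding_type = e$type, parent1 = e$parents[1],
        parent2 = if (length(e$parents) == 2L) e$parents[2] else NA_character_)
    }
    lineage <- lineage_graph(do.call(rbind, edge_rows))

    # media assignment; the reference is replicated in every medium used
    media_of <- spec$strain_media %||%
      stats::setNames(rep("YPD", length(strains)), strains)
    media <- unique(c("YPD", unname(media_of)))
    med_eff <- rep(0, p); names(med_eff) <- ids
    if (length(media) > 1L) {
      me <- spec$medium_effect
      med_eff[] <- (if (length(me) == p) me else rep(me, length.out = p)) * lsd
    }

    draw_replicates <- function(strain, eta, n_reps, medium,
                                rep_ids = paste0("r", seq_len(n_reps))) {
      eta_m <- eta + if (medium != media[1]) med_eff else 0
      vals <- matrix(NA_real_, nrow = n_reps, ncol = p,
                     dimnames = list(NULL, ids))
      nu <- sum(unb); npo <- sum(pos); npr <- sum(prop)
      for (r in seq_len(n_reps)) {
        vals[r, unb] <- stats::rnorm(nu, eta_m[unb], spec$sd_gaussian)
        shape <- 1 / spec$cv_positive^2
        vals[r, pos] <- stats::rgamma(npo, shape = shape,
                                      rate = shape / exp(eta_m[pos]))
        mu <- stats::plogis(eta_m[prop])
        vals[r, prop] <- stats::rbeta(npr, mu * spec$phi_proportion,
                                      (1 - mu) * spec$phi_proportion)
      }
      # guard against underflow to exact 0/1 at extreme mu
      vals[, prop] <- pmin(pmax(vals[, prop], 1e-12), 1 - 1e-12)
      data.frame(strain = strain, replicate = rep_ids,
                 medium = medium,
                 cell_count = sample(200:400, n_reps, replace = TRUE),
                 vals, check.names = FALSE)
    }

    recs <- list()
    for (m in media) {
      rep_ids <- if (length(media) == 1L)
        paste0("r", seq_len(spec$n_ref_replicates))
      else paste0(m, "_r", seq_len(spec$n_ref_replicates))
      recs[[paste0("ref_", m)]] <-
        draw_replicates(spec$reference, base, spec$n_ref_replicates, m,
                        rep_ids = rep_ids)
    }
    for (s in strains)
      recs[[s]] <- draw_replicates(s, base + eff[s, ], spec$n_replicates,
                                   media_of[[s]] %||% "YPD")
    table <- trait_table(do.call(rbind, recs), catalog)

    # genotypes: founder private SNPs + Poisson new SNPs per breeding event
    geno <- matrix(0L, nrow = length(strains) + 1L, ncol = spec$n_sites,
                   dimnames = list(c(spec$reference, strains),
                                   sprintf("site%03d", seq_len(spec$n_sites))))
    mutate <- function(g, lambda) {
      k <- min(stats::rpois(1, lambda), spec$n_sites)
      if (k > 0L) {
        at <- sample(spec$n_sites, k)
        g[at] <- sample(0:2, k, replace = TRUE)
      }
      g
    }
    for (f in spec$founders)
      geno[f, ] <- mutate(geno[spec$reference, ], spec$founder_mutations)
    for (e in spec$events) {
      g <- if (length(e$parents) == 2L) {
        m2 <- colMeans(geno[e$parents, , drop = FALSE])
        floor(m2) + stats::rbinom(spec$n_sites, 1L, m2 - floor(m2))
      } else geno[e$parents, ]
      lambda <- spec$mutations_per_event *
        if (e$type %in% c("mutagen", "cross_mutagen")) 4 else 1
      geno[e$child, ] <- mutate(as.integer(g), lambda)
    }
    genotypes <- genotype_matrix(geno)

    list(table = table, lineage = lineage, genotypes = genotypes,
         truth = list(baseline = base, effects = eff, link_sd = lsd,
                      medium_effect = med_eff, events = truth_events,
                      media_of = media_of))
  })
}

#' Generate a segregant panel in score space
#'
#' Stand-in for a published segregant panel from a cross of two distant
#' strains: each segregant lies at the parents' mid-point plus an isotropic
#' gaussian deviation of SD \code{deviation} per coordinate. Used to
#' benchmark cross-distance ratios of bred hybrids against segregation
#' without an inbreeding-deviation term.
#'
#' @param parent_a,parent_b parent profiles: numeric vectors, or replicate
#'   matrices (averaged).
#' @param n_segregants number of segregants (>= 1).
#' @param deviation isotropic SD around the mid-parent point.
#' @param seed integer seed.
#' @return matrix with \code{n_segregants} rows in the parents' coordinate
#'   space.
#' @export
generate_segregant_panel <- function(parent_a, parent_b, n_segregants,
                                     deviation, seed = 1L) {
  if (!is_count(n_segregants))
    ml_stop("ml_spec_error", "n_segregants must be a positive integer")
  if (!is.numeric(deviation) || deviation < 0)
    ml_stop("ml_spec_error", "deviation must be >= 0")
  a <- if (is.matrix(parent_a)) colMeans(parent_a) else parent_a
  b <- if (is.matrix(parent_b)) colMeans(parent_b) else parent_b
  if (length(a) != length(b))
    ml_stop("ml_schema_error", "parent profiles differ in length")
  mid <- (a + b) / 2
  with_seed(seed, {
    dev <- matrix(stats::rnorm(n_segregants * length(mid), 0, deviation),
                  nrow = n_segregants)
    sweep(dev, 2, mid, `+`)
  })
}
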