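Package: morphlineage
Title: High-Dimensional Morphological Phenotyping of Yeast Breeding Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for diagnosing lineage and differentiation in yeast
    breeding programs from high-dimensional morphological trait tables of the
    kind produced by automated single-cell image analysis (CalMorph-style, 501
    traits). Per-trait generalized linear models normalize raw trait values
    into Wald Z-profiles against a reference strain, with AIC model selection,
    likelihood-ratio screening and Bonferroni correction; principal component
    analysis builds an orthogonal phenotypic space with cumulative contribution
    ratio thresholds; Euclidean-distance statistics over a breeding lineage
    quantify parent-progeny change, mid-parent deviation of hybrids and
    cross-distance ratios; phenotypic potential scores cell-to-cell noise
    traits and compares strains against a control by Dunnett's procedure;
    strains are clustered by correlation dissimilarity of component scores
    with bootstrap support; and pairwise SNP-difference proportions are
    related to phenotypic similarity by rank correlation. A seeded synthetic
    cohort generator with the same statistical structure makes every stage
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
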