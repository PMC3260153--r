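Package: autozyg
Title: Autozygosity Mapping and Recessive-Variant Filtering for Founder
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for disease-gene discovery in consanguineous founder
    populations. Implements homozygosity-LOD (autozygosity) mapping from
    SNP-array genotypes: per-individual runs of homozygosity, shared
    identically-homozygous blocks across affected individuals scored by
    cumulative two-point LOD location scores, and exclusion/linkage-region
    enumeration in nuclear families using unaffected siblings. Implements the
    exome candidate-variant cascade (catalog novelty, homozygosity in
    affecteds, consequence class, mapped-interval intersection, cross-sample
    mutation-homogeneity scan, Mendelian segregation check) and carrier
    screening summaries. Includes a gene-drop simulator of endogamous demes
    with planted identity-by-descent segments and a planted pathogenic
    variant, so that every stage of the pipeline can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
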