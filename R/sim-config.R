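# Simulation configuration ---------------------------------------------------

# Per-class expected autosomal variant calls per exome, and how many of those
# are absent from both reference catalogs. These calibrate the background
# variant generator to what a founder-population exome typically yields
# (roughly 16.5k autosomal variants per sample, ~667 of them novel, ~22
# novel and homozygous).
.consequence_classes <- c(
  "5'-flanking", "5'-UTR", "3'-UTR", "intron", "missense", "nonsense",
  "read-through", "splice site", "synonymous", "miRNA", "IGR", "other",
  "indel"
)

.class_counts_total <- c(
  "5'-flanking" = 12, "5'-UTR" = 25, "3'-UTR" = 29, "intron" = 207,
  "missense" = 6936, "nonsense" = 46, "read-through" = 10,
  "splice site" = 16, "synonymous" = 8931, "miRNA" = 5, "IGR" = 56,
  "other" = 62, "indel" = 203
)

.class_counts_novel <- c(
  "5'-flanking" = 1, "5'-UTR" = 0, "3'-UTR" = 1, "intron" = 8,
  "missense" = 348, "nonsense" = 9, "read-through" = 1, "splice site" = 1,
  "synonymous" = 220, "miRNA" = 1, "IGR" = 1, "other" = 1, "indel" = 75
)

#' Consequence classes recognised by the package
#'
#' The thirteen functional consequence categories a variant record may carry.
#' Consequence classes are consumed as annotations; the package never
#' computes them from sequence.
#'
#' @return Character vector of the thirteen class names.
#' @export
consequence_classes <- function() .consequence_classes

# SNP-array marker densities, markers per Mb of autosome. A genome-wide 10K
# panel over ~2.88 Gb of autosome is ~3.5 markers/Mb; a 50K panel ~17.4/Mb.
.density_presets <- c("10K" = 3.5, "50K" = 17.4)

#' Build a simulation configuration
#'
#' Collects every knob of the founder-population simulator into a validated
#' configuration object. Defaults emulate an endogamous deme study: a
#' 50K-like SNP panel, parental kinship giving offspring inbreeding
#' coefficients in the 2.5--4% range, a planted 4.4 Mb autozygous block
#' shared by all affected individuals, and exome backgrounds of roughly
#' 16.5 thousand variant calls per sample of which ~4% are novel
#' (absent from both simulated catalogs).
#'
#' @param n_founder_haplotypes Number of distinct founder haplotypes in the
#'   deme pool (>= 4).
#' @param chromosome_lengths Named numeric vector, chromosome -> length in bp.
#' @param target_inbreeding_F Expected inbreeding coefficient of affected
#'   individuals; the pedigree builder picks the consanguinity-loop depth
#'   whose expectation is closest (1/16, 1/32 or 1/64).
#' @param marker_density_per_mb Either a preset name (`"10K"`, `"50K"`) or a
#'   numeric density in markers per Mb.
#' @param genotype_error_rate Per-call probability that an array genotype is
#'   replaced by one of the two other codes.
#' @param missing_call_rate Per-call probability of a missing genotype.
#' @param recombination_rate_per_mb Expected crossovers per Mb per meiosis
#'   (0.01 = one crossover per 100 Mb, i.e. 1 cM/Mb, sex-averaged, no
#'   interference).
#' @param exome_variant_rate Expected autosomal variant calls per exome.
#' @param novel_fraction Fraction of variant calls absent from all simulated
#'   catalogs.
#' @param novel_hom_fraction Fraction of novel calls that are homozygous.
#' @param consequence_class_weights Named probability vector over
#'   [consequence_classes()] for catalogued ("known") background variants.
#' @param novel_class_weights Same, for novel background variants (the novel
#'   spectrum is strongly enriched for coding classes).
#' @param pathogenic_block_chrom,pathogenic_block_start,pathogenic_block_end
#'   Location of the planted autozygous segment (1-based closed bp).
#' @param pathogenic_pos Position of the planted pathogenic variant; must lie
#'   inside the planted block. Default: block midpoint.
#' @param pathogenic_consequence Consequence class of the planted variant.
#' @param n_controls Number of unrelated population controls genotyped on the
#'   array panel (used downstream for allele-frequency estimation).
#' @param catalogs Names of the simulated reference catalogs.
#' @param rng_seed Integer seed; fans out to independent per-stage streams,
#'   so identical config + seed gives byte-identical output.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_founder_haplotypes = 40,
                       chromosome_lengths = c(chr1 = 120e6, chr2 = 80e6),
                       target_inbreeding_F = 1 / 32,
                       marker_density_per_mb = "50K",
                       genotype_error_rate = 0.005,
                       missing_call_rate = 0.01,
                       recombination_rate_per_mb = 0.01,
                       exome_variant_rate = 16540,
                       novel_fraction = 667 / 16540,
                       novel_hom_fraction = 22 / 667,
                       consequence_class_weights = NULL,
                       novel_class_weights = NULL,
                       pathogenic_block_chrom = "chr1",
                       pathogenic_block_start = 40e6,
                       pathogenic_block_end = 44.4e6 - 1,
                       pathogenic_pos = NULL,
                       pathogenic_consequence = "splice site",
                       n_controls = 100,
                       catalogs = c("dbSNP129", "1KG"),
                       rng_seed = 1L) {
  if (is.character(marker_density_per_mb)) {
    if (marker_density_per_mb %in% names(.density_presets)) {
      marker_density_per_mb <- .density_presets[[marker_density_per_mb]]
    } else if (!is.na(suppressWarnings(as.numeric(marker_density_per_mb)))) {
      marker_density_per_mb <- as.numeric(marker_density_per_mb)
    } else {
      abort_config("unknown marker density preset: ", marker_density_per_mb)
    }
  }
  # tolerate stringly-typed numbers (e.g. YAML "40.0e6")
  num_field <- function(x) {
    if (is.list(x)) x <- unlist(x)
    if (is.character(x)) {
      y <- suppressWarnings(as.numeric(x))
      if (any(is.na(y) & !is.na(x))) abort_config("non-numeric value in config")
      names(y) <- names(x)
      return(y)
    }
    x
  }
  chromosome_lengths <- num_field(chromosome_lengths)
  target_inbreeding_F <- num_field(target_inbreeding_F)
  genotype_error_rate <- num_field(genotype_error_rate)
  missing_call_rate <- num_field(missing_call_rate)
  recombination_rate_per_mb <- num_field(recombination_rate_per_mb)
  exome_variant_rate <- num_field(exome_variant_rate)
  novel_fraction <- num_field(novel_fraction)
  novel_hom_fraction <- num_field(novel_hom_fraction)
  pathogenic_block_start <- num_field(pathogenic_block_start)
  pathogenic_block_end <- num_field(pathogenic_block_end)
  if (!is.null(pathogenic_pos)) pathogenic_pos <- num_field(pathogenic_pos)
  n_controls <- num_field(n_controls)
  if (is.null(consequence_class_weights)) {
    known <- .class_counts_total - .class_counts_novel
    consequence_class_weights <- known / sum(known)
  }
  if (is.null(novel_class_weights)) {
    novel_class_weights <- .class_counts_novel / sum(.class_counts_novel)
  }
  if (is.null(pathogenic_pos)) {
    pathogenic_pos <- floor((pathogenic_block_start + pathogenic_block_end) / 2)
  }
  cfg <- structure(list(
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    chromosome_lengths = chromosome_lengths,
    target_inbreeding_F = target_inbreeding_F,
    marker_density_per_mb = marker_density_per_mb,
    genotype_error_rate = genotype_error_rate,
    missing_call_rate = missing_call_rate,
    recombination_rate_per_mb = recombination_rate_per_mb,
    exome_variant_rate = exome_variant_rate,
    novel_fraction = novel_fraction,
    novel_hom_fraction = novel_hom_fraction,
    consequence_class_weights = consequence_class_weights,
    novel_class_weights = novel_class_weights,
    pathogenic_block_chrom = pathogenic_block_chrom,
    pathogenic_block_start = pathogenic_block_start,
    pathogenic_block_end = pathogenic_block_end,
    pathogenic_pos = pathogenic_pos,
    pathogenic_consequence = pathogenic_consequence,
    n_controls = as.integer(n_controls),
    catalogs = catalogs,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$genotype_error_rate, cfg$missing_call_rate,
             cfg$novel_fraction, cfg$novel_hom_fraction,
             cfg$target_inbreeding_F)
  if (any(probs < 0 | probs > 1))
    abort_config("all probabilities and F must lie in [0, 1]")
  if (cfg$n_founder_haplotypes < 4)
    abort_config("n_founder_haplotypes must be >= 4")
  if (is.null(names(cfg$chromosome_lengths)) ||
      any(!nzchar(names(cfg$chromosome_lengths))))
    abort_config("chromosome_lengths must be a named vector")
  if (any(cfg$chromosome_lengths <= 0))
    abort_config("chromosome lengths must be positive")
  if (!cfg$pathogenic_block_chrom %in% names(cfg$chromosome_lengths))
    abort_config("pathogenic block chromosome not in chromosome_lengths")
  clen <- cfg$chromosome_lengths[[cfg$pathogenic_block_chrom]]
  if (cfg$pathogenic_block_start < 1 || cfg$pathogenic_block_end > clen ||
      cfg$pathogenic_block_start >= cfg$pathogenic_block_end)
    abort_config("planted block must lie inside its chromosome")
  if (cfg$pathogenic_pos < cfg$pathogenic_block_start ||
      cfg$pathogenic_pos > cfg$pathogenic_block_end)
    abort_config("pathogenic_pos must lie inside the planted block")
  if (!setequal(names(cfg$consequence_class_weights), .consequence_classes) ||
      !setequal(names(cfg$novel_class_weights), .consequence_classes))
    abort_config("class weights must cover exactly the thirteen classes")
  if (abs(sum(cfg$consequence_class_weights) - 1) > 1e-8 ||
      abs(sum(cfg$novel_class_weights) - 1) > 1e-8)
    abort_config("class weights must sum to 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Founder-population simulation config\n")
  cat(sprintf("  founder haplotypes : %d\n", x$n_founder_haplotypes))
  cat(sprintf("  genome             : %s (%.0f Mb)\n",
              paste(names(x$chromosome_lengths), collapse = ", "),
              sum(x$chromosome_lengths) / 1e6))
  cat(sprintf("  marker density     : %.1f /Mb\n", x$marker_density_per_mb))
  cat(sprintf("  target F           : %.4f\n", x$target_inbreeding_F))
  cat(sprintf("  planted block      : %s:%.0f-%.0f (%.1f Mb)\n",
              x$pathogenic_block_chrom, x$pathogenic_block_start,
              x$pathogenic_block_end,
              interval_size_mb(x$pathogenic_block_start,
                               x$pathogenic_block_end)))
  cat(sprintf("  exome rate         : %.0f calls/sample (%.1f%% novel)\n",
              x$exome_variant_rate, 100 * x$novel_fraction))
  cat(sprintf("  seed               : %d\n", x$rng_seed))
  invisible(x)
}
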