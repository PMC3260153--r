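# Candidate-variant filtering cascade ----------------------------------------

#' Flag catalog novelty
#'
#' A variant is novel when it appears in none of the named reference
#' catalogs -- novelty is pure set-membership against catalog flags, never
#' a frequency judgement.
#'
#' @param variants A `variant_table`.
#' @param catalog_names Catalogs that define "known" (e.g.
#'   `c("dbSNP129", "1KG")`).
#' @param available_catalogs The catalog universe; requesting a name outside
#'   it is a configuration error. Default: the names observed in the table
#'   plus `catalog_names` seen there; pass explicitly to be strict.
#' @return The table with a logical `novel` column added.
#' @export
annotate_novelty <- function(variants, catalog_names = c("dbSNP129", "1KG"),
                             available_catalogs = NULL) {
  flags <- strsplit(variants$catalogs, ",", fixed = TRUE)
  observed <- unique(unlist(flags))
  observed <- observed[nzchar(observed)]
  if (is.null(available_catalogs))
    available_catalogs <- union(observed, catalog_names)
  unknown <- setdiff(catalog_names, available_catalogs)
  if (length(unknown))
    abort_config("unknown catalog name(s): ", paste(unknown, collapse = ", "))
  variants$novel <- !vapply(flags, function(f) any(f %in% catalog_names),
                            logical(1))
  variants
}

.default_pathogenic_classes <- c("missense", "nonsense", "read-through",
                                 "splice site", "indel")

#' Classify pathogenic potential of a consequence class
#'
#' Returns `TRUE` for classes with protein-altering potential (by default
#' missense, nonsense, read-through, splice site and indel) and `FALSE` for
#' synonymous, intronic, UTR, flanking, miRNA, intergenic and other classes.
#' The pathogenic set is configurable.
#'
#' @param consequence_class Character vector of classes (see
#'   [consequence_classes()]).
#' @param pathogenic_classes The classes considered potentially pathogenic.
#' @return Logical vector.
#' @export
classify_pathogenic_potential <- function(consequence_class,
                                          pathogenic_classes =
                                            .default_pathogenic_classes) {
  bad <- setdiff(unique(consequence_class), .consequence_classes)
  if (length(bad))
    abort_config("unknown consequence class(es): ",
                 paste(bad, collapse = ", "))
  bad <- setdiff(pathogenic_classes, .consequence_classes)
  if (length(bad))
    abort_config("unknown class(es) in pathogenic set: ",
                 paste(bad, collapse = ", "))
  consequence_class %in% pathogenic_classes
}

# site-level view of a variant table: unique sites + genotype lookup
variant_sites <- function(variants) {
  sites <- unique(variants[c("var_id", "chrom", "pos", "ref", "alt", "gene",
                             "consequence", "catalogs")])
  rownames(sites) <- NULL
  sites
}

# genotype matrix sites x samples; samples genotyped in the table but
# without a row at a site are homozygous reference
site_genotype_matrix <- function(variants, sites, sample_ids) {
  g <- matrix("ref", nrow = nrow(sites), ncol = length(sample_ids),
              dimnames = list(sites$var_id, sample_ids))
  keep <- variants$sample %in% sample_ids
  g[cbind(match(variants$var_id[keep], sites$var_id),
          match(variants$sample[keep], sample_ids))] <- variants$gt[keep]
  g
}

#' Filter exome variants to candidates through the mapping cascade
#'
#' The ordered candidate cascade of recessive disease-gene discovery:
#' restrict to the mapped interval(s), keep catalog-novel variants, keep
#' variants homozygous in every affected individual (indels of unknown
#' zygosity are retained with a warning flag rather than silently dropped),
#' drop variants homozygous in any unaffected sample, then (optionally)
#' keep potentially pathogenic consequence classes. Stage-by-stage counts
#' partition exactly: at every stage, kept + dropped = input.
#'
#' @param variants A `variant_table`.
#' @param mapped_intervals data.frame of mapped intervals (`chrom`, `start`,
#'   `end`, 1-based closed), or `NULL` for a genome-wide scan (requires
#'   `genome_wide = TRUE`).
#' @param affected_ids,unaffected_ids Sample ids. An affected sample that is
#'   not genotyped at a variant counts as non-homozygous there.
#' @param catalog_names Catalogs defining novelty.
#' @param genome_wide Allow `mapped_intervals = NULL`.
#' @param consequence_filter Apply the pathogenic-potential stage (default
#'   `TRUE`; the report shows class counts either way).
#' @param pathogenic_classes Pathogenic set for the consequence stage.
#' @param retain_classes Extra classes to retain through the consequence
#'   stage (e.g. `"5'-UTR"`).
#' @param strict_indels Drop unknown-zygosity indels at the homozygosity
#'   stage instead of retaining them.
#' @return An object of class `filter_report`: list with `candidates`
#'   (site-level data.frame with flag columns), `stages` (cascade count
#'   table), `class_counts` (consequence-class breakdown of novel-homozygous
#'   sites) and `flags` (per-site flag data.frame).
#' @export
filter_candidates <- function(variants, mapped_intervals, affected_ids,
                              unaffected_ids = character(),
                              catalog_names = c("dbSNP129", "1KG"),
                              genome_wide = is.null(mapped_intervals),
                              consequence_filter = TRUE,
                              pathogenic_classes =
                                .default_pathogenic_classes,
                              retain_classes = character(),
                              strict_indels = FALSE) {
  if (length(affected_ids) < 1)
    abort_config("need at least one affected sample")
  if (is.null(mapped_intervals) && !genome_wide)
    abort_config("no mapped intervals supplied and genome_wide is FALSE")
  if (!is.null(mapped_intervals) && nrow(mapped_intervals) == 0 &&
      !genome_wide)
    abort_config("empty mapped interval list and genome_wide is FALSE")
  variants <- annotate_novelty(variants, catalog_names)
  sites <- variant_sites(variants)
  sites$novel <- variants$novel[match(sites$var_id, variants$var_id)]
  genotyped <- unique(variants$sample)
  ga <- site_genotype_matrix(variants, sites, intersect(affected_ids,
                                                        genotyped))
  gu <- site_genotype_matrix(variants, sites, intersect(unaffected_ids,
                                                        genotyped))

  in_interval <- if (is.null(mapped_intervals)) rep(TRUE, nrow(sites)) else {
    hit <- rep(FALSE, nrow(sites))
    for (i in seq_len(nrow(mapped_intervals)))
      hit <- hit | (sites$chrom == mapped_intervals$chrom[i] &
                      sites$pos >= mapped_intervals$start[i] &
                      sites$pos <= mapped_intervals$end[i])
    hit
  }
  is_indel <- sites$consequence == "indel"
  hom_mat <- ga == "hom"
  unk_mat <- ga == "unknown"
  n_aff <- length(affected_ids)
  # an affected absent from the genotyped set is non-homozygous everywhere
  all_typed <- ncol(ga) == n_aff
  hom_all <- all_typed & rowSums(hom_mat) == ncol(ga)
  unk_retained <- !strict_indels & is_indel & all_typed &
    rowSums(hom_mat | unk_mat) == ncol(ga) & !hom_all
  missing_aff <- rowSums(unk_mat & !is_indel) > 0 | !all_typed
  pass_hom <- hom_all | unk_retained
  hom_any_unaff <- if (ncol(gu)) rowSums(gu == "hom") > 0 else
    rep(FALSE, nrow(sites))
  pathogenic <- classify_pathogenic_potential(sites$consequence,
                                              pathogenic_classes) |
    sites$consequence %in% retain_classes

  s1 <- in_interval
  s2 <- s1 & sites$novel
  s3 <- s2 & pass_hom
  s4 <- s3 & !hom_any_unaff
  s5 <- if (consequence_filter) s4 & pathogenic else s4
  stages <- data.frame(
    stage = c("in_mapped_interval", "novel", "homozygous_in_all_affected",
              "not_homozygous_in_unaffected", "potentially_pathogenic"),
    n_in = c(nrow(sites), sum(s1), sum(s2), sum(s3), sum(s4)),
    n_kept = c(sum(s1), sum(s2), sum(s3), sum(s4), sum(s5)),
    stringsAsFactors = FALSE)
  stages$n_dropped <- stages$n_in - stages$n_kept
  if (!consequence_filter)
    stages <- stages[stages$stage != "potentially_pathogenic", , drop = FALSE]

  flags <- data.frame(var_id = sites$var_id, in_interval = in_interval,
                      novel = sites$novel,
                      homozygous_in_all_affected = hom_all,
                      indel_unknown_zygosity = unk_retained,
                      affected_missing_genotype = missing_aff,
                      homozygous_in_any_unaffected = hom_any_unaff,
                      potentially_pathogenic = pathogenic,
                      stringsAsFactors = FALSE)
  candidates <- cbind(sites[s5, , drop = FALSE],
                      flags[s5, setdiff(names(flags), "var_id"),
                            drop = FALSE])
  rownames(candidates) <- NULL
  if (any(candidates$indel_unknown_zygosity))
    warning(sum(candidates$indel_unknown_zygosity),
            " candidate indel(s) retained with unknown zygosity",
            call. = FALSE)
  nh <- sites$novel & pass_hom          # novel-homozygous class breakdown
  class_counts <- table(factor(sites$consequence[nh],
                               levels = .consequence_classes))
  structure(list(candidates = candidates, stages = stages,
                 class_counts = class_counts, flags = flags,
                 params = list(catalog_names = catalog_names,
                               consequence_filter = consequence_filter,
                               pathogenic_classes = pathogenic_classes,
                               strict_indels = strict_indels)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Candidate-variant cascade\n")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-30s %6d -> %6d (dropped %d)\n", x$stages$stage[i],
                x$stages$n_in[i], x$stages$n_kept[i], x$stages$n_dropped[i]))
  cat(sprintf("  candidates: %d\n", nrow(x$candidates)))
  if (nrow(x$candidates))
    for (i in seq_len(nrow(x$candidates)))
      cat(sprintf("    %s (%s)\n", x$candidates$var_id[i],
                  x$candidates$consequence[i]))
  invisible(x)
}

#' Mutation-homogeneity scan across samples
#'
#' The mapping-free mode: with several affected individuals assumed to
#' carry the same pathogenic allele, the candidate is simply the variant
#' that is novel, homozygous in every affected, and homozygous in no other
#' sample in the study -- no mapped interval required. With a single
#' affected this degenerates to that sample's genome-wide novel-homozygous
#' list.
#'
#' @param variants A `variant_table`.
#' @param affected_ids Affected sample ids.
#' @param all_other_ids Every other exome-sequenced sample in the study.
#' @param catalog_names Catalogs defining novelty.
#' @param strict_indels Drop unknown-zygosity indels instead of retaining.
#' @return Site-level data.frame of candidate variants.
#' @export
homogeneity_scan <- function(variants, affected_ids, all_other_ids,
                             catalog_names = c("dbSNP129", "1KG"),
                             strict_indels = FALSE) {
  fr <- filter_candidates(variants, mapped_intervals = NULL,
                          affected_ids = affected_ids,
                          unaffected_ids = all_other_ids,
                          catalog_names = catalog_names,
                          genome_wide = TRUE, consequence_filter = FALSE,
                          strict_indels = strict_indels)
  fr$candidates
}
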