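# Mendelian segregation check ------------------------------------------------

#' Check recessive segregation of a candidate variant in its families
#'
#' Verifies the expected fully penetrant recessive pattern in every family
#' that contains an affected individual: genotyped parents of affecteds are
#' heterozygous carriers, affected individuals are homozygous for the
#' alternate allele, and no unaffected family member is. Samples in the
#' manifest that were never genotyped in the variant table are reported as
#' missing; missing genotypes do not fail the check but are listed.
#'
#' @param variants A `variant_table` holding the candidate's genotypes.
#' @param var_id The candidate variant id (`chrom:pos:ref:alt`).
#' @param manifest A validated manifest resolving family relationships.
#' @return An object of class `segregation_check`: list with `pass`
#'   (logical) and `table` (per-sample data.frame of `id`, `family_id`,
#'   `relation`, `expected`, `observed`, `ok`).
#' @export
check_segregation <- function(variants, var_id, manifest) {
  manifest <- validate_manifest(manifest)
  if (!var_id %in% variants$var_id)
    abort_config("variant ", var_id, " not present in the variant table")
  genotyped <- unique(variants$sample)
  affected <- manifest_affected(manifest)
  fams <- unique(manifest$family_id[manifest$id %in% affected])
  members <- manifest[manifest$family_id %in% fams, , drop = FALSE]
  parents <- unique(unlist(members[members$id %in% affected,
                                   c("father", "mother")]))
  parents <- parents[!is.na(parents)]
  rows <- lapply(seq_len(nrow(members)), function(i) {
    id <- members$id[i]
    relation <- if (id %in% affected) "affected"
    else if (id %in% parents) "parent"
    else "unaffected"
    expected <- switch(relation, affected = "hom", parent = "het",
                       unaffected = "het or ref")
    observed <- if (!id %in% genotyped) "missing"
    else genotype_of(variants, var_id, id)
    ok <- if (observed %in% c("missing", "unknown")) NA else switch(
      relation,
      affected = observed == "hom",
      parent = observed == "het",
      unaffected = observed != "hom")
    data.frame(id = id, family_id = members$family_id[i],
               relation = relation, expected = expected,
               observed = observed, ok = ok, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  pass <- !any(!tab$ok, na.rm = TRUE)
  structure(list(pass = pass, var_id = var_id, table = tab),
            class = "segregation_check")
}

#' @export
print.segregation_check <- function(x, ...) {
  cat(sprintf("Segregation of %s: %s\n", x$var_id,
              if (x$pass) "PASS" else "FAIL"))
  n_missing <- sum(x$table$observed == "missing")
  if (n_missing) cat(sprintf("  (%d sample(s) not genotyped)\n", n_missing))
  bad <- x$table[!is.na(x$table$ok) & !x$table$ok, , drop = FALSE]
  for (i in seq_len(nrow(bad)))
    cat(sprintf("  %s (%s): expected %s, observed %s\n", bad$id[i],
                bad$relation[i], bad$expected[i], bad$observed[i]))
  invisible(x)
}
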