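# End-to-end synthetic study ------------------------------------------------

#' Simulate a complete founder-population study
#'
#' Convenience wrapper tying the simulator stages together into the typical
#' study design: two consanguineous nuclear families from the same deme
#' segregating the same pathogenic allele (mutation homogeneity), plus a
#' cohort of unrelated population controls genotyped on the array panel.
#' Exomes are generated for the nuclear family members only; controls serve
#' the array allele-frequency estimation, as in practice.
#'
#' @param config A [sim_config()] object.
#' @param families List of family manifests (see [pedigree_cousin_family()]).
#'   Default: one 2-affected/6-unaffected sibship and one
#'   2-affected/1-unaffected sibship, giving 15 exome samples.
#' @param controls Control manifest (default [pedigree_controls()] of
#'   `config$n_controls`).
#' @return An object of class `sim_study`: list with `config`, `manifest`,
#'   `panel`, `truth`, `variants`, `exome_samples`.
#' @export
simulate_study <- function(config = sim_config(),
                           families = NULL, controls = NULL) {
  validate_sim_config(config)
  cons <- consanguinity_for_F(config$target_inbreeding_F)
  if (is.null(families)) {
    families <- list(
      pedigree_cousin_family(cons, n_affected = 2, n_unaffected = 6,
                             family_id = "F1", deme = "deme1"),
      pedigree_cousin_family(cons, n_affected = 2, n_unaffected = 1,
                             family_id = "F2", deme = "deme1"))
  }
  if (is.null(controls)) controls <- pedigree_controls(config$n_controls)
  manifest <- do.call(rbind, c(families, list(controls)))
  rownames(manifest) <- NULL
  validate_manifest(manifest)

  founders <- simulate_founders(config)
  drop <- gene_drop(founders, manifest, config)
  # exomes: affected individuals, their parents, and their full siblings
  aff <- manifest$id[manifest$status == "affected"]
  par <- unlist(manifest[manifest$id %in% aff, c("father", "mother")])
  par <- unique(par[!is.na(par)])
  aff_key <- paste(manifest$father[manifest$id %in% aff],
                   manifest$mother[manifest$id %in% aff])
  kids <- manifest$id[!is.na(manifest$father) &
                        paste(manifest$father, manifest$mother) %in% aff_key]
  exome_samples <- unique(c(aff, par, kids))
  variants <- simulate_exomes(drop$panel, drop$truth, config,
                              sample_ids = exome_samples)
  structure(list(config = config, manifest = manifest, panel = drop$panel,
                 truth = drop$truth, variants = variants,
                 exome_samples = exome_samples),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic founder-population study\n")
  cat(sprintf("  %d samples genotyped (%d controls), %d exomes\n",
              length(x$panel$samples),
              sum(x$manifest$role == "population_control"),
              length(x$exome_samples)))
  print(x$truth)
  invisible(x)
}
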