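# Carrier screening of population controls -----------------------------------

#' Allele frequency and carrier rate from a control screen
#'
#' Summarises genotyping of a candidate variant in population controls.
#' Allele frequency counts variant alleles per chromosome screened,
#' `(n_het + 2 n_hom_alt) / (2 n_controls)`, reported as a percentage to
#' two decimals (half-up); carrier rate counts carrier individuals,
#' `(n_het + n_hom_alt) / n_controls`, reported to one decimal. For rare
#' variants the two differ by roughly a factor of two -- both are reported
#' to keep them distinct. A homozygous control is flagged: observing one
#' undermines a fully penetrant recessive candidate.
#'
#' @param n_controls Controls genotyped (> 0).
#' @param n_het Heterozygous controls.
#' @param n_hom_alt Homozygous-alternate controls.
#' @param variant_id Optional label.
#' @return An object of class `control_screen`: list with `variant_id`,
#'   `n_controls`, `n_chromosomes`, `n_het`, `n_hom_alt`,
#'   `allele_frequency_pct` (2 decimals), `carrier_rate_pct` (1 decimal)
#'   and `homozygous_controls` (logical flag).
#' @export
allele_frequency_from_controls <- function(n_controls, n_het, n_hom_alt = 0,
                                           variant_id = NA_character_) {
  if (n_controls <= 0) abort_config("n_controls must be positive")
  if (n_het < 0 || n_hom_alt < 0) abort_config("counts must be non-negative")
  if (n_het + n_hom_alt > n_controls)
    abort_config("carrier count exceeds number of controls")
  af <- (n_het + 2 * n_hom_alt) / (2 * n_controls) * 100
  cr <- (n_het + n_hom_alt) / n_controls * 100
  structure(list(variant_id = variant_id, n_controls = n_controls,
                 n_chromosomes = 2 * n_controls, n_het = n_het,
                 n_hom_alt = n_hom_alt,
                 allele_frequency_pct = round_half_up(af, 2),
                 carrier_rate_pct = round_half_up(cr, 1),
                 homozygous_controls = n_hom_alt > 0),
            class = "control_screen")
}

#' @export
print.control_screen <- function(x, ...) {
  lbl <- if (is.na(x$variant_id)) "" else paste0(x$variant_id, ": ")
  cat(sprintf("%sallele frequency %.2f%% (%d/%d), carrier rate %.1f%%\n",
              lbl, x$allele_frequency_pct, x$n_het + 2 * x$n_hom_alt,
              x$n_chromosomes, x$carrier_rate_pct))
  if (x$homozygous_controls)
    cat("  WARNING: homozygous control(s) observed\n")
  invisible(x)
}
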