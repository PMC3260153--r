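# Allele-frequency estimation from population controls -----------------------

#' Estimate marker allele frequencies from control samples
#'
#' Computes the A-allele frequency of every panel marker from a set of
#' unrelated population controls, with a Laplace pseudocount per allele so
#' that no frequency is ever exactly 0 or 1 (which would make a homozygous
#' genotype infinitely informative). Missing calls are excluded from the
#' denominator. Markers at which every control call is missing get an
#' undefined frequency (`NA`) and are flagged; LOD computation skips them.
#'
#' @param panel A [genotype_panel()].
#' @param control_sample_ids Control sample ids present in the panel.
#' @param pseudocount Pseudocount added per allele (default 0.5):
#'   `f = (n_A + pseudocount) / (2 n_called + 2 pseudocount)`.
#' @return An `allele_freqs` data.frame: `marker_id`, `chrom`, `pos`, `f_a`
#'   (frequency of allele A; `f_b = 1 - f_a`), `n_chrom` (chromosomes
#'   observed), `pseudocount`.
#' @export
estimate_allele_freqs <- function(panel, control_sample_ids,
                                  pseudocount = 0.5) {
  if (length(control_sample_ids) < 1)
    abort_config("need at least one control sample")
  panel_check_samples(panel, control_sample_ids)
  if (pseudocount < 0) abort_config("pseudocount must be >= 0")
  calls <- panel$calls[control_sample_ids, , drop = FALSE]
  n_a <- colSums(calls == "AA", na.rm = TRUE) * 2 +
    colSums(calls == "AB", na.rm = TRUE)
  n_called <- colSums(!is.na(calls))
  f <- (n_a + pseudocount) / (2 * n_called + 2 * pseudocount)
  f[n_called == 0] <- NA_real_
  out <- data.frame(marker_id = panel$markers$marker_id,
                    chrom = panel$markers$chrom, pos = panel$markers$pos,
                    f_a = unname(f), n_chrom = unname(2 * n_called),
                    pseudocount = pseudocount, stringsAsFactors = FALSE)
  class(out) <- c("allele_freqs", "data.frame")
  out
}
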