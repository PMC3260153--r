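# Homozygosity LOD and block location scores ---------------------------------

#' Two-point homozygosity LOD for a single SNP genotype
#'
#' Log10 likelihood ratio that a homozygous genotype arises because the
#' marker sits in an autozygous segment rather than by chance under
#' Hardy-Weinberg. With allele frequency `f` of the observed homozygous
#' allele and genotyping error rate `eps`, an autozygous locus shows the
#' homozygote with probability `(1 - eps) f + eps f^2` (the allele drawn
#' once, or an error landing on a chance homozygote), while under HWE the
#' probability is `f^2`:
#'
#'   `lod = log10( ((1 - eps) f + eps f^2) / f^2 )`
#'
#' At `eps = 0` this is `-log10(f)`: a homozygote for a rare allele is
#' highly informative, a homozygote for a near-fixed allele carries almost
#' none. Missing genotypes contribute 0. Heterozygous calls violate the
#' contract -- callers handle them through block tolerances, not here.
#'
#' @param genotype_call `"AA"`, `"BB"` or `NA`; `"AB"` is an error.
#' @param f_of_homozygous_allele Frequency of the allele the call is
#'   homozygous for; must be strictly inside (0, 1) (use a pseudocount
#'   upstream, see [estimate_allele_freqs()]).
#' @param error_rate Genotyping error rate `eps` in `[0, 1)`.
#' @return LOD score(s) in log10 units; vectorized over calls/frequencies.
#' @export
snp_lod <- function(genotype_call, f_of_homozygous_allele,
                    error_rate = 0.01) {
  f <- f_of_homozygous_allele
  if (any(!is.na(f) & (f <= 0 | f >= 1)))
    abort_config("allele frequency must be strictly between 0 and 1")
  if (error_rate < 0 || error_rate >= 1)
    abort_config("error_rate must be in [0, 1)")
  if (any(!is.na(genotype_call) & genotype_call == "AB"))
    abort_config("snp_lod is defined for homozygous calls only")
  lod <- log10(((1 - error_rate) * f + error_rate * f^2) / f^2)
  lod[is.na(genotype_call)] <- 0
  lod
}

#' Cumulative location score of a homozygous block
#'
#' Sums the per-marker two-point homozygosity LODs over every affected
#' individual and every non-missing homozygous marker inside the block --
#' the cumulative score that ranks candidate disease intervals (a relative,
#' not a formal linkage, measure; affecteds are treated as independent).
#' The score is additive over any subdivision of the block. Markers with an
#' undefined allele frequency are skipped and counted.
#'
#' @param block One block: a list or single-row data.frame with `chrom`,
#'   `start`, `end` (bp, 1-based closed).
#' @param panel A [genotype_panel()].
#' @param affected_ids Affected sample ids.
#' @param freqs An [estimate_allele_freqs()] table for the same panel.
#' @param error_rate Genotyping error rate passed to [snp_lod()].
#' @return Numeric score (log10 units) with attribute `n_skipped`: the
#'   number of (marker, sample) contributions skipped for undefined
#'   frequency.
#' @export
location_score <- function(block, panel, affected_ids, freqs,
                           error_rate = 0.01) {
  if (length(affected_ids) == 0) return(structure(0, n_skipped = 0L))
  panel_check_samples(panel, affected_ids)
  idx <- which(panel$markers$chrom == block$chrom &
                 panel$markers$pos >= block$start &
                 panel$markers$pos <= block$end)
  if (!length(idx)) return(structure(0, n_skipped = 0L))
  f_a <- freqs$f_a[match(panel$markers$marker_id[idx], freqs$marker_id)]
  score <- 0
  skipped <- 0L
  for (sid in affected_ids) {
    calls <- panel$calls[sid, idx]
    hom <- !is.na(calls) & calls != "AB"
    undef <- hom & is.na(f_a)
    skipped <- skipped + sum(undef)
    use <- hom & !undef
    if (!any(use)) next
    f_hom <- ifelse(calls[use] == "AA", f_a[use], 1 - f_a[use])
    score <- score + sum(snp_lod(calls[use], f_hom, error_rate))
  }
  structure(score, n_skipped = skipped)
}

# per-marker LOD track summed over affecteds (heterozygous and missing
# calls contribute 0); the Fig-4-style profile
lod_track <- function(panel, affected_ids, freqs, error_rate = 0.01) {
  m <- nrow(panel$markers)
  total <- numeric(m)
  n_hom <- integer(m)
  f_a <- freqs$f_a[match(panel$markers$marker_id, freqs$marker_id)]
  for (sid in affected_ids) {
    calls <- panel$calls[sid, ]
    hom <- !is.na(calls) & calls != "AB" & !is.na(f_a)
    f_hom <- ifelse(calls[hom] == "AA", f_a[hom], 1 - f_a[hom])
    total[hom] <- total[hom] + snp_lod(calls[hom], f_hom, error_rate)
    n_hom[hom] <- n_hom[hom] + 1L
  }
  data.frame(marker_id = panel$markers$marker_id,
             chrom = panel$markers$chrom, pos = panel$markers$pos,
             lod = total, n_hom = n_hom, stringsAsFactors = FALSE)
}
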