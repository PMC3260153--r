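# Shared identically-homozygous blocks ---------------------------------------

# collapse affected calls at each marker to a shared status:
#   hom  - every called affected is homozygous for the same allele
#   soft - exactly one called affected deviates from a >= 2-strong
#          homozygous majority (with >= 3 affecteds): most likely a
#          genotyping error, consistent with sharing but not boundary-grade
#          evidence
#   het  - two or more called affecteds break identical homozygosity
#   miss - every affected is missing
shared_status <- function(calls) {
  n_aff <- nrow(calls)
  n_aa <- colSums(calls == "AA", na.rm = TRUE)
  n_bb <- colSums(calls == "BB", na.rm = TRUE)
  n_ab <- colSums(calls == "AB", na.rm = TRUE)
  n_called <- n_aa + n_bb + n_ab
  major <- pmax(n_aa, n_bb)
  deviants <- n_called - major
  status <- rep("het", length(n_called))
  status[n_called == 0] <- "miss"
  status[n_called > 0 & deviants == 0] <- "hom"
  if (n_aff >= 3)
    status[n_called > 0 & deviants == 1 & major >= 2] <- "soft"
  status
}

#' Find blocks identically homozygous across affected individuals
#'
#' The mapping signal of a recessive founder allele: maximal intervals in
#' which every affected individual is homozygous for the same allele at
#' every non-missing marker, under mutation and locus homogeneity. A marker
#' where two or more called affecteds break identical homozygosity counts
#' against the `max_het_per_run` tolerance; with three or more affecteds a
#' single deviant call against a homozygous majority of at least two is
#' treated as a probable genotyping error ("soft": consistent with sharing,
#' free of budget, but not usable as a block boundary or flank evidence).
#' A marker missing in all affecteds counts against `max_missing_per_run`.
#' Block boundaries are the outermost strictly qualifying markers. With a
#' single affected individual this reduces exactly to [detect_runs()].
#'
#' @inheritParams detect_runs
#' @param affected_ids Affected sample ids (>= 1).
#' @return data.frame of blocks with the columns of [detect_runs()] plus
#'   `n_affected`; `location_score` is `NA` until filled by
#'   [location_score()] or [autozygosity_scan()].
#' @export
shared_blocks <- function(panel, affected_ids, min_markers = 25,
                          max_missing_per_run = 4, max_het_per_run = 4,
                          min_flank = 5) {
  if (length(affected_ids) < 1)
    abort_config("need at least one affected sample")
  panel_check_samples(panel, affected_ids)
  status_all <- shared_status(panel$calls[affected_ids, , drop = FALSE])
  out <- runs_from_status(panel, status_all, min_markers, max_het_per_run,
                          max_missing_per_run, min_flank,
                          extra = list(n_affected = length(affected_ids)))
  out$location_score <- rep(NA_real_, nrow(out))
  out
}
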