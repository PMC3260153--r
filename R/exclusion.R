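# Exclusion / linkage-region enumeration in nuclear families -----------------

#' Enumerate regions consistent with linkage in a nuclear family
#'
#' Exclusion mapping for a family with affected children and unaffected
#' siblings. A region is consistent with linkage when (a) all affected
#' individuals carry identical genotypes at every informative marker across
#' it, and (b) no unaffected sibling matches the shared affected genotype
#' vector across it -- a sibling that carries the same genotypes over an
#' extended stretch would share both parental haplotypes there and the
#' region cannot harbour a fully penetrant recessive allele.
#'
#' Mechanically, maximal affected-identity intervals are computed first
#' (mismatches up to `max_mismatch` tolerated, absorbing genotyping error),
#' then every stretch of at least `min_exclude_markers` consecutive
#' mismatch-free markers over which an unaffected sibling matches the
#' affected vector is subtracted; isolated chance matches shorter than
#' `min_exclude_markers` do not exclude. Remaining pieces shorter than `min_size_mb` are discarded.
#' Families are processed independently.
#'
#' @param panel A [genotype_panel()].
#' @param manifest A validated manifest; affecteds are `status == "affected"`,
#'   unaffected siblings are `role == "sibling"` samples present in the
#'   panel.
#' @param min_size_mb Minimum region size in Mb (default 5).
#' @param min_markers Minimum markers per affected-identity interval.
#' @param max_mismatch Base number of identity-breaking markers tolerated
#'   per affected-identity interval (absorbs genotyping error).
#' @param mismatch_rate Length-proportional mismatch allowance: an interval
#'   of L markers tolerates up to `max(max_mismatch, ceiling(mismatch_rate
#'   * L))` breaks. Genuine identity accumulates error mismatches in
#'   proportion to its length, so a fixed budget would truncate long
#'   intervals; chance identity (~45% discordance per marker) still cannot
#'   chain.
#' @param min_exclude_markers Minimum length (markers) of a sibling
#'   match-run for it to exclude; shorter chance matches do not.
#' @param match_run_trim Markers pulled back from each match-run end that
#'   lies strictly inside the identity interval, so that the short chance
#'   tail of a genuine match cannot amputate adjacent markers.
#' @return data.frame of regions: `family_id`, `chrom`, `start`, `end` (bp),
#'   `size_mb`, `n_markers`.
#' @export
exclusion_linkage_regions <- function(panel, manifest, min_size_mb = 5,
                                      min_markers = 25, max_mismatch = 4,
                                      mismatch_rate = 0.02,
                                      min_exclude_markers = 25,
                                      match_run_trim = 4) {
  manifest <- validate_manifest(manifest)
  out <- list()
  for (fam in unique(manifest$family_id)) {
    fm <- manifest[manifest$family_id == fam, , drop = FALSE]
    affected <- intersect(fm$id[fm$status == "affected"], panel$samples)
    if (!length(affected)) next
    sibs <- intersect(fm$id[fm$role == "sibling" &
                              fm$status == "unaffected"], panel$samples)
    if (!length(sibs))
      warning("family ", fam, ": no unaffected siblings; regions reduce ",
              "to affected-sharing only", call. = FALSE)
    regions <- family_linkage_regions(panel, affected, sibs, min_markers,
                                      max_mismatch, mismatch_rate,
                                      min_exclude_markers, match_run_trim)
    if (nrow(regions)) {
      regions$family_id <- fam
      out[[length(out) + 1]] <- regions
    }
  }
  if (!length(out)) {
    return(data.frame(family_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      size_mb = numeric(), n_markers = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[res$size_mb >= min_size_mb, , drop = FALSE]
  rownames(res) <- NULL
  res[c("family_id", "chrom", "start", "end", "size_mb", "n_markers")]
}

family_linkage_regions <- function(panel, affected, sibs, min_markers,
                                   max_mismatch, mismatch_rate,
                                   min_exclude_markers, match_run_trim) {
  acalls <- panel$calls[affected, , drop = FALSE]
  # identity status: hom = affecteds identical (>=1 call), het = conflict,
  # miss = all missing. Reuses the tolerant run scanner.
  n_distinct <- apply(acalls, 2, function(x) length(unique(x[!is.na(x)])))
  ident_status <- ifelse(n_distinct == 0, "miss",
                         ifelse(n_distinct > 1, "het", "hom"))
  # the shared affected genotype where defined
  shared_call <- apply(acalls, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) x[1] else NA_character_
  })
  out <- list()
  for (chrom in unique(panel$markers$chrom)) {
    idx <- panel_chrom_idx(panel, chrom)
    ident <- scan_identity_runs(ident_status[idx], min_markers,
                                max_mismatch, mismatch_rate)
    if (!nrow(ident)) next
    for (r in seq_len(nrow(ident))) {
      # sibling match-runs are evaluated inside the identity interval only:
      # matching the affected vector where the affecteds do not share is
      # meaningless and must not bleed exclusions across the boundary
      sub <- idx[ident$start_idx[r]:ident$end_idx[r]]
      excl <- list()
      for (sib in sibs) {
        sc <- panel$calls[sib, sub]
        match_status <- ifelse(is.na(shared_call[sub]), "miss",
                               ifelse(is.na(sc) | sc == shared_call[sub],
                                      "hom", "het"))
        # zero mismatch tolerance: one genuine discordant genotype proves
        # the sibling does not share both haplotypes there
        mr <- scan_status_runs(match_status, min_exclude_markers,
                               0L, length(sub), min_flank = 1L)
        if (nrow(mr)) {
          # a genuine both-haplotype match continues past its true end by
          # chance state matching for a marker or two; where a run ends
          # strictly inside the interval, pull that end back so the chance
          # tail cannot amputate adjacent linkage-consistent markers
          inner_s <- mr$start_idx > 1L
          inner_e <- mr$end_idx < length(sub)
          mr$start_idx <- mr$start_idx + ifelse(inner_s, match_run_trim, 0L)
          mr$end_idx <- mr$end_idx - ifelse(inner_e, match_run_trim, 0L)
          mr <- mr[mr$start_idx <= mr$end_idx, , drop = FALSE]
          if (nrow(mr)) {
            mr$start_idx <- mr$start_idx + ident$start_idx[r] - 1L
            mr$end_idx <- mr$end_idx + ident$start_idx[r] - 1L
            excl[[length(excl) + 1]] <- mr[c("start_idx", "end_idx")]
          }
        }
      }
      excl <- if (length(excl)) do.call(rbind, excl) else
        data.frame(start_idx = integer(), end_idx = integer())
      pieces <- subtract_index_ranges(ident$start_idx[r], ident$end_idx[r],
                                      excl)
      for (p in seq_len(nrow(pieces))) {
        gi <- idx[pieces$start[p]]; gj <- idx[pieces$end[p]]
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom, start = panel$markers$pos[gi],
          end = panel$markers$pos[gj],
          n_markers = pieces$end[p] - pieces$start[p] + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), size_mb = numeric(),
                      n_markers = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$size_mb <- interval_size_mb(res$start, res$end)
  res
}

# Affected-identity intervals with a length-proportional mismatch
# allowance: from a start the interval extends across interruption blocks
# while the running mismatch count stays within
# max(base, ceiling(rate * length-so-far)), ending at the last identical
# marker reached. Selection is longest-first with re-derivation (as in the
# homozygosity scanner), so a chance-identity prefix cannot consume the
# allowance of a long genuine interval behind it.
identity_extent <- function(status, i, n, base_tolerance, mismatch_rate) {
  m <- 0L; m_at_last <- 0L; last_end <- i
  j <- i + 1L
  while (j <= n) {
    if (status[j] == "hom") {
      last_end <- j; m_at_last <- m; j <- j + 1L
      next
    }
    k <- j; im <- 0L
    while (k <= n && status[k] != "hom") { im <- im + 1L; k <- k + 1L }
    if (k > n) break
    allowance <- max(base_tolerance,
                     ceiling(mismatch_rate * (k - i + 1L)))
    if (m + im > allowance) break
    m <- m + im; j <- k
  }
  c(last_end, m_at_last)
}

scan_identity_runs <- function(status, min_markers, base_tolerance = 4,
                               mismatch_rate = 0.02) {
  scan_segment <- function(lo, hi) {
    if (hi - lo + 1L < min_markers) return(NULL)
    seg <- status[lo:hi]
    best <- NULL
    for (i in seq_len(hi - lo + 1L)) {
      if (seg[i] != "hom") next
      ext <- identity_extent(seg, i, hi - lo + 1L, base_tolerance,
                             mismatch_rate)
      if (ext[1] - i + 1L >= min_markers &&
          (is.null(best) || ext[1] - i > best[2] - best[1]))
        best <- c(i, ext[1], ext[2])
    }
    if (is.null(best)) return(NULL)
    rbind(scan_segment(lo, lo + best[1] - 2L),
          c(lo + best[1] - 1L, lo + best[2] - 1L, best[3]),
          scan_segment(lo + best[2], hi))
  }
  m <- scan_segment(1L, length(status))
  if (is.null(m)) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      n_mismatch = integer()))
  }
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start_idx = as.integer(m[, 1]), end_idx = as.integer(m[, 2]),
             n_mismatch = as.integer(m[, 3]))
}

# subtract a set of index ranges from [s, e]; returns remaining sub-ranges
subtract_index_ranges <- function(s, e, ranges) {
  keep_s <- integer(); keep_e <- integer()
  cur <- s
  if (nrow(ranges)) {
    ranges <- ranges[order(ranges$start_idx), , drop = FALSE]
    for (i in seq_len(nrow(ranges))) {
      rs <- ranges$start_idx[i]; re <- ranges$end_idx[i]
      if (re < cur || rs > e) next
      if (rs > cur) { keep_s <- c(keep_s, cur); keep_e <- c(keep_e, rs - 1L) }
      cur <- max(cur, re + 1L)
      if (cur > e) break
    }
  }
  if (cur <= e) { keep_s <- c(keep_s, cur); keep_e <- c(keep_e, e) }
  data.frame(start = keep_s, end = keep_e)
}
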