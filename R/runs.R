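# Runs of homozygosity -------------------------------------------------------
#
# The core scanner works on a per-marker status vector with values "hom"
# (strict evidence for the run), "soft" (consistent but weak -- e.g. a
# single deviant call among several affecteds, most likely a genotyping
# error), "het" and "miss" (budgeted interruptions). A qualifying window:
#   * starts and ends on a strict "hom" marker;
#   * contains at most `max_het` het and `max_miss` missing markers
#     ("soft" markers are free);
#   * obeys the flank rule: if the window contains any budgeted
#     interruption, the segments before the first and after the last
#     interruption must each contain at least `min_flank` strict hom
#     markers. The flank rule separates an isolated error deep inside a
#     long autozygous block (absorbed) from a chance homozygote just beyond
#     the block boundary, which cannot recruit the tolerance budget to
#     extend the run.
# Selection is longest-first with re-derivation: the longest qualifying
# window in the region (ties broken by leftmost start) is accepted, and
# the scan recurses on the stretches to its left and right. Longest-first
# matters: a long true block whose tolerance budget could otherwise be
# consumed by a chance stretch to its left is never pre-empted by that
# shorter window; recursing on the remainder guarantees no qualifying
# territory is silently dropped. The result is a deterministic,
# non-overlapping set, reported sorted by position.

# furthest qualifying end from start i, with the het/miss counts at that
# end; NULL when i is not a valid start
run_extent <- function(status, filler, i, max_het, max_miss, min_flank) {
  n <- length(status)
  seg_end <- i
  while (seg_end + 1L <= n && filler[seg_end + 1L]) seg_end <- seg_end + 1L
  seg_idx <- i:seg_end
  strict <- seg_idx[status[seg_idx] == "hom"]
  best_end <- strict[length(strict)]
  best_het <- 0L; best_miss <- 0L
  if (length(strict) >= min_flank) {
    het <- 0L; miss <- 0L
    p <- seg_end + 1L
    repeat {
      int_het <- 0L; int_miss <- 0L
      while (p <= n && !filler[p]) {
        if (status[p] == "het") int_het <- int_het + 1L
        else int_miss <- int_miss + 1L
        p <- p + 1L
      }
      if (p > n || het + int_het > max_het || miss + int_miss > max_miss)
        break
      het <- het + int_het; miss <- miss + int_miss
      cs <- p
      while (p + 1L <= n && filler[p + 1L]) p <- p + 1L
      seg <- cs:p
      strict <- seg[status[seg] == "hom"]
      if (length(strict) >= min_flank) {
        best_end <- strict[length(strict)]
        best_het <- het; best_miss <- miss
      }
      p <- p + 1L
    }
  }
  c(best_end, best_het, best_miss)
}

scan_status_runs <- function(status, min_markers, max_het, max_miss,
                             min_flank = 5) {
  n <- length(status)
  filler <- status == "hom" | status == "soft"
  scan_segment <- function(lo, hi) {
    if (hi - lo + 1L < min_markers) return(NULL)
    seg <- status[lo:hi]
    seg_filler <- filler[lo:hi]
    best <- NULL
    for (i in seq_len(hi - lo + 1L)) {
      if (seg[i] != "hom") next
      ext <- run_extent(seg, seg_filler, i, max_het, max_miss, min_flank)
      if (ext[1] - i + 1L >= min_markers &&
          (is.null(best) || ext[1] - i > best[2] - best[1]))
        best <- c(i, ext[1], ext[2], ext[3])
    }
    if (is.null(best)) return(NULL)
    rbind(scan_segment(lo, lo + best[1] - 2L),
          c(lo + best[1] - 1L, lo + best[2] - 1L, best[3], best[4]),
          scan_segment(lo + best[2], hi))
  }
  m <- scan_segment(1L, n)
  if (is.null(m)) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      n_het = integer(), n_missing = integer()))
  }
  out <- data.frame(start_idx = as.integer(m[, 1]),
                    end_idx = as.integer(m[, 2]),
                    n_het = as.integer(m[, 3]),
                    n_missing = as.integer(m[, 4]))
  out[order(out$start_idx), , drop = FALSE]
}

call_status <- function(calls) {
  ifelse(is.na(calls), "miss", ifelse(calls == "AB", "het", "hom"))
}

#' Detect runs of homozygosity in one sample
#'
#' Finds maximal stretches of homozygous calls along each chromosome,
#' tolerating a bounded number of heterozygous calls (genotyping errors)
#' and missing calls per run. Runs are reported at their outermost
#' homozygous markers, are non-overlapping, and are sorted by position.
#'
#' @param panel A [genotype_panel()].
#' @param sample_id Sample to scan.
#' @param min_markers Minimum markers per run.
#' @param max_missing_per_run,max_het_per_run Tolerance budgets per run.
#' @param min_flank Minimum consecutive homozygous markers that must flank
#'   any tolerated interruption (see Details in the package vignette): an
#'   isolated heterozygous call deep inside a long run is absorbed, but the
#'   tolerance cannot be spent to creep past a run boundary.
#' @return data.frame with one row per run: `sample`, `chrom`,
#'   `start_idx`/`end_idx` (marker indices within the chromosome),
#'   `start_marker`/`end_marker` (flanking marker ids), `start`/`end` (bp,
#'   1-based closed), `n_markers`, `n_het`, `n_missing`.
#' @export
detect_runs <- function(panel, sample_id, min_markers = 25,
                        max_missing_per_run = 4, max_het_per_run = 4,
                        min_flank = 5) {
  panel_check_samples(panel, sample_id)
  status_all <- call_status(panel$calls[sample_id, ])
  runs_from_status(panel, status_all, min_markers, max_het_per_run,
                   max_missing_per_run, min_flank,
                   extra = list(sample = sample_id))
}

# shared driver: cut the genome-wide status vector by chromosome, scan,
# and translate marker indices back to ids and bp
runs_from_status <- function(panel, status_all, min_markers, max_het,
                             max_miss, min_flank = 5, extra = list()) {
  out <- list()
  for (chrom in unique(panel$markers$chrom)) {
    idx <- panel_chrom_idx(panel, chrom)
    runs <- scan_status_runs(status_all[idx], min_markers, max_het, max_miss,
                             min_flank)
    if (!nrow(runs)) next
    gi <- idx[runs$start_idx]; gj <- idx[runs$end_idx]
    df <- data.frame(
      chrom = chrom, start_idx = runs$start_idx, end_idx = runs$end_idx,
      start_marker = panel$markers$marker_id[gi],
      end_marker = panel$markers$marker_id[gj],
      start = panel$markers$pos[gi], end = panel$markers$pos[gj],
      n_markers = runs$end_idx - runs$start_idx + 1L,
      n_het = runs$n_het, n_missing = runs$n_missing,
      stringsAsFactors = FALSE)
    for (nm in names(extra)) df[[nm]] <- extra[[nm]]
    out[[length(out) + 1]] <- df
  }
  if (!length(out)) {
    df <- data.frame(chrom = character(), start_idx = integer(),
                     end_idx = integer(), start_marker = character(),
                     end_marker = character(), start = numeric(),
                     end = numeric(), n_markers = integer(),
                     n_het = integer(), n_missing = integer(),
                     stringsAsFactors = FALSE)
    for (nm in names(extra)) df[[nm]] <- rep(extra[[nm]], 0)
    return(df)
  }
  do.call(rbind, out)
}
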