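# One-call autozygosity mapping fit ------------------------------------------

#' Autozygosity mapping of a genotype panel
#'
#' The one-call mapping interface: estimates marker allele frequencies from
#' population controls, detects per-affected runs of homozygosity, finds
#' blocks identically homozygous across all affected individuals, fills in
#' their cumulative two-point LOD location scores, and computes the
#' per-marker LOD profile. Returns a classed fit with `print`, `summary`
#' and `plot` methods.
#'
#' @param panel A [genotype_panel()].
#' @param manifest A validated sample manifest; affecteds are taken from
#'   `status == "affected"`.
#' @param control_ids Control sample ids for allele-frequency estimation;
#'   default all `role == "population_control"` samples in the panel.
#' @param pseudocount Laplace pseudocount for [estimate_allele_freqs()].
#' @param error_rate Genotyping error rate used in [snp_lod()].
#' @param min_markers,max_missing_per_run,max_het_per_run,min_flank
#'   Run/block tolerances (see [detect_runs()]).
#' @param min_size_mb Discard blocks smaller than this (default 0: keep
#'   all).
#' @return An object of class `autozygosity_scan`: list with `blocks`
#'   (shared blocks with filled `location_score`, ordered by descending
#'   score, ties broken by (chrom, start)), `runs` (per-affected ROH),
#'   `freqs`, `lod_track`, `affected`, `controls` and `params`.
#' @export
autozygosity_scan <- function(panel, manifest, control_ids = NULL,
                              pseudocount = 0.5, error_rate = 0.01,
                              min_markers = 25, max_missing_per_run = 4,
                              max_het_per_run = 4, min_flank = 5,
                              min_size_mb = 0) {
  manifest <- validate_manifest(manifest)
  affected <- intersect(manifest_affected(manifest), panel$samples)
  if (!length(affected))
    abort_config("mapping requires at least one affected sample in the panel")
  if (is.null(control_ids))
    control_ids <- intersect(manifest_controls(manifest), panel$samples)
  freqs <- estimate_allele_freqs(panel, control_ids, pseudocount)
  runs <- do.call(rbind, lapply(affected, function(a)
    detect_runs(panel, a, min_markers, max_missing_per_run,
                max_het_per_run, min_flank)))
  blocks <- shared_blocks(panel, affected, min_markers,
                          max_missing_per_run, max_het_per_run, min_flank)
  if (min_size_mb > 0 && nrow(blocks))
    blocks <- blocks[interval_size_mb(blocks$start, blocks$end) >=
                       min_size_mb, , drop = FALSE]
  n_skipped <- integer(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    sc <- location_score(blocks[i, ], panel, affected, freqs, error_rate)
    blocks$location_score[i] <- as.numeric(sc)
    n_skipped[i] <- attr(sc, "n_skipped")
  }
  blocks$n_freq_skipped <- n_skipped
  if (nrow(blocks)) {
    chrom_rank <- match(blocks$chrom, unique(panel$markers$chrom))
    blocks <- blocks[order(-blocks$location_score, chrom_rank,
                           blocks$start), , drop = FALSE]
    rownames(blocks) <- NULL
  }
  track <- lod_track(panel, affected, freqs, error_rate)
  structure(list(blocks = blocks, runs = runs, freqs = freqs,
                 lod_track = track, affected = affected,
                 controls = control_ids,
                 params = list(pseudocount = pseudocount,
                               error_rate = error_rate,
                               min_markers = min_markers,
                               max_missing_per_run = max_missing_per_run,
                               max_het_per_run = max_het_per_run,
                               min_flank = min_flank,
                               min_size_mb = min_size_mb)),
            class = "autozygosity_scan")
}

#' @export
print.autozygosity_scan <- function(x, ...) {
  cat(sprintf("Autozygosity scan: %d affected, %d control(s)\n",
              length(x$affected), length(x$controls)))
  cat(sprintf("  shared blocks: %d\n", nrow(x$blocks)))
  if (nrow(x$blocks)) {
    top <- head(x$blocks, 5)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s:%.0f-%.0f  %.1f Mb  %d markers  score %.1f\n",
                  top$chrom[i], top$start[i], top$end[i],
                  interval_size_mb(top$start[i], top$end[i]),
                  top$n_markers[i], top$location_score[i]))
  }
  invisible(x)
}

#' @export
#' @describeIn autozygosity_scan Summary with block table and ROH totals.
summary.autozygosity_scan <- function(object, ...) {
  bs <- summarize_blocks(object$blocks)
  out <- list(n_affected = length(object$affected),
              n_controls = length(object$controls),
              blocks = bs$per_block, stats = bs$stats,
              roh_per_sample = if (nrow(object$runs))
                table(object$runs$sample) else table(character()),
              params = object$params)
  class(out) <- "summary.autozygosity_scan"
  out
}

#' @export
print.summary.autozygosity_scan <- function(x, ...) {
  cat(sprintf("Autozygosity scan of %d affected (freqs from %d controls)\n",
              x$n_affected, x$n_controls))
  s <- x$stats
  if (s$n_blocks) {
    cat(sprintf("Shared blocks: %d; mean %.1f Mb (range %.1f-%.1f)\n",
                s$n_blocks, s$mean_size_mb, s$min_size_mb, s$max_size_mb))
    print(x$blocks[c("chrom", "start_marker", "end_marker", "size_mb",
                     "n_markers", "location_score")])
  } else cat("No shared blocks found.\n")
  invisible(x)
}

#' Plot the mapping profile of an autozygosity scan
#'
#' Draws the per-marker cumulative LOD profile along the genome
#' (chromosomes concatenated) and marks the shared blocks.
#'
#' @param x An `autozygosity_scan` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.autozygosity_scan <- function(x, ...) {
  tr <- x$lod_track
  chroms <- unique(tr$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(tr$pos[tr$chrom == ch]), numeric(1))))
  names(offs) <- c(chroms, "end")
  gx <- tr$pos + offs[tr$chrom]
  plot(gx / 1e6, tr$lod, type = "h", col = "grey60",
       xlab = "genome position (Mb)", ylab = "two-point LOD",
       main = "Homozygosity LOD profile", ...)
  if (nrow(x$blocks)) {
    bs <- x$blocks$start + offs[x$blocks$chrom]
    be <- x$blocks$end + offs[x$blocks$chrom]
    segments(bs / 1e6, 0, be / 1e6, 0, col = "red", lwd = 4)
  }
  abline(v = offs[-1] / 1e6, lty = 3, col = "grey80")
  invisible(x)
}
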