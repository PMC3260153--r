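# GenotypePanel container ----------------------------------------------------

.genotype_codes <- c("AA", "AB", "BB")

#' Construct a genotype panel
#'
#' The shared substrate of all mapping operations: an ordered marker map plus
#' a sample-by-marker matrix of unphased biallelic calls. Marker alleles are
#' abstract A/B; calls are `"AA"`, `"AB"`, `"BB"` or `NA` (missing). Markers
#' must be strictly sorted by (chromosome, position); chromosome order is the
#' order of first appearance in the map.
#'
#' @param markers data.frame with columns `marker_id`, `chrom`, `pos`
#'   (1-based bp).
#' @param calls character matrix, one row per sample (rownames = sample ids),
#'   one column per marker (colnames = marker ids), entries in
#'   `c("AA","AB","BB", NA)`.
#' @param sort If `TRUE`, re-sort an unsorted map (with a warning) instead of
#'   failing.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(markers, calls, sort = TRUE) {
  stopifnot(is.data.frame(markers),
            all(c("marker_id", "chrom", "pos") %in% names(markers)),
            is.matrix(calls))
  markers$marker_id <- as.character(markers$marker_id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.numeric(markers$pos)
  if (anyDuplicated(markers$marker_id))
    abort_format("duplicate marker ids: ",
                 paste(unique(markers$marker_id[duplicated(markers$marker_id)]),
                       collapse = ", "))
  if (is.null(rownames(calls)) || anyDuplicated(rownames(calls)))
    abort_format("calls must have unique sample rownames")
  if (is.null(colnames(calls)) || !identical(sort(colnames(calls)),
                                             sort(markers$marker_id)))
    abort_format("calls columns must match marker ids")
  bad <- !is.na(calls) & !calls %in% .genotype_codes
  if (any(bad))
    abort_format("invalid genotype codes: ",
                 paste(unique(calls[bad]), collapse = ", "))
  chrom_levels <- unique(markers$chrom)
  ord <- order(match(markers$chrom, chrom_levels), markers$pos)
  if (!identical(ord, seq_len(nrow(markers)))) {
    if (!sort) abort_format("marker map is not sorted by (chrom, position)")
    warning("marker map not sorted by (chrom, position); re-sorting",
            call. = FALSE)
    markers <- markers[ord, , drop = FALSE]
  }
  if (anyDuplicated(markers[c("chrom", "pos")]))
    abort_format("duplicate marker positions within a chromosome")
  rownames(markers) <- NULL
  calls <- calls[, markers$marker_id, drop = FALSE]
  structure(list(markers = markers, samples = rownames(calls), calls = calls),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d samples x %d markers on %d chromosome(s)\n",
              length(x$samples), nrow(x$markers),
              length(unique(x$markers$chrom))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$calls)

# marker indices of one chromosome, in map order
panel_chrom_idx <- function(panel, chrom) {
  which(panel$markers$chrom == chrom)
}

panel_check_samples <- function(panel, ids) {
  missing <- setdiff(ids, panel$samples)
  if (length(missing))
    abort_config("samples not in panel: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
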