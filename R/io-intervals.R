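# Interval IO: BED on disk, 1-based closed in memory -------------------------
#
# BED is 0-based half-open on disk (the standard). The internal convention
# everywhere else in the package is 1-based fully closed, matching how
# mapping tables report blocks by their inclusive flanking SNPs. These two
# functions are the single conversion site, tested in both directions:
# BED (start, end) <-> internal [start+1, end].

#' Read intervals from a BED file
#'
#' @param path BED file (>= 3 columns; a 4th column is kept as `name`).
#' @return data.frame with `chrom`, `start`, `end` (1-based closed) and
#'   optionally `name`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) abort_format("file not found: ", path)
  tab <- read.table(path, header = FALSE, sep = "\t", quote = "",
                    colClasses = "character")
  if (ncol(tab) < 3) abort_format(path, ": BED needs >= 3 columns")
  start0 <- as.numeric(tab[[2]]); end0 <- as.numeric(tab[[3]])
  bad <- which(start0 >= end0)
  if (length(bad))
    abort_format(path, ": line ", bad[1], ": start >= end")
  out <- data.frame(chrom = tab[[1]], start = start0 + 1, end = end0,
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 4) out$name <- tab[[4]]
  out
}

#' Write intervals to a BED file
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based closed)
#'   and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  if (any(intervals$start > intervals$end))
    abort_format("interval start > end")
  cols <- list(intervals$chrom,
               format(intervals$start - 1, scientific = FALSE, trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE))
  if (!is.null(intervals$name)) cols <- c(cols, list(intervals$name))
  write.table(do.call(data.frame, c(cols, stringsAsFactors = FALSE)), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write shared blocks as BED plus a mapping-summary TSV
#'
#' The TSV mirrors the shape of a genetic-mapping summary table: chromosome,
#' flanking SNP ids, size in Mb (1 decimal), marker count, location score
#' and (when annotated) gene count.
#'
#' @param blocks A block data.frame from [shared_blocks()] /
#'   [autozygosity_scan()].
#' @param prefix Output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @return The two paths, invisibly.
#' @export
write_blocks <- function(blocks, prefix) {
  bed <- paste0(prefix, ".bed"); tsv <- paste0(prefix, ".tsv")
  if (nrow(blocks) == 0) {
    writeLines(character(), bed)
  } else {
    write_intervals(data.frame(chrom = blocks$chrom, start = blocks$start,
                               end = blocks$end,
                               name = paste0("block", seq_len(nrow(blocks))),
                               stringsAsFactors = FALSE), bed)
  }
  if (nrow(blocks) == 0) {
    writeLines(paste(c("chrom", "snp_start", "snp_stop", "start", "end",
                       "size_mb", "n_markers", "location_score"),
                     collapse = "\t"), tsv)
    return(invisible(c(bed = bed, tsv = tsv)))
  }
  out <- data.frame(
    chrom = blocks$chrom,
    snp_start = blocks$start_marker %||% NA,
    snp_stop = blocks$end_marker %||% NA,
    start = blocks$start, end = blocks$end,
    size_mb = round_half_up(interval_size_mb(blocks$start, blocks$end), 1),
    n_markers = blocks$n_markers %||% NA,
    location_score = blocks$location_score %||% NA,
    stringsAsFactors = FALSE)
  if (!is.null(blocks$n_genes)) out$n_genes <- blocks$n_genes
  write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed, tsv = tsv))
}
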