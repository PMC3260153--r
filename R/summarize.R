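# Block summaries against a gene annotation ----------------------------------

#' Summarize shared blocks and count overlapping genes
#'
#' Annotates each block with the number of gene intervals it overlaps by at
#' least 1 bp and reports summary statistics in the conventions of a
#' genetic-mapping summary table: block sizes in Mb to one decimal, the mean
#' gene count rounded half-up to an integer, plus ranges.
#'
#' @param blocks data.frame with `chrom`, `start`, `end` (1-based closed);
#'   typically from [shared_blocks()] or [autozygosity_scan()].
#' @param gene_annotation data.frame of gene intervals (`chrom`, `start`,
#'   `end`, 1-based closed; e.g. from [read_intervals()]), or `NULL` for no
#'   annotation (all gene counts 0).
#' @return A `block_summary` list: `per_block` (blocks with `size_mb` and
#'   `n_genes`) and `stats` (`n_blocks`, `mean_size_mb`, `min_size_mb`,
#'   `max_size_mb`, `mean_genes`, `min_genes`, `max_genes`).
#' @export
summarize_blocks <- function(blocks, gene_annotation = NULL) {
  blocks <- as.data.frame(blocks)
  n_genes <- integer(nrow(blocks))
  if (!is.null(gene_annotation) && nrow(blocks)) {
    if (any(gene_annotation$start > gene_annotation$end))
      abort_format("gene annotation has start > end")
    for (i in seq_len(nrow(blocks))) {
      same <- gene_annotation$chrom == blocks$chrom[i]
      n_genes[i] <- sum(same &
                          intervals_overlap(gene_annotation$start,
                                            gene_annotation$end,
                                            blocks$start[i], blocks$end[i]))
    }
  }
  per_block <- blocks
  per_block$size_mb <- if (nrow(blocks))
    round_half_up(interval_size_mb(blocks$start, blocks$end), 1) else numeric()
  per_block$n_genes <- n_genes
  stats <- if (nrow(blocks)) {
    list(n_blocks = nrow(blocks),
         mean_size_mb = round_half_up(mean(per_block$size_mb), 1),
         min_size_mb = min(per_block$size_mb),
         max_size_mb = max(per_block$size_mb),
         mean_genes = round_half_up(mean(n_genes), 0),
         min_genes = min(n_genes), max_genes = max(n_genes))
  } else {
    list(n_blocks = 0L, mean_size_mb = NA_real_, min_size_mb = NA_real_,
         max_size_mb = NA_real_, mean_genes = NA_real_,
         min_genes = NA_integer_, max_genes = NA_integer_)
  }
  structure(list(per_block = per_block, stats = stats),
            class = "block_summary")
}

#' @export
print.block_summary <- function(x, ...) {
  s <- x$stats
  if (s$n_blocks == 0) {
    cat("Block summary: no blocks\n")
    return(invisible(x))
  }
  cat(sprintf("Block summary: %d block(s)\n", s$n_blocks))
  cat(sprintf("  size : mean %.1f Mb (range %.1f-%.1f)\n", s$mean_size_mb,
              s$min_size_mb, s$max_size_mb))
  cat(sprintf("  genes: mean %d (range %d-%d)\n", s$mean_genes,
              s$min_genes, s$max_genes))
  invisible(x)
}
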