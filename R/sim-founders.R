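# Founder haplotype pool -----------------------------------------------------

#' Simulate a founder haplotype pool
#'
#' Draws a marker map at the configured density and a pool of founder
#' haplotypes carrying abstract A/B alleles. Per-marker A-allele frequencies
#' (the generating spectrum) are drawn uniformly on \[0.1, 0.9\] --
#' SNP-array content is ascertained towards common variation, so extreme
#' frequencies are avoided -- and recorded so downstream checks can compare
#' realized frequencies against the spectrum that generated them.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `founder_pool`: a list with `markers`
#'   (marker map data.frame), `spectrum` (generating A-allele frequency per
#'   marker) and `haplotypes` (haplotype-by-marker integer matrix, 1 = A,
#'   2 = B).
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  if (config$n_founder_haplotypes < 4)
    abort_config("need at least 4 founder haplotypes")
  set.seed(derive_seed(config$rng_seed, "founders"))
  maps <- lapply(names(config$chromosome_lengths), function(chrom) {
    len <- config$chromosome_lengths[[chrom]]
    n <- max(2L, round(len / 1e6 * config$marker_density_per_mb))
    pos <- sort(sample.int(len, n))
    data.frame(marker_id = sprintf("%s_m%05d", chrom, seq_len(n)),
               chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, maps)
  rownames(markers) <- NULL
  m <- nrow(markers)
  spectrum <- runif(m, 0.1, 0.9)
  nh <- config$n_founder_haplotypes
  # allele 1 = A with probability spectrum[j]
  haplotypes <- matrix(2L, nrow = nh, ncol = m)
  draws <- matrix(runif(nh * m), nrow = nh)
  haplotypes[draws < rep(spectrum, each = nh)] <- 1L
  colnames(haplotypes) <- markers$marker_id
  structure(list(markers = markers, spectrum = spectrum,
                 haplotypes = haplotypes),
            class = "founder_pool")
}

#' @export
print.founder_pool <- function(x, ...) {
  cat(sprintf("Founder pool: %d haplotypes x %d markers\n",
              nrow(x$haplotypes), nrow(x$markers)))
  invisible(x)
}
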