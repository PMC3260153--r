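# Fixture builders: tiny panels, manifests and variant tables built in code.

# panel from per-sample call strings, e.g. list(s1 = c("AA","AB",NA))
make_panel <- function(calls_by_sample, chrom = "chr1", pos = NULL) {
  n <- length(calls_by_sample[[1]])
  if (is.null(pos)) pos <- seq_len(n) * 1e5
  markers <- data.frame(marker_id = sprintf("m%03d", seq_len(n)),
                        chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  calls <- do.call(rbind, calls_by_sample)
  rownames(calls) <- names(calls_by_sample)
  colnames(calls) <- markers$marker_id
  genotype_panel(markers, calls)
}

# minimal manifest rows
manifest_row <- function(id, family = "F1", father = NA, mother = NA,
                         status = "unaffected", role = "sibling",
                         deme = "deme1") {
  data.frame(id = id, family_id = family, father = father, mother = mother,
             status = status, role = role, deme = deme,
             stringsAsFactors = FALSE)
}

# variant-table rows from a compact spec:
#   list(c(id, consequence, catalogs, sample, gt), ...)
make_variants <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    parts <- strsplit(r[[1]], ":", fixed = TRUE)[[1]]
    data.frame(var_id = r[[1]], chrom = parts[1], pos = as.numeric(parts[2]),
               ref = parts[3], alt = parts[4], gene = NA_character_,
               consequence = r[[2]], catalogs = r[[3]], sample = r[[4]],
               gt = r[[5]], stringsAsFactors = FALSE)
  }))
  class(df) <- c("variant_table", "data.frame")
  df
}

# small, fast simulation configuration used across tests
small_sim_config <- function(seed, ...) {
  args <- list(chromosome_lengths = c(chr1 = 40e6),
               pathogenic_block_start = 18e6,
               pathogenic_block_end = 22.4e6 - 1,
               n_controls = 50, rng_seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# default two-family study manifest without controls (exome-scale tests)
two_family_manifest <- function() {
  rbind(pedigree_cousin_family("first_cousin_once_removed", 2, 6, "F1"),
        pedigree_cousin_family("first_cousin_once_removed", 2, 1, "F2"))
}
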