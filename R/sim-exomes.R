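# Exome variant-table simulation ---------------------------------------------

.bases <- c("A", "C", "G", "T")

#' Simulate exome variant tables
#'
#' Emits per-sample exome variant calls calibrated to what a founder-
#' population exome yields: catalogued ("known") background variants are
#' drawn from a shared site pool so they recur across samples, novel
#' variants are private rare alleles, and the planted pathogenic variant is
#' novel, homozygous in every affected carrier and heterozygous-or-absent
#' elsewhere. Per-sample background counts are Poisson around the configured
#' rates. Indel calls carry unknown zygosity (mirroring automated indel
#' callers that do not call zygosity), and known indels are catalogued
#' against dbSNP only.
#'
#' @param panel A [genotype_panel()] (defines the genome and sample universe).
#' @param truth A `truth_set` from [gene_drop()].
#' @param config A [sim_config()] object.
#' @param sample_ids Samples to emit exomes for (default: all panel samples).
#' @param plant If `FALSE`, the pathogenic variant is not emitted.
#' @return A `variant_table`: data.frame with one row per variant call,
#'   columns `var_id`, `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`,
#'   `catalogs` (comma-separated catalog names, `""` = novel), `sample`,
#'   `gt` (`"ref"`, `"het"`, `"hom"`, `"unknown"`).
#' @export
simulate_exomes <- function(panel, truth, config,
                            sample_ids = panel$samples, plant = TRUE) {
  validate_sim_config(config)
  panel_check_samples(panel, sample_ids)
  pv <- truth$pathogenic_variant
  if (plant && (pv$pos < truth$planted$start || pv$pos > truth$planted$end))
    abort_config("planted variant position lies outside the planted block")
  set.seed(derive_seed(config$rng_seed, "exomes"))

  chroms <- names(config$chromosome_lengths)
  lens <- as.numeric(config$chromosome_lengths)
  rate_known <- config$exome_variant_rate * (1 - config$novel_fraction)
  rate_novel <- config$exome_variant_rate * config$novel_fraction

  draw_sites <- function(n) {
    ch <- sample(chroms, n, replace = TRUE, prob = lens)
    pos <- ceiling(runif(n) * lens[match(ch, chroms)])
    ref <- sample(.bases, n, replace = TRUE)
    alt_shift <- sample.int(3, n, replace = TRUE)
    alt <- .bases[((match(ref, .bases) - 1L + alt_shift) %% 4L) + 1L]
    data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }

  # shared pool of catalogued sites; 3x the per-sample rate so roughly a
  # third of any two samples' known calls coincide
  n_pool <- max(10L, round(3 * rate_known))
  pool <- draw_sites(n_pool)
  pool$consequence <- sample(names(config$consequence_class_weights), n_pool,
                             replace = TRUE,
                             prob = config$consequence_class_weights)
  in_1kg <- runif(n_pool) < 0.7
  pool$catalogs <- ifelse(pool$consequence == "indel", config$catalogs[1],
                          ifelse(in_1kg,
                                 paste(config$catalogs, collapse = ","),
                                 config$catalogs[1]))
  pool$var_id <- sprintf("%s:%d:%s:%s", pool$chrom, pool$pos, pool$ref,
                         pool$alt)

  out <- vector("list", length(sample_ids) + 1L)
  for (i in seq_along(sample_ids)) {
    sid <- sample_ids[i]
    nk <- rpois(1, rate_known)
    nk <- min(nk, n_pool)
    ki <- sample.int(n_pool, nk)
    k_gt <- ifelse(pool$consequence[ki] == "indel", "unknown",
                   ifelse(runif(nk) < 1 / 3, "hom", "het"))
    nn <- rpois(1, rate_novel)
    nv <- draw_sites(nn)
    nv$consequence <- sample(names(config$novel_class_weights), nn,
                             replace = TRUE,
                             prob = config$novel_class_weights)
    n_gt <- ifelse(nv$consequence == "indel", "unknown",
                   ifelse(runif(nn) < config$novel_hom_fraction, "hom",
                          "het"))
    out[[i]] <- data.frame(
      var_id = c(pool$var_id[ki],
                 sprintf("%s:%d:%s:%s", nv$chrom, nv$pos, nv$ref, nv$alt)),
      chrom = c(pool$chrom[ki], nv$chrom),
      pos = c(pool$pos[ki], nv$pos),
      ref = c(pool$ref[ki], nv$ref),
      alt = c(pool$alt[ki], nv$alt),
      gene = NA_character_,
      consequence = c(pool$consequence[ki], nv$consequence),
      catalogs = c(pool$catalogs[ki], rep("", nn)),
      sample = sid,
      gt = c(k_gt, n_gt),
      stringsAsFactors = FALSE)
  }

  if (plant) {
    carriers_here <- intersect(truth$carriers, sample_ids)
    hom_here <- intersect(truth$hom_carriers, sample_ids)
    ref_here <- setdiff(sample_ids, carriers_here)
    pid <- sprintf("%s:%d:%s:%s", pv$chrom, pv$pos, pv$ref, pv$alt)
    out[[length(sample_ids) + 1L]] <- data.frame(
      var_id = pid, chrom = pv$chrom, pos = pv$pos, ref = pv$ref,
      alt = pv$alt, gene = NA_character_, consequence = pv$consequence,
      catalogs = "",
      sample = c(hom_here, setdiff(carriers_here, hom_here), ref_here),
      gt = c(rep("hom", length(hom_here)),
             rep("het", length(carriers_here) - length(hom_here)),
             rep("ref", length(ref_here))),
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  variants <- variants[order(match(variants$chrom, chroms), variants$pos,
                             variants$sample), , drop = FALSE]
  rownames(variants) <- NULL
  class(variants) <- c("variant_table", "data.frame")
  variants
}

#' @export
print.variant_table <- function(x, ...) {
  nonref <- x[x$gt != "ref", , drop = FALSE]
  cat(sprintf(
    "Variant table: %d calls (%d non-ref) at %d sites in %d sample(s)\n",
    nrow(x), nrow(nonref), length(unique(x$var_id)),
    length(unique(x$sample))))
  cat(sprintf("  novel calls: %d\n", sum(nonref$catalogs == "")))
  invisible(x)
}
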