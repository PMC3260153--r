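# Gene-drop simulation: haplotype mosaics through a pedigree -----------------
#
# A haplotype is represented per chromosome as a mosaic of founder-haplotype
# ids: `brk` (segment start positions, brk[1] == 1) and `hap` (founder id of
# each segment). Identity-by-descent is read directly off the two mosaics of
# an individual, so realized autozygosity is known exactly.

mosaic_new <- function(hap_id) list(brk = 1, hap = as.integer(hap_id))

mosaic_at <- function(m, pos) m$hap[findInterval(pos, m$brk)]

mosaic_compress <- function(brk, hap) {
  keep <- c(TRUE, hap[-1] != hap[-length(hap)])
  list(brk = brk[keep], hap = hap[keep])
}

# gamete from two parental mosaics: Poisson crossovers, no interference,
# random starting phase
mosaic_gamete <- function(mA, mB, chrom_len, rate_per_mb) {
  k <- rpois(1, chrom_len / 1e6 * rate_per_mb)
  cp <- if (k > 0) sort(unique(ceiling(runif(k, 1, chrom_len)))) else numeric()
  start <- sample.int(2, 1)
  seg_starts <- c(1, cp)
  brk <- sort(unique(c(seg_starts, mA$brk, mB$brk)))
  # segment 1 comes from the starting source, alternating at each crossover
  use_A <- ((findInterval(brk, seg_starts) - 1) %% 2 == 0) == (start == 1)
  hap <- ifelse(use_A, mA$hap[findInterval(brk, mA$brk)],
                mB$hap[findInterval(brk, mB$brk)])
  mosaic_compress(brk, as.integer(hap))
}

# overwrite mosaic over the closed interval [start, end] with either a
# constant founder id or the matching slice of a donor mosaic
mosaic_splice <- function(m, start, end, donor) {
  left_keep <- m$brk < start
  lb <- m$brk[left_keep]; lh <- m$hap[left_keep]
  if (is.numeric(donor) && length(donor) == 1) {
    mb <- start; mh <- as.integer(donor)
  } else {
    inner <- donor$brk > start & donor$brk <= end
    mb <- c(start, donor$brk[inner])
    mh <- c(mosaic_at(donor, start), donor$hap[inner])
  }
  rb <- end + 1; rh <- mosaic_at(m, end + 1)
  right_keep <- m$brk > end + 1
  mosaic_compress(c(lb, mb, rb, m$brk[right_keep]),
                  as.integer(c(lh, mh, rh, m$hap[right_keep])))
}

# TRUE if both mosaics equal founder id `h` anywhere inside [start, end]
mosaic_both_equal_within <- function(m1, m2, h, start, end) {
  brk <- sort(unique(c(start, m1$brk[m1$brk > start & m1$brk <= end],
                       m2$brk[m2$brk > start & m2$brk <= end])))
  any(m1$hap[findInterval(brk, m1$brk)] == h &
        m2$hap[findInterval(brk, m2$brk)] == h)
}

# autozygous (IBD) segments of one individual on one chromosome,
# 1-based closed intervals
mosaic_ibd <- function(m1, m2, chrom_len) {
  brk <- sort(unique(c(m1$brk, m2$brk)))
  same <- m1$hap[findInterval(brk, m1$brk)] == m2$hap[findInterval(brk, m2$brk)]
  ends <- c(brk[-1] - 1, chrom_len)
  runs <- mosaic_compress(brk, as.integer(same))
  rend <- c(runs$brk[-1] - 1, chrom_len)
  keep <- runs$hap == 1L
  data.frame(start = runs$brk[keep], end = rend[keep])
}

#' Drop genotypes through a pedigree
#'
#' Simulates meiosis through the pedigree (Poisson crossover process,
#' sex-averaged, no interference), plants a shared autozygous segment in all
#' affected individuals, and renders the resulting haplotypes into an
#' array-like genotype panel with configurable genotyping error and missing
#' call rates. The planted founder haplotype is spliced so that each parent
#' of an affected child carries exactly one copy over the planted span,
#' every affected child carries two (autozygosity by descent), and no
#' unaffected sibling carries two.
#'
#' @param founders A [simulate_founders()] pool.
#' @param pedigree A manifest data.frame (see [validate_manifest()]);
#'   founders of the pedigree are assigned two distinct pool haplotypes.
#' @param config A [sim_config()] object. If `target_inbreeding_F > 0` the
#'   parents of every affected individual must be connected by a
#'   consanguinity loop.
#' @return A list of class `gene_drop` with `panel` (a [genotype_panel()]),
#'   `truth` (a `truth_set`: realized IBD segments, the planted block, the
#'   planted pathogenic variant and its carriers) and `manifest`.
#' @export
gene_drop <- function(founders, pedigree, config) {
  validate_sim_config(config)
  pedigree <- as.data.frame(pedigree)
  validate_manifest(pedigree)
  set.seed(derive_seed(config$rng_seed, "genedrop"))

  affected <- manifest_affected(pedigree)
  if (config$target_inbreeding_F > 0 && length(affected)) {
    for (a in affected) {
      if (!manifest_has_loop(pedigree, a))
        abort_config("target_inbreeding_F > 0 but affected sample ", a,
                     " has no consanguinity loop in the pedigree")
    }
  }
  parents_of_affected <- unique(unlist(
    pedigree[pedigree$id %in% affected, c("father", "mother")]))
  parents_of_affected <- parents_of_affected[!is.na(parents_of_affected)]
  sibs <- pedigree$id[pedigree$status == "unaffected" &
                        !is.na(pedigree$father) &
                        paste(pedigree$father, pedigree$mother) %in%
                          paste(pedigree$father[pedigree$id %in% affected],
                                pedigree$mother[pedigree$id %in% affected])]

  chroms <- names(config$chromosome_lengths)
  h_star <- 1L                       # planted founder haplotype
  h_alt <- 2L                        # replacement when a copy must be removed
  pchrom <- config$pathogenic_block_chrom
  pstart <- config$pathogenic_block_start
  pend <- config$pathogenic_block_end
  ppos <- config$pathogenic_pos

  # haps[[sample]][[chrom]] = list(m1, m2)
  haps <- setNames(vector("list", nrow(pedigree)), pedigree$id)
  done <- setNames(rep(FALSE, nrow(pedigree)), pedigree$id)

  assign_sample <- function(id) {
    row <- pedigree[pedigree$id == id, ]
    if (is.na(row$father)) {
      pair <- sample.int(config$n_founder_haplotypes, 2)  # distinct copies
      hh <- lapply(chroms, function(ch)
        list(mosaic_new(pair[1]), mosaic_new(pair[2])))
    } else {
      fa <- haps[[row$father]]; mo <- haps[[row$mother]]
      hh <- lapply(seq_along(chroms), function(i) {
        len <- config$chromosome_lengths[[i]]
        list(mosaic_gamete(fa[[i]][[1]], fa[[i]][[2]], len,
                           config$recombination_rate_per_mb),
             mosaic_gamete(mo[[i]][[1]], mo[[i]][[2]], len,
                           config$recombination_rate_per_mb))
      })
    }
    names(hh) <- chroms
    # planting rules on the planted chromosome
    if (length(affected)) {
      hc <- hh[[pchrom]]
      if (id %in% parents_of_affected) {
        # obligate heterozygous carrier across the whole planted span
        hc[[1]] <- mosaic_splice(hc[[1]], pstart, pend, h_star)
        if (mosaic_both_equal_within(hc[[1]], hc[[2]], h_star, pstart, pend))
          hc[[2]] <- mosaic_splice(hc[[2]], pstart, pend, h_alt)
      } else if (id %in% affected) {
        hc[[1]] <- mosaic_splice(hc[[1]], pstart, pend, h_star)
        hc[[2]] <- mosaic_splice(hc[[2]], pstart, pend, h_star)
      } else if (id %in% sibs) {
        # an unaffected sibling is never autozygous for the planted
        # haplotype anywhere across the span
        if (mosaic_both_equal_within(hc[[1]], hc[[2]], h_star, pstart, pend))
          hc[[2]] <- mosaic_splice(hc[[2]], pstart, pend,
                                   haps[[pedigree$mother[pedigree$id == id]]][[pchrom]][[2]])
      }
      hh[[pchrom]] <- hc
    }
    hh
  }

  # topological order: founders first, then anyone whose parents are done
  while (!all(done)) {
    progressed <- FALSE
    for (i in seq_len(nrow(pedigree))) {
      id <- pedigree$id[i]
      if (done[[id]]) next
      fa <- pedigree$father[i]; mo <- pedigree$mother[i]
      if ((is.na(fa) || done[[fa]]) && (is.na(mo) || done[[mo]])) {
        haps[[id]] <- assign_sample(id)
        done[[id]] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) abort_config("pedigree is not acyclic")
  }

  # render genotypes
  markers <- founders$markers
  H <- founders$haplotypes
  calls <- matrix(NA_character_, nrow = nrow(pedigree), ncol = nrow(markers),
                  dimnames = list(pedigree$id, markers$marker_id))
  for (ch in chroms) {
    idx <- which(markers$chrom == ch)
    pos <- markers$pos[idx]
    for (id in pedigree$id) {
      m1 <- haps[[id]][[ch]][[1]]; m2 <- haps[[id]][[ch]][[2]]
      a1 <- H[cbind(m1$hap[findInterval(pos, m1$brk)], idx)]
      a2 <- H[cbind(m2$hap[findInterval(pos, m2$brk)], idx)]
      calls[id, idx] <- c("AA", "AB", "BB")[a1 + a2 - 1L]
    }
  }

  # genotyping error: replace the call by one of the other two codes
  nc <- length(calls)
  if (config$genotype_error_rate > 0) {
    err <- which(runif(nc) < config$genotype_error_rate)
    if (length(err)) {
      cur <- match(calls[err], .genotype_codes)
      shift <- 1L + (runif(length(err)) > 0.5)
      calls[err] <- .genotype_codes[((cur - 1L + shift) %% 3L) + 1L]
    }
  }
  if (config$missing_call_rate > 0) {
    calls[runif(nc) < config$missing_call_rate] <- NA_character_
  }
  panel <- genotype_panel(markers, calls)

  # realized IBD segments
  seg_list <- list()
  for (id in pedigree$id) {
    for (ch in chroms) {
      segs <- mosaic_ibd(haps[[id]][[ch]][[1]], haps[[id]][[ch]][[2]],
                         config$chromosome_lengths[[ch]])
      if (nrow(segs))
        seg_list[[length(seg_list) + 1]] <-
          data.frame(sample = id, chrom = ch, start = segs$start,
                     end = segs$end, stringsAsFactors = FALSE)
    }
  }
  ibd <- if (length(seg_list)) do.call(rbind, seg_list) else
    data.frame(sample = character(), chrom = character(),
               start = numeric(), end = numeric())

  carriers <- pedigree$id[vapply(pedigree$id, function(id) {
    hc <- haps[[id]][[pchrom]]
    mosaic_at(hc[[1]], ppos) == h_star || mosaic_at(hc[[2]], ppos) == h_star
  }, logical(1))]
  hom_carriers <- pedigree$id[vapply(pedigree$id, function(id) {
    hc <- haps[[id]][[pchrom]]
    mosaic_at(hc[[1]], ppos) == h_star && mosaic_at(hc[[2]], ppos) == h_star
  }, logical(1))]

  truth <- structure(list(
    ibd_segments = ibd,
    planted = list(chrom = pchrom, start = pstart, end = pend,
                   haplotype = h_star),
    pathogenic_variant = list(chrom = pchrom, pos = ppos, ref = "A",
                              alt = "T",
                              consequence = config$pathogenic_consequence),
    carriers = carriers,
    hom_carriers = hom_carriers
  ), class = "truth_set")

  structure(list(panel = panel, truth = truth, manifest = pedigree,
                 haplotypes = haps),
            class = "gene_drop")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("Truth set: planted block %s:%.0f-%.0f (%.1f Mb)\n",
              x$planted$chrom, x$planted$start, x$planted$end,
              interval_size_mb(x$planted$start, x$planted$end)))
  cat(sprintf("  pathogenic variant %s:%.0f %s>%s (%s)\n",
              x$pathogenic_variant$chrom, x$pathogenic_variant$pos,
              x$pathogenic_variant$ref, x$pathogenic_variant$alt,
              x$pathogenic_variant$consequence))
  cat(sprintf("  carriers: %d (%d homozygous)\n", length(x$carriers),
              length(x$hom_carriers)))
  cat(sprintf("  realized IBD segments: %d\n", nrow(x$ibd_segments)))
  invisible(x)
}

# realized inbreeding coefficient: IBD fraction of the genome
realized_F <- function(truth, sample_id, chromosome_lengths) {
  segs <- truth$ibd_segments
  segs <- segs[segs$sample == sample_id, , drop = FALSE]
  if (!nrow(segs)) return(0)
  sum(segs$end - segs$start + 1) / sum(chromosome_lengths)
}
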