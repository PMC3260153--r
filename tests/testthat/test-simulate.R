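# Synthetic founder-population generator

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_founder_haplotypes = 3), ">= 4",
               class = "autozyg_config_error")
  expect_error(sim_config(genotype_error_rate = 1.5), "probabilities")
  expect_error(sim_config(chromosome_lengths = c(chr1 = -1)), "positive")
  expect_error(small_sim_config(1, pathogenic_block_end = 99e6),
               "inside its chromosome")
  expect_error(small_sim_config(1, pathogenic_pos = 1e6),
               "inside the planted block")
})

test_that("founder pool has forced cardinality and is seed-deterministic", {
  cfg <- small_sim_config(5)
  pool <- simulate_founders(cfg)
  expect_equal(nrow(pool$haplotypes), 40)
  expect_equal(ncol(pool$haplotypes), nrow(pool$markers))
  expect_true(all(pool$haplotypes %in% c(1L, 2L)))
  pool2 <- simulate_founders(small_sim_config(5))
  expect_identical(pool, pool2)
  pool3 <- simulate_founders(small_sim_config(6))
  expect_false(identical(pool$haplotypes, pool3$haplotypes))
})

test_that("founder allele frequencies track the generating spectrum", {
  # exact binomial 99.9% envelope at 40 draws per marker
  cfg <- small_sim_config(11)
  pool <- simulate_founders(cfg)
  n <- nrow(pool$haplotypes)
  counts <- colSums(pool$haplotypes == 1L)
  lo <- qbinom(0.0005, n, pool$spectrum)
  hi <- qbinom(0.9995, n, pool$spectrum)
  frac_inside <- mean(counts >= lo & counts <= hi)
  expect_gte(frac_inside, 0.995)
})

test_that("error-free planting makes affecteds fully homozygous in block", {
  cfg <- small_sim_config(3, genotype_error_rate = 0, missing_call_rate = 0)
  pool <- simulate_founders(cfg)
  fam <- pedigree_cousin_family("first_cousin", 2, 2)
  gd <- gene_drop(pool, fam, cfg)
  idx <- which(gd$panel$markers$chrom == cfg$pathogenic_block_chrom &
                 gd$panel$markers$pos >= cfg$pathogenic_block_start &
                 gd$panel$markers$pos <= cfg$pathogenic_block_end)
  for (a in fam$id[fam$status == "affected"]) {
    calls <- gd$panel$calls[a, idx]
    expect_true(all(calls %in% c("AA", "BB")))
  }
  # all affecteds identical inside the block
  expect_equal(gd$panel$calls["F1_A1", idx], gd$panel$calls["F1_A2", idx])
})

test_that("truth set covers the planted segment and pathogenic homozygotes", {
  cfg <- small_sim_config(9)
  pool <- simulate_founders(cfg)
  fam <- pedigree_cousin_family("first_cousin_once_removed", 3, 1)
  gd <- gene_drop(pool, fam, cfg)
  segs <- gd$truth$ibd_segments
  expect_true(all(segs$start < segs$end))
  for (ch in unique(segs$chrom))
    expect_true(all(segs$end[segs$chrom == ch] <=
                      cfg$chromosome_lengths[[ch]]))
  for (a in fam$id[fam$status == "affected"]) {
    mine <- segs[segs$sample == a, ]
    covers <- any(mine$start <= cfg$pathogenic_block_start &
                    mine$end >= cfg$pathogenic_block_end)
    expect_true(covers, label = paste("planted segment covered for", a))
    expect_true(a %in% gd$truth$hom_carriers)
  }
  # parents of affecteds are obligate heterozygous carriers
  parents <- unique(unlist(fam[fam$status == "affected",
                               c("father", "mother")]))
  expect_true(all(parents %in% gd$truth$carriers))
  expect_false(any(parents %in% gd$truth$hom_carriers))
})

test_that("realized inbreeding of first-cousin offspring is near 1/16", {
  # closed-form kinship says E[F] = 1/16; Monte-Carlo over >= 3 seeds,
  # children unaffected so no segment is planted
  fs <- numeric()
  for (seed in c(21, 22, 23)) {
    cfg <- sim_config(chromosome_lengths = c(chr1 = 100e6, chr2 = 100e6),
                      target_inbreeding_F = 1 / 16,
                      marker_density_per_mb = 3.5, rng_seed = seed)
    pool <- simulate_founders(cfg)
    peds <- lapply(1:70, function(i)
      pedigree_cousin_family("first_cousin", 0, 1,
                             family_id = sprintf("FAM%02d", i)))
    gd <- gene_drop(pool, do.call(rbind, peds), cfg)
    kids <- grep("_U1S$", gd$manifest$id, value = TRUE)
    genome <- sum(cfg$chromosome_lengths)
    fs <- c(fs, vapply(kids, function(k) {
      segs <- gd$truth$ibd_segments
      segs <- segs[segs$sample == k, , drop = FALSE]
      sum(segs$end - segs$start + 1) / genome
    }, numeric(1)))
  }
  se <- sd(fs) / sqrt(length(fs))
  expect_lt(abs(mean(fs) - 1 / 16), 3 * se + 0.005)
})

test_that("missing-call rate matches its binomial expectation", {
  cfg <- small_sim_config(17, missing_call_rate = 0.05,
                          genotype_error_rate = 0)
  pool <- simulate_founders(cfg)
  gd <- gene_drop(pool, pedigree_controls(30), cfg)
  n <- length(gd$panel$calls)
  observed <- sum(is.na(gd$panel$calls))
  expect_gte(observed, qbinom(0.005, n, 0.05))
  expect_lte(observed, qbinom(0.995, n, 0.05))
})

test_that("consanguinity loop is required when F > 0", {
  cfg <- small_sim_config(2)
  pool <- simulate_founders(cfg)
  no_loop <- rbind(
    manifest_row("P1", role = "parent"),
    manifest_row("P2", role = "parent"),
    manifest_row("A1", father = "P1", mother = "P2", status = "affected",
                 role = "case"))
  expect_error(gene_drop(pool, no_loop, cfg), "consanguinity loop",
               class = "autozyg_config_error")
  cfg0 <- small_sim_config(2, target_inbreeding_F = 0)
  expect_s3_class(gene_drop(pool, no_loop, cfg0)$panel, "genotype_panel")
})

test_that("exome backgrounds hit their Poisson calibration", {
  cfg <- small_sim_config(31)
  pool <- simulate_founders(cfg)
  fam <- pedigree_cousin_family("first_cousin_once_removed", 2, 1)
  gd <- gene_drop(pool, fam, cfg)
  ids <- c("F1_A1", "F1_A2", "F1_U1S", "F1_P1")
  vt <- simulate_exomes(gd$panel, gd$truth, cfg, sample_ids = ids)
  nonref <- vt[vt$gt != "ref", ]
  for (sid in ids) {
    mine <- nonref[nonref$sample == sid, ]
    # totals and novel counts inside Poisson 99% bounds of configured means
    expect_gte(nrow(mine), qpois(0.005, cfg$exome_variant_rate))
    expect_lte(nrow(mine), qpois(0.995, cfg$exome_variant_rate) + 1)
    n_novel <- sum(mine$catalogs == "")
    rate_novel <- cfg$exome_variant_rate * cfg$novel_fraction
    expect_gte(n_novel, qpois(0.005, rate_novel))
    expect_lte(n_novel, qpois(0.995, rate_novel) + 1)
  }
  # class conservation: every call has exactly one class; counts sum
  expect_true(all(nonref$consequence %in% consequence_classes()))
  expect_equal(sum(table(nonref$consequence)), nrow(nonref))
  # indels never carry a determined zygosity
  expect_true(all(vt$gt[vt$consequence == "indel"] == "unknown"))
  expect_false(any(vt$gt[vt$consequence != "indel"] == "unknown"))
})

test_that("planted variant is always homozygous-alt in affecteds and novel", {
  for (seed in c(41, 42, 43)) {
    cfg <- small_sim_config(seed, exome_variant_rate = 200)
    pool <- simulate_founders(cfg)
    fam <- pedigree_cousin_family("first_cousin", 2, 1)
    gd <- gene_drop(pool, fam, cfg)
    vt <- simulate_exomes(gd$panel, gd$truth, cfg,
                          sample_ids = fam$id[fam$role %in%
                                                c("case", "sibling")])
    pid <- with(gd$truth$pathogenic_variant,
                sprintf("%s:%d:%s:%s", chrom, pos, ref, alt))
    aff <- fam$id[fam$status == "affected"]
    for (a in aff)
      expect_identical(vt$gt[vt$var_id == pid & vt$sample == a], "hom")
    expect_true(all(vt$catalogs[vt$var_id == pid] == ""))
    # never homozygous outside the affecteds
    others <- setdiff(unique(vt$sample), aff)
    expect_false(any(vt$gt[vt$var_id == pid & vt$sample %in% others] ==
                       "hom"))
  }
})

test_that("novel_fraction 0 with planting disabled emits no novel variant", {
  cfg <- small_sim_config(4, novel_fraction = 0, exome_variant_rate = 500)
  pool <- simulate_founders(cfg)
  fam <- pedigree_cousin_family("first_cousin", 1, 0)
  gd <- gene_drop(pool, fam, cfg)
  vt <- simulate_exomes(gd$panel, gd$truth, cfg, sample_ids = "F1_A1",
                        plant = FALSE)
  expect_true(all(nzchar(vt$catalogs)))
})

test_that("identical config and seed reproduce identical outputs", {
  run <- function() {
    cfg <- small_sim_config(77, exome_variant_rate = 300)
    pool <- simulate_founders(cfg)
    fam <- pedigree_cousin_family("first_cousin", 2, 1)
    gd <- gene_drop(pool, fam, cfg)
    vt <- simulate_exomes(gd$panel, gd$truth, cfg,
                          sample_ids = fam$id[fam$status == "affected"])
    list(gd$panel, gd$truth, vt)
  }
  expect_identical(run(), run())
})

test_that("Hardy-Weinberg holds at markers in unrelated controls", {
  # chi-square GOF (1 df) per marker, alpha = 0.001, over 3 seeds
  worst <- 1
  for (seed in c(51, 52, 53)) {
    cfg <- small_sim_config(seed, genotype_error_rate = 0,
                            missing_call_rate = 0)
    pool <- simulate_founders(cfg)
    gd <- gene_drop(pool, pedigree_controls(100), cfg)
    calls <- gd$panel$calls
    n_aa <- colSums(calls == "AA"); n_ab <- colSums(calls == "AB")
    n_bb <- colSums(calls == "BB")
    n <- n_aa + n_ab + n_bb
    p <- (2 * n_aa + n_ab) / (2 * n)
    informative <- p > 0.05 & p < 0.95
    e_aa <- n * p^2; e_ab <- n * 2 * p * (1 - p); e_bb <- n * (1 - p)^2
    x2 <- (n_aa - e_aa)^2 / e_aa + (n_ab - e_ab)^2 / e_ab +
      (n_bb - e_bb)^2 / e_bb
    not_rejected <- mean(x2[informative] < qchisq(0.999, df = 1))
    worst <- min(worst, not_rejected)
  }
  expect_gte(worst, 0.95)
})
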