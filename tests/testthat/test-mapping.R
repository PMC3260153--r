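# Allele frequencies, ROH detection, shared blocks, LOD scores

test_that("allele frequencies follow the pseudocount formula", {
  # 100 controls all AA, pseudocount 0.5 -> (200 + 0.5) / 201
  calls <- setNames(lapply(1:100, function(i) c("AA", "AB", "BB")),
                    sprintf("c%03d", 1:100))
  panel <- make_panel(calls)
  f <- estimate_allele_freqs(panel, panel$samples, pseudocount = 0.5)
  expect_equal(f$f_a[1], 200.5 / 201)
  expect_equal(f$f_a[2], 0.5)                     # all heterozygous
  expect_equal(f$f_a[3], 0.5 / 201)               # zero A observed, smoothed
  expect_true(all(f$f_a > 0 & f$f_a < 1))
  # pseudocount 0 with a 50/50 split is exactly one half
  half <- make_panel(list(c1 = c("AA"), c2 = c("BB")))
  f0 <- estimate_allele_freqs(half, c("c1", "c2"), pseudocount = 0)
  expect_equal(f0$f_a, 0.5)
})

test_that("markers with no control calls get undefined frequency", {
  panel <- make_panel(list(c1 = c("AA", NA), c2 = c("AA", NA)))
  f <- estimate_allele_freqs(panel, c("c1", "c2"))
  expect_true(is.na(f$f_a[2]))
  expect_equal(f$n_chrom[2], 0)
})

test_that("run detection matches hand-worked examples", {
  panel <- make_panel(list(s = c("AB", "AB", "AB", "AB")))
  expect_equal(nrow(detect_runs(panel, "s", min_markers = 1,
                                max_het_per_run = 0)), 0L)
  panel2 <- make_panel(list(s = c("AA", "AA", "AA", "AB", "AA")))
  runs <- detect_runs(panel2, "s", min_markers = 3,
                      max_missing_per_run = 0, max_het_per_run = 0)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start_idx, 1L)
  expect_equal(runs$end_idx, 3L)
  expect_equal(runs$n_markers, 3L)
})

test_that("run detection equals exhaustive window enumeration", {
  # >= 100 random panels of <= 200 markers, random tolerance settings
  set.seed(4001)
  for (trial in 1:120) {
    n <- sample(20:200, 1)
    calls <- random_calls(n, p_het = runif(1, 0.1, 0.5),
                          p_miss = runif(1, 0, 0.2))
    mh <- sample(0:3, 1); mm <- sample(0:3, 1); mk <- sample(2:12, 1)
    fl <- sample(1:6, 1)
    panel <- make_panel(list(s = calls))
    got <- detect_runs(panel, "s", min_markers = mk,
                       max_missing_per_run = mm, max_het_per_run = mh,
                       min_flank = fl)
    status <- ifelse(is.na(calls), "miss",
                     ifelse(calls == "AB", "het", "hom"))
    want <- brute_force_runs(status, mk, mh, mm, fl)
    expect_equal(got$start_idx, want$start_idx,
                 info = paste("trial", trial))
    expect_equal(got$end_idx, want$end_idx, info = paste("trial", trial))
  }
})

test_that("shared blocks require identical homozygosity across affecteds", {
  panel <- make_panel(list(a1 = c("AA", "AA", "BB"),
                           a2 = c("AA", "AA", "AA")))
  blocks <- shared_blocks(panel, c("a1", "a2"), min_markers = 2,
                          max_het_per_run = 0)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$start_idx, 1L)
  expect_equal(blocks$end_idx, 2L)
})

test_that("one affected degenerates shared blocks to ROH detection", {
  set.seed(4002)
  calls <- random_calls(150)
  panel <- make_panel(list(a = calls))
  b <- shared_blocks(panel, "a", min_markers = 5)
  r <- detect_runs(panel, "a", min_markers = 5)
  core <- c("chrom", "start_idx", "end_idx", "start_marker", "end_marker",
            "start", "end", "n_markers", "n_het", "n_missing")
  expect_equal(b[core], r[core])
})

test_that("shared blocks equal brute force on random multi-sample panels", {
  set.seed(4003)
  for (trial in 1:100) {
    n <- sample(20:150, 1)
    k <- sample(2:4, 1)
    calls <- setNames(lapply(seq_len(k), function(i)
      random_calls(n, p_het = 0.25, p_miss = 0.1)),
      paste0("a", seq_len(k)))
    panel <- make_panel(calls)
    mh <- sample(0:2, 1); mm <- sample(0:2, 1); mk <- sample(2:10, 1)
    fl <- sample(1:6, 1)
    got <- shared_blocks(panel, names(calls), min_markers = mk,
                         max_missing_per_run = mm, max_het_per_run = mh,
                         min_flank = fl)
    status <- brute_shared_status(do.call(rbind, calls))
    want <- brute_force_runs(status, mk, mh, mm, fl)
    expect_equal(got$start_idx, want$start_idx,
                 info = paste("trial", trial))
    expect_equal(got$end_idx, want$end_idx, info = paste("trial", trial))
  }
})

test_that("snp_lod evaluates the autozygosity likelihood ratio", {
  expect_equal(snp_lod("AA", 0.1, error_rate = 0), 1)
  expect_equal(snp_lod("AA", 0.999, error_rate = 0), -log10(0.999))
  expect_lt(abs(snp_lod("AA", 0.999, error_rate = 0) - 4.3e-4), 5e-5)
  expect_equal(snp_lod("BB", 0.1, error_rate = 0.01),
               log10((0.99 * 0.1 + 0.01 * 0.01) / 0.01))
  expect_lt(abs(snp_lod("BB", 0.1, error_rate = 0.01) - 0.9961), 1e-4)
  expect_equal(snp_lod(NA, 0.3), 0)           # missing contributes nothing
  expect_error(snp_lod("AB", 0.5), "homozygous",
               class = "autozyg_config_error")
  expect_error(snp_lod("AA", 1), "between 0 and 1")
})

test_that("snp_lod is strictly decreasing in allele frequency", {
  for (eps in c(0, 0.005, 0.01, 0.1)) {
    f <- seq(0.001, 0.999, length.out = 400)
    lods <- snp_lod(rep("AA", length(f)), f, error_rate = eps)
    expect_true(all(diff(lods) < 0), info = paste("eps", eps))
  }
})

test_that("location score matches closed form and is additive", {
  # 3 markers at f = 0.5, 2 affecteds, eps 0 -> 6 log10(2)
  panel <- make_panel(list(a1 = c("AA", "AA", "AA"),
                           a2 = c("BB", "BB", "BB"),
                           c1 = c("AB", "AB", "AB")))
  freqs <- estimate_allele_freqs(panel, "c1", pseudocount = 0)
  block <- list(chrom = "chr1", start = 1, end = 4e5)
  sc <- location_score(block, panel, c("a1", "a2"), freqs, error_rate = 0)
  expect_equal(as.numeric(sc), 6 * log10(2))
  # zero affecteds and empty block
  expect_equal(as.numeric(location_score(block, panel, character(), freqs)),
               0)
  empty <- list(chrom = "chr9", start = 1, end = 100)
  expect_equal(as.numeric(location_score(empty, panel, "a1", freqs)), 0)
})

test_that("location score is additive over arbitrary splits", {
  set.seed(4004)
  for (trial in 1:20) {
    n <- 60
    calls <- setNames(lapply(1:3, function(i) random_calls(n)), paste0("a", 1:3))
    ctrl <- setNames(lapply(1:20, function(i) random_calls(n, 0.4, 0.05)),
                     paste0("c", 1:20))
    panel <- make_panel(c(calls, ctrl))
    freqs <- estimate_allele_freqs(panel, names(ctrl))
    split_pos <- sort(sample(panel$markers$pos, 1))
    whole <- list(chrom = "chr1", start = 1, end = max(panel$markers$pos))
    left <- list(chrom = "chr1", start = 1, end = split_pos)
    right <- list(chrom = "chr1", start = split_pos + 1,
                  end = max(panel$markers$pos))
    s_all <- as.numeric(location_score(whole, panel, names(calls), freqs))
    s_l <- as.numeric(location_score(left, panel, names(calls), freqs))
    s_r <- as.numeric(location_score(right, panel, names(calls), freqs))
    expect_equal(s_all, s_l + s_r, tolerance = 1e-12)
  }
})

test_that("markers with undefined frequency are skipped and counted", {
  panel <- make_panel(list(a = c("AA", "AA"), c1 = c("AA", NA)))
  freqs <- estimate_allele_freqs(panel, "c1")
  sc <- location_score(list(chrom = "chr1", start = 1, end = 3e5),
                       panel, "a", freqs)
  expect_equal(attr(sc, "n_skipped"), 1L)
})

test_that("autozygosity_scan fills scores recomputable from scratch", {
  cfg <- small_sim_config(61)
  pool <- simulate_founders(cfg)
  fam <- pedigree_cousin_family("first_cousin_once_removed", 2, 2)
  manifest <- rbind(fam, pedigree_controls(60))
  gd <- gene_drop(pool, manifest, cfg)
  scan <- autozygosity_scan(gd$panel, manifest)
  expect_s3_class(scan, "autozygosity_scan")
  expect_gt(nrow(scan$blocks), 0)
  for (i in seq_len(nrow(scan$blocks))) {
    redo <- location_score(scan$blocks[i, ], gd$panel, scan$affected,
                           scan$freqs, error_rate = scan$params$error_rate)
    expect_equal(scan$blocks$location_score[i], as.numeric(redo),
                 tolerance = 1e-9)
  }
  # the planted block is the top-scoring one and covers the truth span
  top <- scan$blocks[1, ]
  expect_equal(top$chrom, cfg$pathogenic_block_chrom)
  expect_lte(top$start, cfg$pathogenic_pos)
  expect_gte(top$end, cfg$pathogenic_pos)
  # summary and plot methods run
  s <- summary(scan)
  expect_s3_class(s, "summary.autozygosity_scan")
  tmp_png <- tempfile(fileext = ".png")
  grDevices::png(tmp_png); plot(scan); grDevices::dev.off()
  expect_true(file.exists(tmp_png))
})

test_that("appending a qualifying marker never decreases the score", {
  set.seed(4005)
  panel <- make_panel(c(list(a = rep("AA", 40)),
                        setNames(lapply(1:30, function(i)
                          random_calls(40, 0.3, 0)), paste0("c", 1:30))))
  freqs <- estimate_allele_freqs(panel, paste0("c", 1:30))
  scores <- vapply(2:40, function(j)
    as.numeric(location_score(list(chrom = "chr1", start = 1,
                                   end = panel$markers$pos[j]),
                              panel, "a", freqs)), numeric(1))
  expect_true(all(diff(scores) >= 0))
})
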