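# Candidate-variant cascade and homogeneity scan

test_that("novelty is pure catalog set-membership", {
  vt <- make_variants(list(
    list("chr1:1:A:T", "missense", "dbSNP129", "s1", "het"),
    list("chr1:2:A:T", "missense", "", "s1", "het"),
    list("chr1:3:A:T", "missense", "1KG", "s1", "het"),
    list("chr1:4:A:T", "missense", "dbSNP129,1KG", "s1", "het")))
  out <- annotate_novelty(vt, c("dbSNP129", "1KG"))
  expect_equal(out$novel, c(FALSE, TRUE, FALSE, FALSE))
  # restricting the catalog set changes novelty accordingly
  out2 <- annotate_novelty(vt, "1KG")
  expect_equal(out2$novel, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(annotate_novelty(vt, "dbSNP999",
                                available_catalogs = c("dbSNP129", "1KG")),
               "unknown catalog", class = "autozyg_config_error")
})

test_that("novel counts match brute-force set membership on random tables", {
  set.seed(5001)
  cats <- c("dbSNP129", "1KG")
  for (trial in 1:25) {
    n <- 200
    flags <- replicate(n, paste(sample(cats, sample(0:2, 1)),
                                collapse = ","))
    vt <- make_variants(lapply(seq_len(n), function(i)
      list(sprintf("chr1:%d:A:T", i), "missense", flags[i], "s1", "het")))
    out <- annotate_novelty(vt, cats)
    brute <- vapply(strsplit(flags, ","), function(f)
      !any(cats %in% f), logical(1))
    expect_equal(sum(out$novel), sum(brute))
  }
})

test_that("pathogenic potential follows the consequence-class rule", {
  expect_false(classify_pathogenic_potential("synonymous"))
  expect_true(classify_pathogenic_potential("read-through"))
  expect_equal(classify_pathogenic_potential(
    c("missense", "nonsense", "splice site", "indel", "intron", "5'-UTR",
      "3'-UTR", "5'-flanking", "miRNA", "IGR", "other", "synonymous")),
    c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE))
  expect_error(classify_pathogenic_potential("frameshift"),
               "unknown consequence", class = "autozyg_config_error")
  # the set is configurable
  expect_false(classify_pathogenic_potential(
    "indel", pathogenic_classes = c("missense", "nonsense", "splice site")))
})

# a 20-variant toy table with known cascade outcome, 2 affecteds 1 unaffected
toy_table <- function() {
  rows <- list()
  add <- function(pos, cls, cat, gts) {
    id <- sprintf("chr1:%d:A:T", pos)
    for (s in names(gts))
      rows[[length(rows) + 1]] <<- list(id, cls, cat, s, gts[[s]])
  }
  inside <- function(i) 1000 + i          # interval [1001, 1020]
  # 1-6: outside the mapped interval
  for (i in 1:6) add(5000 + i, "missense", "", c(a1 = "hom", a2 = "hom"))
  # 7-10: inside but catalogued
  for (i in 1:4) add(inside(i), "missense", "dbSNP129",
                     c(a1 = "hom", a2 = "hom"))
  # 11-13: inside, novel, not homozygous in all affecteds
  add(inside(5), "missense", "", c(a1 = "hom", a2 = "het"))
  add(inside(6), "missense", "", c(a1 = "het", a2 = "het"))
  add(inside(7), "nonsense", "", c(a1 = "hom"))          # a2 untyped
  # 14: inside, novel, hom in affecteds, but hom in the unaffected
  add(inside(8), "missense", "", c(a1 = "hom", a2 = "hom", u1 = "hom"))
  # 15-17: survive to consequence stage; synonymous ones drop there
  add(inside(9), "synonymous", "", c(a1 = "hom", a2 = "hom"))
  add(inside(10), "synonymous", "", c(a1 = "hom", a2 = "hom", u1 = "het"))
  # 18: indel with unknown zygosity, retained with warning flag
  add(inside(11), "indel", "", c(a1 = "unknown", a2 = "unknown"))
  # 19-20: clean candidates
  add(inside(12), "missense", "", c(a1 = "hom", a2 = "hom", u1 = "het"))
  add(inside(13), "splice site", "", c(a1 = "hom", a2 = "hom"))
  make_variants(rows)
}

test_that("cascade counts on the toy table match hand enumeration", {
  vt <- toy_table()
  iv <- data.frame(chrom = "chr1", start = 1001, end = 1020)
  expect_warning(
    fr <- filter_candidates(vt, iv, c("a1", "a2"), "u1"),
    "unknown zygosity")
  # hand-enumerated: 19 sites -> 13 in interval -> 9 novel -> 6 hom-in-all
  # (incl. the unknown-zygosity indel) -> 5 after unaffected-hom -> 3
  expect_equal(fr$stages$n_in, c(19, 13, 9, 6, 5))
  expect_equal(fr$stages$n_kept, c(13, 9, 6, 5, 3))
  expect_true(all(fr$stages$n_in - fr$stages$n_kept == fr$stages$n_dropped))
  expect_setequal(fr$candidates$var_id,
                  c("chr1:1011:A:T", "chr1:1012:A:T", "chr1:1013:A:T"))
  expect_true(fr$candidates$indel_unknown_zygosity[
    fr$candidates$var_id == "chr1:1011:A:T"])
  # strict indel mode drops the unknown-zygosity indel
  fr2 <- filter_candidates(vt, iv, c("a1", "a2"), "u1",
                           strict_indels = TRUE)
  expect_equal(fr2$stages$n_kept, c(13, 9, 5, 4, 2))
})

test_that("stage counts partition exactly on random tables", {
  set.seed(5002)
  for (trial in 1:20) {
    n <- 150
    rows <- lapply(seq_len(n), function(i) {
      list(sprintf("chr1:%d:A:T", i),
           sample(consequence_classes(), 1),
           sample(c("", "dbSNP129", "dbSNP129,1KG"), 1),
           sample(c("a1", "a2", "u1"), 1),
           sample(c("het", "hom", "ref"), 1))
    })
    vt <- make_variants(rows)
    vt$gt[vt$consequence == "indel"] <- "unknown"
    iv <- data.frame(chrom = "chr1", start = 40, end = 110)
    fr <- suppressWarnings(
      filter_candidates(vt, iv, c("a1", "a2"), "u1"))
    expect_equal(fr$stages$n_kept + fr$stages$n_dropped, fr$stages$n_in)
    expect_equal(fr$stages$n_in[-1], fr$stages$n_kept[-nrow(fr$stages)])
    expect_true(all(diff(fr$stages$n_kept) <= 0))
  }
})

test_that("interval and novelty filters commute", {
  set.seed(5003)
  vt <- toy_table()
  iv <- data.frame(chrom = "chr1", start = 1001, end = 1020)
  # order A: interval then novelty (the cascade's own order)
  a <- suppressWarnings(
    filter_candidates(vt, iv, c("a1", "a2"), "u1"))$candidates$var_id
  # order B: novelty first (restrict table to novel sites), then interval
  novel_ids <- unique(annotate_novelty(vt)$var_id[annotate_novelty(vt)$novel])
  b <- suppressWarnings(
    filter_candidates(vt[vt$var_id %in% novel_ids, ], iv,
                      c("a1", "a2"), "u1"))$candidates$var_id
  expect_setequal(a, b)
})

test_that("genome-wide scans must be explicit", {
  vt <- toy_table()
  expect_error(filter_candidates(vt, NULL, "a1", genome_wide = FALSE),
               "genome_wide", class = "autozyg_config_error")
  expect_error(filter_candidates(vt, data.frame(chrom = character(),
                                                start = numeric(),
                                                end = numeric())[0, ],
                                 "a1", genome_wide = FALSE),
               class = "autozyg_config_error")
})

test_that("homogeneity scan excludes variants homozygous elsewhere", {
  vt <- make_variants(list(
    list("chr1:10:A:T", "missense", "", "a1", "hom"),
    list("chr1:10:A:T", "missense", "", "a2", "hom"),
    list("chr1:10:A:T", "missense", "", "u1", "het"),
    list("chr1:20:G:C", "missense", "", "a1", "hom"),
    list("chr1:20:G:C", "missense", "", "a2", "hom"),
    list("chr1:20:G:C", "missense", "", "u1", "hom"),
    list("chr1:30:G:C", "missense", "dbSNP129", "a1", "hom"),
    list("chr1:30:G:C", "missense", "dbSNP129", "a2", "hom")))
  cand <- homogeneity_scan(vt, c("a1", "a2"), "u1")
  expect_equal(cand$var_id, "chr1:10:A:T")
  # planting the same homozygote in an unaffected empties the result
  vt2 <- vt
  vt2$gt[vt2$var_id == "chr1:10:A:T" & vt2$sample == "u1"] <- "hom"
  expect_equal(nrow(homogeneity_scan(vt2, c("a1", "a2"), "u1")), 0L)
})

test_that("single-affected homogeneity scan is the genome-wide novel-hom list", {
  set.seed(5004)
  rows <- lapply(1:60, function(i)
    list(sprintf("chr1:%d:A:T", i), "missense",
         sample(c("", "dbSNP129"), 1), "a1",
         sample(c("het", "hom"), 1)))
  vt <- make_variants(rows)
  cand <- homogeneity_scan(vt, "a1", character())
  brute <- unique(vt$var_id[vt$catalogs == "" & vt$gt == "hom"])
  expect_setequal(cand$var_id, brute)
})

test_that("synthetic multi-family study yields exactly the planted variant", {
  cfg <- small_sim_config(71)
  pool <- simulate_founders(cfg)
  manifest <- two_family_manifest()
  gd <- gene_drop(pool, manifest, cfg)
  aff <- manifest$id[manifest$status == "affected"]
  nuclear <- unique(c(aff,
                      unlist(manifest[manifest$id %in% aff,
                                      c("father", "mother")]),
                      manifest$id[manifest$role == "sibling"]))
  nuclear <- nuclear[!is.na(nuclear)]
  vt <- simulate_exomes(gd$panel, gd$truth, cfg, sample_ids = nuclear)
  pid <- with(gd$truth$pathogenic_variant,
              sprintf("%s:%d:%s:%s", chrom, pos, ref, alt))
  cand <- homogeneity_scan(vt, aff, setdiff(nuclear, aff))
  expect_equal(cand$var_id, pid)
})
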