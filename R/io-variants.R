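# Variant table IO: VCF 4.2 --------------------------------------------------
#
# On disk a variant table is a VCF 4.2 with GT-only FORMAT. Consequence
# class and catalog membership travel in INFO (key names configurable);
# spaces inside a class name are written as underscores because INFO values
# may not contain whitespace. Zygosity-unknown calls (indels) are written as
# the partially missing genotype ./1.

.gt_levels <- c("ref", "het", "hom", "unknown")

#' Read exome variants from a VCF file
#'
#' Parses a VCF 4.2 (via \pkg{vcfR}) into the long variant-table layout used
#' throughout the package: one row per ALT allele per sample. Multiallelic
#' sites are decomposed into one record per ALT allele. A genotype
#' containing a missing allele is mapped to `"unknown"`; otherwise the
#' count of the record's ALT allele gives `"ref"`, `"het"` or `"hom"`.
#'
#' @param path VCF file (plain text).
#' @param info_class,info_catalogs,info_gene INFO keys carrying the
#'   consequence class, comma-separated catalog names, and gene symbol.
#' @return A `variant_table` data.frame (see [simulate_exomes()] for the
#'   columns).
#' @export
read_variants <- function(path, info_class = "CLASS",
                          info_catalogs = "CATALOGS", info_gene = "GENE") {
  if (!file.exists(path)) abort_format("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(empty_variant_table())
  gt <- v@gt
  if (is.null(gt) || !"FORMAT" %in% colnames(gt))
    abort_format(path, ": VCF has no genotype (FORMAT/GT) columns")
  samples <- setdiff(colnames(gt), "FORMAT")
  gt_field <- function(row) {
    keys <- strsplit(gt[row, "FORMAT"], ":", fixed = TRUE)[[1]]
    gi <- match("GT", keys)
    if (is.na(gi)) abort_format(path, ": record ", row, " has no GT field")
    vapply(gt[row, samples], function(x)
      strsplit(x, ":", fixed = TRUE)[[1]][gi], character(1))
  }
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  out <- list()
  errors <- character()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    raw <- gt_field(i)
    cls <- info_get(fix$INFO[i], info_class)
    cls <- if (is.na(cls)) "other" else gsub("_", " ", cls)
    if (!cls %in% .consequence_classes) {
      errors <- c(errors, paste0(fix$CHROM[i], ":", fix$POS[i],
                                 ": unknown consequence class '", cls, "'"))
      next
    }
    cats <- info_get(fix$INFO[i], info_catalogs)
    cats <- if (is.na(cats)) "" else cats
    gene <- info_get(fix$INFO[i], info_gene)
    for (k in seq_along(alts)) {
      alleles <- strsplit(raw, "[/|]")
      code <- vapply(alleles, function(a) {
        if (any(a == ".")) return("unknown")
        n_alt <- sum(a == as.character(k))
        c("ref", "het", "hom")[n_alt + 1]
      }, character(1))
      out[[length(out) + 1]] <- data.frame(
        var_id = sprintf("%s:%s:%s:%s", fix$CHROM[i], fix$POS[i],
                         fix$REF[i], alts[k]),
        chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]), ref = fix$REF[i],
        alt = alts[k], gene = gene, consequence = cls, catalogs = cats,
        sample = samples, gt = unname(code), stringsAsFactors = FALSE)
    }
  }
  if (length(errors))
    abort_format(path, ": ", length(errors), " bad record(s):\n  ",
                 paste(errors, collapse = "\n  "))
  variants <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(variants)) return(empty_variant_table())
  rownames(variants) <- NULL
  class(variants) <- c("variant_table", "data.frame")
  variants
}

empty_variant_table <- function() {
  structure(data.frame(var_id = character(), chrom = character(),
                       pos = numeric(), ref = character(), alt = character(),
                       gene = character(), consequence = character(),
                       catalogs = character(), sample = character(),
                       gt = character(), stringsAsFactors = FALSE),
            class = c("variant_table", "data.frame"))
}

#' Write exome variants to a VCF file
#'
#' Inverse of [read_variants()]. Samples without a row at a site are written
#' as homozygous reference.
#'
#' @param variants A `variant_table`.
#' @param path Output VCF path.
#' @param samples Sample column order; default all samples seen in the table.
#' @param info_class,info_catalogs,info_gene INFO key names.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, samples = NULL,
                           info_class = "CLASS", info_catalogs = "CATALOGS",
                           info_gene = "GENE") {
  if (is.null(samples)) samples <- sort(unique(variants$sample))
  sites <- unique(variants[c("var_id", "chrom", "pos", "ref", "alt", "gene",
                             "consequence", "catalogs")])
  sites <- sites[order(sites$chrom, sites$pos, sites$alt), , drop = FALSE]
  gt_code <- c(ref = "0/0", het = "0/1", hom = "1/1", unknown = "./1")
  gmat <- matrix("0/0", nrow = nrow(sites), ncol = length(samples),
                 dimnames = list(sites$var_id, samples))
  keep <- variants$sample %in% samples
  gmat[cbind(match(variants$var_id[keep], sites$var_id),
             match(variants$sample[keep], samples))] <-
    gt_code[variants$gt[keep]]
  info <- paste0(info_class, "=", gsub(" ", "_", sites$consequence))
  has_cat <- nzchar(sites$catalogs)
  info[has_cat] <- paste0(info[has_cat], ";", info_catalogs, "=",
                          sites$catalogs[has_cat])
  has_gene <- !is.na(sites$gene) & nzchar(sites$gene)
  info[has_gene] <- paste0(info[has_gene], ";", info_gene, "=",
                           sites$gene[has_gene])
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=autozyg",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Consequence class\">",
            info_class),
    sprintf("##INFO=<ID=%s,Number=.,Type=String,Description=\"Catalog membership\">",
            info_catalogs),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">",
            info_gene),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- paste(sites$chrom, format(sites$pos, scientific = FALSE,
                                    trim = TRUE),
                ".", sites$ref, sites$alt, ".", "PASS", info, "GT",
                sep = "\t")
  if (length(samples))
    body <- paste(body, apply(gmat, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# genotype of `sample` at variant `var_id`; samples absent from the table at
# a site are homozygous reference
genotype_of <- function(variants, var_id, sample) {
  hit <- variants$var_id == var_id & variants$sample == sample
  if (any(hit)) variants$gt[which(hit)[1]] else "ref"
}
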