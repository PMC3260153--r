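# Genotype panel IO: wide TSV and PED/MAP ------------------------------------

.missing_in_codes <- c("--", "00", "NN", "./.", "NA", "")

#' Read a genotype panel
#'
#' Two on-disk layouts are supported. `"tsv"` is a wide table with columns
#' `marker_id`, `chrom`, `pos` followed by one column per sample holding
#' `AA`/`AB`/`BB` calls (`--`, `00`, `NN` or `./.` for missing). `"pedmap"`
#' is a classic PED/MAP pair: `path` is the `.ped` file and the `.map` file
#' is expected alongside (same stem). Markers are re-sorted by
#' (chromosome, position) with a warning if the map is unsorted; duplicate
#' ids, ragged rows and non-biallelic codes are rejected with the offending
#' line named.
#'
#' @param path File path (`.tsv`, or `.ped` of a PED/MAP pair).
#' @param format `"tsv"` or `"pedmap"`; default guessed from the extension.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "pedmap")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ped$", path, ignore.case = TRUE)) "pedmap" else "tsv"
  if (!file.exists(path)) abort_format("file not found: ", path)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_pedmap(path)
}

read_genotypes_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  need <- c("marker_id", "chrom", "pos")
  if (!all(need %in% names(tab)))
    abort_format(path, ": expected columns marker_id, chrom, pos")
  sample_cols <- setdiff(names(tab), need)
  if (!length(sample_cols)) abort_format(path, ": no sample columns")
  calls <- t(as.matrix(tab[sample_cols]))
  calls[calls %in% .missing_in_codes] <- NA_character_
  bad <- which(!is.na(calls) & !calls %in% .genotype_codes, arr.ind = TRUE)
  if (nrow(bad))
    abort_format(path, ": invalid genotype code '",
                 calls[bad[1, 1], bad[1, 2]], "' at line ", bad[1, 2] + 1,
                 " (marker ", tab$marker_id[bad[1, 2]], ")")
  colnames(calls) <- tab$marker_id
  markers <- data.frame(marker_id = tab$marker_id, chrom = tab$chrom,
                        pos = as.numeric(tab$pos), stringsAsFactors = FALSE)
  genotype_panel(markers, calls)
}

read_genotypes_pedmap <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path, ignore.case = TRUE)
  if (!file.exists(map_path)) abort_format("MAP file not found: ", map_path)
  map <- read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) != 4)
    abort_format(map_path, ": expected 4 columns (chrom, id, cM, pos)")
  markers <- data.frame(marker_id = map[[2]], chrom = map[[1]],
                        pos = as.numeric(map[[4]]), stringsAsFactors = FALSE)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[ \t]+")
  expected <- 6 + 2 * nrow(markers)
  calls <- matrix(NA_character_, nrow = length(fields), ncol = nrow(markers))
  ids <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != expected)
      abort_format(ped_path, ": line ", i, " has ", length(f),
                   " fields, expected ", expected)
    ids[i] <- f[2]
    a1 <- f[seq(7, expected, by = 2)]
    a2 <- f[seq(8, expected, by = 2)]
    bad <- !(a1 %in% c("A", "B", "0")) | !(a2 %in% c("A", "B", "0"))
    if (any(bad))
      abort_format(ped_path, ": line ", i, " marker ",
                   markers$marker_id[which(bad)[1]],
                   ": non-biallelic allele code")
    g <- paste0(pmin(a1, a2), pmax(a1, a2))
    g[a1 == "0" | a2 == "0"] <- NA_character_
    calls[i, ] <- g
  }
  rownames(calls) <- ids
  colnames(calls) <- markers$marker_id
  genotype_panel(markers, calls)
}

#' Write a genotype panel
#'
#' Inverse of [read_genotypes()]; `write_genotypes()` followed by
#' [read_genotypes()] reproduces the panel exactly.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path (`.tsv`, or `.ped`; the `.map` is written
#'   alongside).
#' @param format `"tsv"` or `"pedmap"`.
#' @param manifest Optional manifest supplying family/parent columns for the
#'   PED output; defaults to placeholder values.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, format = c("tsv", "pedmap"),
                            manifest = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    calls <- t(panel$calls)
    calls[is.na(calls)] <- "--"
    out <- cbind(panel$markers, as.data.frame(calls, optional = TRUE))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    map_path <- sub("\\.ped$", ".map", path, ignore.case = TRUE)
    write.table(data.frame(panel$markers$chrom, panel$markers$marker_id, 0,
                           format(panel$markers$pos, scientific = FALSE,
                                  trim = TRUE)),
                map_path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    n <- length(panel$samples)
    meta <- data.frame(fam = rep("0", n), id = panel$samples,
                       father = "0", mother = "0", sex = "0", pheno = "0",
                       stringsAsFactors = FALSE)
    if (!is.null(manifest)) {
      m <- match(panel$samples, manifest$id)
      ok <- !is.na(m)
      meta$fam[ok] <- manifest$family_id[m[ok]]
      meta$father[ok] <- ifelse(is.na(manifest$father[m[ok]]), "0",
                                manifest$father[m[ok]])
      meta$mother[ok] <- ifelse(is.na(manifest$mother[m[ok]]), "0",
                                manifest$mother[m[ok]])
      meta$pheno[ok] <- ifelse(manifest$status[m[ok]] == "affected", "2", "1")
    }
    lines <- vapply(seq_len(n), function(i) {
      calls <- panel$calls[i, ]
      a1 <- substr(calls, 1, 1); a2 <- substr(calls, 2, 2)
      a1[is.na(calls)] <- "0"; a2[is.na(calls)] <- "0"
      paste(c(unlist(meta[i, ]), rbind(a1, a2)), collapse = " ")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a sample manifest from TSV
#'
#' @param path TSV with the columns of [validate_manifest()].
#' @return A validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_format("file not found: ", path)
  m <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                  quote = "", na.strings = c("NA", ""))
  validate_manifest(m)
  m
}

#' Write a sample manifest to TSV
#' @param manifest A manifest data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
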