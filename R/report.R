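# Report assembly and the top-level pipeline driver --------------------------

#' Assemble a structured study report
#'
#' Combines mapping, filtering and screening outputs into one
#' machine-readable report mirroring the three summary tables of a
#' disease-gene study: the mapping table (per-block interval, size, genes,
#' score), the filter-cascade table, and the candidate/screen summary. The
#' report is deterministic: identical inputs give byte-identical JSON.
#'
#' @param blocks Block data.frame (from [autozygosity_scan()]`$blocks`),
#'   may be empty.
#' @param filter A `filter_report` from [filter_candidates()], or `NULL`.
#' @param screens List of `control_screen` objects, may be empty.
#' @param manifest A validated manifest.
#' @param gene_annotation Optional gene intervals for per-block gene counts.
#' @return An object of class `study_report` (a nested list with
#'   `schema_version`, `samples`, `mapping`, `cascade`, `candidates`,
#'   `screens`).
#' @export
assemble_report <- function(blocks, filter = NULL, screens = list(),
                            manifest = NULL, gene_annotation = NULL) {
  bs <- summarize_blocks(blocks, gene_annotation)
  mapping <- list(
    n_blocks = bs$stats$n_blocks,
    mean_size_mb = bs$stats$mean_size_mb,
    size_range_mb = c(bs$stats$min_size_mb, bs$stats$max_size_mb),
    mean_genes = bs$stats$mean_genes,
    gene_range = c(bs$stats$min_genes, bs$stats$max_genes),
    blocks = if (nrow(bs$per_block)) bs$per_block else NULL)
  cascade <- if (!is.null(filter)) filter$stages else
    data.frame(stage = character(), n_in = integer(), n_kept = integer(),
               n_dropped = integer())
  candidates <- if (!is.null(filter) && nrow(filter$candidates))
    filter$candidates else NULL
  samples <- if (!is.null(manifest)) {
    list(n_samples = nrow(manifest),
         n_affected = sum(manifest$status == "affected"),
         n_controls = sum(manifest$role == "population_control"),
         demes = sort(unique(manifest$deme)))
  } else NULL
  structure(list(schema_version = "1.0", samples = samples,
                 mapping = mapping, cascade = cascade,
                 candidates = candidates,
                 screens = lapply(screens, unclass)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (schema", x$schema_version, ")\n")
  if (!is.null(x$samples))
    cat(sprintf("  samples: %d (%d affected, %d controls)\n",
                x$samples$n_samples, x$samples$n_affected,
                x$samples$n_controls))
  cat(sprintf("  mapping: %d block(s)", x$mapping$n_blocks))
  if (x$mapping$n_blocks > 0)
    cat(sprintf(", mean %.1f Mb", x$mapping$mean_size_mb))
  cat("\n")
  if (nrow(x$cascade))
    cat(sprintf("  cascade: %d -> %d\n", x$cascade$n_in[1],
                x$cascade$n_kept[nrow(x$cascade)]))
  cat(sprintf("  candidates: %d\n",
              if (is.null(x$candidates)) 0L else nrow(x$candidates)))
  invisible(x)
}

#' Write a study report as JSON
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline from a configuration file
#'
#' Executes simulate (optional) -> map -> filter -> report from a single
#' YAML configuration, writing every artifact under the output directory:
#' genotype TSV, manifest TSV, analysis VCF, truth BED/JSON (simulation
#' runs only; the analysis VCF never marks the planted variant), block
#' BED/TSV, per-marker LOD track, candidate VCF, cascade TSV, segregation
#' TSV and the JSON report. Identical config and seed reproduce identical
#' artifacts.
#'
#' Configuration keys: either a `simulate:` stanza (any [sim_config()]
#' argument) or an `inputs:` stanza with `genotypes`, `manifest` and `vcf`
#' paths (plus optional `intervals` BED); optional `map:` overrides
#' ([autozygosity_scan()] arguments) and `filter:` stanza with `mode`
#' (`"mapped"` or `"homogeneity"`) and `catalogs`.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param outdir Output directory (created if needed).
#' @param seed Overrides the config seed when not `NULL`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `status` (0 on success), `report`, the
#'   mapping fit `scan`, the `filter` report and the artifact `paths`.
#' @export
run_pipeline <- function(config, outdir = ".", seed = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) abort_config("config must be a file path or a list")
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  seed <- seed %||% cfg$seed %||% 1L

  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (!is.null(sim_args$chromosome_lengths))
      sim_args$chromosome_lengths <- unlist(sim_args$chromosome_lengths)
    sim_args$rng_seed <- seed
    scfg <- do.call(sim_config, sim_args)
    say("simulate: seed %d, %d founder haplotypes, %.1f markers/Mb",
        seed, scfg$n_founder_haplotypes, scfg$marker_density_per_mb)
    study <- simulate_study(scfg)
    panel <- study$panel; manifest <- study$manifest
    variants <- study$variants; truth <- study$truth
    paths$genotypes <- file.path(outdir, "genotypes.tsv")
    write_genotypes(panel, paths$genotypes)
    paths$manifest <- file.path(outdir, "manifest.tsv")
    write_manifest(manifest, paths$manifest)
    paths$vcf <- file.path(outdir, "exomes.vcf")
    write_variants(variants, paths$vcf)
    paths$truth_bed <- file.path(outdir, "truth_ibd.bed")
    write_intervals(data.frame(chrom = truth$ibd_segments$chrom,
                               start = truth$ibd_segments$start,
                               end = truth$ibd_segments$end,
                               name = truth$ibd_segments$sample,
                               stringsAsFactors = FALSE),
                    paths$truth_bed)
    paths$truth_json <- file.path(outdir, "truth_variant.json")
    jsonlite::write_json(truth$pathogenic_variant, paths$truth_json,
                         auto_unbox = TRUE, digits = NA)
  } else {
    inp <- cfg$inputs
    if (is.null(inp)) abort_config("config needs a 'simulate' or 'inputs' stanza")
    for (field in c("genotypes", "manifest", "vcf"))
      if (is.null(inp[[field]]))
        abort_config("config field missing: inputs$", field)
    say("inputs: %s", inp$genotypes)
    panel <- read_genotypes(inp$genotypes)
    manifest <- read_manifest(inp$manifest)
    variants <- read_variants(inp$vcf)
  }

  map_args <- cfg$map %||% list()
  scan <- do.call(autozygosity_scan,
                  c(list(panel = panel, manifest = manifest), map_args))
  say("map: %d affected, %d shared block(s)", length(scan$affected),
      nrow(scan$blocks))
  blk <- write_blocks(scan$blocks, file.path(outdir, "blocks"))
  paths$blocks_bed <- blk[["bed"]]
  paths$blocks_tsv <- blk[["tsv"]]
  paths$lod <- file.path(outdir, "lod_track.tsv")
  write.table(scan$lod_track, paths$lod, sep = "\t", quote = FALSE,
              row.names = FALSE)

  fcfg <- cfg$filter %||% list()
  mode <- fcfg$mode %||% "mapped"
  catalogs <- unlist(fcfg$catalogs %||% c("dbSNP129", "1KG"))
  exomed <- unique(variants$sample)
  affected <- intersect(manifest_affected(manifest), exomed)
  others <- setdiff(exomed, affected)
  if (mode == "homogeneity") {
    cand <- homogeneity_scan(variants, affected, others, catalogs)
    filt <- filter_candidates(variants, NULL, affected, others, catalogs,
                              genome_wide = TRUE,
                              consequence_filter = FALSE)
  } else {
    filt <- filter_candidates(variants, scan$blocks, affected, others,
                              catalogs)
    cand <- filt$candidates
  }
  say("filter (%s): %d candidate(s)", mode, nrow(cand))
  paths$cascade <- file.path(outdir, "cascade.tsv")
  write.table(filt$stages, paths$cascade, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(cand)) {
    paths$candidates <- file.path(outdir, "candidates.vcf")
    write_variants(variants[variants$var_id %in% cand$var_id, ,
                            drop = FALSE], paths$candidates)
    seg <- check_segregation(variants, cand$var_id[1], manifest)
    paths$segregation <- file.path(outdir, "segregation.tsv")
    write.table(seg$table, paths$segregation, sep = "\t", quote = FALSE,
                row.names = FALSE)
    say("segregation of %s: %s", cand$var_id[1],
        if (seg$pass) "PASS" else "FAIL")
  }

  screens <- list()
  if (!is.null(truth)) {
    ctrl <- manifest$id[manifest$role == "population_control"]
    n_het <- length(intersect(setdiff(truth$carriers, truth$hom_carriers),
                              ctrl))
    n_hom <- length(intersect(truth$hom_carriers, ctrl))
    screens <- list(allele_frequency_from_controls(
      length(ctrl), n_het, n_hom,
      variant_id = with(truth$pathogenic_variant,
                        sprintf("%s:%d:%s:%s", chrom, pos, ref, alt))))
  }

  report <- assemble_report(scan$blocks, filt, screens, manifest)
  paths$report <- file.path(outdir, "report.json")
  write_report(report, paths$report)
  say("report: %s", paths$report)
  invisible(list(status = 0L, report = report, scan = scan, filter = filt,
                 candidates = cand, paths = paths))
}
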