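# Internal helpers shared across modules.

# Round-half-up at `digits` decimals. base::round() rounds half to even,
# which would report a 78.5-gene mean as 78; screening tables in this field
# print half-up values, so we do too.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a relative epsilon so that values like 0.495 stored as
  # 0.49499999... still round the way their decimal reading suggests
  floor(x * p + 0.5 + sqrt(.Machine$double.eps) * sign(x)) / p
}

# Deterministic per-stage seed derivation. A single top-level seed fans out
# to independent stage streams so that e.g. regenerating exomes does not
# perturb the genotype panel. All arithmetic stays below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((((seed %% 50021) + 1) * 69621 + h * 10007) %% 2147483563L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("autozyg_config_error", "error")))
}

abort_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("autozyg_format_error", "error")))
}

# intervals are data.frames with chrom/start/end, 1-based closed
interval_size_mb <- function(start, end) (end - start + 1) / 1e6

# TRUE where [s1,e1] overlaps [s2,e2] by >= 1 bp (1-based closed)
intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2

new_intervals <- function(chrom = character(), start = integer(),
                          end = integer(), ...) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(start > end)) abort_format("interval start > end")
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), ..., stringsAsFactors = FALSE)
}
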