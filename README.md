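# autozyg

Autozygosity mapping and recessive-variant filtering for founder
populations.

In endogamous communities such as the Old Order Amish and Mennonite demes,
rare recessive disorders arise when both copies of a founder allele meet
in one child. Because the two copies descend from a single recent
ancestor, affected individuals are homozygous not just at the disease
locus but across a multi-megabase block of surrounding markers. `autozyg`
implements the complete discovery workflow built on that signal:

1. **Autozygosity mapping** from SNP-array genotypes — runs of
   homozygosity, blocks identically homozygous across all affected
   individuals, homozygosity-LOD location scores, and exclusion mapping in
   nuclear families using unaffected siblings.
2. **Exome variant filtering** — the candidate cascade (mapped interval →
   catalog novelty → homozygous in all affecteds → homozygous in no
   unaffected → consequence class), the mapping-free mutation-homogeneity
   scan, Mendelian segregation checks, and carrier screening summaries.
3. **A synthetic founder-population generator** — gene-drop simulation
   through consanguineous pedigrees with a planted autozygous block and a
   planted pathogenic variant, so every stage can be validated against
   known ground truth without any external data.

## The statistic

For a homozygous genotype at a marker whose homozygous allele has
population frequency *f*, the two-point homozygosity LOD compares the
probability of the observation under autozygosity (allowing genotyping
error ε) with its probability under Hardy–Weinberg equilibrium:

```
lod = log10( ((1 − ε) f + ε f²) / f² )        (ε = 0  ⇒  −log10 f)
```

Allele frequencies are estimated from unrelated population controls with
a Laplace pseudocount (default 0.5 per allele) so no marker is ever
infinitely informative. The **location score** of a shared homozygous
block is the sum of these LODs over every affected individual and every
non-missing homozygous marker in the block — a relative measure that
ranks candidate intervals; it is additive over any subdivision of the
block.

## Worked example

Simulate a two-family study (four affected children who share a planted
4.4 Mb autozygous block and a pathogenic splice-site variant, 100
genotyped population controls, 15 exomes), map it, and filter the exomes:

```r
library(autozyg)

cfg <- sim_config(chromosome_lengths = c(chr1 = 120e6),
                  pathogenic_block_start = 40e6,
                  pathogenic_block_end = 44.4e6 - 1, rng_seed = 42)
study <- simulate_study(cfg)

scan <- autozygosity_scan(study$panel, study$manifest, min_size_mb = 1)
scan
#> Autozygosity scan: 4 affected, 100 control(s)
#>   shared blocks: 1
#>     chr1:40024734-44354103  4.3 Mb  85 markers  score 85.6

aff    <- study$manifest$id[study$manifest$status == "affected"]
others <- setdiff(study$exome_samples, aff)
fr <- filter_candidates(study$variants, scan$blocks, aff, others)
fr
#> Candidate-variant cascade
#>   in_mapped_interval              57581 ->   2086 (dropped 55495)
#>   novel                            2086 ->    371 (dropped 1715)
#>   homozygous_in_all_affected        371 ->      1 (dropped 370)
#>   not_homozygous_in_unaffected        1 ->      1 (dropped 0)
#>   potentially_pathogenic              1 ->      1 (dropped 0)
#>   candidates: 1
#>     chr1:42199999:A:T (splice site)

check_segregation(study$variants, fr$candidates$var_id[1], study$manifest)
#> Segregation of chr1:42199999:A:T: PASS
```

The single surviving candidate is exactly the planted pathogenic variant
(`study$truth$pathogenic_variant`), its genotypes segregate as a fully
penetrant recessive allele (parents heterozygous, affecteds homozygous,
no unaffected homozygote), and the mapped block recovers the planted
span to its flanking markers. A control screen is summarised with both
conventions, allele frequency per chromosome and carrier rate per
individual:

```r
allele_frequency_from_controls(201, 2, 0)
#> allele frequency 0.50% (2/402), carrier rate 1.0%
```

The same steps run from the shell through `inst/scripts/autozyg.R`
(`simulate`, `map`, `filter`, `screen`, `run` subcommands) or in one call
with `run_pipeline()` from a YAML config.

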