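---
title: "Autozygosity mapping and recessive-variant filtering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity mapping and recessive-variant filtering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

This vignette is the package's account of its science: the model behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical conventions that make results reproducible.

## The mapping model

In an endogamous deme, a child affected by a rare recessive disorder has
usually inherited two copies of one founder allele through a
consanguinity loop. At the disease locus the child is *autozygous*:
homozygous by descent, across an entire haplotype block whose expected
size is set by the number of meioses in the loop (a few megabases for
loops 10–14 generations deep). Mapping therefore reduces to finding
intervals where every affected individual is homozygous for the *same*
marker alleles — the assumption of mutation and locus homogeneity — and
ranking those intervals by how surprising that much homozygosity would be
by chance.

### Two-point homozygosity LOD

For a homozygous call at a marker whose homozygous allele has frequency
$f$ in the deme, with genotyping error rate $\varepsilon$,

$$\mathrm{lod} = \log_{10}\frac{(1-\varepsilon)f + \varepsilon f^2}{f^2},$$

the log-ratio of the genotype's probability under autozygosity (the
allele is drawn once; an error can also land on a chance homozygote)
against Hardy–Weinberg. At $\varepsilon = 0$ this is $-\log_{10} f$: a
homozygote for a 10% allele contributes a full LOD unit, a homozygote for
a near-fixed allele almost nothing. Heterozygous calls are never scored
(they are handled by the block tolerances below); missing calls
contribute 0.

The **location score** of a block sums these LODs over all affected
individuals and all non-missing homozygous markers in the block.
Affecteds are treated as independent, matching the cumulative
construction; because relatives share controls-estimated allele
frequencies and haplotypes, the score overstates formal linkage evidence
and should be read as a *relative* ranking of candidate intervals, which
is how it is used. The score is additive over any split of a block, a
property the test suite checks to $10^{-9}$ log units.

Whether per-affected LODs should be summed or reported per individual is
genuinely open; summation was chosen because it is the natural reading of
a cumulative score and reduces to the single-affected case when only one
genome is available.

### Allele frequencies

Frequencies come from unrelated population controls (the classical design
genotypes about 100 deme-specific females). With $n_A$ A-alleles observed
on $2n$ called chromosomes and pseudocount $c$ (default 0.5 per allele),

$$\hat f_A = \frac{n_A + c}{2n + 2c}.$$

The pseudocount keeps $0 < \hat f < 1$, so a marker whose variant allele
was never seen in controls cannot contribute an infinite LOD. Markers
with no called control genotypes get an undefined frequency and are
skipped (and counted) during scoring.

## Run detection: statuses, budgets, and the flank rule

All scanning is done on a per-marker status vector and a single scanner,
so runs of homozygosity in one sample and shared blocks across affecteds
have identical semantics.

For one sample the statuses are `hom`, `het`, `miss`. For a set of
affecteds each marker is collapsed to:

* `hom` — every called affected homozygous for the same allele;
* `soft` — with ≥ 3 affecteds, exactly one called deviant against a
  homozygous majority of at least two. A single discordant call against an
  otherwise perfect column is far more likely a genotyping error than a
  real recombination, so it neither breaks the block nor spends budget —
  but it is *not* boundary-grade evidence;
* `het` — two or more called affecteds break identical homozygosity;
* `miss` — no affected called.

A qualifying window starts and ends on a strict `hom` marker and may
contain at most `max_het_per_run` het and `max_missing_per_run` missing
markers (defaults 4 and 4). The budgets are sized from the expected error
load: at a 0.5% per-call error rate, a 4–8 Mb block on a 50K-like panel
(≈ 75–140 markers) genotyped in up to ~6 affecteds accumulates roughly
one to three error-corrupted marker columns, so a budget of four absorbs
that load with high probability while staying far below what chance
homozygosity could exploit.

**The flank rule.** If a window contains any budgeted interruption, the
stretches before the first and after the last interruption must each
carry at least `min_flank` (default 5) strict `hom` markers. This is the
discriminator between an isolated error deep inside a long autozygous
block (absorbed, because both flanks are strict-rich) and a chance
homozygote just beyond the block boundary (which would need five
consecutive strict markers to recruit the budget across the boundary —
vanishingly unlikely).

**Selection.** Runs are selected longest-first with re-derivation: the
longest qualifying window in a stretch is accepted (ties to the leftmost
start) and the stretches to its left and right are searched again. A
plain left-to-right greedy scan can let a mediocre chance stretch consume
the tolerance budget that a long true block immediately to its right
needed; longest-first removes that failure mode, and re-derivation
guarantees no qualifying territory is silently dropped. The scanner is
property-tested for exact equality against an exhaustive $O(n^2)$ window
enumeration implementing the same definition independently.

Block boundaries are reported at the outermost strictly qualifying
markers, matching the convention of reporting blocks by their inclusive
flanking SNPs. `min_markers` defaults to 25, which at 50K-like density
(~17 markers/Mb) corresponds to ~1.4 Mb — below the smallest blocks this
workflow is expected to find (~1.6 Mb) — while at 10K-like density
(~3.5 markers/Mb) the same 25 markers correspond to ~7 Mb, which is why
small blocks are invisible on sparse panels (see *Validation* below).

## Exclusion mapping

For a nuclear family with affected children and unaffected siblings, a
region is consistent with linkage when all affecteds carry identical
genotypes across it and no unaffected sibling matches that shared
genotype vector across it (a sibling matching over an extended stretch
shares both parental haplotypes and would be affected too).

Two numerical choices differ from the homozygosity scanner, both because
the cost structure is asymmetric — an identity interval that over-extends
merely widens a candidate region, while one clipped at a genotyping error
can amputate the disease locus:

* **Length-proportional mismatch allowance.** Sibling pairs are
  genuinely identical over multi-megabase stretches, so identity
  intervals can span hundreds of markers and accumulate error mismatches
  in proportion to length. An interval of $L$ markers tolerates
  $\max(\texttt{max\_mismatch}, \lceil \texttt{mismatch\_rate}\cdot L
  \rceil)$ breaks (defaults 4 and 2%); chance identity, discordant at
  roughly 45% of markers, still cannot chain. Selection is again
  longest-first with re-derivation.
* **Sibling match-runs are strict and interval-local.** A sibling
  excludes only where it matches the affected vector for at least
  `min_exclude_markers` (default 25) consecutive markers with *zero*
  mismatches, evaluated inside the identity interval — matching where the
  affecteds do not share is meaningless. Because a genuine
  both-haplotype match continues past its true end by chance state
  matching (a geometric tail with per-marker continuation probability
  well under one half), each match-run end that lies strictly inside the
  interval is pulled back by `match_run_trim` markers (default 4,
  roughly the 99% quantile of that tail), at the cost of ~4 markers of
  spatial resolution at genuine exclusion boundaries.

Regions smaller than `min_size_mb` (default 5) are discarded, matching
the convention of reporting only regions large enough to harbour an
undetected autozygous block.

## The exome filtering cascade

Variant records carry one of thirteen consequence classes, per-sample
genotypes (`ref`, `het`, `hom`, `unknown`), and catalog-membership flags.
The cascade applies, in order: mapped-interval intersection, catalog
novelty (pure set-membership — absence from every named catalog, by
default dbSNP129 and 1KG), homozygosity in every affected, absence of
homozygosity in any unaffected, and (optionally, on by default) the
potentially pathogenic consequence set {missense, nonsense, read-through,
splice site, indel}. Stage counts partition exactly at every stage.

Indel calls carry unknown zygosity (automated indel callers typically do
not call it), and are *retained* through the homozygosity stage with a
warning flag rather than dropped — silently discarding a class the
workflow keeps visible would be worse than a flagged pass; `strict_indels
= TRUE` restores the hard filter. An affected sample with no genotype at
a variant counts as non-homozygous there and is tallied in the report.

The **homogeneity scan** is the mapping-free mode: with several affecteds
assumed to carry the same allele, the candidate is the variant that is
novel, homozygous in all affecteds and homozygous in no other sequenced
sample — no intervals needed. With mapping supplied, both modes must (and
in the validation suite do) return the same planted variant.

**Segregation** of a candidate is checked per family: genotyped parents
of affecteds must be heterozygous, affecteds homozygous, and no
unaffected member homozygous; missing genotypes are reported but never
fail the check.

**Carrier screens** report both conventions, allele frequency per
chromosome, $(n_{het} + 2n_{hom})/2N$, to two decimals, and carrier rate
per individual, $(n_{het} + n_{hom})/N$, to one decimal — the two differ
by about a factor of two for rare variants and are easily conflated.
Rounding is half-up throughout the reporting layer (so a mean of 78.5
genes prints as 79), because that is how screening tables are
conventionally printed; base R's round-half-even would disagree at the
boundary. A homozygous control is flagged prominently: one such
observation undermines a fully penetrant recessive candidate.

## The synthetic-data generator

The generator exists so that every downstream stage is testable against
known truth. What it emulates, stage by stage:

* **Founder pool** — per-marker A-allele frequencies drawn uniformly on
  [0.1, 0.9] (array content is ascertained towards common variation);
  founder haplotypes drawn independently per marker from that spectrum.
  Marker maps at 10K-like (3.5/Mb) or 50K-like (17.4/Mb) density, the
  genome-wide averages of the two classical array generations.
* **Gene drop** — meioses follow a sex-averaged Poisson crossover process
  (default 1 crossover per 100 Mb, i.e. 1 cM/Mb, no interference) through
  a pedigree whose consanguinity-loop depth is chosen from the target
  inbreeding coefficient: first cousins (F = 1/16), first cousins once
  removed (1/32 ≈ 3.1%, the default, bracketing the 2.5–4% typical of
  the demes of interest) or second cousins (1/64). Haplotypes are founder
  mosaics, so realized identity-by-descent segments — and hence each
  sample's realized F — are known exactly and recorded in the truth set.
* **Planting** — one founder haplotype is spliced homozygously into every
  affected across the configured span (default 4.4 Mb, the average block
  size of the calibration studies); each parent of an affected carries
  exactly one copy across the span, and no unaffected sibling carries
  two anywhere in it. The pathogenic variant sits at the span midpoint,
  is absent from all catalogs, homozygous in affecteds and
  heterozygous-or-absent elsewhere.
* **Array noise** — per-call genotyping error (default 0.5%; an erroneous
  call becomes one of the other two codes uniformly) and missingness
  (default 1%).
* **Exomes** — per-sample background counts are Poisson around the
  calibrated means (~16,540 autosomal calls of which ~4% novel and ~3.3%
  of novel calls homozygous, reproducing the ~22 novel-homozygous
  variants per founder-population exome). Catalogued variants are drawn
  from a shared site pool three times the per-sample rate, so roughly a
  third of any two samples' known calls coincide; novel variants are
  private to each sample, reflecting their rarity. Consequence classes
  follow separate calibrated spectra for catalogued and novel calls (the
  novel spectrum is strongly coding-enriched); indels are flagged
  unknown-zygosity and catalogued against dbSNP only.

What it deliberately does **not** emulate: linkage disequilibrium and
real deme haplotype structure (founder alleles are independent across
markers; generation depth is a knob, not a fit to real LD), coalescent
mutation-drift realism, read-level data, recurrent novel variants shared
across samples, and exonic position clustering (variant positions are
uniform over the simulated genome, so mapped-interval counts scale with
interval fraction rather than exon content). Passing tests therefore
demonstrate the algorithms' correctness and calibration under a clean
population model — not performance on real arrays, where LD lengthens
chance homozygosity runs and block-boundary precision is somewhat worse
than the simulation suggests.

Determinism: a single seed fans out to independent per-stage streams
(founders, gene drop, exomes), so identical configuration and seed yield
byte-identical panels, truth sets, variant tables and pipeline reports.

## Validation designs and problem sizes

The test suite validates each stage at deliberately modest scale:

* scanner-vs-enumeration equality on ≥ 120 random panels of ≤ 200
  markers with randomized tolerances;
* planted-block recovery on a 40 Mb chromosome at 50K-like density with
  0.5% genotyping error, nine affected children from three sibships (the
  largest of the calibration mapping designs), 100 seeds: boundaries must
  land within one inter-marker gap of truth in ≥ 95 runs. Boundary
  precision is a function of the number of distinct haplotypes flanking
  the block: with only one sibship pair of affecteds, chance identical
  homozygosity just outside the block is common enough that the
  within-one-gap rate drops noticeably — the practical reason the
  classical workflow prefers multiple affecteds from separate sibships;
* the same design with a 1.6 Mb block: recovered on the 50K-like panel,
  essentially never on the 10K-like panel (~6 markers), reproducing the
  need for denser arrays for small blocks;
* exclusion mapping with the classic two-affected/six-sibling family and
  a 6.6 Mb planted block, 100 seeds;
* cascade and homogeneity-scan recovery at fully calibrated exome rates
  with 15 sequenced samples (4 affected), 100 seeds;
* an end-to-end pipeline run on a 120 Mb chromosome with 131 genotyped
  samples, required to finish in minutes on one CPU.

## Known limitations

* The location score is a ranking device, not a calibrated linkage
  statistic: summing over related affecteds overstates evidence, and no
  genome-wide significance threshold is provided.
* Phase is never used; marker alleles are abstract A/B with no strand
  reconciliation, so panels from different sources must already share a
  labelling convention.
* Consequence classes are consumed as annotations, never computed; the
  package does no in-silico pathogenicity prediction.
* The exclusion-mapping state-matching proxy trades a few markers of
  boundary resolution (the match-run trim) for robustness to chance
  matching; haplotype-resolved exclusion would be sharper but requires
  phasing, which is out of scope.
* With two affecteds the `soft` single-deviant rule cannot apply (no
  majority exists), so shared-block detection in a single sibship pair is
  fully exposed to genotyping error at block edges.
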