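---
title: "Prioritizing causal variants in small retinitis pigmentosa families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing causal variants in small retinitis pigmentosa families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpcascade)
```

## The model

`rpcascade` operationalizes the diagnostic logic of exome screens in small
Mendelian families. The underlying genetic model is the standard one for
retinitis pigmentosa: a single causal genotype per family, drawn from one
of four hypothesis classes — a heterozygous allele in a dominant-capable
gene (inherited from an affected parent or arisen de novo), a homozygous
allele in a recessive gene, two distinct alleles of one recessive gene in
trans (compound heterozygosity), or a hemizygous/homozygous allele of an
X-chromosome gene. Causality is never proven by the pipeline; it is made
*plausible* by surviving a cascade of exclusion rules, each of which
encodes a population-genetic or biochemical expectation:

* a dominant pathogenic allele for a fully penetrant, early-onset disease
  should be absent from population references — any observed reference
  frequency excludes it;
* a recessive pathogenic allele may circulate in carriers, so the ceiling
  is a minor allele frequency of 0.005 per consulted source (allele count
  over allele number, with AN = 0 defined as frequency 0: absence of
  observation is not evidence of commonness). X-linked candidates use the
  recessive ceiling, since carrier females appear in references;
* synonymous and non-coding changes are excluded unless they alter a
  splice site;
* a missense change dismissed *unanimously* by PROVEAN (Neutral), SIFT
  (Tolerated) and PolyPhen-2 (benign) is excluded. Unanimity is deliberate
  and is evaluated per candidate unit, not per variant: within a
  compound-heterozygote pair one damaging allele keeps the pair alive
  (screens report such pairs), and variants with missing verdicts —
  truncating and splice variants are not scored by these tools — can never
  be excluded this way.

Pedigree information is used twice. First, positively: compound-heterozygote
pairs are phased against parental (or unaffected-relative) genotypes — a
pair is `trans_confirmed` when each parent carries exactly one allele,
rejected as cis when both alleles are unambiguously from one parent, and
`phase_unknown` otherwise (singleton probands are reported with this
explicit caveat); a heterozygous allele absent from both sequenced parents
is annotated de novo, and an unsequenced parent makes the test `untestable`
rather than negative. Second, negatively: any unit whose *full* causal
genotype is carried by an unaffected sequenced relative is removed
(heterozygous carriers of half a recessive unit are expected, not
violations; relatives of unknown affection status can neither confirm nor
violate).

## Data model and formats

Variants are flat rows keyed by `(gene, normalized cDNA change)` — the
published tables the fixtures transcribe omit genomic coordinates, and this
key is exactly what deduplication and novelty lookup need. HGVS strings are
treated as opaque tokens: whitespace stripped, `>` spacing canonicalized,
stray trailing parentheses dropped; no grammatical parsing, because
equality is the only operation required. Predictor verdicts are normalized
case-insensitively through an editable mapping table
(`inst/extdata/predictor_token_map.tsv`); the irregular tokens that appear
in print ("possibly neutral", "possibly deleterious") map to the nearest
member of each tool's closed vocabulary.

Two ingestion routes yield the same internal representation and are tested
for agreement: a tab-separated annotated table whose
genotype-configuration keyword (`heterozygous`, `homozygous`,
`compound heterozygous`, `hemizygote`) stands in for per-sample calls, and
an annotated VCF (read through `vcfR`) plus a 6-column PED pedigree, from
which per-sample zygosity is derived from GT fields. Multi-allelic records
are split per ALT with parsimony trimming of the allele pair (a
reference-free stand-in for full left-normalization, which would need the
genome); haploid calls are hemizygous; a diploid heterozygous X call in a
male is coerced to missing with a warning, since pseudoautosomal regions
are not modeled.

## Tunable parameters

All thresholds live in one `filter_policy()` object:

| parameter | default | meaning |
|---|---|---|
| `min_quality` | 30 | phred call quality, strict `>` |
| `min_depth` | 5 | read depth, `>=` |
| `maf_recessive` | 0.005 | reference-MAF ceiling, recessive/X-linked |
| `maf_dominant` | 0 | ceiling under the dominant model ("any frequency excludes") |
| `maf_rescue` | 0.001 | external-reference ceiling of the rescue scan |
| `frequency_sources` | inhouse, 1kg, exac, dbsnp135_common | sources consulted, in order |
| `excluded_regions` | none | BED intervals (0-based half-open), e.g. MHC-homologous sequence |
| `rescue_requires` | provean, sift | predictors that must call a rescue candidate deleterious |

The defaults are the study conditions the packaged fixtures were filtered
under. Steps short-circuit in the fixed order QC → frequency → consequence
→ predictor, and the trace records the first failing step per variant —
deterministic, auditable output was preferred over exhaustive per-rule
reporting.

The **rescue scan** exists because the dominant rule is maximally strict: a
true dominant allele present in one in-house control (for instance a
control who develops RP late, after sampling) would be discarded. The scan
therefore revisits heterozygous missense variants of unsolved sporadic
families and keeps those with in-house MAF below 0.5%, deleterious calls
from both PROVEAN and SIFT, and MAF ≤ 0.001 in the *external* references.
The ceiling is applied to external sources only: the in-house gate is the
scan's own first step, and the external lookup is a separate, subsequent
step. Survivors are tiered `uncertain_candidate`, never counted as solved.

## Tiering and summaries

Genes are tiered against two panels: a known-RP panel (with per-gene
permitted modes, `ad`/`ar`/`xl`; dual-mode genes list both) and an
other-retinopathy panel. "Solved" means at least one surviving known-panel
unit; other-panel and rescue units are reported separately and never
increment the solved count. Distinct mutations are counted by the
`(gene, hgvs_c)` key, so an allele recurring in two families counts once.
Novelty is an exact catalog lookup on the same key. Per-gene proportions
are computed over the full recruited cohort (98 families for the packaged
composition) and printed to the nearest integer percent. When one family
retains monoallelic units in two different genes, all cross-gene pairs are
flagged as advisory digenic hypotheses without suppressing the individual
units; in gene-level counts such a family counts once per gene.

## The synthetic cohort generator

The simulator emulates the study design so that every rule is exercisable
with known truth: 22 dominant, 19 recessive, 52 sporadic and 5 X-linked
families by default, with per-class causal fractions set to the published
per-class diagnostic yields (0.59, 0.42, 0.31, 0.80) and sporadic probands
recruited without parents 80% of the time. Pedigree templates are
three-generation or quartet for dominant families (an affected transmitting
parent), trio or quartet for recessive ones, singleton or trio for sporadic
ones, and a carrier-mother trio for X-linked ones. Causal units are
implanted to satisfy every rule by construction: reference-absent alleles,
fully damaging (or truncating, hence verdict-missing) annotations,
Mendelian-consistent transmission, trans configuration for
compound-heterozygote pairs, carrier relatives that are consistent rather
than violating. Biallelic causal hypotheses are placed in recessive-only
genes so the implanted unit is the unique admissible solution.

Decoys exercise the exclusion rules: per family, one common variant
(MAF > 0.005 in-house), one rare synonymous, one rare non-coding, one
unanimously-benign missense, and — where the pedigree permits — one
segregation violator (the full causal genotype in an unaffected relative)
and one cis pair (both alleles threaded down one parental haplotype).
Segregation and cis decoys are infeasible in singletons, so class coverage
is guaranteed, and asserted, at cohort level. The background variant load
(Poisson, mean 150 per family) is drawn from the same rule classes: in this
generator every non-causal variant fails at least one named rule, because a
variant that survives every published filter is by definition
indistinguishable from a candidate — the generator makes the boundary
explicit instead of leaving it to chance. Genes carrying rare heterozygous
decoys are kept disjoint within a family so decoys cannot pair with each
other or with the causal unit. Positions are synthetic integers on
synthetic contigs (X for the X-linked panel genes); no reference genome is
shipped or needed. Allele numbers per source are fixed (4040 in-house
alleles for a 2020-control panel, 5008 for a phase-III-sized reference,
121412 for an ExAC-sized one) — only the MAF comparison matters to the
pipeline. One seed determines the whole cohort; the same seed reproduces
byte-identical output files.

What passing recovery tests do and do not show: with noise-free
annotations, unit-level sensitivity 1.0 and zero decoy leaks demonstrate
that the engine implements its stated rules exactly; they do not
demonstrate performance on real exomes, where annotation error, incomplete
panels, structural variants, mosaicism and phenocopies all reduce yield.
Predictor noise is the one error mode the generator models
(`predictor_false_benign`: causal missense annotated unanimously benign),
and it produces exactly the expected loss — single-missense units vanish,
pairs with a damaging or truncating partner survive.

## Numerical and design choices

* Ties and ordering: with more than two heterozygotes in one gene, all
  trans-compatible pairs are reported, ranked by number of truncating
  alleles and then by lower maximum reference MAF.
* The proband is the lexicographically first affected sequenced member, so
  results are invariant under family-member permutation.
* Unknown-affection relatives are treated as uninformative for
  segregation; an unsequenced parent yields `untestable` de novo status,
  while a single carrying parent refutes de novo even if the other parent
  is unavailable.
* Affected heterozygous females in X-linked genes are emitted but flagged
  low-confidence: the matching rule admits them, yet hemizygous males are
  the expected solution.
* Degenerate inputs: an empty variant file parses to an empty table; an
  empty gene panel is an error (a panel-restricted run with no genes is
  always a misconfiguration); records lacking quality/depth (flat tables
  carry neither) pass QC rather than silently failing it.
* Genotype storage is sparse: an absent call of a sequenced sample means
  homozygous reference; explicit `missing` marks an uncalled genotype.

## Problem sizes

The packaged-table analyses run in well under a second. The default
98-family simulation produces roughly 15,000 variants and 30,000 genotype
rows; generation plus prioritization plus recovery evaluation completes in
a few seconds, and the full test suite — including an end-to-end
simulate/write/read/prioritize/evaluate chain through the VCF route — in
about half a minute.

## Known limitations

No statistical phasing (trans calls need informative relatives), no
structural variants, no mosaicism, no linkage analysis, no annotation
generation (predictor verdicts and consequence classes are consumed as
inputs), no liftover, and no live mutation-database queries (the novelty
catalog is a local file). The burden operation reports per-gene missense
counts per 100 samples against any cohort you supply; no external control
cohort is shipped.
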