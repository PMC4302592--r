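---
title: "Trio-based inference of imprinted X inactivation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based inference of imprinted X inactivation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcitrio)
```

## The inference problem

Female marsupials silence the paternally inherited X chromosome
(imprinted XCI), but silencing is leaky: some loci escape and express
both alleles. Bulk RNA-seq of a single female cannot, by itself, say
*which* parental allele is expressed at a heterozygous SNP. A
mother–father–daughter trio resolves this: the father carries one X, so
his allele at any X site is necessarily the daughter's paternal allele,
and the maternal allele is whatever remains. `xcitrio` implements that
chain of reasoning as a pipeline of small, separately testable stages.

Assumptions worth stating explicitly:

* Sites are biallelic SNPs with strandless read counts; indels and
  multiallelic sites are excluded at ingest (and counted in a skip log).
* The father is hemizygous on every X-assigned scaffold. Apparent
  biallelic expression in his transcriptome at an X site is treated as
  evidence of an X–Y homolog or multicopy artefact, not of diploidy, and
  the site is excluded.
* Parental *genome* evidence outranks parental transcriptome evidence:
  a mother may look homozygous in RNA purely because one allele is
  silenced by her own XCI, which is exactly the bias the DNA evidence
  corrects.
* Allele counts at a phased SNP are treated as a pure fraction; no
  statistical ASE test is performed. The classification rule is the
  fixed threshold described below, chosen for comparability with the
  prior literature rather than power.

## Genotype inference and phasing

For each daughter-covered site the pipeline assembles: the daughter's
expressed alleles (plus her genome alleles when available), the mother's
genotype, and the father's hemizygous allele. The daughter's genotype is
`het_observed` when both alleles are seen; `het_inferred` when she shows
one allele but the parental genotypes force heterozygosity (e.g. mother
homozygous A, father carrying B — the classic monoallelically expressed
heterozygote that single-sample analyses overlook); `hom` when parents
force homozygosity; `unknown` otherwise.

Phase is assigned whenever it is *uniquely* Mendelian-forced. This is
slightly broader than "father allele known": a homozygous mother pins the
maternal allele on her own, so the remaining allele must be paternal
even if the father has no coverage at the site. The unit suite checks
the full truth table — mother genotype × father allele × daughter
expression pattern — against an independently written brute-force
enumerator of Mendelian-consistent assignments, so this decision is
enforced mechanically rather than by convention. Sites where the
daughter expresses an allele neither parent can donate are logged as
Mendelian-inconsistent and excluded, never raised as errors: real call
sets contain genotyping mistakes.

## Classification rules and their parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_coverage` | 5 | reads | per-sample floor at every SNP |
| `neighbor_window` | 20 000 | bp | total intergenic vicinity span |
| `min_hom_neighbors` | 3 | sites | singleton-het removal threshold |
| `father_biallelic_min_reads` | 2 | reads | minor-allele support for an X–Y flag |
| `father_biallelic_min_fraction` | 0.05 | fraction | minor fraction for the same flag |
| `escape_threshold` | 0.10 | fraction | strict minor-allele escape rule |
| `intergenic_cluster_bp` | 1000 | bp | single-linkage locus clustering |

The escape rule is strict: a SNP escapes only when its minor-allele
fraction *exceeds* 0.10, so a 1-in-10 site is still called monoallelic.
The window is interpreted as 20 kb *total* (±10 kb around the SNP); the
alternative ±20 kb reading is a one-line configuration change. The
father-biallelic thresholds are this package's own operationalisation of
"apparent biallelic expression": at least two minor reads and at least a
5% minor fraction, which separates genuine Y-homolog signal from
single-read sequencing noise while remaining configurable.

Loci aggregate SNPs sharing an annotated gene, or intergenic SNPs linked
at ≤ 1 kb. The 1 kb default deliberately keeps nearby intergenic SNPs
~1.3 kb apart as *separate* loci, matching the granularity at which
discordant neighbouring SNPs have been reported. Locus status is the
unanimous SNP status when there is one, otherwise the majority with a
conflict flag; a tie resolves to `escaper` (with the flag), on the
reasoning that credible biallelic expression at any SNP demonstrates
transcription from both X chromosomes. Ambiguous SNPs never vote but
stay attached to the locus for reporting. The locus-level paternal
fraction is read-weighted (total paternal reads over total reads),
consistent with the per-SNP ratio definition. The escaper paternal
average is reported both per SNP and per locus, since published summary
values of this kind are ambiguous about the unit; the per-SNP figure is
the primary one.

`escape_fraction` is computed over decisively classified loci
(ambiguous loci are excluded from the denominator), which reduces to the
plain escaper/total ratio whenever nothing is ambiguous.

## Strata assignment

X-linkage is decided by 1:1 orthology: a gene is X-assigned when its 1:1
orthologue lies on the human X conserved region or the opossum X,
autosomal when it lies elsewhere in human, and unplaced (dropped, with a
log entry) without a 1:1 orthologue. Loci are placed on the stratum
map's coordinate system through a scaffold→offset lookup supplied with
the map — a precomputed stand-in for conserved-synteny anchoring, which
is upstream of this package. A locus that *is* a labelled map gene takes
its own label; any other locus takes `old` or `new` when both nearest
flanking labelled genes agree, `excluded` when they disagree, and
`unassigned` when a flank is missing or unlabelled. The rule is
symmetric in the two flanks, so mirroring the map orientation cannot
change an assignment (property-tested).

## The exact test

`fisher_exact_two_sided()` implements the classical conditional test:
with margins fixed, the first cell is hypergeometric, and the two-sided
p-value sums the point probabilities of all tables no more likely than
the observed one. Two numerical choices matter. First, the
minimum-likelihood comparison uses a relative tolerance of 1e-7, so
floating-point ties at the opposite tail are counted as ties. Second,
probabilities are computed in log space via `dhyper(log = TRUE)` and
summed after recentring on the observed table's log-probability, which
keeps tables with totals in the thousands away from underflow. The test
suite sweeps every 2×2 table with total ≤ 40 against an independent
`choose()`-based enumerator.

The stratum comparison defaults to the observed-vs-expected
construction: row 1 is the stratum's observed escaper split, row 2 the
rounded expected split in a pseudo-group of the same size at the
whole-chromosome escape rate (rounding half away from zero). This is the
construction under which the published opossum old-stratum comparison is
exactly reproducible; the more conventional stratum-vs-rest-of-X table
is available via `construction = "rest_of_x"`.

## What the synthetic generator emulates — and what it does not

`simulate_trio()` draws, per locus: an escape indicator
(`escape_prob`, default 0.32), an escaper paternal fraction from a Beta
distribution with mean 0.46 and concentration 30 (so escapers straddle
the 10% boundary occasionally, exercising the classifier edge), and
per-SNP inheritance — paternal allele uniform, mother homozygous for the
transmitted allele (60%) or heterozygous (40%). Read depths are
negative-binomial (mean 20, size 5, truncated at ≥ 1, matching per-site
coverages of roughly 5–50 in published trio tables); allele splits are
binomial at the true paternal fraction (or at `inactivated_leakage`,
default 0, for silenced loci); a symmetric base error flips reads at
`error_rate` (default 0). Non-informative shared SNPs are injected so
that they make up 68% of all sites, and father-biallelic confounders at
5% of informative SNPs. The mother receives her own imprinted silencing
so the single-sample biallelic-only mode has realistic input. Half the
loci are intergenic. Scaffold count (8) and locus spacing (30 kb) are
fixed once as realistic for a fragmented marsupial assembly; spacing is
deliberately wider than the vicinity window so curation rules never
bridge loci. The daughter has no genome observations by default,
mirroring a design in which only the parents were DNA-sequenced
(`daughter_genome_mean` turns them on).

All randomness flows from one seed. The generator does *not* simulate
reads, mapping or reference bias, base-quality structure, overdispersed
(beta-binomial) allele counts, or linkage between neighbouring loci.
Passing the recovery tests therefore shows the *inference logic* is
correct under the stated sampling model — not that the pipeline is
robust to alignment artefacts, which the father-biallelic and
singleton-het filters only partially emulate.

## Problem sizes and tolerances in the test suite

Parameter-recovery checks run at 500 loci, where the binomial standard
error of the escape fraction is about 0.021; recovery is required within
three standard errors, and the escaper paternal mean within ±0.05.
End-to-end fixtures use 120–200 loci; the exact-test sweep enumerates
all tables with total ≤ 40. These sizes make the inference statistically
sharp while the whole suite stays fast. Degenerate inputs are defined,
not crashed on: empty annotation warns and yields an empty table, a
sample with no biallelic sites warns and reports zero loci, zero-coverage
phased SNPs are an upstream-filter error, and an empty locus set refuses
to summarize.

## Known limitations

* One trio, one tissue per sample: no replicate structure, no
  tissue-specific escape modelling.
* The fixed 10% rule ignores coverage, so low-coverage SNPs classify
  noisily; a beta-binomial test would be the natural extension but is
  intentionally out of scope for comparability.
* Stratum assignment inherits whatever error the supplied synteny
  offsets carry; the package does not infer strata or synteny.
* Autosomal sites are reported only in the skip log; the pipeline's
  scope is the X chromosome.
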