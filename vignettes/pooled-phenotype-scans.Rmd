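---
title: "Pooled-sequencing phenotype-contrast scans: model, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-sequencing phenotype-contrast scans: model, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolkdr)
```

## The design and its statistical model

`poolkdr` analyses pooled-sequencing (pool-seq) data from an insecticide
bioassay that partitions exposed mosquitoes into phenotype groups —
knockdown-resistant (`kdr`), `recovered`, and `dead` — with two biological
replicate pools of 25 diploid individuals per phenotype. Each library's
data reduce to per-site nucleotide counts; the pipeline's entry point is a
sync-style count table (`A:T:C:G:N:del` per library), not reads or
alignments.

The estimator of the alternate-allele frequency at a site is the read
fraction of the principal non-reference nucleotide. Its sampling variance
has two stages:

* **pool stage** — the 2N = 50 chromosomes in a pool of 25 individuals are
  a binomial draw from the phenotype's true allele frequency q, so the
  realized pool frequency has variance q(1 − q)/50 per library;
* **read stage** — reads are a binomial draw from the realized pool
  frequency, adding roughly q(1 − q)/depth.

At the design's typical depth (~240×) the pool stage dominates: with two
replicates summed, the frequency estimate's variance is about
q(1 − q)(1/100 + 1/480), roughly 5.8 times the read-only binomial
variance. This matters for interpreting the scan statistic (below). The
`generate_pool_counts()` generator implements exactly this two-stage
model, and a property test verifies the empirical variance against an
independent Monte-Carlo simulation of it.

## Pipeline stages and their conventions

**Site filters.** A site is kept for a comparison when every one of its
four libraries has coverage within [`min_depth` = 25, `max_depth` = 1000]
and mean base quality at least `min_base_quality` = 30 (Phred). The
exclusion clauses are "fewer than 25 reads" and "coverage > 1000", so
depths of exactly 25 and exactly 1000 are retained; coverage above 1000 is
treated as repetitive DNA and applied per library, since repeat-driven
coverage inflation manifests in each library individually. Sync tables
carry no per-base qualities, so the quality filter operates on the
per-site per-library mean quality the generator emits; when a count set
has no quality channel the filter is treated as satisfied upstream and
this is logged once.

**SNP definition.** The alternate allele is any nucleotide differing from
the reference assembly base. A site enters the scan only if at least one
non-reference nucleotide has a positive count across the comparison's
libraries *and* the site is not fixed for a single allele — a site fixed
for one alternate carries no frequency contrast and is excluded (this is
why loci approaching fixation fall out of such scans). Deletion counts
contribute to coverage but are not alleles; the N column is ignored.

**Replicate screen.** Within each phenotype, a Pearson goodness-of-fit χ²
compares the two replicates' allele counts (2 × k table, alleles with
nonzero totals, no continuity correction — the plainest reading of a
"goodness of fit test"). A site proceeds only when p > 0.05 in *both*
phenotypes, after which replicate counts are summed per phenotype. Two
consequences are worth stating plainly:

* the screen preferentially removes sites where pool-stage noise is
  largest, which is its purpose;
* under its own null it still removes ≈ 1 − 0.95² ≈ 9.8% of perfectly
  well-behaved sites. Any site — including a genuinely associated one —
  enters the association test with probability at most ≈ 0.90. The
  recovery test in this package therefore measures detection among sites
  that enter the test; the unconditional rate is bounded near 0.90 by the
  screen itself, an inherent property of the method, and both rates are
  printed when the test runs.

**Heterogeneity test.** The association statistic is the Pearson χ² on
the full 2 × k phenotype-by-allele table with df = k − 1, where k counts
the distinct alleles present (for biallelic sites this coincides with the
alt-vs-rest collapse). No continuity correction and no exact-test
fallback are applied: the depth floor of 25 keeps expected counts
reasonable. The p-value is the upper χ² tail and is reported as
LOD = −log₁₀(p); for very large statistics the tail is evaluated in log
space, so representable χ² values never produce infinite LODs. Expected
heterozygosity H_exp = 1 − Σ pᵢ² is reported per phenotype and for the
two phenotypes' pooled counts combined ("total heterozygosity").

Because the χ² models read-level binomial sampling only, pool-stage
resampling inflates it by ≈ (1/100 + 1/480)/(1/480) ≈ 5.8 under the
biological null at this design's depth. The statistic is therefore
calibrated with respect to its *own* null — equal read-generating
proportions — and the package's calibration tests run the generator with
`pool_size = Inf`, which skips the pool stage. With finite pools the scan
is anticonservative with respect to the population-level null; this is a
property of the plain heterogeneity χ² on pool-seq data (the reason
model-based pool-seq estimators exist, which are out of scope here), and
users should read genome-wide significance counts accordingly.

**Multiple testing.** Benjamini–Hochberg step-up at α = 0.01, applied to
each chromosome separately. All ties at the cutoff are significant (the
standard step-up convention), and the reported LOD cutoff is −log₁₀ of
the largest significant p, defined only when there is at least one
discovery. The per-chromosome convention makes each chromosome's cutoff a
function of its own p-value distribution, so cutoffs differ across
chromosomes and runs.

**Annotation.** Significant SNPs are classified against GFF3 gene models:
intergenic, 5'/3' UTR, intron, ncRNA, or — inside CDS — synonymous vs
nonsynonymous by locating the codon in the spliced, strand-oriented CDS,
substituting the (strand-complemented) alternate base, and translating
under the standard nuclear code. Codons are numbered from the initiator
methionine, giving residue labels like `V410L`; stop gains carry `*` as
the alternate amino acid (`Q23*`). When a site overlaps several
transcripts, all memberships are recorded and one primary class is chosen
by precedence CDS > UTR > intron > ncRNA > intergenic, breaking ties by
lowest transcript id — feature-class tallies are therefore emitted under
both denominators (primary classes partition the SNP set; per-membership
percentages can sum past 100).

**Categories and selection.** Genes map to resistance categories
(cuticle, detoxification, target_site; everything unmapped is `other`)
through a curated TSV; conflicting duplicate entries are an error. LOD
means per category are compared across the pairwise comparisons with a
one-way fixed-effects ANOVA (groups of fewer than two values are excluded
with a warning). Selection calls compare the alternate frequency between
the resistant-role phenotype (kdr in kdr-vs-recovered and kdr-vs-dead;
recovered in recovered-vs-dead) and its comparator: higher in the
resistant role is `directional`, lower is `purifying`, equal is
`ambiguous`. The favored (higher) frequency is binned low [0, 0.4),
moderate [0.4, 0.8), high [0.8, 1]; the published bin ranges overlap at
0.4 and 0.8, so lower-inclusive/upper-exclusive boundaries were fixed
here, with the last bin closed, and the *favored* phenotype's frequency
was chosen as the binned quantity — both conventions are deliberate
choices where the source description is gene-level prose.

**Genotype contingency analysis.** For one locus genotyped in
individuals, the phenotype × genotype table gets a plain Pearson χ² of
independence (df = (r−1)(c−1); zero-margin rows/columns dropped with a
warning), Pearson residuals (O − E)/√E whose squares sum to the χ²
exactly, and per-phenotype allele frequencies q = (2 n_RR + n_het)/(2N).
A helper reconstructs integer counts from published percentage tables and
verifies each row recovers its sample size. On the V410L table
reconstructed from the published percentages, the package's χ² is the
oracle-verified Pearson value (≈ 151.5); the originally printed 168.8 is
not reproducible from the printed percentages and presumably reflects
slightly different underlying counts, so tests assert oracle agreement
rather than that constant.

## What the generator emulates — and what it does not

`sim_config()` defaults describe the study design the pipeline targets:
3 chromosomes, pools of 25 diploid individuals, 2 replicates per
phenotype, phenotypes kdr/recovered/dead, negative-binomial depth with
mean 240 (the middle of the 196–288× range such libraries achieve; size
parameter 8 gives a modestly heavy tail), per-base miscall rate 0.002
with Phred qualities ~ N(36, 3), 2% of sites flagged repetitive and
emitted with coverage uniform on [1001, 3000], and planted sites
defaulting to frequencies (kdr 0.9, recovered 0.5, dead 0.1) — the
frequency pattern of a strong target-site resistance locus. Null-site
frequencies are uniform on [0.05, 0.95]. All stages derive their RNG
streams deterministically from one master seed, so outputs are
byte-identical for the same seed and stages can be regenerated
independently.

Deliberately not modeled: read-level FASTQ structure, alignment error,
indels and structural variation, linkage disequilibrium between sites
(sites are independent), unequal DNA contributions within a pool, and
selective sweeps. Passing tests on this generator therefore validate the
pipeline's statistics and bookkeeping, not robustness to alignment
artifacts or LD structure in real data.

## Numerical choices and degenerate inputs

* χ² tails via `pchisq(..., lower.tail = FALSE, log.p = TRUE)` where
  underflow threatens; `lod()` itself refuses p = 0 and directs callers
  to the log-space path.
* Alleles absent from both groups are dropped before testing, so no
  expected cell is zero; tables left with fewer than two rows or columns
  are undefined and raise an error (or, in the vectorized scan, yield NA
  and are excluded with the stage tallies recording how many sites were
  tested).
* An undefined replicate test (single replicate or a single allele) is
  treated as a pass: no evidence of discordance.
* Frequencies must sum to 1 within 1e-9 for H_exp; positions are 1-based
  inclusive everywhere on disk (GFF3 convention), and any half-open
  arithmetic stays internal.
* Percent-to-count reconstruction rounds to the nearest integer and
  errors if a row fails to recover its sample size.

## Problem sizes used by the test suite

The suite validates statistics at sizes chosen to make Monte-Carlo error
small while staying comfortably desk-scale: type-I calibration on 10⁴
null sites at depth 240; BH false-discovery proportion over 500 null-
genome runs of 300 sites on 3 chromosomes; parameter recovery over 60
runs of 400 sites with 8 planted effects of |Δq| = 0.4; oracle
equivalence on 10³ random tables at 10⁻⁹ relative tolerance; and
translation-oracle checks over every coding transcript of a 2 × 30 kb
synthetic genome with all three alternate bases at sampled CDS positions,
on both strands, plus an exact strand-symmetry check on the
reverse-complemented genome.

## Known limitations

* The heterogeneity χ² ignores pool-stage sampling; with 25-individual
  pools at depth ≳ 100 it overstates evidence against the
  population-level null by a factor ≈ 5–6 on the χ² scale. The replicate
  screen mitigates but does not remove this. Cross-replicate model-based
  estimators (e.g. CMH-type tests) are the standard remedy and are out of
  scope.
* The replicate screen costs ≈ 10% of all sites under its own null —
  including truly associated ones.
* Annotation assumes the standard nuclear genetic code and ignores
  splice-site disruption, indel effects, and cross-species residue
  renumbering.
* BAM/pileup ingestion is an extension point: the pipeline starts at
  count tables.
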