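# poolkdr

Pool-seq allele-frequency contrast scans for insecticide-resistance
phenotypes.

## The problem

When a pyrethroid-resistant *Aedes aegypti* population is exposed to
insecticide in a bottle bioassay, three phenotypes emerge: mosquitoes that
are never knocked down (knockdown-resistant, *kdr*), mosquitoes that are
knocked down but recover within a few hours off-insecticide (*recovered*),
and mosquitoes that die (*dead*). Sequencing pooled DNA from replicate
pools of each phenotype (pool-seq) lets us estimate per-site allele
frequencies from read counts and ask, genome-wide, which variants
distinguish the phenotypes — candidate loci for target-site resistance
(e.g. the voltage-gated sodium channel), detoxification, and cuticle
mechanisms.

`poolkdr` implements that analysis as a tested, reusable pipeline running
from per-library nucleotide count tables (sync-style text), together with
a synthetic-data generator that emulates the pooled design so every stage
can be validated without raw sequencing data.

## The method

For each pairwise phenotype comparison (e.g. kdr vs dead), with two
replicate pools of 25 diploid individuals per phenotype:

1. **Site filters** — keep sites with coverage in [25, 1000] and mean base
   quality ≥ 30 in every library; coverage > 1000 marks repetitive DNA.
2. **SNP detection** — the alternate allele is any nucleotide differing
   from the reference assembly; sites fixed for a single allele are not
   SNPs.
3. **Replicate screen** — a Pearson goodness-of-fit χ² on the 2 × k
   replicate-by-allele table; a site proceeds only if p > 0.05 in both
   phenotypes.
4. **Heterogeneity test** — with replicates summed per phenotype, the
   Pearson χ² on the 2 × k phenotype-by-allele table with df = k − 1
   (k = number of alleles at the site), transformed to a LOD:

   LOD = −log₁₀(p),  with p = P(χ²₍ₖ₋₁₎ ≥ X²).

   Expected heterozygosity per phenotype is H_exp = 1 − Σᵢ pᵢ².
5. **Significance** — Benjamini–Hochberg step-up at α = 0.01 applied to
   each chromosome separately; the LOD cutoff is −log₁₀ of the largest
   significant p.
6. **Annotation** — each significant SNP is classified (intergenic,
   5'/3' UTR, intron, ncRNA, synonymous, nonsynonymous) against FASTA +
   GFF3 gene models; coding effects are codon-aware and strand-aware with
   residue labels like `V410L`.
7. **Categories and selection** — SNPs map to resistance categories
   (cuticle, detoxification, target_site, other); per-category LOD means
   are compared across comparisons by one-way ANOVA, and each SNP is
   called directional (alternate allele more frequent in the resistant
   phenotype) or purifying, binned low [0, 0.4), moderate [0.4, 0.8), or
   high [0.8, 1].

A separate module analyses individual genotypes at one locus: the
phenotype × genotype Pearson χ², its Pearson residuals
(O − E)/√E, and the allele frequency q = (2 n_RR + n_het)/(2N).

## Worked example

```r
library(poolkdr)

cfg    <- sim_config(seed = 11)          # 3 chromosomes, 2 x 3 pools of 25,
genome <- generate_genome(cfg)           # depth ~ 240x, 20 planted sites
truth  <- sim_truth(genome, cfg)
counts <- generate_pool_counts(truth, cfg)

scan <- pool_scan(counts, c("kdr", "dead"), models = genome)
scan
#> Pool-seq scan: kdr vs dead
#>   sites passing depth/quality filters: 1960
#>   polymorphic: 1960; replicate-consistent: 758; tested: 758
#>   significant (BH per chromosome, alpha = 0.01): 146
#>   per-chromosome LOD cutoffs:
#>     chr1: m = 263, discoveries = 51, LOD cutoff = 2.81
#>     chr2: m = 250, discoveries = 45, LOD cutoff = 2.75
#>     chr3: m = 245, discoveries = 50, LOD cutoff = 2.73
```

2000 simulated sites enter; 1960 survive the depth/quality filters (the
2% repeat-flagged sites exceed coverage 1000 and drop out), the replicate
screen keeps 758, and per-chromosome BH at α = 0.01 declares 146
significant — planted sites with strongly phenotype-dependent frequencies
rank at the top:

```r
sig <- scan$records[scan$records$significant, ]
head(sig[order(-sig$lod), c("pos", "alt_freq_a", "alt_freq_b", "lod")], 3)
#>       pos alt_freq_a alt_freq_b lod
#> 119 46944      0.916     0.0712 179
#> 577 24392      0.913     0.0702 158
#> 361 37378      0.909     0.1173 146
```

Here `alt_freq_a` / `alt_freq_b` are the kdr and dead alternate-allele
frequencies; a LOD of 179 means p ≈ 10⁻¹⁷⁹.

The individual-genotype module reproduces the published V410L analysis
from its per-phenotype genotype percentages (50 individuals each):

```r
gt <- genotype_table_from_percent(
  rbind(kdr = c(90, 10, 0), recovered = c(8, 80, 12), dead = c(0, 36, 64)),
  n_per_phenotype = c(50, 50, 50), locus = "V410L")
allele_freq_from_genotypes(gt)
#>       kdr recovered      dead
#>      0.95      0.48      0.18
round(pearson_residuals(gt), 2)
#>              RR    RS    SS
#> kdr        7.09 -3.49 -3.56
#> recovered -3.05  4.15 -1.87
#> dead      -4.04 -0.65  5.43
```

The positive residuals associate kdr with resistant homozygotes,
recovery with heterozygotes, and death with wild-type homozygotes.

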