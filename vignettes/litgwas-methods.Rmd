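---
title: "Methods: permutation GWAS of gestational age with literature-mined gene-set enrichment"
author: "litgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation GWAS of gestational age with literature-mined gene-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis this package implements

`litgwas` implements an end-to-end association workflow for a continuous,
deliberately case-oversampled phenotype: gestational age at delivery in
days. The design oversamples preterm deliveries by drawing samples from two
day ranges (154–258 and 273–286), which makes the phenotype distribution
bimodal and strongly non-normal. Two consequences drive most of the
methodological choices:

* asymptotic p-values from linear regression cannot be trusted, so every
  association p-value is a **permutation** p-value;
* single-SNP hits are weak and noisy, so the interesting signal is sought
  at the level of **gene-sets** built independently of the genotype data,
  by mining the biomedical literature for genes attached to anatomical and
  pregnancy-related keywords.

The pipeline is: genotype/sample QC → per-SNP association under three
genetic models with adaptive permutations → per-SNP min-p combination →
greedy LD clumping into independent loci → interval-based gene-set
enrichment against SNP-density-matched random intervals. A synthetic-data
module generates genotypes, phenotypes, gene annotation and a labelled
abstract corpus with the statistical structure the analysis assumes, so
every stage can be verified offline.

# Quality control

`run_qc()` applies, in order: sample missingness, SNP missingness,
heterozygosity outliers, relatedness, the Hardy–Weinberg exact test and a
PCA ancestry filter. Entity-level filters run before the statistics that
assume clean data; the order is a package choice and each stage is also
exposed as its own function.

* **Missingness** (default 3% for both samples and SNPs): samples first,
  then SNPs recomputed on the remaining samples.
* **Heterozygosity**: observed autosomal heterozygosity rate per sample;
  outliers beyond mean ± 3 SD removed. If the SD is zero nothing is
  removed.
* **Relatedness**: method-of-moments genome-wide IBD (PI_HAT) from IBS
  counts and population allele frequencies, computed on an LD-thinned SNP
  subset (greedy thinning, r² > 0.2 within 50-SNP windows) and within
  genome-type groups (mother–mother, child–child). For each pair above the
  threshold one random member is removed; the choice is fixed by the seed.
  The default PI_HAT cut of 0.05 separates second cousins (expected
  ≈ 0.031) from third cousins, *assuming genome-scale marker counts*: the
  moments estimator has a sampling SD of roughly `1/sqrt(m)` at `m`
  markers, so desk-scale simulations (hundreds of markers) should use a
  higher cut — the test suite uses 0.4, which any duplicate pair still
  exceeds by a wide margin.
* **HWE exact test**: the exact conditional test summing the probabilities
  of all heterozygote configurations no more probable than the observed
  one, computed with the standard recurrence over heterozygote counts.
  SNPs with p < 1e-6 are removed; monomorphic SNPs get p = 1. The test
  suite checks the recurrence against an independent log-factorial
  enumeration for every genotype table with n ≤ 50.
* **PCA ancestry**: reference and study genotypes are standardised by the
  reference allele frequencies (`(x - 2p)/sqrt(2p(1-p))`, missing calls
  mean-imputed for the decomposition only) and decomposed **jointly**, so
  that a study-specific axis of variation is visible even when the
  reference panel is homogeneous. Study samples whose Euclidean distance
  from the reference centroid in the first three components exceeds 10
  SD of the reference distance distribution are removed. Without a
  reference panel the stage is skipped with a warning.
* **Genomic inflation**: λ = median(χ²)/0.4549 over additive-model 1-df
  statistics at MAF > 0.06.

# Association testing

Each SNP is tested under additive, recessive and dominant codings of the
minor (effect) allele; X-chromosome SNPs under the additive coding only.
The statistic is |t| from simple linear regression of gestational age on
the coded dosage with pairwise deletion of missing calls — the natural
quantitative-trait statistic, and the one whose permutation distribution
the empirical p-values are built from. Codings with zero dosage variance
(e.g. no minor homozygote under the recessive model) are reported as
`skipped-degenerate` and excluded from the min-p combination.

**Permutation scheme.** One replicate permutes the phenotype vector once
and serves every SNP × model test still active — this mirrors the
semantics of the standard adaptive permutation implementation and is what
makes the desk-scale runtime feasible (the per-replicate statistics for
whole batches of tests reduce to one BLAS cross-product). A replicate
counts as an exceedance when the permuted |t| is greater than or equal to
the observed |t|; ties count, and the estimator is `(R + 1)/(N + 1)`, so
the p-value is never anti-conservative under exchangeability and is always
at least `1/(N + 1)`.

**Adaptive stopping.** All tests perform at least `min_perms = 10`
replicates. At checkpoints (the first at `min_perms`, then every
`max(1, ceiling(init + slope * N))` replicates with init = 1 and
slope = 0.001) a two-sided normal interval at confidence `1 - beta`
(beta = 5e-8) is placed around R/N; a test is pruned when the interval
excludes alpha = 5e-8 from below, i.e. only clearly non-significant tests
stop early. Since nothing is ever declared significant early, pruning
affects only how precisely large p-values are resolved. The production cap
is `max_perms = 1e9`; the package desk default is 1e5. The interval
parameters are exposed under explicit names (`prune_interval_init`,
`prune_interval_slope`) because the two conventional single-letter names
are used inconsistently in the field.

**Min-p combination.** Each SNP is assigned the most extreme empirical
p-value across its non-skipped models, uncorrected for the three-way
model choice (the reporting convention this package reproduces); ties
break additive > dominant > recessive so results are deterministic.

# Clumping

Greedy LD clumping collapses correlated neighbouring signals: SNPs with
p < 5e-4 are processed in ascending p (ties by chromosome then position);
each new index SNP collects every unassigned same-chromosome SNP strictly
within 250 kb, with r² with the index strictly above 0.25, and p < 0.05.
Each SNP joins at most one clump — the first-processed index — which keeps
the intervals disjoint for enrichment. r² defaults to maximum-likelihood
haplotype frequencies via EM (50 iterations or log-likelihood change
below 1e-10, r² = D²/(pA qA pB qB)) computed on founders; squared
genotype correlation is available as a fast fallback. Monomorphic pairs
give `NA`, treated as below any threshold. Singleton clumps keep a ±1 kb
span so a degenerate interval remains usable downstream; the original
report is silent on this case and the choice only affects intervals that
carry no members anyway.

# Literature-mined gene-sets

Gene-sets are built from an abstract corpus, not from the genotype data.
For each keyword (12 candidate keywords covering pregnancy conditions,
female anatomy and fetal anatomy; 16 control keywords unrelated to
pregnancy), an abstract matches when it contains a keyword term variant
**and** a genetic-context word (gene, genes, genomic, genetic, GWAS — in
the text or MeSH terms) **and** no non-human indicator **and** no
medical-condition indicator. The condition indicators are generated from a
vocabulary by suffix mining (-osis, -itis, -emia, -oma; words of length
≥ 5, minus an allowlist of non-condition words such as "diagnosis").
Gene mentions are tokens that match an authoritative symbol list
case-sensitively, or all-uppercase tokens matching case-insensitively;
symbols on the acronym blacklist (e.g. SPTB) are dropped when their
forbidden context phrase ("spontaneous preterm birth") co-occurs. Two
final filters reduce false assignment: a gene must be mentioned in more
than one of the keyword's abstracts, and an abstract contributing to a
non-exempt keyword must match no other non-exempt keyword (the very
common keywords and all controls are exempt). The term lists shipped with
the package are curated defaults — editable configuration, not mined
facts; the full original indicator lists are not public, so the package
ships a same-shaped, smaller configuration and treats it as such.

Live literature querying is deliberately out of the tested path: the
corpus interface reads a local JSON-lines snapshot, which keeps the whole
pipeline reproducible.

# Interval enrichment

The top 300 clumps (by index p) become target intervals: intervals
overlapping no gene within a 25 kb flank are dropped, and overlapping
spans are merged (union span, summed SNP counts). The statistic per
gene-set is T, the number of intervals overlapping ≥ 1 set gene at the
25 kb flank; the distinct genes hit are reported alongside. Boundary
touching counts as overlap, so a gene ending exactly 25,000 bp from an
interval is a hit and one at 25,001 bp is not.

The null distribution matches interval structure empirically: each
replicate replaces every target interval with a random interval anchored
at a uniformly chosen SNP of the analyzed map and extended rightward to
cover m' map SNPs with m'/m in 90–110% of the template (SNP-density
matching, the hard criterion); the physical span is a soft band (0.5–2×
by default) that widens stepwise when a template cannot be matched. One
shared replicate serves all sets, and the empirical p is
`(1 + #{T_perm ≥ T_obs})/(1 + n_permutations)`. Random intervals may be
gene-less by default (only *observed* gene-less intervals are dropped,
because they can contribute no hits); a conservative resample-until-
gene-containing mode is one flag away, and an optional second permutation
stage produces FWER-corrected p-values from the per-replicate minimum p
across sets. The production replicate count is 100,000; the desk default
is 10,000.

# The synthetic cohort

`sim_config()`/`simulate_genotypes()` build LD-blocked diploid genotypes
from per-block founder-haplotype pools: each individual haplotype picks a
pool member per block and re-draws it at block boundaries with probability
`recomb_prob`. Small pools give strong within-block r²; pool size,
allele-frequency range and recombination are the LD dials. A coalescent
simulator would model realistic haplotype diversity and allele-frequency
spectra, but tunable block LD is exactly what clumping and enrichment
need, and this model is desk-scale and dependency-free. SNP spacing
within blocks (10 kb) and gaps between blocks (500 kb) are defaults
chosen so that a 250 kb clumping window spans SNPs within a block but
never bridges blocks. Causal SNPs named in `causal_spec` get an exact
founder-pool allele count (clamped to at least one copy of each allele)
so planted loci always segregate.

`simulate_phenotype()` draws latent gestational age as baseline +
model-coded causal effects + Gaussian noise, rounds to integer days
(registry dating granularity), and then **rejection-samples the noise**
until the two sampling ranges hold exactly their configured counts —
reproducing the bimodal case-oversampled design, including its awkward
statistical consequences. Chief among them: the oversampling constraint
attenuates the *marginal* genotype–phenotype association relative to the
latent effect, because samples are forced into day ranges once quotas
tighten. The reference scenario in `planted_cohort_config()` therefore
calibrates its planted effects on the *realized* scale: GA-lowering
effects of −4 (additive), −8 (recessive) and −7 (dominant) days with the
baseline re-centred to 284 days yield loci that each explain roughly 2%
of the realized phenotypic variance at n = 1,000 and 5,000 SNPs. Effects
must lower gestational age in this design: positive effects push latent
values above both sampling ranges and the generator correctly refuses
(`simulation error`) when range targets become unattainable within the
rejection budget (100 draws per sample on average).

Onset (labor/PROM, default 80.7/19.3%) and genome-type (mother/child)
labels are drawn independently from configured proportions; the six
stratified analyses subset on them. The preterm:term sampling ratio is a
free parameter (default an even split), as the original design does not
publish a numeric ratio.

`simulate_annotation_and_corpus()` tiles one gene per LD block (so causal
SNPs fall inside genes by construction), builds an enrichment collection
keyed by the default keyword names — the designated truth set contains
every causal gene, padded with random genes to 8% of the gene count,
while control-analog sets are drawn at 24% of the gene count so that
their null hit distributions are informative rather than degenerate at
desk scale — and writes an abstract corpus with known ground truth,
covering the five trap kinds the mining filters must handle (non-human
indicator, condition indicator, acronym collision, single-mention gene,
multi-keyword abstract), each labelled with its expected fate.

## What the generator does *not* emulate

Realistic human allele-frequency spectra, population structure beyond one
optional shifted cluster, genotyping batch effects, imputation
uncertainty, family structure beyond planted duplicates, and real
literature language (corpus abstracts are templated sentences). Passing
tests therefore demonstrate algorithmic correctness and calibration under
the stated generative assumptions — not performance on real cohort data.

# Numerical choices

* Empirical p-values use +1/+1 smoothing everywhere (validity under
  exchangeability / Monte-Carlo nulls).
* Permutation exceedances compare |r| within a test (monotone in |t| at
  fixed degrees of freedom) with a 1e-12 slack so exact permutation ties
  count as exceedances despite floating-point noise.
* The HWE recurrence and its enumeration oracle both use a 1e-7 relative
  slack when deciding "no more probable than observed", the standard way
  to make float comparisons reproduce exact-arithmetic ties.
* EM for haplotype frequencies starts at linkage equilibrium and stops at
  50 iterations or a log-likelihood change below 1e-10; the test suite
  bounds its r² against an exhaustive grid search.
* Stage seeds derive deterministically from the global seed and the
  stage/stratum label, so strata are independent but every table is
  byte-reproducible; re-running a pipeline configuration reproduces all
  outputs exactly.

# Problem sizes used in the test suite

The suite simulates at desk scale, chosen so each check exercises the
full code path with adequate statistical resolution: HWE enumeration over
all tables with n ≤ 50; permutation calibration with 1,000 independent
null SNPs at n = 300 and 10,000 fixed replicates; clumping against a
brute-force reference on 200 random 30-SNP instances; enrichment against
exhaustive placement enumeration on a 20-SNP toy genome with 100,000
replicates; end-to-end recovery on twenty seeds of the n = 1,000 /
5,000-SNP planted cohort with 10,000 enrichment replicates; association
permutation caps of 5,000 in the end-to-end runs (the smallest cap whose
p-value floor of 2e-4 still resolves the 5e-4 clump-index threshold).

# Known limitations

* The relatedness estimator needs genome-scale marker counts for its
  production threshold, as discussed above.
* The exclusivity filter is per-abstract and per-keyword-pair only; no
  semantic disambiguation is attempted beyond the acronym blacklist.
* Clumping is single-signal per locus: no conditional analysis.
* The enrichment null conditions on SNP density and span, not on gene
  count; the optional gene-containing-null mode brackets the difference.
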