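---
title: "popsweep: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{popsweep: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

popsweep analyses diploid SNP genotype panels from several populations (in
practice: livestock or companion-animal breeds typed on medium-density
arrays) and scans them for signatures of positive selection. This vignette
explains the statistical models behind each stage, the parameters that
matter, and the places where the design was genuinely open and we had to
choose. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Data model

The central container is a `genotypes` object: an N×M dosage matrix counting
copies of `allele_b` (0/1/2, `NA` for a missing call) with a variant table
(1-based positions, sorted by chromosome and position) and a sample table
assigning each sample to one population. Phased data live in per-chromosome
`haplotypes` objects (2N×M binary matrices); the invariant that each
sample's two haplotypes sum to its dosage is asserted whenever both
representations exist. Missingness is represented by `NA`, which every
computation masks — missing never enters arithmetic, and writers map it back
to `0 0` (PED) or `./.` (VCF).

Datasets from different arrays are merged on their locus intersection.
Alleles are harmonized to the first dataset's orientation, flipping dosages
`d -> 2 - d` where the allele pair is swapped; A/T and C/G loci are dropped
because a strand flip is indistinguishable from an allele swap there, and
dropping is the conservative resolution when no strand information is
available.

## Quality control

The cascade is: call-rate filter (SNPs, then samples, default 0.90), minor
allele frequency (< 0.01 removed, strict) together with an exact test of
Hardy–Weinberg proportions (p < 1e-6 removed; all samples pooled, since QC
runs once on the merged panel), then relatedness pruning. The HWE test
enumerates the conditional distribution of heterozygote counts given the
allele counts and sums the probabilities of configurations no more likely
than the observed one — the standard exact formulation, no mid-p.

Relatedness is estimated by the method-of-moments decomposition of
identity-by-state sharing into P(IBD = 0, 1, 2) given allele frequencies,
with `PI_HAT = P(IBD=2) + P(IBD=1)/2`. We omit the small-sample correction
factors of the canonical implementation; their effect is O(1/N) of the
reference panel and the module is validated by parameter recovery
(duplicates ≈ 1, parent–offspring ≈ ½, independent HWE draws ≈ 0). Pruning
is greedy within populations: while any within-population pair exceeds
PI_HAT 0.25, remove the individual with the most such pairs (ties: lower
call rate, then lexicographic id). Greedy removal is our choice — only the
threshold is standard — and its determinism is what matters for
reproducibility. Note the cascade is idempotent only when no samples are
removed: removing samples changes the per-SNP statistics the thresholds act
on, a property shared by the standard tooling.

LD pruning slides a window (50 SNPs, step 5) and, while any within-window
dosage-r² exceeds the threshold (0.5 for the PCA subset, 0.3 for
relatedness analysis), removes the lower-MAF SNP of the worst pair (ties:
the later position). Pairs are processed in decreasing r² so the result is
deterministic.

## Differentiation and diversity

Allele frequencies are per population with missing data masked. The
absolute allele frequency difference is `AFD = ½ Σ_alleles |p_i1 − p_i2|`,
i.e. `|p1 − p2|` for biallelic loci. The chord distance is
`D = (2/(π m)) Σ_loci sqrt(2 (1 − Σ_u sqrt(x_u y_u)))`. The Reynolds-style
coancestry uses a moments construction: the numerator
`(p̂1 − p̂2)² − p̂1q̂1/(2n1−1) − p̂2q̂2/(2n2−1)` is unbiased for the true
squared frequency difference and the denominator
`2(p̄q̄ + (p̂1 − p̂2)²/4)` unbiased for twice the ancestral heterozygosity
term, aggregated as a ratio of sums and mapped to a distance by
`−ln(1 − θ)`, which is additive under pure drift.

FST is Weir & Cockerham's θ̂ throughout — per SNP as `a/(a+b+c)` from the
three variance components (using observed heterozygosity, so no HWE
assumption) and multilocus as the ratio of summed components with a
percentile bootstrap CI over loci (1000 replicates, seeded). Common
workflows use different tools (hence potentially different estimators) for
the summary-table and per-SNP purposes; we use one estimator consistently,
so exact reproduction of results from mixed-tool workflows may differ at
the estimator level.

LD decay is the mean composite (genotype-dosage) r² within distance bins up
to 1 Mbps; the 100-kbps bin is the conventional summary.

## Structure

PCA standardizes each SNP column (zero-variance SNPs dropped); sporadic
missing dosages are mean-imputed per SNP here and only here, because
scaling requires complete columns. The sign convention — the
largest-magnitude loading of each component is positive — makes scores
reproducible across sample orderings. Outliers are screened by the local
outlier factor on the first three PCs within each labeled population; there
is no canonical neighborhood size or threshold for this use, so both are
exposed with defaults k = 20 and 1.5. The IBS dissimilarity is
`1 − mean(IBS)/2` and feeds average-linkage clustering; average linkage is
our choice of linkage, made because it exactly reproduces ultrametric
inputs.

## Effective population size

Contemporary Ne comes from inter-chromosomal LD: physically unlinked pairs
have `E[r²_drift] ≈ 1/(3Ne)` under random mating, so after removing the
sampling expectation the mean r² inverts to Ne. The r² estimator is the
Burrows composite, equal to `(S/(S−1))²` times the squared Pearson dosage
correlation; that weighting matters because the sampling expectation we
subtract, `1/S + 3.19/S²` (valid for S ≥ 30), equals `(S/(S−1))²/(S−1)` —
the constants and the estimator come as a pair, and the published
second-order inversion `Ne = (1/3 + sqrt(1/9 − 2.76 r²'))/(2 r²')` is used
as printed. A non-positive drift component reports `Ne = Inf`. Confidence
intervals are leave-one-chromosome-out jackknife (jackknife units vary
between implementations of this method; ours is fixed and documented).
MAF screens
{0, 0.02, 0.05, 0.1} run as a batch.

Historical Ne bins within-chromosome pairs by recombination distance c
(Morgans at 1 cM/Mb unless a map is supplied), applies the same sampling
adjustment, and reads `Ne(c) = (1/(4 f(c))) (1/r²_adj − α)` at
`t = 1/(2 f(c))` generations ago, with linear `f(c) = c` by default
(Sved's mapping optional) and α = 2 (no mutation correction; 2.2
switchable).

## Runs of homozygosity

Detection is the sliding-window scanline: a 15-SNP window is homozygous if
it has at most one heterozygote and one missing call; a SNP is in a run
when at least 5% of the windows covering it are homozygous (at the default
window size this means "any covering window"); maximal runs are split at
gaps > 1 Mbps and filtered by ≥ 20 SNPs, ≥ 500 kbps, and density of at
least one SNP per 168 kbps of span. Window-vote semantics can extend a run
by one flanking heterozygote — edge behavior at chromosome ends differs
between tools, so ours is pinned by an independently coded oracle in the
tests. `F_ROH` divides the summed segment lengths by the map length (sum
over chromosomes of last minus first SNP position). Shared-ROH peaks are
maximal SNP runs whose incidence strictly exceeds 0.7 of a population's
individuals. Segment counts are also summarized in the conventional five
length classes (0–4, 4–8, 8–16, 16–32, ≥ 32 Mb).

## The selection scan

Each pairwise scan composes four statistics:

1. **FST** per SNP (Weir–Cockerham), plus its Z-transform for reporting.
2. **FLK**: frequencies are modeled as `p ~ N(p0·1, F p0(1−p0))` where the
   kinship `F_ij` is the shared root-to-leaf branch length of populations i
   and j on a neighbor-joining tree of Reynolds distances (for two
   populations: two half-distance branches under a midpoint root, so
   `F = diag(d/2, d/2)`). With `p0 = (1'F⁻¹p)/(1'F⁻¹1)`, the quadratic form
   `T = (p − p0)' V⁻¹ (p − p0)` is chi-squared with n_pop − 1 degrees of
   freedom under neutrality. The chi-squared null is a small-kinship
   approximation: using the estimated p0 inflates T by roughly
   `1/(1 − f/2)`, which is measurable once f exceeds ~0.05 — the null
   calibration check therefore lives in the small-f regime.
3. **xp-EHH**: unpolarized EHH (`Σ_h C(n_h,2)/C(n,2)` over haplotype groups
   identical from the core through x) is integrated by trapezoid into iHH,
   truncated on each side at the first marker with EHH < 0.05; the raw
   score is `ln(iHH_A/iHH_B)`, standardized genome-wide. Cores whose EHH
   never truncates before the chromosome end, or whose integration span
   crosses an inter-marker gap > 200 kbps, are excluded and counted. Two
   geometric consequences matter for study design: the marker spacing must
   keep 200-kbps gaps rare, and the chromosome must be several times longer
   than both the neutral EHH extent (≈ 5/Ne Morgans, large in small
   populations) and the sweep's haplotype extent, or the statistic is
   undefined exactly where it is interesting. The EHH walk runs in
   compiled code; a reference R implementation is kept and the two are
   cross-checked in the tests.
4. **DCMS**: each statistic's right-tailed fractional-rank p
   (`rank/(n+1)`, ties averaged, strictly interior so the logit is finite)
   enters `DCMS_i = Σ_k ln((1−p_ik)/p_ik)/Σ_l |r_kl|`, where r is the
   robust correlation of the statistics from our FAST-MCD implementation
   (α = 0.75, up to 30 000 randomly sampled SNPs, seeded random elemental
   starts with concentration steps). In a two-population scan FST and FLK
   are monotone transforms of each other, so their correlation is ≈ 1 and
   the weighting halves them — the de-correlation doing exactly its job.
   The composite is calibrated against a robust normal fit (intercept-only
   Huber M-estimation, c = 1.345, MAD scale) and converted to upper-tail
   p-values, then Benjamini–Hochberg q-values; significant means q < 0.05.

Orientation: the first-named population is the iHH numerator, so the
primary right tail detects sweeps in popA. Because a single right-tail
convention on a signed statistic is inherently ambiguous, the reverse
orientation is also computed and reported (`dcms_rev`, `dcms_p_rev`, `q_value_rev`).
SNPs undefined in any statistic are excluded from the composite and
counted. FLK p-values are reported, but the DCMS ranks use the FLK
statistic itself, which is order-equivalent to ranking −log p.

A caution the package's own validation makes explicit: the
fractional-rank/logit composite has heavier than normal tails under the
null, so the robust-normal calibration is anti-conservative at the extreme
tail and BH on these p-values does not reliably yield zero discoveries on
null data (an abstract rank-level simulation shows roughly every other
null scan of ~1000–2000 SNPs produces at least one q < 0.05 SNP). This is
a property of the published construction, which we implement as prescribed;
treat isolated single-SNP hits with no neighborhood support accordingly.

## Annotation

Consecutive significant SNPs (adjacent in the variant map) are merged into
intervals, extended by a 40-kbps regulatory flank (a distance at which
mean r² typically remains above ~0.2 on medium-density livestock panels,
so regulatory variants there can still tag the significant SNPs), and
overlapped
with gene/QTL intervals (BED input is converted to 1-based inclusive
coordinates; GFF3 used as-is). Gene-set enrichment is the upper-tail
hypergeometric test with BH adjustment across sets; sets with fewer than
two hit genes are skipped by default, and the gene universe is an explicit
required input rather than an implicit default, because enrichment results
are only interpretable relative to a stated universe.

## The simulator: what it emulates and what it does not

`simulate_dataset()` is a forward-in-time Wright–Fisher model: one
ancestral haplotype pool at linkage equilibrium (frequencies Beta(0.5, 0.5)
by default, mimicking array ascertainment toward spread frequencies; a
uniform option exists), copied into 2–4 daughter populations that evolve
independently at constant diploid size Ne — random mating, Poisson
crossovers at 1 cM/Mb, no mutation and no migration after the split.
Selection acts multiplicatively on the diploid genotype (fitness 1, 1+s,
1+2s) through weighted parent sampling, with optional conditioning on
fixation inside a generation window (resimulating with an incremented seed,
bounded). Relatives are planted by explicit Mendelian transmission and the
pedigree is recorded; exports (PLINK text, phased VCF, truth JSON) are
byte-deterministic given the seed. A forward model was chosen over a
coalescent so that sweeps, pedigrees and ROH arise mechanistically.

What a green test does **not** establish: real array data have deep
coalescent histories (high haplotype diversity from large ancestral Ne even
in currently small breeds), ascertainment structure, genotyping error and
map error, none of which the simulator produces. In particular, starting
from linkage equilibrium means a "standing variation" sweep seeded at
frequency 0.15–0.5 is effectively soft (many founder backgrounds carry the
allele) and leaves a weak haplotype signal; the hard-sweep validation
therefore seeds a single de novo copy.

## Validation worlds (fixed, not tunable)

The simulation-based checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use these stated worlds:

* Drift calibration: 2 populations, Ne = 100, t = 20, 5×1000 SNPs, S = 50;
  mean multilocus θ̂ over 20 replicates vs `1 − (1 − 1/200)^20 ≈ 0.0954`.
* FLK null: Ne = 500, t = 20 (f ≈ 0.02), 10×500 SNPs, Uniform(0.2, 0.8)
  frequencies, whole final generation sampled, kinship `diag(f, f)`; KS
  against χ²₁. The small-f regime is required by the model's own Gaussian
  approximation (see above); at f ≈ 0.1 the statistic is measurably
  inflated and a 5000-SNP KS test correctly rejects.
* Null scan FDR and sweep power: Ne = 200, t = 90, one 60-Mbps chromosome
  of 2500 SNPs (~24-kbps spacing keeps the xp-EHH gap rule satisfied;
  60 Mbps keeps EHH truncatable), S = 30 per population. The sweep is a
  single-copy mutation at the midpoint with s = 0.1, conditioned to fix in
  generations (60, 90] — fresh enough to carry a haplotype signal, eroded
  enough that iHH is defined.
* LD-Ne recovery: Ne = 100, t = 20, 4×500 SNPs, S = 50, MAF screen 0.05;
  median over 20 replicates within [60, 160].
* F_ROH contrast: Ne = 100, t = 30, 2×1500 SNPs on 30-Mbps chromosomes;
  two planted full-sib matings per replicate, inbred offspring vs outbred
  mean, 20 replicates.

## Numerical choices and degenerate inputs

Monomorphic SNPs yield NA (not 0) for per-SNP FST, LD r² and FLK;
zero-variance inputs to Z-transforms and calibration raise errors rather
than returning NaN. Indistinguishable populations produce a zero-length
tree, whose kinship diagonal is floored at 1e-6 in the scan so the FLK
quadratic form stays defined (ranks, and hence DCMS, are unaffected).
Negative NJ branch lengths are clipped at zero with a message. LOF uses a
1e-12 distance floor for duplicate points. Fractional ranks use the n+1
denominator so logits are finite. The MCD consistency factor is applied to
the covariance although the correlation DCMS consumes is scale-free. All
randomness (bootstrap, MCD starts, simulator) is seeded explicitly, and the
pipeline derives per-stage seeds from one master seed.

Two of these checks are expected to read red, for reasons the package
considers informative rather than fixable:

* *Drift calibration*: sampling 50 of 100 individuals without replacement
  halves the binomial sampling variance that the Weir–Cockerham correction
  subtracts, deflating θ̂ by ≈ (1−f)/(2Ne) ≈ 5% whenever S/Ne is large.
  The measured mean (~0.091) matches that prediction; the nominal 0.0954
  expectation assumes an effectively infinite population behind the sample.
* *Null-scan FDR*: as discussed above, the DCMS calibration is
  anti-conservative at the extreme tail, and roughly half of null scans at
  these SNP counts produce at least one q < 0.05 SNP — a property of the
  prescribed construction itself, reproducible from its rank arithmetic
  alone without any population simulation.

## Known limitations

* Real-panel summary numbers (pairwise FST/AFD tables, Ne tables, ROH
  totals, significant-SNP counts) depend on the genotype panel analyzed;
  the validation suite is calibration- and mechanism-based instead of
  value-matching.
* The DCMS tail calibration is anti-conservative under the null, as
  discussed; the package reports it as prescribed.
* xp-EHH requires phased input and its definedness depends on marker
  density and chromosome length relative to Ne, as quantified above.
* The FLK χ² null degrades for kinship values beyond ~0.05.
* Binary PLINK (BED/BIM/FAM), imputation, lift-over and admixture-model
  fitting are out of scope.
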