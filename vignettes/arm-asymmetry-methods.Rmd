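---
title: "Methods: quantifying DICER1-driven miRNA arm asymmetry"
author: "armshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying DICER1-driven miRNA arm asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armshift)
```

## The biological model

Dicer's two RNase III domains cleave opposite strands of the pre-miRNA
hairpin: RNase IIIa releases the 3p arm and RNase IIIb the 5p arm. Recurrent
somatic cancer mutations cluster at the RNase IIIb metal-ion-binding
catalytic residues (E1705, D1709, D1810, E1813), the adjacent G1809, and —
unexpectedly, given the domain division of labor — at S1344 in RNase IIIa,
which sits on the IIIa/IIIb heterodimer interface close to the IIIb active
site. All of these alleles selectively impair 5p-arm processing. The
downstream signatures this package quantifies are therefore:

1. a per-sample depression of 5p-arm relative to 3p-arm miRNA expression;
2. concentration of hotspot genotypes in particular tumor types
   (uterine/endometrial cancers), with most other types devoid of them;
3. a requirement for biallelic DICER1 inactivation (hotspot plus second
   hit) for the strongest phenotype; and
4. derepression of the mRNA targets of the miRNA families whose dominant
   strand is 5p.

## Genotype classification

`classify_sample()` reduces a sample's somatic record to one of `WT`, `VUS`,
`HOTSPOT`, or `HOTSPOT_BIALLELIC`. A hotspot allele is a missense
substitution at a configured residue whose reference amino acid matches the
configuration; a mismatched reference (a transcript-numbering artifact)
warns and does not count. Second hits are truncating mutations (nonsense,
frameshift, splice), a *distinct* second hotspot allele (identical
protein-change strings are deduplicated, guarding against pipeline
duplication; S1344L + S1344T counts), deep deletions, and heterozygous copy
loss. Copy loss is gated behind `use_copy_loss` because targeted panels are
underpowered to call it; deep deletions are eligible in either mode.
Phasing is not attempted: co-occurrence within a sample is the operative
definition of "biallelic", with the usual cis/trans caveat.

Hypermutated samples (POLE-like/MSI-like) are flagged either from metadata
(default) or by a nonsilent mutation-count threshold (default 1000 per
sample; the threshold rule exists as a fallback because a universal numeric
cutoff is not well established). D1699 alterations are *not* in the default
hotspot list: they recur but lack consistent biallelic support.

## Arm quantification and normalization

Annotated mature-arm intervals are widened by a 2 nt flank on each side
before counting, capturing end-heterogeneous reads. The bundled overlap
counter is a deliberately simple demonstration tool (largest-overlap
assignment, ties to 5p); production counts should come from a dedicated
counter and enter via `read_count_matrix()`.

Size factors are median-of-ratios: for arms with positive counts in every
sample, the factor of sample *j* is the median of
\(c_{rj} / (\prod_k c_{rk})^{1/n}\). Factors are rescaled to geometric mean
1; this makes them identifiable, at the cost that a global rescaling of all
libraries changes normalized values by a common constant (ratio statistics,
including m53, are unaffected). If no arm is positive everywhere the
function stops rather than silently switching reference.

Loci with byte-identical mature products (e.g. the three mir-124 genes) are
collapsed by summing member counts; discordant arm structure within a
declared group is an error.

The analysis miRNA set is the union of "broadly expressed" loci — mean over
samples of \(\log_2(\text{locus expression} + 1) \ge 5\), where locus
expression is the *sum of the two arm values* — and "broadly conserved"
loci supplied by the user. Reading the expression filter per locus (rather
than per arm) is a package decision: a hairpin is expressed if it is
processed at all, and a per-arm filter would bias the set toward symmetric
loci, which is exactly what the downstream statistic must not do. The
threshold is inclusive at 5.0.

## The m53 statistic

For sample *i*,
\[ m^i_{53} = \log_2\!\left(\frac{m^i_5}{m^i_3}\right), \]
where \(m^i_5\) and \(m^i_3\) are the medians of normalized 5p-arm and
3p-arm expression over the curated set. Numerical choices that matter:

* Medians are taken over linear-scale normalized values with **no
  pseudocount**. This keeps the statistic exactly invariant to per-sample
  scaling and makes the constructed-matrix identities exact (equal arms
  give 0, doubled 5p gives 1).
* For positive data and odd set sizes, the median of logs equals the log of
  the median, so taking medians before or after the log transform is
  equivalent. For even set sizes the two readings differ slightly (midpoint
  mean of raw values vs. geometric midpoint); this package uses the
  standard midpoint-mean median of linear values.
* A zero median on either arm leaves the score undefined; `m53_score()`
  errors naming the sample, and `m53_cohort()` carries such samples with
  `defined = FALSE` instead of dropping them.

Within-cohort ranking uses dense ascending ranks with shared ranks on ties,
because the phenomenon of interest is "lowest in its tumor type": each
tissue has its own characteristic m53 range, so absolute scores are not
comparable across types.

## Arm differential expression and the strand-shift test

Between two sample groups (normalized jointly), each arm is tested with
Welch's t-test on \(\log_2(\text{normalized}+1)\), and fold change is
reported as \(\log_2((\bar{x}_A + 1)/(\bar{x}_B + 1))\). This is a stated
substitution for a negative-binomial GLM: the inferential target here is
the *direction* of arm-level shifts at FDR 0.01, which the log-scale Welch
test preserves while remaining light and directly oracle-testable
(its null calibration is asserted in the test suite). Arms with zero
variance in both groups get p = 1. Adjustment is Benjamini–Hochberg;
`bh_adjust()` implements the step-up directly and is tested against both
`stats::p.adjust` and a brute-force double loop.

The strand-shift test then asks whether 5p-arm log fold changes are
distributed differently from 3p-arm ones: a two-sided Wilcoxon rank-sum
test using the normal approximation with tie correction, reporting the
direction as the sign of the difference of strand medians. With a genuine
5p-processing defect the 5p distribution separates almost completely from
the 3p distribution, at which point the p-value saturates at the value
fixed by the two group sizes.

## Bootstrap enrichment testing across tumor types

Only tumor types with **more than** `min_cohort_size = 50` eligible samples
are tested; hypermutated samples are excluded from both the pool and the
observed counts in the conservative first pass (`include_hypermutated =
FALSE`), and a second pass retaining them is standard. For each tested type
of size *n*, each of *B* = 10,000 replicates draws *n* samples **with
replacement** from the pooled eligible samples of all tested types and
counts hotspot carriers. The raw p-value is the fraction of replicates
whose count *strictly exceeds* the observed count. Strict inequality makes
p = 0 attainable when the pool rate is degenerate, so the add-one companion
\((r+1)/(B+1)\) is always reported alongside. Bonferroni correction
multiplies by the number of tested types.

With-replacement sampling makes the null count exactly
Binomial(*n*, pool rate), which gives an analytic oracle
(`exact_binomial_tail()`) used to validate the Monte-Carlo machinery to
within three Monte-Carlo standard errors.

Depletion is called from the percentile interval of the null counts
(2.5%/97.5% at the default `alpha_ci = 0.05`): a type is depleted when its
observed count falls below the lower percentile — but only when the null
mean count is at least 5, since percentile intervals on a sparse discrete
null are meaningless. This reproduces the qualitative behavior that
depletion is only callable for very large cohorts.

## Target gene sets

TargetScan-style predictions are filtered to conservation \(\ge 90\)% and
context score strictly below −0.3555 (the constant is the configurable
source of truth for the "strongest ~5% of sites" filter; the conservation
boundary keeps exactly-90). Family sets pool and deduplicate targets across
family members and drop sets below 5 genes.

Enrichment uses a competitive permutation test: observed mean statistic of
the set versus means of random same-size gene draws (without replacement
within a draw) from the statistic universe, with add-one p-values and BH
FDR across sets. This replaces rotation-based inference: the scientific
question — is this set's statistic extreme relative to random sets? — is
answered directly, at the cost of ignoring inter-gene correlation, which a
rotation test partially retains. Planted-signal recovery is judged at the
FDR < 0.15 reporting threshold conventional for this analysis.

## Structure checks

`read_structure()` parses PDB and mmCIF into a uniform atom table (polymer
atoms only), and `residue_min_distance()` reports the minimum Euclidean
distance over selected atom pairs. The default subset is all heavy atoms,
because published proximity figures rarely state an atom convention;
CA-only and side-chain-only modes are exposed for sensitivity checks.
Metal-ion placement by superposition onto a homodimer structure is out of
scope: distances are measured between residues present in the deposited
model only.

## The synthetic-data generator

`simulate_cohort()` draws, per tumor type (a pseudo-tissue), a lognormal
baseline expression profile per locus (meanlog log 200, sdlog 1.0), a
per-locus 5p fraction from Beta(2, 2), lognormal library-size factors
(sdlog 0.3), and negative-binomial counts with dispersion 0.15 — values in
the range typical of bulk small-RNA-seq. The genotype effect is a
**multiplicative deficiency on expected 5p counts only** (`delta_biallelic
= 0.5`, `delta_hotspot = 0.75`, wild type and VUS 1): experimental evidence
indicates the primary defect of these mutants is 5p depletion rather than
3p 'gain', with apparent 3p upregulation attributable to depth
normalization. An optional `compensate` mode rescales each sample to its
pre-deficiency expected depth to emulate that artifact; it is off by
default. The intermediate non-biallelic deficiency mirrors the intermediate
asymmetry of hotspot cases lacking a second hit. Because the deficiency
multiplies every 5p mean by a constant, the expected m53 gap between a
genotype group and wild type is exactly \(\log_2 \delta\) — the basis for
parameter-recovery testing.

`simulate_mutation_table()` plants the genotypes as mutation records:
hotspot missense alleles at the configured residues, biallelic second hits
drawn among truncating mutation / deep deletion / heterozygous loss /
distinct second hotspot allele, non-hotspot DICER1 missense for VUS, and
Poisson background passengers confined to non-DICER1 genes (multiplied
20-fold in hypermutated samples). Passengers are kept out of DICER1 so the
planted genotype is *exactly* recoverable — a deliberate idealization:
real tumors contain DICER1 passengers, and real classification accuracy is
bounded by caller quality, not by this logic. Baseline genotype
frequencies (4% hotspot, 4% biallelic per type) are far above pan-cancer
reality (~0.3%) and are chosen so that cohorts of a few hundred synthetic
samples contain enough carriers to exercise every code path; enrichment
planting multiplies hotspot frequencies 10-fold in designated types.

What the generator does **not** emulate: isomiR-level count structure,
mapping artifacts, tumor purity dilution, correlated miRNA programs within
a tissue, mutational signatures, or subclonal copy number. Passing recovery
tests therefore demonstrates correctness of the statistical machinery under
its own model, not performance on real TCGA data.

## Validation problem sizes

The test suite and the acceptance script run on deliberately compact
cohorts chosen to make every Monte-Carlo tolerance comfortable: m53
recovery at 50 samples per genotype group across deficiency 0.25/0.5/0.75;
bootstrap-versus-exact comparisons at B = 10,000 over four pool geometries;
calibration over 50 generator runs of 6 types x 80 samples at B = 2,000
with Bonferroni familywise control; strand-shift power at 15 mutants vs 50
wild type over 60 loci; gene-set power at a +1 sigma shift on a 50-gene set
in a 2,000-gene universe. Seeds are fixed where a single realization is
asserted and varied where a rate is asserted.

## Known limitations

* The bootstrap pool is pan-cohort sample resampling; alternatives
  (per-dataset pools, burden-conditioned permutations) are not implemented.
* Welch-on-logs loses power relative to a well-specified NB GLM at very
  low counts; conclusions at FDR 0.01 on arms with single-digit counts
  should be treated cautiously.
* The competitive permutation test ignores inter-gene correlation, so its
  p-values are anti-conservative for strongly co-expressed sets.
* `m53` is undefined for samples whose curated-set median is zero on
  either arm; such samples are surfaced, not rescued. With the default
  curation this requires an essentially silent library.
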