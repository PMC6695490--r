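# armshift

Somatic hotspot mutations in the RNase III domains of **DICER1** — the
catalytic residues E1705, D1709, D1810, E1813 of RNase IIIb, the adjacent
G1809, and the RNase IIIa interface residue S1344 — selectively impair the
processing of miRNA **5p arms**, because RNase IIIb cleaves the 5p side of
the pre-miRNA hairpin (and S1344 sits on the IIIa/IIIb interface next to
the IIIb active site). Tumors carrying these alleles, especially with a
biallelic second hit, show a genome-wide depression of 5p relative to 3p
miRNA expression, concentrate in uterine/endometrial cancer types, and
derepress the mRNA targets of 5p-dominant miRNA families.

`armshift` is an R package for the full computational pipeline around this
phenomenon, aimed at cancer genomics analysts working with somatic mutation
tables and small-RNA-seq count matrices:

* **Genotype classification** — per-sample DICER1 status
  (`WT` / `VUS` / `HOTSPOT` / `HOTSPOT_BIALLELIC`) from MAF-style mutation
  tables and GISTIC copy-number calls, with second-hit rules (truncating
  mutation, distinct second hotspot allele, deep deletion, optional
  heterozygous loss) and hypermutation flagging.
* **Arm quantification** — miRBase-dialect GFF3 annotation input, 2 nt
  interval flanking, median-of-ratios normalization, collapsing of loci
  with identical mature products, and curation of the analysis miRNA set
  (broadly expressed ∪ broadly conserved).
* **The m53 score** — per sample `i`,
  `m53(i) = log2(m5(i) / m3(i))`, where `m5`/`m3` are the medians of
  normalized 5p-arm / 3p-arm expression over the curated set; plus
  within-cohort ranking, arm-level differential expression (FDR 0.01) and a
  5p-vs-3p strand-shift rank-sum test.
* **Cohort enrichment** — seeded bootstrap resampling (10,000 replicates,
  cohorts > 50 samples) of hotspot counts per tumor type, with strict-tail
  p-values, Bonferroni correction, and percentile-interval depletion calls.
* **Target gene sets** — TargetScan-style prediction filtering
  (conservation ≥ 90, context score < −0.3555), family-set construction,
  and a competitive permutation enrichment test.
* **Structure checks** — minimum residue–residue heavy-atom distances on
  PDB/mmCIF models (e.g. S1344 against the RNase IIIb catalytic residues).
* **Synthetic cohorts** — seeded generators with ground truth for every
  stage: NB counts with a multiplicative genotype-dependent 5p deficiency,
  mutation tables with planted hotspot enrichment, and shifted gene
  statistics for target sets.

See the methods vignette (`vignettes/arm-asymmetry-methods.Rmd`) for the
statistical details and design decisions.

## Worked example

An end-to-end run on a synthetic two-type cohort with hotspot enrichment
planted in type `TT01`:

```r
library(armshift)

cfg <- sim_config(n_tumor_types = 2, samples_per_type = 80,
                  enriched_types = "TT01", seed = 20)

## classify genotypes from the simulated mutation table
mut   <- simulate_mutation_table(cfg)
calls <- classify_cohort(mut$mutations, mut$cna, mut$metadata)
table(calls$tumor_type, calls$status)
#>        HOTSPOT HOTSPOT_BIALLELIC VUS WT
#>   TT01      14                16   2 48
#>   TT02       4                 7   7 62

## bootstrap enrichment across tumor types
enr <- bootstrap_enrichment(calls, mut$metadata,
                            resampling_config(n_replicates = 10000, seed = 21))
enr[, c("tumor_type", "observed_hotspots", "null_mean", "p_raw", "p_bonferroni")]
#>   tumor_type observed_hotspots null_mean  p_raw p_bonferroni
#> 1       TT01                28      19.5 0.0103       0.0206
#> 2       TT02                11      19.5 0.9863       1.0000

## m53 arm-asymmetry scores on the matched count cohort
co   <- simulate_cohort(cfg)
norm <- normalize_counts(co$counts)
mset <- curate_mirna_set(norm, co$truth$loci$mirna_id[co$truth$loci$conserved])
sc   <- rank_within_cohort(m53_cohort(norm, mset, co$metadata))
sc$genotype <- co$metadata$genotype[match(sc$sample_id, co$metadata$sample_id)]
aggregate(m53 ~ genotype, sc, function(x) round(mean(x), 3))
#>            genotype    m53
#> 1           HOTSPOT -0.691
#> 2 HOTSPOT_BIALLELIC -1.321
#> 3               VUS -0.200
#> 4                WT -0.167
```

Reading the numbers: the planted type `TT01` carries 28 hotspot samples
where resampling expects ~19.5, giving Bonferroni p ≈ 0.02, while `TT02`
is unremarkable. Biallelic hotspot samples sit ~1.15 log2 units below wild
type in m53 — close to `log2(0.5) = -1`, the planted 5p deficiency — and
non-biallelic hotspot samples are intermediate (planted deficiency 0.75,
`log2(0.75) ≈ -0.42`). The lowest-ranked samples within each cohort are
overwhelmingly the biallelic cases.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/armshift.R` (subcommands `simulate`, `classify`, `m53`,
`enrich`, `diffexp`, `structdist`, `run`).

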