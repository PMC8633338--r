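# mhtrace

Screening and pedigree tracing of actionable malignant hyperthermia (MH)
variants.

MH susceptibility is a rare, autosomal-dominant, incompletely penetrant
reaction to volatile anesthetics and succinylcholine, most often caused by
protein-altering variants in *RYR1* (and more rarely *CACNA1S*). Because
exposure is avoidable, pathogenic and likely pathogenic variants in these
genes are reportable incidental findings. `mhtrace` is an R package for the
two analyses that follow from that:

* **Population screening.** Read a multi-sample VCF, restrict to the MH
  gene regions and protein-altering/splice consequences, apply the strict
  rare-variant filter (MAF < 0.1% over called alleles), aggregate
  ClinVar-style submission tallies into actionable / conflicting /
  not-actionable verdicts (majority and strict rules), and report carrier
  frequencies with union-of-carriers semantics — optionally extended by
  imputed dosages.
* **Origin tracing.** For a family segregating one variant: test each
  member's allelic balance with a two-sided exact binomial test (alternate
  reads vs. the heterozygous 50/50 expectation), classify carrier states
  including somatic/germline mosaic candidates, find the haplotype segment
  shared by all carriers in phased parent-of-origin genotypes, detect
  relatives who share the background without the variant, and infer the
  originating individual and mutation mode.
* **Clinical grading.** Score observed clinical indicators on the MH
  clinical grading scale (configurable point table and rank boundaries).
* **Synthetic data.** A gene-dropping simulator (pedigrees, recombining
  phased haplotypes, planted heterozygous/mosaic mutations, read depths,
  cohort VCFs and classification tables) with a ground-truth ledger, so the
  entire pipeline is testable offline.

The core statistic: for alternate read count $k$ of depth $n$, the balance
test p-value is the minimum-likelihood two-sided exact binomial
$p = \sum_{x:\,\Pr(x)\le\Pr(k)} \Pr(x \mid n, \tfrac12)$, which for the
symmetric null equals $\min(1,\, 2\min(F(k), 1-F(k-1)))$. A mosaic with
cell fraction $m$ has expected alternate fraction $m/2$.

## Worked example

Allelic balance and carrier states for the index family's read depths
(reference/alternate reads at the focal *RYR1* variant):

```r
library(mhtrace)

depths <- tibble::tibble(
  individual = c("IV-4", "III-5", "IV-1", "II-5", "II-2"),
  ref_reads  = c(18L, 15L, 14L, 22L, 25L),
  alt_reads  = c(19L, 16L, 15L,  6L,  0L),
  genotype   = c("0/1", "0/1", "0/1", "0/1", "0/0"))
tidy(classify_carrier_state(depths))
#> # A tibble: 5 × 5
#>   individual ratio     n  p_two_sided state
#>   <chr>      <dbl> <int>        <dbl> <chr>
#> 1 IV-4        0.51    37 1            heterozygous
#> 2 III-5       0.52    31 1            heterozygous
#> 3 IV-1        0.52    29 1.000        heterozygous
#> 4 II-5        0.21    28 0.00372      mosaic_candidate
#> 5 II-2        0       25 0.0000000596 non_carrier
```

The proband (IV-4) and the two other descendant carriers are balanced
heterozygotes; the grandmother (II-5) carries the variant on only 6 of 28
reads — her ratio of 0.21 rejects the 50/50 expectation (p ≈ 0.0037) and,
being below the mosaic ratio bound, flags her as a mosaic candidate. From
there `shared_segment()`, `trace_parental_origin()`,
`detect_discordant_sharers()` and `infer_origin()` resolve the family to a
de novo germline mosaic origin in II-5 (see the vignette for the full run).

Carrier frequency with the package's reporting conventions (reciprocal to
the nearest 10, percentage at two significant figures):

```r
tab <- tibble::tibble(chrom = "chr19", pos = 38496455L, ref = "G",
                      alt = "A", carriers = list(sprintf("C%02d", 1:43)))
carrier_report(tab, cohort_size = 62240, merge = TRUE)
#>   n_carriers cohort_size percent one_in_n
#> 1         43       62240   0.069     1450
```

43 carriers among 62,240 sequenced individuals is a carrier frequency of
0.069%, or 1 in 1450. And the clinical grading of the index presentation:

```r
grade_case(c("masseter_spasm", "ck_elevation", "respiratory_acidosis",
             "inappropriate_temperature_increase", "metabolic_acidosis"))
#> <mh_grade> score 70 -> "almost certain"
```

Results carry `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
figures throughout.

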