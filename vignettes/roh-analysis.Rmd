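---
title: "Detecting runs of homozygosity and estimating genomic inbreeding with rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of homozygosity and estimating genomic inbreeding with rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## The model

A run of homozygosity (ROH) is a contiguous stretch of homozygous genotype
calls long enough that identity by state alone is an implausible
explanation; the two haplotypes are then most likely identical by descent.
rohscan detects ROH in medium-density SNP-array data with the
sliding-window procedure that the livestock-genomics literature has
standardised on, and derives from the called segments the genomic
inbreeding coefficient

$$F_{ROH} = \frac{\sum L_{ROH}}{L_{auto}},$$

where the numerator is the summed length of an individual's segments and
$L_{auto}$ is the autosomal length actually covered by the array, computed
as the per-chromosome span between the first and last mapped SNP
(`autosome_span()`). Using the covered span rather than the assembly length
keeps the denominator consistent with what the array can observe.

The companion coefficient $F_{HOM}$ is the method-of-moments
excess-homozygosity estimator over an individual's $m$ non-missing SNPs:

$$F_{HOM} = \frac{O_{hom} - E_{hom}}{m - E_{hom}}, \qquad
E_{hom} = \sum_i \left(1 - 2\hat p_i \hat q_i \tfrac{N_i}{N_i - 1}\right),$$

with $\hat p_i$ the sample allele frequency and $N_i$ the non-missing
allele count at SNP $i$. A one-line description of "the proportion of
homozygotes" does not by itself produce negative values; this estimator
does, whenever observed heterozygosity exceeds Hardy–Weinberg expectation,
which is exactly the sign behaviour reported for real cashmere-goat data.
The finite-sample factor $N/(N-1)$ is on by default and exposed as
`finite_sample_correction` because the constant cannot be pinned down from
a verbal description; both variants differ only at small sample sizes.

## Detection procedure and its parameters

Per individual and chromosome (`detect_roh()`):

1. A window of `window_snps` (default 50) consecutive SNPs slides one SNP
   at a time. A window is *homozygous* if it contains at most
   `max_het_per_window` (1) heterozygous and `max_missing_per_window` (1)
   missing calls — the allowance that keeps a single genotyping error from
   splitting a real run.
2. Each SNP receives the fraction of windows covering it that are
   homozygous; it is *in-run* when that fraction exceeds
   `window_hit_threshold` (0.05). The threshold is not part of the usual
   five published parameter groups, so the conventional default of the
   standard toolchain is adopted and exposed as a parameter. A chromosome
   with fewer SNPs than the window has no windows and yields no runs.
3. Maximal in-run stretches are split wherever consecutive SNPs are more
   than `max_gap_bp` (1 Mb) apart, then trimmed so both ends sit on
   homozygous non-missing calls — reported bounds are always supported by
   observed genotypes.
4. A stretch survives only if it is at least `min_length_bp` (1 Mb) long,
   at least 1 SNP per `min_density_bp_per_snp` (100 kb) dense, and contains
   at least $l$ SNPs, where
   $l = \lceil \ln(\alpha/(n_s n_i)) / \ln(1-\overline{het}) \rceil$
   with $\alpha$ = `fp_alpha` (0.05), $n_s$ SNPs, $n_i$ individuals and
   $\overline{het}$ the panel mean heterozygosity (`lencz_min_snps()`).
   This makes the genome-wide expected count of chance all-homozygous runs
   at most $\alpha$. The realized $l$ and $\overline{het}$ are attached to
   the segment table and logged in the pipeline manifest, since they are
   the analysis' key unreported intermediates. `min_snps_override` pins the
   count for exact replication of a published run.

The 1 Mb minimum length deliberately replaces LD pruning: short homozygous
tracts created by local linkage disequilibrium fall below it, while true
autozygous segments survive. The per-window heterozygote allowance follows
the cited toolchain's semantics; a strict per-segment cap is additionally
available (`segment_het_cap`) but off by default, because published wording
("per ROH") is ambiguous on this point.

Length classes are half-open in Mb — [1,5), [5,10), [10,20), [20,∞) — so a
segment of exactly 5 Mb belongs to 5–10 Mb. Per-chromosome coverage
averages per-individual coverage
($100 \cdot \sum L / (n_i \cdot \mathrm{chr\ length})$); a cohort-total
variant (`per_individual = FALSE`) exists because the usual verbal
definition does not say whether the denominator is per individual.

## Quality control

`apply_qc()` applies, in a fixed documented order: (1) removal of
non-autosomal and unplaced SNPs (chromosome label outside the autosome set,
or position < 1); (2) individuals with missing rate > 0.10; (3) SNPs with
call rate < 0.90; (4) minor allele frequency < 0.05; (5) Hardy–Weinberg
exact-test p < 1e-6. Individuals are filtered before the frequency-based
SNP filters because MAF and HWE depend on the retained individual set; the
order is a package decision, stated here because published methods rarely
fix it. All inequalities are strict exactly as the thresholds are worded.
MAF is computed from non-missing calls only and always lies in [0, 0.5].

The HWE test is the exact conditional test: conditioning on the observed
allele counts, the probability of every compatible heterozygote count is
computed with the stable ratio recurrence, and the two-sided p-value sums
the probabilities no larger than the observed configuration's. At a 1e-6
floor the chi-square approximation is unusable, which is why the exact
test is the field's QC standard. Monomorphic SNPs have a single
configuration and p = 1; all-zero counts are an input error.

## ROH islands

Per-SNP incidence is the fraction of individuals whose called segments
cover the SNP (closed intervals, one count per individual). The island
threshold is the $k$-th largest incidence with
$k = \lceil \mathrm{top\_fraction} \cdot n_{SNP} \rceil$ (default top 1%).
"Top 1% of SNPs" is a count statement, so ties at the cutoff are kept on
the ≥ side rather than split arbitrarily; if every SNP has identical
incidence the threshold is degenerate and a warning says so. Islands are
maximal runs of map-consecutive candidate SNPs with at least
`min_snps = 2` members — singletons are dropped, matching the smallest
islands observed in published tables. No intra-island gap constraint is
imposed (none is ever stated), but each island's largest physical gap is
reported so sparse islands can be audited. Gene annotation assigns a gene
to an island on ≥1 bp overlap of closed intervals, computed with
GenomicRanges; GFF3 input is filtered to `gene` records and identifiers
are taken from `Name`, then `gene_id`, then `ID`.

## The synthetic-data generator

`simulate_panel()` emulates a medium-density array panel: SNP positions
with exponential inter-SNP spacing (mean 40 kb, so a goat-scale ~2.5 Gb
autosome set yields ~60k markers), per-SNP minor allele frequencies uniform
on [0.05, 0.5] (the post-QC range), background genotypes drawn from
Hardy–Weinberg proportions, and per-individual autozygous tracts planted as
founder-allele homozygosity — the founder allele is drawn by population
frequency, so tract SNPs are a frequency-weighted mix of the two homozygote
states, as in real autozygosity, rather than reference homozygosity.
Genotyping errors flip a call to one of the other two states uniformly
(the simplest model that injects heterozygotes into tracts — the failure
mode the window allowance exists for); missingness masks calls at random.
Tract lengths come from the four study length classes with weights
0.50/0.29/0.15/0.06 by default, or uniformly from `tract_length_range_bp`;
the final tract is truncated toward the per-individual target fraction but
never below 2 Mb, so every planted tract stays comfortably callable. The
realized planted fraction `f_true` is recorded per individual as the
overlap of tracts with the SNP-covered span, so recovery is always judged
against what was actually planted.

What the generator does *not* emulate: linkage disequilibrium outside
planted tracts, recombination-map heterogeneity, allele-frequency spectra
shaped by ascertainment, or pedigree structure. Consequently, passing
recovery tests demonstrates that the detector and the inbreeding
estimators are correct implementations of their definitions under the
stated noise models — not that the 1 Mb/50-SNP parameterisation is optimal
for any particular real population, which is an empirical question the
original analyses answer with sensitivity arguments, not simulation.

## Numerical and degenerate-input choices

- SNPs sort by (chromosome, position, snp_id); the id breaks position
  ties deterministically. Chromosome labels stay strings; numeric labels
  order numerically, autosome recognition defaults to goat's 1–29 and is
  configurable.
- Segment length is `end_bp - start_bp + 1` (1-based inclusive, BIM/MAP
  convention); BED output converts to 0-based half-open.
- PED allele labels follow a first-seen rule; hom/het state — the only
  thing any downstream statistic uses — is format-invariant, while the
  A/B labelling of a PED round-trip may swap per SNP.
- A chromosome holding a single SNP contributes 1 bp to $L_{auto}$ (logged).
- `pearson_correlation()` errors on constant vectors;
  `correlation_matrix()` converts that error into an NA row with a warning,
  because a panel without, say, >20 Mb segments is a legitimate analysis
  state, not a failure.
- An individual set whose every SNP is monomorphic makes $m - E_{hom} = 0$;
  $F_{HOM}$ is undefined there and raises a degenerate-input error.
- F_ROH is stored as the sum of its four class components, which both
  equals the direct ratio mathematically and makes the additivity identity
  hold bitwise.

## Problem sizes used by the test-suite and acceptance script

Unit tests run on panels of up to 200 SNPs × 5 individuals against an
exhaustive-interval brute-force oracle (200 random panels in the
acceptance suite, zero tolerated discrepancies), and on simulated panels of
10–60 individuals for property checks. Recovery checks use 100 individuals
× ~20k SNPs (10 chromosomes × 80 Mb at 40 kb spacing) with planted
$F_{true} \in \{0.01, 0.05, 0.15\}$ at zero genotyping error, asking the
mean $F_{ROH}$ to land within ±20% relative error; the Hardy–Weinberg null
panel uses the same dimensions and asks the mean $F_{HOM}$ to sit within
±0.01 of zero. These sizes are the package's chosen balance between
statistical resolution and a test suite that runs in about a minute.

## Known limitations

- The window-hit threshold (0.05) and the $F_{HOM}$ correction constant
  are conventions of the standard toolchain, not published numbers;
  replicating a specific published run exactly may require adjusting them
  (both are exposed as parameters) and pinning `min_snps_override`.
- No LD is simulated, so the generator cannot measure the false-positive
  rate that the 1 Mb length floor is designed to control in real data.
- Sex chromosomes are excluded, not analysed; no imputation, phasing or
  liftover.
- Model-based (HMM) ROH calling and sequence-data ROH are out of scope.
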