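---
title: "Methods: run detection, genomic inbreeding and relationship matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: run detection, genomic inbreeding and relationship matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`runscan` implements the genomic-diversity toolkit used to characterize
small, partially pedigreed livestock populations from medium-density SNP
array data: detection of runs of homozygosity (ROH) and heterozygosity-rich
regions (ROHet), inbreeding estimated from pedigree, from single-SNP
genotypes and from ROH, run islands, three kinds of relationship matrices,
and a sensitivity-sweep engine for the detection parameters. This vignette
is the package's own account of the underlying models, the numerical
choices made where a published description leaves the behavior open, and
what the simulation-based validation does and does not demonstrate.

## Data model

Genotypes are biallelic autosomal SNP calls coded 0/1/2 as copies of a
per-SNP *counted allele*, with `NA` for missing; columns follow a marker
map (chromosome label, 1-based basepair position) sorted by chromosome and
position. When reading PLINK PED/MAP text files the counted allele is the
first allele symbol encountered for that SNP in file order — a
deterministic rule that requires no external allele reference. Every
downstream statistic is invariant to which allele is counted, with one
documented caveat: a written-then-reread panel reproduces the genotype
matrix only up to per-SNP 0/2 relabeling when a SNP's first non-missing
genotype carries zero copies of the counted allele. One write/read round
trip reaches a fixed point: a second round trip is bit-identical.

Run coordinates are 1-based and inclusive at both ends; run length is the
open difference `end_bp - start_bp`, matching the kb lengths reported by
the standard detection tools. BED exports convert to 0-based half-open
intervals.

## Quality control

Filters are applied in a fixed order: non-autosomal and unplaced
chromosomes (labels in a configurable exclusion set, default X, Y, MT, 0),
then SNPs with call rate below 0.95, then samples with strictly more than
15% missing calls (a sample at exactly 15% is retained). No MAF filter is
applied: in a single-population design, rare alleles carry exactly the
homozygosity signal run detection needs. The procedure is idempotent and
its report accounts for every removed SNP and sample.

## Sliding-window ROH detection

The detector scores every window of `window_snps` consecutive SNPs (default
50) as eligible when it contains at most `max_het` heterozygous (default 1)
and `max_missing` missing (default 1) calls. A SNP's *hit rate* is the
eligible fraction of the windows that contain it; near chromosome ends,
where fewer windows exist, the reduced window count is the denominator, so
edge SNPs can still be called. SNPs with hit rate at least
`window_hit_proportion` (default 0.05, inclusive comparison) become
candidates. Maximal candidate stretches are split at inter-SNP gaps wider
than `max_gap_kb` (default 1000) and then partitioned greedily into maximal
pieces that *themselves* contain at most `max_het` and `max_missing`
offending calls; pieces are trimmed to homozygous, non-missing endpoints
and finally filtered by `min_snps` (default 30), `min_length_mb` (default
2) and mean density (`length_kb / n_snps` at most `density_kb_per_snp`,
default 100).

Two points here were genuinely open design choices:

* **Where the het/missing allowance acts.** The standard tool applies the
  allowance at window level only, so an emitted run can in principle
  contain more heterozygous calls than the stated allowance. `runscan`
  additionally enforces the allowance per emitted run. Enforcing it by
  *dropping* violating segments turned out to break a property one wants
  from a sensitivity analysis — relaxing an allowance could then shrink
  the total detected run length, because newly merged candidate stretches
  failed the per-run check that their halves had passed. The greedy
  partition used instead keeps the per-run guarantee without discarding
  coverage. Even so, a larger budget can occasionally re-partition a
  segment so that a remainder falls below `min_snps`/`min_length`;
  strict monotonicity of total run length in the allowances therefore
  holds structurally only for the window-level-only semantics, available
  as `roh_params(window_only = TRUE)`, which is what the sensitivity
  acceptance checks use.
* **Minimum detectable run.** A homozygous tract shorter than the window
  can never be called, because no window fits inside it and windows
  straddling its edge fail eligibility in heterozygous surroundings; edge
  SNPs of a true segment are trimmed until enough covering windows are
  eligible (about two SNPs at the default 50-SNP window and 0.05
  threshold). Detector-sensitivity checks therefore use truth segments
  comfortably longer than the window span.

## Consecutive-method detection

The window-free detector scans each chromosome left to right, extending a
segment until adding the next SNP would exceed `max_opposite`
opposite-state calls (homozygous calls when targeting heterozygosity-rich
regions; default 3), exceed `max_missing` (default 2), or jump a gap wider
than `max_gap_kb` (interpreted as the gap between consecutive SNPs of the
run, whatever their state). The segment is trimmed so both endpoints are
target-state SNPs and emitted if it retains `min_snps` (default 15) and
`min_length_kb` (default 250); scanning restarts at the SNP that caused the
break. ROHet defaults follow the usual heterozygosity-rich-region settings;
with `target = "hom"` the same scanner detects ROH, and with single-SNP
windows and unit hit proportion the sliding-window detector degenerates to
it exactly (a tested equivalence).

## Summaries

ROH are tabulated in seven size classes (2–4 up to >30 Mb) with
left-closed, right-open bins; runs below the first boundary land in an
explicit underflow row. FROH is the summed run length over the autosomal
genome length covered by the panel (`l_auto_mb`), overall and within the
length bins 2–4, 4–8, 8–16 and >16 Mb (left-closed, so the bins partition
the total — the published prose is ambiguous at the boundaries). The
per-SNP in-run frequency is the number of runs covering each position over
the number of animals. Islands are maximal stretches of consecutive SNPs
above a threshold: the empirical 0.999 quantile for ROH (inverse empirical
CDF, `type = 1`, membership `>=` the threshold — a reproducible choice on
discrete frequency data) or a fixed 0.25 for ROHet (strict `>`, following
the usual statement of that rule). Island bounds are the member SNPs'
positions. Stretches separated by even one below-threshold SNP stay
separate.

The length/generation relation uses the exponential model for IBD segment
lengths with mean `1/(2g)` Morgans: `g = 100 / (2 * length_cM)`, so at
1 cM/Mb a 4 Mb run points about 12.5 generations back and a 16 Mb run
about 3.

## Relationship matrices and inbreeding

* **A matrix** — tabular (recursive) method; founders and unknown parents
  are assumed non-inbred and unrelated, which matters in shallow pedigrees
  and is the standard convention. `F = diag(A) - 1`.
* **G matrix** — VanRaden's first method with sample-derived allele
  frequencies; missing genotypes are imputed with the SNP mean (`2p`)
  before centering. Mean imputation replaces haplotype-based imputation
  deliberately: it is dependency-free and, at the under-5% missingness the
  QC step guarantees, its effect on G is negligible.
* **ROH matrix** — the numerator for a pair is the total basepair
  intersection of their runs; the denominator is the population-wide sum
  over maximal constant-carrier intervals of interval length times carrier
  frequency. This normalizer was chosen from an under-specified one-line
  published description because it is dimensionless, symmetric, invariant
  to splitting any run at an interior point, and weights long, shared runs
  proportionally more. A per-pair variant (each pair scaled by the
  frequency-weighted coverage of the intervals either animal carries) is
  available behind `denominator = "pairwise"` for comparison.
* **FIS** — method-of-moments excess homozygosity. The expected
  homozygosity of animal *i* sums `1 - 2 p_j (1 - p_j) n_j/(n_j - 1)` over
  its non-missing SNPs; the `n/(n-1)` correction mirrors the reference
  implementation. Reported HE stays uncorrected (`2pq`), with the
  corrected version exposed as a column.

Coefficient comparisons inner-join animals present in all tables and
report Pearson and Spearman correlation matrices.

## Gene-drop simulator

The simulator exists so that every stage can be validated against known
identity-by-descent structure. Pedigrees follow one of three mating
designs: random within (optionally two weakly connected) herds, a rotating
circular scheme, or repeated full-sib matings, whose expected inbreeding is
known in closed form (F = 0.25 after one sib mating). Founder haplotypes
draw each SNP allele from a frequency uniform in
`[founder_maf_low, founder_maf_high]`; meioses place crossovers as a
Poisson process (Haldane map function, no interference) at `cm_per_mb`
(default 1 cM/Mb, the conventional cattle-scale equivalence), and every
transmitted chromosome is tracked by founder haplotype of origin, so
autozygous segments and the true autozygous fraction are known exactly.
Missingness masks calls first; genotyping errors then flip one allele of a
surviving call, so a masked call is never also an error. Marker positions
are drawn uniformly without replacement, giving the irregular spacing of
real arrays (on a uniform lattice the mean-density filter degenerates into
a step function). Default genome and panel dimensions emulate a
medium-density bovine array: 29 autosomes of 87.6 Mb and about 49,000
SNPs at ~52 kb mean spacing, with per-call error 0.002 and missingness
0.02.

What the simulator does *not* emulate: linkage disequilibrium among
founder haplotypes (founders are in linkage equilibrium), ascertainment
bias of array SNP frequency spectra (the uniform founder spectrum yields
higher average heterozygosity than a real array), selection, or sex
chromosomes. Consequently, passing validation here demonstrates the
correctness of the algorithms and estimators — recovering planted runs,
matching closed-form and Monte-Carlo inbreeding expectations, reproducing
interval arithmetic — not that any particular empirical value from a real
population will be reproduced.

The deterministic `plant_runs()` fixture generator complements the gene
drop: an alternating het/hom background (which cannot contain a run of
either kind by accident), forced homozygous or heterozygous windows with a
stated number of evenly spaced opposite/missing calls, and opposite-state
flanking SNPs so each planted run is exactly maximal.

## Validation strategy and problem sizes

The test suite validates each detector against independent brute-force
re-derivations (explicit window enumeration; naive greedy scans with full
recounting; an exhaustive maximal-segment enumerator on clean fixtures)
across hundreds of randomized planted fixtures; the A matrix against
100,000-replicate single-locus allele drops; G against a double-loop
oracle at 1e-10; FROH against the 0.25 pedigree expectation on error-free
full-sib gene drops (60 offspring, ten 100-Mb chromosomes at 50 kb
spacing, where the mean detected FROH must fall within three standard
errors and the pedigree/FROH correlation above 0.6); and IBD tract
lengths against the exponential model by a Kolmogorov–Smirnov test on a
long (2000 Mb) chromosome with end-censored tracts excluded. Simulation
problem sizes in tests are chosen to make each check statistically
meaningful at interactive runtimes; the acceptance script runs the full
pipeline at study scale (about 240 animals on a 29-chromosome, 49k-SNP
panel).

## Known limitations

* Runs shorter than the sliding window are undetectable by design of the
  window method; use the consecutive detector with `target = "hom"` when
  short runs matter.
* The ROH relationship normalizer is a package-level definition of an
  under-specified published statistic; absolute values are comparable
  within one panel and parameter set only (run-set provenance is checked).
* FIS and G use frequencies from the analysed sample; both are
  sample-dependent statistics and behave accordingly in small panels.
* The pipeline's per-SNP frequency profiles are computed on the QC-passed
  panel; genome regions without markers are invisible to island detection.
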