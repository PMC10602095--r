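---
title: "Cohort analysis of structural variants after joint genotyping"
author: "svcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort analysis of structural variants after joint genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcohort)
```

# The problem

Short-read whole-genome sequencing studies call structural variants (SVs --
deletions, duplications, insertions, inversions, and unresolved breakends)
per sample, merge the per-sample callsets, and joint-genotype the merged
sites across the cohort so that calls are comparable between samples.  What
comes out of that pipeline is not yet analysis-ready: one locus may appear
as several records under different genotyping models, many records are
low-confidence, some lie in genomic regions where short-read signal is
unreliable, and some samples have pathological call counts.  `svcohort`
implements the downstream half of such a study -- everything between the
jointly genotyped VCF and the association results -- together with a
synthetic-cohort generator that reproduces the statistical structure those
stages assume, so the whole pipeline can be exercised and tested without
access-controlled cohort data.

The pipeline stages are:

1. **Ingest and record selection** (`read_sv_vcf()`,
   `select_model_records()`, `prefilter_sites()`): parse the multi-sample
   VCF, resolve multi-model duplicate records, drop breakends and SVs over
   10 Mb.
2. **Quality** (`is_high_quality()`, `load_region_mask()`,
   `flag_problematic()`, `classify_high_confident_insertions()`): per-type
   metric clauses, problematic-region masking, high-confident insertions.
3. **Concordance** (`match_callsets()`, `validation_summary()`,
   `genotype_concordance()`): reciprocal-overlap matching against reference
   callsets and validation arithmetic.
4. **Cohort QC and spectra** (`summarize_sites()`,
   `detect_outlier_samples()`, `sv_pca()`, `spectrum_report()`).
5. **Association** (`eligible_sites()`, `single_variant_test()`,
   `recessive_recode()`, `bh_fdr()`, `ld_scan()`).
6. **Burden and aggregation** (`per_sample_burden()`, `burden_test()`,
   `ultra_rare_set()`, `aggregate_test()`).

# Record selection and prefilters

A graph-based joint genotyper can emit one SV locus under up to three
algorithmic models -- *aggregated*, *breakpoint*, and *coverage* -- as
separate VCF records.  `select_model_records()` keeps one record per
identity key `(chrom, pos, end, svtype)`, preferring aggregated over
breakpoint over coverage (the aggregated model has the highest recall).
The identity key is a package choice: genotypers do not document a
canonical key for model duplicates, and coordinates plus type is the
tightest key that never merges distinct loci.

`prefilter_sites()` removes breakend (BND) records, which carry no resolved
type or span, and any SV longer than 10 Mb (strictly; a 10,000,000 bp
deletion survives).  Insertions of unknown length are never removed by the
size cap, since short reads usually cannot size an insertion.

**Length convention.**  For deletions, duplications and inversions the
package uses the breakpoint distance `svlen = end - pos`.  This matches the
sizes printed in published SV tables (e.g. a deletion at
chr19:1050368--1050973 reported as 605 bp).  Insertions take `|SVLEN|` from
the VCF when present, else 0.

# High-quality clauses

`is_high_quality()` evaluates, with strict comparisons throughout:

* **DEL**: `QD > 12` and (`ABHet > 0.30` or `ABHet < 0`) and
  `AC / NUM_MERGED_SVS < 25` and `PASS_AC > 0` and `PASS_ratio > 0.1`;
* **DUP**: `QD > 5` and `PASS_AC > 0` and `AC / NUM_MERGED_SVS < 25`;
* **INS**, **INV**: `PASS_AC > 0` and `AC / NUM_MERGED_SVS < 25` and
  `PASS_ratio > 0.1` and (`ABHet > 0.25` or `ABHet < 0`) and `MaxAAS > 4`.

`ABHet` is the allele balance of heterozygous calls and is `-1` when a site
has none; the sentinel passes through the `ABHet < 0` arm.  A metric absent
from a record fails its clause -- except `ABHet`, whose absence maps to the
sentinel at parse time.  These rules make the flag a pure function of the
record's metrics, which the test suite exploits as a truth table with every
boundary probed from both sides.

# Problematic regions and high-confident insertions

Masks are read from BED (0-based half-open), unioned and merged once at
load; all coordinate conversion happens in that single place.  A deletion,
duplication or inversion is flagged when its span overlaps a masked
interval by at least 1 bp; an insertion when its breakpoint falls inside
one.  Any-overlap is deliberately conservative -- published methods say SVs
"residing in" such regions are unreliable without fixing an overlap
fraction -- and the flag is advisory rather than a filter.

Deletions, duplications and inversions become "high-confident" only through
orthogonal evidence (alignment inspection, PCR), which is out of scope
here; insertions cannot be inspected that way, so
`classify_high_confident_insertions()` applies the computational rule:
high-quality and not problematic.

# Callset concordance

`match_callsets()` matches per type and chromosome: spanned types by
reciprocal overlap (both overlap fractions at or above the threshold,
default 0.5), insertions by breakpoint distance (default 500 bp,
inclusive).  Assignment is one-to-one and greedy, by descending minimum
reciprocal-overlap fraction (insertions: ascending distance), ties broken
toward the smaller reference start.  The one-to-one rule is a package
choice -- multiplicity handling is rarely stated in publications -- and it
prevents a fragmented caller from inflating recall by matching several
query pieces to one reference site.  The matcher is verified against an
O(n²) brute-force oracle on random callsets.

`validation_summary()` and `genotype_concordance()` are the integer-percent
arithmetic used when reporting wet-lab validation (e.g. 78 confirmed of 95
tested is 82%).

# Cohort QC

`summarize_sites()` derives AC, AN, AF, MAC, missing rate, homozygote
counts and a Hardy-Weinberg p-value per site.  HWE uses the 1-df chi-square
against expectations at the estimated allele frequency -- the conventional
genotype-QC filter -- rather than the exact test; with the package's PCA
threshold of `hwe_p > 1e-5` the difference is immaterial at cohort sample
sizes, and the chi-square is exactly what threshold-style filtering
expects.  Monomorphic sites are given a statistic of 0.

`detect_outlier_samples()` excludes samples with more total calls than
`median + 4*MAD` or fewer high-quality calls than `median - 4*MAD`.  The
MAD is **unscaled** (no 1.4826 factor): the rule is written as a plain
robust range, not as a normal-theory estimator, and the scaled variant is
available via an argument.  The rule is computed jointly over all samples;
computing it within batches would require batch metadata the module does
not assume.

`sv_pca()` follows genotype-PCA convention: restrict to common
(`MAF > 0.01`) sites in HWE (`p > 1e-5`), mean-impute missing dosages,
standardise by `sqrt(2p(1-p))`, and return orthonormal left singular
vectors.

# Association

`eligible_sites()` applies the analysis filter -- missing rate `< 0.5` and
minor allele count `> 5`, both strict.  `single_variant_test()` fits
covariate-adjusted logistic regression (binary traits) or OLS
(quantitative) and reports the Wald test for the genotype term; the
recessive model recodes dosage 2 to 1 and 0/1 to 0 first.  Degenerate
inputs (constant genotype, single phenotype class, separation) produce a
flagged row with `p = NA` and a `note`, never a silent number.

The replacement of a mixed linear model (sparse genetic relationship
matrix) by fixed-effects regression is the package's single largest
methodological substitution.  It is exact under the synthetic cohorts,
which contain no cryptic relatedness, and it is documented rather than
hidden: on real data with related samples the fixed-effects p-values would
be anti-conservative.

`bh_fdr()` is Benjamini-Hochberg step-up (via `p.adjust`), the standard
reading of "FDR" thresholds.  `ld_scan()` computes genotypic r² --
squared Pearson correlation of dosage vectors over pairwise-complete
samples, at least 30 of them -- rather than phased haplotype r²; for
tagging purposes the two agree closely and dosage correlation requires no
phasing step.

# Burden and aggregation

`per_sample_burden()` counts, per sample, carried high-quality sites of a
class (CNV = DEL + DUP, INS, INV, or ALL), with `singleton` (cohort AC
exactly 1 -- note a privately homozygous site has AC = 2 and is excluded)
and `homozygous` (sample is hom-alt) strata.

`burden_test()` regresses status on the count with covariates and reports
the Wald z plus a one-sided empirical p-value under the alternative of
*increased* burden in cases, from `B` phenotype-label permutations with the
add-one estimator `(1 + r)/(1 + B)` (never 0, floor `1/(B+1)`).  Simple
label permutation is the default scheme because the generator draws
covariates independently of genotypes, making it exact there; a residual
permutation scheme would be the conservative choice if covariates were
genotype-correlated.

`aggregate_test()` is a SKAT-O-style statistic: per-variant scores
`S_j = sum_i G_ij (y_i - mu_i)` from the covariate-only null model are
combined as

`Q_rho = (1 - rho) * sum(w_j^2 S_j^2) + rho * (sum(w_j S_j))^2`

over a mixing grid (default `{0, 0.01, 0.04, 0.09, 0.25, 0.5, 1}`; `rho = 0`
is the variance-component SKAT form, `rho = 1` the collapsing burden form).
Rather than the Davies/Liu mixture-of-chi-squares approximations, the null
is calibrated by permutation: each `Q_rho` becomes a permutation p-value,
the statistic is the minimum p over the grid, and the reported p-value
compares that minimum with the same quantity in every permutation (min-p
method).  At the cohort sizes this package targets, a few thousand
permutations are cheap, and the permutation route is exact for the
generator's sampling scheme.  Default weights are the Beta(1, 25) density
at each variant's MAF -- the conventional rare-variant up-weighting; no
published SV analysis this package emulates states its weights, so they
are configurable and the default is a convention, not a reproduction.  Two
algebraic reductions anchor correctness in the tests: a single-variant set
must reproduce the squared-score permutation test, and `rho = 1` with unit
weights must reproduce a collapsed-count permutation test.

# The synthetic cohort generator

The generator's defaults are the study conditions the analyses expect:

* **Type mix**: the per-type shares of a 400,234-site discovery callset
  (57.8% DEL, 11.5% DUP, 29.9% INS, 0.8% INV); breakends default to 0 and
  are given weight only to exercise the prefilter.
* **Sizes**: a two-component log-normal mixture parameterised by its modes
  at 300 bp and 6,000 bp (`sdlog` 0.35) -- the Alu and L1 peaks of a
  short-read SV size spectrum.  The component weights (0.7/0.3) express
  that Alu-scale events dominate; published figures show the 300 bp peak
  clearly taller but print no proportion, so the split is a package choice
  fixed once.
* **Allele frequencies**: a 24% singleton point mass, rare sites
  (AF < 1%, singletons included) totalling 58%, and a log-uniform common
  band up to AF 0.5.  Singletons are realised as exactly one heterozygote
  (AC = 1 semantics); a rare non-singleton site that happens to draw a
  single alternate allele is given a second carrier so the realized
  singleton fraction tracks the configured mass.
* **Genotypes**: `Binomial(2, AF)` per site and sample (Hardy-Weinberg),
  with configurable per-call missingness (default 2%) that never removes a
  singleton's sole carrier.
* **High-quality fraction**: 42% of non-BND sites draw metrics satisfying
  their clause set; failing sites break exactly one clause, chosen among
  those independent of the realized allele count, so the realized fraction
  is binomial around the target.
* **Multi-model duplicates**: 15% of sites are emitted twice under a
  second model tag (no published rate exists; the fraction only needs to
  be large enough to exercise deduplication).
* **Outliers**: 3.5% of samples (the ratio 463/13,371 of excluded to
  retained samples in the study this emulates) receive inflated call
  counts, implemented as extra carriers at common sites so that rare-site
  allele counts, and hence the high-quality clauses, are undisturbed.
* **LD coupling**: SNVs are coupled to an SV on haplotypes -- each of the
  two haplotype alleles is copied with probability `sqrt(r2)` and redrawn
  from the allele frequency otherwise -- then collapsed to dosages, so
  genotypic r² approximates the haplotype target; `r2 = 1` returns
  the SV dosages verbatim.
* **Phenotypes**: binary traits from a logistic model over an intercept,
  covariate effects, a per-CNV burden effect and per-site dosage effects;
  quantitative traits are Gaussian on the same linear predictor.  Case
  ages are "age at onset", control ages "age at last exam", drawn around
  74.6 (SD 10.4) and 77.4 (SD 8.0) years respectively.

What the generator does **not** emulate: read-level evidence, reference
sequence, batch-specific metric shifts (the covariates include generic
center/platform factors but no planted batch effect on metrics), cryptic
relatedness, and ancestry structure beyond what a mean-shift experiment in
the test suite constructs by hand.  Green tests therefore certify the
pipeline's arithmetic and its statistical calibration under clean sampling
assumptions -- not robustness to the confounding structure of real cohort
data.

# Numerical choices and degenerate inputs

* Empirical p-values always use the add-one estimator; permutation streams
  are seeded and reproducible.
* `select_model_records()` breaks model ties toward the earlier record;
  the matcher breaks overlap ties toward the smaller reference start.
* VCF emission formats floating metrics to 4 decimals and writes no
  timestamps, so a fixed seed yields byte-identical files.
* Monomorphic sites: HWE statistic 0; PCA drops them via the MAF filter;
  association flags them as `no_genotype_variance`.
* `sv_pca()` with `k` above the matrix rank warns and returns the rank.
* An all-missing genotype comparison, an empty variant set, zero
  permutations, or a single-class phenotype are errors, not numbers.

# Problem sizes used in the packaged checks

The test suite and the acceptance script run at desk scale, chosen so the
binomial/Monte-Carlo tolerances they assert are comfortably met: cohorts of
a few hundred to 1,500 samples and 800--6,000 sites for pipeline
round-trips; n = 5,000 for effect-recovery and LD-recovery checks; 199--
5,000 permutations per test with 300--500 replicate cohorts for size
calibration.  These sizes are statements about the tolerances, not about
the method: every operation is O(samples x sites) or better and runs
unchanged at cohort scale.

# Known limitations

* The high-quality clauses are those of one graph-genotyper's metric
  vocabulary; callsets lacking those INFO keys will flag almost nothing
  as high-quality (missing metrics fail their clauses by design).
* Fixed-effects association assumes unrelated samples; see above.
* The aggregation test's permutation null refits the covariate-only model
  per permutation -- exact but O(B) model fits; for very large B an
  analytic null would be cheaper.
* The insertion matcher compares single breakpoints, not interval ends;
  published methods do not specify which, and the single-point reading is
  the weaker (more permissive) assumption only when records carry
  interval ends, which insertion records here do not.
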