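---
title: "Designing and evaluating low-density SNP panels from RAD data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating low-density SNP panels from RAD data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpanel)
library(dplyr)
```

## The problem radpanel addresses

Population-genetic monitoring of non-model species -- the motivating case is
brown trout (*Salmo trutta*), monitored for hatchery introgression and
river-scale structure -- has historically relied on microsatellites, which are
hard to standardise across laboratories and cover little of the genome.  A
low-density SNP array (one or two 96-well genotyping plates, roughly 100-200
markers) is a cheap, portable alternative, provided the markers are chosen
well: polymorphic in the lineages of interest, technically genotypeable by
allele-specific PCR (KASP-type) assays, and spread evenly across the genome so
that the panel tags independent genomic blocks.

radpanel implements that design workflow starting from RAD-seq derived
variants anchored on a linkage map, and the statistical evaluation of the
resulting panel.  Everything is tabular: genotypes are a long tibble (one row
per individual x locus call), maps, frequencies and panels are tibbles, and
results chain with the pipe.

## Panel design

### The filter cascade

Candidate loci are reduced in a fixed, order-independent cascade.  Each
filter is a predicate evaluated on the *original* objects, and the candidate
set is the intersection of the per-filter pass sets, so the narrated order
(MAF first, sequence filters second, assay filter last) only affects the
telescoping counts of the report, never the final set.

* **Minor allele frequency.** `filter_by_maf()` keeps a locus iff its pooled
  MAF (over all individuals, both lineages, counted on non-missing gene
  copies) is at least the threshold, default 0.05, boundary inclusive.
  Rare variants are removed both because they are error-enriched and because
  a marker discovered at low frequency in the development sample is unlikely
  to be polymorphic elsewhere.  A tag passes iff every SNP it carries passes.
* **Tag quality.** `filter_rad_tags()` keeps a tag iff it has at most 2
  SNPs, every SNP offset `o` (0-based) satisfies `30 <= o < length - 30`
  (the "first or last 30 bp" windows are excluded; the boundary offset is
  allowed), the sequence has no undetermined `N` base, and the tag is
  anchored on the linkage map.
* **Assay suitability.** `filter_for_assay()` keeps tags with *exactly one*
  SNP lying outside the 50 bp primer design zones at the two extremities --
  the stricter reading in which the target SNP itself must sit in
  `[50, length - 50)`, since a SNP inside a primer zone cannot be assayed
  and a second segregating site anywhere disturbs primer binding.

All windows use 0-based offsets so the arithmetic in the filters and the
export format is unambiguous.

### Even spacing on the linkage map

`select_spaced_markers()` picks an evenly spread panel with a guaranteed
minimum spacing (default 3.5 cM) by a greedy left-to-right scan within each
linkage group: keep the first candidate, then every candidate at least the
minimum distance beyond the last kept one.  Greedy scanning was chosen over
optimal (maximum-count or minimum-variance) placement because it is
deterministic, trivially auditable, attains the stated spacing constraint,
and guarantees that every linkage group with at least one candidate
contributes at least one marker.  Co-located candidates (common on linkage
maps, where many tags share a cM bin) are tie-broken toward higher MAF --
the more informative marker -- then lexicographic id, keeping the whole
design a pure function of its inputs.

`downsample_panel()` (uniform, seeded, removed ids recorded) shrinks a panel
to a plate-friendly size; `append_fixed_markers()` adds externally chosen
ancestry-informative and mitochondrial markers with collision checking; and
`replace_failed_markers()` swaps assay failures for reserves, preferring the
nearest same-linkage-group reserve so map coverage is preserved.  A
replacement that lands closer than the design spacing is *accepted but
logged* as a spacing violation in the provenance -- in a real campaign a
slightly crowded replacement beats a lost marker, but the deviation must be
visible.  `write_panel_export()` emits the KASP-style submission format,
`left-flank[REF/ALT]right-flank`, flanks truncated at tag boundaries.

## Panel evaluation

### Diversity and differentiation

For each site the package reports the Table-style summary: sample size,
multilocus mean observed (`Ho`) and expected (`He = 1 - sum p_j^2`)
heterozygosity with their across-locus SDs, `Fis = 1 - Ho/He` (per locus,
then averaged over polymorphic loci; undefined loci are dropped), allelic
richness, and the site-uniqueness statistic `Fst = 1 - He_site/He_total`
computed as a ratio of multilocus means.  Multilocus means are taken over
polymorphic loci, matching the convention of the field's standard packages;
per-locus `Fis` values are averaged rather than recomputed from rounded
means, which is why a summary table's `Fis` column is generally not exactly
`1 - Ho/He` of its own printed `Ho` and `He`.

Pairwise differentiation uses the Nei-style estimator
`Fst = (Ht - Hs)/Ht`, where `Hs` is the sample-size-weighted mean
within-population expected heterozygosity and `Ht` the expected
heterozygosity of the pooled pair, each *summed over loci before the ratio*
(ratio of sums).  Negative estimates, which arise by sampling noise when
true differentiation is near zero, are reported as computed rather than
clipped, preserving the estimator's symmetry.  Note a structural property of
this estimator: between two demes that have each drifted independently by
`F` from a common ancestor, its expectation is approximately
`(F/2)/(1 - F/2)`, not `F` -- the classic `(K-1)/K` deflation of pairwise
Gst with `K = 2`.  Users comparing against a generative divergence parameter
should expect roughly half its value; a Hudson-type estimator would be
needed to recover `F` itself, and is deliberately not substituted here
because the ratio-of-sums Nei form is what the standard population-genetics
toolchain reports.

Allelic richness uses the rarefaction form
`Ar = sum_j [1 - C(N - c_j, n)/C(N, n)]` per locus (copy counts `c_j`, `N`
non-missing copies, subsample size `n` gene copies), computed with
log-binomial coefficients for numerical safety; `n` defaults to the
smallest copy count across the cells being compared so all sites are on the
same footing, and `n = N` returns the observed allele count exactly.

Haploid mitochondrial markers are carried as homozygous diploid pairs so all
statistics see a single call shape, but contribute exactly one gene copy per
individual to every frequency, and are excluded from `Ho`/`Fis` (a haploid
locus has no observed heterozygosity).

### Outlier scan

`fst_outlier_scan()` flags loci whose global Fst is extreme for their
heterozygosity: loci are split into equal-count bins of total He (default
10), the empirical 2.5% and 97.5% Fst quantiles are taken per bin (95%
envelope by default), and the envelope is linearly interpolated between bin
midpoints.  Equal-count binning keeps the per-bin quantiles equally
reliable across the He range; the scan refuses to run below 50 polymorphic
loci, where the envelope would be noise.  Flagged loci are *not* removed
from any downstream statistic by default -- ancestry-informative outliers
improve assignment, and removal is an analysis decision, not a data fix.

### Informativeness for assignment

Rosenberg's informativeness for assignment is computed per locus as

`In = sum_j ( -pbar_j ln pbar_j + sum_i (p_ij / K) ln p_ij )`

with `pbar_j` the unweighted mean allele frequency across the `K`
populations and the convention `0 ln 0 = 0`.  Natural logarithms are used,
so a locus fixed for opposite alleles in two populations contributes
`ln 2 ~ 0.693`, the statistic's standard normalisation.  The multi-locus
value is the sum over loci, which is what makes the informativeness-versus-
panel-size relation linear and a linear regression `I = a N + b`
meaningful.  `informativeness_curve()` estimates that relation by seeded
random subsampling; `equivalent_marker_count()` inverts the fitted line at a
target informativeness (e.g. that of a reference microsatellite panel) and
returns the *smallest integer* panel size whose prediction reaches the
target -- the ceiling, since a fractional marker cannot be genotyped and the
floor value would fall short of the target by construction.

### Isolation by distance and admixture

`mantel_test()` correlates the lower triangles of a pairwise-Fst matrix and
a riparian distance matrix, permuting site labels of one matrix jointly and
reporting the one-tailed `p = (1 + #{r_perm >= r_obs})/(n_perm + 1)` --
the add-one form that can never report zero.  1000 permutations is the
default.

`supervised_admixture()` is an explicit, labelled stand-in for unsupervised
Bayesian clustering (which needs MCMC machinery out of scope here): with
known reference allele frequencies for the captive-bred and wild pools, each
individual's hatchery ancestry `q` maximises the binomial likelihood
`prod_loci Binom(g | ploidy, q f_cap + (1 - q) f_wild)`.  The log-likelihood
is concave in `q`, so deterministic golden-section search finds the global
maximum; reference frequencies are floored away from 0 and 1 by the
pseudo-count `1/(n_copies + 1)` so a private allele cannot produce an
infinite log-likelihood.  Classification uses the strict rule: captive-bred
iff `q > 0.7`, wild iff `1 - q > 0.7`, otherwise admixed; `q` exactly at
the threshold stays admixed.  The supervised estimator requires reference
samples (it does not discover clusters), and its output records the method
in an attribute so downstream reports cannot mistake it for an unsupervised
fit.  `ancestry_concordance()` compares two `q` vectors by tie-aware
Spearman rank correlation, appropriate because admixture proportions are
strongly bimodal.

## The synthetic-data generators

The generators exist so every stage of the workflow is testable end to end
with known truth; their defaults are fixed study conditions, not tuning
knobs.

* `simulate_linkage_map()`: 40 linkage groups totalling 1453 cM (a salmonid-
  scale map), lengths Dirichlet-split (concentration 5, moderately even).
* `simulate_rad_tags()`: 230 bp tags (two 125 bp paired-end reads minus
  overlap), SNPs placed in the 50 bp-safe interior unless a violation is
  planted; each tag carries labels recording exactly which filter rule it
  was built to violate, giving the filter tests an exact truth oracle.
* `simulate_two_lineage_genotypes()`: Balding-Nichols frequencies
  (`Beta(p(1-F)/F, (1-p)(1-F)/F)` around ancestral `p ~ U(0.05, 0.95)`) per
  population plus a captive lineage; individual genotypes
  `Binomial(2, q f_cap + (1 - q) f_pop)` with per-individual admixture `q`;
  per-call missingness (default 0.01, the "under 1% per individual" regime
  of a successful KASP run); optional planted outlier loci with inflated
  divergence.  The default divergence `F = 0.3` represents a deep
  between-lineage split (wild versus domesticated-other-lineage), which is
  what makes a ~90-locus panel diagnostic for ancestry.
* `simulate_microsatellites()`: 13 loci, 6-10 alleles with fragment-size-like
  ids, per-population Dirichlet perturbation of a base frequency vector.
* `simulate_site_network()`: sites on a 15 km river (a small-basin scale),
  pairwise Fst rising linearly with riparian distance (0.004 per km) plus
  Gaussian noise (sd 0.01) -- a positive control for the Mantel test; zero
  noise gives r = 1 exactly.

What the generators do *not* emulate: linkage between loci (loci are drawn
independently, so the generators cannot probe LD-related properties of
spacing), genotyping error (missingness is the only data pathology),
ascertainment bias in the discovery panel, and coalescent ancestry with
recombination.  Tests passing on these generators therefore certify the
estimators and the design algebra, not robustness to every real-data
pathology.

## Numerical and interface conventions

* All generators and every stochastic analysis step take an explicit
  integer seed and are pure functions of (inputs, config, seed); identical
  seeds give byte-identical outputs.
* Within-tag offsets are 0-based; linkage positions are cM reals.
* The missing sentinel in delimited files is configurable (default `"NA"`);
  VCF uses `.`.  Writers emit a header row and `\n` line endings.
* Frequencies are validated to sum to 1 within 1e-9; distance matrices to
  be symmetric within 1e-9 with a zero diagonal.
* Greedy selection ties, replacement ties and classification boundaries are
  all resolved deterministically (documented above), so no analysis result
  depends on row order or platform.

## Problem sizes used by the test-suite and acceptance script

The shipped tests exercise the workflow at deliberately moderate sizes --
1000 tags for filter truth-label checks, 1000 random candidate maps for the
spacing guarantee, 20 replicates of 50-locus/100-individual pairs for Fst
recovery, 84 individuals at 90 loci for admixture recovery, 50 replicates of
8-site networks for Mantel power -- sizes at which the checked properties
are statistically decisive while the whole suite stays fast enough to run
routinely.

## Known limitations

* The greedy selector guarantees spacing and coverage, not the maximum
  possible marker count; on adversarial candidate layouts an optimal
  selector could place more markers.
* The supervised admixture estimator assumes the two reference pools are
  correctly specified and treats loci as independent; it reports no
  credible intervals.
* The outlier envelope is an empirical-quantile heuristic, not a
  coalescent-calibrated null; it flags candidates for inspection rather
  than testing selection formally.
* Pairwise Fst between two demes underestimates the per-deme drift
  parameter by the factor discussed above; comparisons *between* marker
  sets (the intended use) are unaffected.
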