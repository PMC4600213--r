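---
title: "Detecting runs of homozygosity and selection signatures with rohscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of homozygosity and selection signatures with rohscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscape)
```

## The problem

A run of homozygosity (ROH) is a contiguous chromosomal stretch over which a
diploid individual's genotypes are homozygous, indicating that both haplotypes
descend from a recent common ancestor.  The size and number of ROH summarise
inbreeding and population history, and regions where ROH pile up across
individuals — especially consensus regions homozygous in *every* individual of
a panel — are candidate targets of positive selection.  rohscape implements
the full desk workflow around this idea for small multi-sample panels of
whole-genome genotypes (the motivating datasets are panels of about ten
animals from contrasting populations, e.g. intensively selected breeds versus
feral, naturally selected populations):

1. genotype filtering (`filter_for_roh()`),
2. sliding-window ROH detection at two scales (`scan_all()`),
3. the genomic inbreeding coefficient F~ROH~ (`f_roh()`),
4. private / group-shared / consensus ROH region algebra
   (`private_rohs()`, `shared_private_rohs()`, `consensus_rohs()`),
5. sequencing-error estimation against SNP-array genotypes
   (`cross_classify()`, `array_roh_regions()`, `robust_fp()`),
6. windowed neutrality statistics (`neutrality_scan()`,
   `flag_roh_windows()`), and
7. gene annotation and group-contrast variant reports
   (`genes_in_intervals()`, `group_contrast_variants()`).

A synthetic-panel generator (`sim_config()`, `simulate_panel()`,
`simulate_array()`) provides ground-truthed inputs for every stage.

## The sliding-window scanner

The scanner follows the PLINK 1.07 `--homozyg` window-hit formulation, which
we restate because every later stage depends on its semantics.  For one
sample and one chromosome with sites at positions $p_1 < \dots < p_m$:

1. every window of `window_snps` consecutive sites is marked *passing* iff it
   contains at most `max_het_per_window` heterozygous and
   `max_missing_per_window` missing calls;
2. a SNP is *eligible* iff at least `hit_proportion` of the windows covering
   it pass (at chromosome ends the denominator is the number of windows that
   exist);
3. maximal runs of eligible SNPs are trimmed so that their first and last SNP
   are homozygous non-missing calls — reported heterozygote/missing counts
   are therefore interior, and edge heterozygotes never inflate a segment;
4. a trimmed candidate is kept if it has at least `min_snps_per_segment`
   SNPs, is *strictly* longer than `min_length_bp`, contains no inter-SNP
   gap above `max_gap_bp`, and has average spacing at most
   `max_density_kb_per_snp`.

Coordinates are 1-based inclusive at the first/last SNP of the run, with
`length_bp = end - start + 1`; BED exports convert to 0-based half-open at
the system boundary only (`segments_to_bed()`).

Defaults are PLINK 1.07's (`hit_proportion` 0.05, `max_gap_bp` 1000 kb,
`max_density_kb_per_snp` 50) with the two canonical scales exposed as
`scan_settings(50, min_length_bp = 40000)` and
`scan_settings(500, min_length_bp = 400000)`.  Two deliberate choices:

* **Strict minimum length.** "Longer than 40 kb" is implemented as a strict
  inequality at the bp level (a 40,000-bp run fails; 40,001 passes);
  `strict_min_length = FALSE` switches to `>=` for users who read the
  threshold inclusively.
* **Density units.** A per-SNP-spacing value of 0.8 is sometimes quoted for
  dense sequence panels (the panel-wide mean spacing of a ~11M-SNP horse
  genome is ~0.2 kb/SNP, so 0.8 kb/SNP rejects segments supported by
  unusually sparse cover).  We do not make 0.8 the default because it is
  stricter than any other constraint and silently discards legitimate
  segments of moderate density — for example a fully homozygous stretch of
  600 SNPs over 500 kb (0.83 kb/SNP).  The PLINK default of 50 kb/SNP is
  kept; users reproducing the strict-spacing analysis can set
  `max_density_kb_per_snp = 0.8` explicitly.

A consequence of the window-hit rule worth knowing: raising the heterozygote
allowance can *merge* adjacent segments, so the segment count is not
monotone in that parameter — but the covered position set is.  Conversely,
raising `min_length_bp` can only remove segments.

## ROH set algebra

Private, shared and consensus regions are computed on *positions of
homozygous variants inside ROH segments*, not on segment intervals:

* the position set of a sample is every panel site that lies inside one of
  its segments and carries a homozygous non-missing call;
* *private* positions of a sample are those found in no other sample's set;
  *shared-private* positions of a group are in every in-group set and no
  out-group set; *consensus* is the intersection across all samples;
* surviving positions are regrouped into maximal runs that break wherever an
  intervening panel SNP is *not* in the surviving set, so an individual ROH
  can contribute several "parts"; a single surviving SNP yields a degenerate
  interval of length 1 bp;
* intervals span the first to last supporting SNP, and `n_snps` counts the
  supporting positions.

Matching is by position only by default — two samples homozygous for
*different* alleles at a site still share that position.  This is the
appropriate reading when array data lack allele orientation and when
consensus regions are defined on homozygosity rather than allele identity;
`roh_position_sets(..., allele_aware = TRUE)` restricts matching to the same
homozygous class.  No minimum-length re-filtering is applied after
intersection: short shared fragments (down to one SNP) are real outputs of
this algebra and are reported as such.

F~ROH~ divides the summed segment lengths of a sample by the length of the
genome covered by the SNP set.  That denominator is a property of the
dataset, not of the sample — for the motivating horse panel it is
2,242,879,462 bp — and is configurable everywhere; when absent it defaults
to the summed per-chromosome spans of the panel's sites.

## Array-versus-sequence concordance

With array genotypes treated as the truth set, a *false negative* is an
array heterozygote called homozygous from sequence (the dominant error mode
of moderate-coverage sequencing) and a *false positive* is an array
homozygote called heterozygous.  All published-style rates use the number of
positions called on both platforms as the denominator: that is the
convention under which the motivating study's printed percentages reproduce
exactly (e.g. 12,867 / 49,813 = 25.83 %), although a prose reading of
"rate of false negatives" might suggest dividing by array heterozygotes
instead; both numerators and the margins are returned so either rate can be
formed.  The *robust* false-positive rate restricts attention to long array
ROH (by default detected with 20-SNP windows, zero heterozygotes, two
missing calls, 1 Mb minimum, 50 kb/SNP density, then filtered to regions
strictly above 10 Mb), where the true genotype can be assumed homozygous
throughout, so every heterozygous sequence call inside is an error.  Both
thresholds (1 Mb detection, 10 Mb selection) are exposed because they play
different roles.

## Neutrality statistics

For each non-overlapping window (40 kb and 400 kb are the canonical sizes;
`step_bp` allows overlapping slides) the per-site derived-allele counts are
tallied treating each diploid genotype as two chromosomes and the reference
allele as ancestral — no outgroup is available, so reference-ancestral is an
assumption, and `folded = TRUE` provides the fallback that computes only the
folding-invariant quantities (θ~π~, θ~W~, Tajima's D).  From the spectrum we
compute θ~π~, θ~W~, θ~L~, θ~H~ and the tests: Tajima's D, Fu & Li's D and F
(singleton-based, with the corrected variance constants), and the normalized
Fay & Wu's H and Zeng's E (variances per the standard high-frequency-variant
parameterization, with θ estimated by S/a₁ and θ² by S(S−1)/(a₁²+a₂)).

Missing data are handled by reducing each site's chromosome count to the
number of called chromosomes: the theta estimators are sums of per-site
unbiased terms (a site with n′ called chromosomes contributes
2k(n′−k)/(n′(n′−1)) to θ~π~, 1/a₁(n′) to θ~W~, and so on), sites with fewer
than four called chromosomes are skipped, and the variance normalizations
use the window's `n_chromosomes` (twice the number of samples with data).
On complete data this reduces exactly to the classical fixed-n formulas,
which is where the implementation is checked against an independently coded
enumeration.  Statistics are `NA` with `defined = FALSE` when S = 0, when
n < 4, or when a variance term is non-positive; when θ~π~ equals θ~W~
exactly, D is exactly 0.  All statistics are invariant to sample order.

These are hard-call statistics.  The motivating study computed them from
genotype likelihoods (ANGSD); replicating likelihood-based estimation is out
of scope, and on low-coverage data hard calls will understate heterozygosity
(see the false-negative rates above), which inflates homozygosity-based
signals.  The flagging rule for sweep candidates is deliberately simple:
windows overlapping a consensus ROH by at least 1 bp whose Tajima's D is
*strictly* below −1.2.

## The synthetic-panel generator

`simulate_panel()` emulates the features of a sequenced multi-sample panel
that the pipeline is sensitive to, with every parameter surfaced in
`sim_config()` rather than hard-coded:

* SNP positions are a Poisson process along each chromosome
  (`snp_density`, default 5 SNPs/kb ≈ one SNP per 0.2 kb, the density of
  the motivating trimmed SNP set);
* outside planted tracts each call is heterozygous with a per-sample rate
  (default 0.25; the motivating panel's per-sample heterozygosities span
  0.21–0.29) and otherwise homozygous, reference or alternate with equal
  probability;
* planted autozygous tracts (sample-private, group-shared or panel-wide)
  force homozygosity over their span, with the homozygous class drawn per
  site and *shared by all members of a tract* — a consensus tract is a
  shared haplotype, so its sites must not segregate between members (this is
  what makes in-tract windows show S ≈ 0);
* per-call depths are Poisson (mean 18; the motivating coverages span
  6–35×) and per-site qualities uniform on 30–90, so that default filters
  pass almost everything and filter tests can plant violations explicitly;
* missingness is applied last, independently per call (default 0.02);
* `simulate_array()` retains a uniform fraction of sites, treats the array
  as error-free, and injects discordance into the *sequence* calls:
  heterozygote undercalling at rate `array_discord_fn` (default 0.78 — in
  the motivating BeadChip comparison 12,867 of 16,426 array heterozygotes
  were sequence-homozygous) and spurious heterozygotes at
  `array_discord_fp` (default 6e-4, matching the published ~19/33,403
  structure).  Every injection is logged, so recovered error rates can be
  compared against exact ground truth.

What the generator does **not** emulate: linkage disequilibrium outside
planted tracts, coalescent genealogies, recombination, allele-frequency
spectra of real populations, reference bias, or depth-correlated genotype
error.  Passing tests on synthetic panels therefore demonstrates the
*algorithmic* correctness of detection, algebra and rate estimation — that
planted truth is recovered — not that biological panels will show any
particular ROH landscape.  Background genotypes are exchangeable across
sites, which makes the neutrality background D ≈ +1.4 (binomial allele
counts are mid-frequency-heavy); the in-tract versus out-of-tract *contrast*
is the meaningful signal.

Determinism: the same `sim_config()` (including its `seed`) reproduces
panels and written fixtures byte-identically.

## Numerical and edge-case choices

* Genotypes are coded 0/1/2/NA (alternate-allele dosage); phased and
  unphased heterozygotes collapse to the same class.
* `filter_for_roh()` applies mean-depth and quality at the site level and
  the depth bounds at the call level, so the retained site set is identical
  across samples; calls failing depth bounds become missing.  Filtering is
  idempotent, sites with unknown quality are kept, and an emptied panel is
  an explicit error.
* A chromosome with fewer sites than the window yields no windows and no
  segments — not an error.
* Windows with undefined statistics carry `NA` plus a `defined` flag rather
  than sentinel numbers.
* Duplicate VCF positions keep the first record and warn; unknown samples
  in a group mapping are errors, not warnings.
* Size classes partition segments as small ≤ 59 kb < medium < 400 kb ≤
  large, with both bounds configurable.

## Problem sizes used by the shipped checks

The test-suite and `scripts/acceptance.R` exercise the pipeline at sizes
chosen to make brute-force verification exact and fast: scanner equivalence
against an exhaustive-window oracle on hundreds of random panels of up to
500 SNPs; set algebra against a position-by-position oracle on instances of
up to 100 positions and 5 samples; neutrality statistics against enumeration
of *all* spectra with n ≤ 8 and S ≤ 12; and end-to-end recovery on
simulated genomes of ~24 Mb with planted tracts drawn log-uniformly between
40 kb and 10 Mb, where detected segments achieve better than 99 % aggregate
reciprocal overlap with the planted truth and F~ROH~ errors below 0.001.
Tract boundaries are recovered only to within roughly the span of one
window (the hit-proportion rule lets eligibility leak a few kb past a
boundary before trimming), so per-tract reciprocal overlap approaches 1 for
megabase tracts but is structurally below ~0.9 for tracts near the 40-kb
minimum; recovery is therefore assessed length-aggregated.

## Known limitations

* Hard genotype calls only; no genotype-likelihood machinery.
* Reference-ancestral polarisation for the unfolded statistics.
* The set algebra is position-based and sensitive to missing calls: a
  missing call removes a position from a sample's set and can split shared
  intervals.  This is faithful to the definition ("intersection of
  homozygous variants") but means consensus intervals fragment as
  missingness grows.
* No LD pruning, no haplotype phasing, no IBD probability modelling, no
  enrichment analysis; impact labels and deleteriousness scores are consumed
  from upstream annotation, never computed.
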