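---
title: "Charting the mutational landscape of a peptide-hormone precursor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charting the mutational landscape of a peptide-hormone precursor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Prohormone genes such as proglucagon (*GCG*) encode a single precursor that
is cleaved, tissue-specifically, into several mature peptides — for
preproglucagon: a 20-residue signal peptide, GRPP, glucagon, IP-1, GLP-1,
IP-2 and GLP-2, with the composite products glicentin, oxyntomodulin and the
major proglucagon fragment. Population sequencing now covers hundreds of
thousands of individuals, so even a 180-residue precursor carries a rich
spectrum of rare missense variation. The questions this package addresses
are: which variants exist across cohorts and at what frequency; how much of
the theoretically possible missense space they cover; how the variation is
distributed over the precursor's peptides; which peptides are under
evolutionary constraint; and which substitutions are predicted to
destabilize the peptide's receptor complex.

`pepscape` implements that workflow generically for any precursor gene:
cohort aggregation, saturation enumeration, peptide mapping, conservation
scoring, per-peptide statistics, and stability classification, plus seeded
generators that simulate every input with known ground truth.

# Cohort aggregation

Each cohort is a set of N diploid individuals; a variant observed on `ac`
alleles out of `an` (typically 2N) has cohort allele frequency `ac/an`.
Variants are keyed by `(pos, ref, alt)` after left-normalization of
alleles; merging cohorts takes, per variant, the **maximum** per-cohort AF
(a deliberate choice that is robust to one cohort's depleted frequency for
a variant it barely sampled), the **sharing class** (number of carrying
cohorts), and a **singleton** flag.

Two singleton conventions exist. Within one cohort a singleton is a
variant seen on exactly one allele. At the merged level we define a
singleton as *observed on exactly one allele in exactly one cohort and
absent from all others*; `merge_cohorts(singleton_rule = "per_cohort")`
gives the laxer alternative. The stricter rule is the default because a
variant present in two cohorts is by definition carried by at least two
individuals and calling it a singleton would misstate its population
frequency. A singleton in a cohort of N individuals sits at AF `1/(2N)` —
about `10^-5.4` for a 132,345-genome cohort — which is the detection floor
of this kind of analysis.

When a source table reports AF without allele counts, `ac` is
back-computed as `round(af * 2N)` so singleton status can still be
called; the tiny rounding this introduces is below any AF the tables
print. No liftover is performed: inputs must share one genome build or be
expressed in CDS coordinates (an explicit exon map converts genomic
coordinates, reverse-complementing on the minus strand).

# Saturation enumeration

For a CDS of L sense codons there are exactly `9L` possible
single-nucleotide substitutions (three alternative bases at each of `3L`
positions). `enumerate_possible_missense()` translates each mutated codon
and partitions the events into missense, synonymous and stop-gain — a
conservation law (`missense + synonymous + stop_gain = 9L`) that the test
suite asserts on random sequences. Two conventions matter:

* The terminal stop codon is excluded from the scan by default (the scan
  counts amino-acid substitutions, and stop-loss is not missense);
  `include_stop_codon = TRUE` restores it for sensitivity analysis.
* Substitutions in the start codon count as missense in the enumeration,
  while the *variant annotation* filter excludes start-lost records —
  enumeration describes the mutational space, annotation mirrors how
  cohort missense sets are curated.

Distinct SNVs in one codon can encode the same amino-acid substitution, so
the unique-substitution count is at most the event count. Per-peptide
variant counts use nucleotide-level uniqueness, matching how cohort union
counts are reported.

# Peptide architecture and dual numbering

A `precursor_annotation` partitions the precursor into non-overlapping
primary regions (signal, peptides, spacers) plus composite views. Dibasic
cleavage residues (e.g. the KR pair following GRPP) belong to no peptide:
leaving them out keeps per-peptide statistics from double-counting
boundary residues; variants there are reported as `linker`. Variant labels
carry dual numbering — `R70H^glucagon,18` is precursor residue 70 and
glucagon residue 18 — with GLP-1 numbered from GLP-1(1–37) (precursor 92 =
GLP-1 position 1), the convention used for precursor-wide work; the
therapeutic (7–36) numbering is a display alternative. Composite regions
(glicentin, oxyntomodulin, MPGF) are derived views and never enter
statistical contrasts.

The bundled fixture (`gcg_annotation()`, `make_fixture()`) is a
**synthetic** preproglucagon-like precursor: the region coordinates follow
the UniProt molecule-processing convention for P01275 (signal 1–20, GRPP
21–50, glucagon 53–81, IP-1 84–89, GLP-1 92–128, IP-2 131–142, GLP-2
146–178) and the mature-peptide stretches use well-characterized
sequences, but the file is a constructed stand-in, labelled synthetic,
not a reference record. Its reverse-translated CDS (most common human
codon per residue) translates back exactly and yields 1224 possible
missense events — close to, but not identical with, the count of the real
transcript, which depends on real codon usage.

# Conservation scoring

Orthologue sets are first filtered on three Ensembl-style quality metrics
(Gene Order Conservation ≥ 50, Whole Genome Alignment coverage ≥ 50,
percent identity ≥ 25; boundary-inclusive). The built-in per-site rate
estimator is deliberately tree-free: sequences receive Henikoff
position-based weights so clusters of near-identical orthologues do not
dominate, and a column's raw rate is the weighted fraction of non-gap
residues differing from the weighted consensus. Gaps are excluded from
the diversity count; columns with more than half gaps are flagged
low-confidence; invariant columns take the alignment's minimum rate;
all-gap columns are missing. Tree-based empirical-Bayes rates are a
different estimator with different units — `read_external_rates()` ingests
such per-site scores for exact reproduction of externally computed
traces, and the built-in estimator is for self-contained and simulated
analyses. On simulated alignments (gamma-law site rates, single-branch
Poisson substitution) the estimator recovers the truth at Spearman ≈ 0.98
with the default 100 sequences × 200 sites.

Normalization is z-scoring to mean 0, sd 1 (population denominator), so
lower = more conserved. A second convention pins the most conserved
position at −1; the two are mutually inconsistent in general, so both are
exposed (`mode = "z"`, the default, and `mode = "min_neg1"`) rather than
silently blended.

The smoothed trace convolves the scores with a discrete Gaussian kernel
(sigma = 1 residue by default, truncated at 4σ and renormalized) under
reflect boundary handling, and the 50% band is `smoothed ± 0.6745 × local
sd`, the local sd being computed under the same kernel weights. A
constant trace passes through unchanged, an impulse reproduces the
kernel, and a ramp is unchanged away from the edges — all asserted in the
tests.

# Per-peptide statistics

Deleteriousness tracks (CADD-like PHRED scores, PrimateAI-like [0,1]
scores) are per-variant quantities; conservation scores are per-position
quantities. Contrasts against a reference peptide (glucagon by default)
therefore use per-variant units for score metrics and per-position units
for conservation, and both modes are available where the distinction is
debatable.

The Mann–Whitney test enumerates all assignments exactly for pooled sizes
up to 12 (handling ties exactly) and otherwise uses the tie-corrected
normal approximation with continuity correction; the two-sided exact p is
the probability of a U at least as far from its null mean as observed,
which on tie-free data equals twice the smaller one-sided p (capped at 1).
Two-sided is the default since published "p ≤" figures rarely state
sidedness. No multiple-testing correction is applied by default — the
contrasts are descriptive, per the estimation-statistics style — with Holm
adjustment available.

The estimation-statistics contrast reports `mean(b) − mean(a)` exactly,
with a percentile bootstrap interval (5000 resamples by default, matching
common estimation-tool defaults; BCa available). Given a seed the
resampling is bit-for-bit reproducible; interval coverage for a planted
shift of 0.5 at n = 50 per group measures ≈ 95% over seeded replicates.

# Stability classification

Replicate free-energy scans (10 independent runs per substitution, the
convention for stochastic rotamer searches) are aggregated as mean ±
sample sd. Categories follow the 0.46/0.92/1.84 kcal/mol ladder; the
"neutral (−0.46 to −0.46)" phrasing found in some write-ups is read as
the symmetric (−0.46, +0.46) band, and a `highly_stabilizing` bin below
−1.84 completes the mirror symmetry its thresholds imply. Boundary
policy: the top bin is strict (`> +1.84`), so exactly +1.84 is
destabilizing; interior positive boundaries assign to the more
destabilizing bin and negative boundaries mirror this. The bins partition
the real line and classification is monotone — both property-tested.
Hotspots are substitutions strictly above +1.84. The force-field
evaluation itself is out of scope: replicate tables are ingested, and the
alanine-scan comparison outer-joins natural variants, alanine
substitutions and literature fold-changes per position, flagging
positions where variant and alanine effects sit on opposite sides of
neutral.

# What the generators emulate — and what they do not

`simulate_cohorts()` draws a union of distinct missense SNVs from the
transcript's enumerated space, marks ≈ 47% as singletons (the observed
share in large multi-cohort landscapes), assigns the rest to random
non-empty cohort subsets, and draws non-singleton AFs log-uniformly over
10^−5.5..10^−2.5 — reproducing the singleton-dominated AF spectrum and
the sharing-class structure. It does **not** model linkage, demography,
selection or sequencing error; recovery tests on it validate pipeline
arithmetic, not population-genetic realism. `simulate_msa()` uses a
star-phylogeny Poisson model — adequate for rank-recovery of site rates,
not for tree inference. `simulate_scores()` couples two Gaussian tracks
at a target Pearson of 0.65 (monotone mapping to the CADD/PrimateAI
scales shrinks the realized correlation by a few percent — the probit map
alone by a factor ≈ 0.977). `simulate_ddg()` adds Gaussian run noise to
known true means. One global seed fans out to per-stage substreams
(`derive_seed()`), so any stage can be regenerated alone; all derived
seeds stay below 2^31.

Default problem sizes (184-variant unions, 100 × 200 alignments, 1000
substitutions for recovery studies, 300–500 bootstrap-coverage
replicates, 1000 random CDSs for the conservation-law sweep) were chosen
as the package's own benchmark scale: large enough for stable estimates,
small enough to iterate on routinely.

# Degenerate inputs and numerical choices

Zero-variance inputs error in `normalize_scores()` and `pearson()` (a
constant track carries no signal); empty samples error in
`mann_whitney()`; a single replicate run reports sd 0; `ac = 0` rows are
dropped on read; AF/ac/an inconsistencies beyond 1e−12 (relative 1e−9)
are rejected; malformed rows are reported with their line numbers;
mixed coordinate systems refuse to merge. Bootstrap intervals use type-7
quantiles. Exact Mann–Whitney comparisons use an epsilon of 1e−9 when
comparing rank statistics to avoid floating-point boundary effects.

# Known limitations

* The built-in rate estimator is not an empirical-Bayes tree method;
  absolute rates are not comparable to tree-based scores (use the adapter
  for those), only the profile shape and ranks are.
* The merged-level singleton rule is a composition choice; per-cohort
  counting is available but changes singleton totals.
* Variant identity assumes a shared genome build; no liftover.
* The stability module ingests, never computes, free energies.
* Reproducing published headline numbers for a real gene requires the
  corresponding cohort extracts, score tables, per-site rates and the
  canonical CDS, which are not redistributable with the package; the
  formats expected under `inst/extdata/external/` are documented there.
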