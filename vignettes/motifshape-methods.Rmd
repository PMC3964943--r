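---
title: "Methods: DNA shape profiles and shape-augmented specificity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA shape profiles and shape-augmented specificity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifshape)
```

## The shape model

`motifshape` predicts four DNA structural features from sequence by
table lookup over sliding pentamers. The premise is that the local
conformation of a base pair (minor groove width, propeller twist) or of a
base-pair step (roll, helix twist) is determined, to a good approximation,
by its two flanking base pairs on either side — i.e. by the 5-mer centred on
it. A structural query table assigns each of the 512 reverse-complement
classes of pentamers one MGW value (Å) and one ProT value (°) for the
centre base pair, and two Roll and two HelT values (°) for the two central
steps.

Three conventions complete the model, and all three are forced by strand
symmetry:

* **Canonicalization.** A pentamer and its reverse complement describe the
  same double-stranded molecule, so lookups go through the canonical key
  (the lexicographic minimum of the pair). No odd-length DNA word is its
  own reverse complement, hence exactly 1024/2 = 512 classes.
* **Step assignment.** The window centred at position *i* supplies MGW and
  ProT at *i* (strand-invariant quantities) and contributes its two
  central-step values to the steps (*i*−1, *i*) and (*i*, *i*+1). When the
  lookup used the reverse-complement key, the two step values are swapped
  before assignment, because the pentamer read on the other strand
  traverses the same two physical steps in the opposite order. A step
  covered by two overlapping windows stores the mean of the two
  contributions. The upstream method does not document how overlapping
  windows combine; plain averaging is our choice, and it is the only
  symmetric combination we found under which prediction commutes exactly
  with reverse complementation (a property the test suite checks on 10,000
  random sequences).
* **Missingness.** Positions without a full pentamer window carry explicit
  `NA`, never sentinel values: an unflanked sequence of length *L* has
  *L*−4 defined base-pair positions (two undefined at each end) and its
  terminal steps undefined. This is why 2-bp flanks are needed to cover an
  entire core motif, and why unflanked heat maps show white margins.

Ambiguous bases (`N`) are a hard error by default; a lenient mode
(`na_action = "mask"`) instead marks every window touching the `N` as
missing. Coordinates are 0-based relative to the core start: flanks occupy
negative positions, and step features sit at half-integer midpoints
(*j* + 0.5) so base-pair and step tracks share one axis.

**Symmetrization.** For palindromic cores (e.g. the E-box CACGTG) the two
strands are equivalent descriptions of the same site, and profiles are
symmetrized by averaging each track with its mirror image about the core
centre (half-integer centres are allowed). Missing values propagate as the
mean of the available values; the operation is idempotent.

## Dataset assembly

**Case-annotated FASTA.** Records carry the core in upper case and flanks
in lower case; exactly one contiguous upper-case run is required, and
violating records are rejected individually with diagnostics rather than
failing the file. The retention rule computes the fraction *q* of records
with ≥ 2 bp of flank on *both* sides (both, because only then is the whole
core predictable). If *q* > 0.5, unflanked records are dropped and the rest
trimmed to exactly 2-bp flanks; otherwise (including *q* = 0.5 exactly) all
records are kept and flanks are stripped. Flanks longer than 2 bp are
trimmed rather than kept so that all assembled matrices are rectangular;
over-long flank retention would be the only other defensible choice and is
recorded here as the road not taken.

**PBM probes.** Motif occurrences are called by scanning both strands of
every probe with a log-odds PWM and thresholding the *exact* p-value of the
window score at 10⁻³ (the conventional occurrence-calling level for probe
data). The p-value map is computed by dynamic programming: PWM entries are
rounded to a fixed grid (default 1/1000 bit) and the exact distribution of
the discretized score of a random W-mer under the background model is built
by positional convolution. Observed window scores are computed *with the
same rounded matrix*, so p-value lookups are self-consistent, and the map
equals brute-force enumeration over all 4^W W-mers exactly — the test suite
and the acceptance script verify this for widths up to 8. The background is
0-order uniform by default and configurable; p-values are per-strand with
no two-strand correction, since occurrences serve as units of assembly
rather than hypothesis tests. The assembly pipeline then (1) optionally
removes probes with two or more occurrences, (2) optionally keeps the top
fraction of remaining probes by signal intensity (the customary choice for
genomic-context PBM data is 0.25; intensity ties at the cutoff are kept),
and (3) extracts each occurrence with 2-bp flanks, reverse-complementing
minus-strand sites into motif orientation; sites too close to a probe end
are dropped. Every stage records its count in the dataset's provenance.

## Profile analysis

Heat-map rows (per-sequence profiles) are clustered agglomeratively with
distances defined as the Euclidean distance between rows. The linkage
criterion is not fixed by convention; the default is average linkage, with
single and complete available, and the choice is recorded in the result.
Rows with missing cells use pairwise-complete ED rescaled by
√(n_total/n_complete), which keeps distances on the scale of complete rows.
Clustering is skipped (input order returned, with a notice) above 3000 rows,
mirroring the practical cap for interactive heat maps. For *n* ≤ 12 the
merge tree is verified in tests against a naive O(n³) agglomeration written
independently of `stats::hclust`.

Two average profiles are compared, after an integer alignment offset chosen
by the user, by Pearson's correlation coefficient and the Euclidean
distance over the overlapping defined positions (at least 2 required).
Per-position distributional differences between two datasets use the
two-sample two-sided Kolmogorov–Smirnov test: asymptotic p-values, exact
when the combined sample size is ≤ 25, with positions categorised at
p < 0.001 (strong) and p < 0.05 (weak); positions with fewer than 8 values
per group are reported untested. The null calibration of this pipeline is
measured in the acceptance suite: over 1000 replicate pairs of 200-vs-200
null samples the 0.05-level rejection rate must fall in 5 % ± 2 %. The 200
per group size is chosen because the asymptotic K-S distribution is
well-calibrated there; at much smaller samples the asymptotic test is
conservative, which is why the implementation switches to exact p-values
for small groups.

Factor-level dendrograms are built from pairwise EDs between average MGW
profiles with the same linkage options. The Newick serialization places
branch lengths so that the depth of each internal node above its leaves
equals its merge height (an `hclust`-to-phylo conversion that halves heights
would not honour the stated output contract, so the package serializes the
merge table directly). Ties are broken deterministically by factor label.

## Specificity models

Binding intensity (natural log by default, the standard transform for
fluorescence signals) is regressed on feature blocks:

* `seq_mononucleotide` — 4 indicator columns per position, flanks included.
  No reference level is dropped: with ridge regularization the collinear
  parameterization is well-posed and simplest.
* `core_variant` — one indicator per observed core sequence variant, with
  the most frequent variant as the reference. This captures within-core
  interdependencies beyond independent positions without inventing explicit
  interaction terms.
* `shape_MGW`, `shape_ProT`, `shape_Roll`, `shape_HelT` — raw per-position
  (bp) or per-step values. Sites with missing shape values in a requested
  block are excluded and counted.

All columns are standardized; constant columns are dropped and recorded.
The model is ridge regression (glmnet, α = 0) with an outer 10-fold
cross-validation whose fold assignment is a seeded permutation, and the
penalty chosen on each training split by inner 5-fold cross-validation over
a log-spaced grid (10⁻³…10³, 13 points) — the penalty-selection protocol is
our choice, as is reporting the held-out coefficient of determination as
the primary R² with squared Pearson correlation alongside, since "R²" is
ambiguous between the two in common usage. Everything is deterministic
given the seed.

The **shuffled-shape control** permutes each shape column independently
across sites (sequence columns untouched) and refits. The permutation
preserves every column's marginal distribution while destroying its linkage
to the sites, so any accuracy gain that survives shuffling would indicate
overfitting to column count rather than shape signal.

## What the generators emulate — and what they do not

* `simulate_pentamer_table()` draws values uniformly within physically
  plausible ranges (MGW 2.8–6.2 Å, ProT −18–0°, Roll −8–10°,
  HelT 30–40°). It preserves the *structure* of a real query table —
  canonical keys, per-feature layout, strand conventions — but not the
  sequence–structure correlations of tables derived from molecular
  simulation: neighbouring pentamers are uncorrelated here. Tests passing
  on synthetic tables validate the engine's bookkeeping, not the physics.
* `simulate_jaspar_sites()` emulates motif-database FASTA with variable
  flank availability: a fraction ⌈f·n⌉ of records carries ≥ 2-bp flanks on
  both sides, the rest 0–1 bp, so the retention rule's behaviour is known
  in advance. Cores are a consensus with independent per-position
  mutations, without the positional dependence structure of curated sites.
* `simulate_pbm_experiment()` plants consensus occurrences (one site in
  half the probes, two sites in 10 % by default, ≥ 2-bp probe flanks
  always) in random 36-bp probes — the length order of universal PBM
  probes — and assigns log-normal intensities
  `exp(0.25·score + 0.2·(site MGW − table mean) + ε)`, ε ~ N(0, 0.3).
  The log-normal form matches fluorescence data and supports rank-based
  probe selection; the generator does not reproduce de Bruijn probe
  design, position effects or replicate spot structure. Background probes
  can contain chance motif matches at the 10⁻³ level, as on real arrays,
  so manifests are a subset of scan results, not an exact match.
* `simulate_specificity_dataset()` produces aligned sites (consensus core,
  mutation rate 0.15, fully random 2-bp flanks) and intensities with a
  sequence term and a shape term each scaled to unit variance
  (weights 1 and 1) plus N(0, 0.5) noise. Because shape is a
  pentamer-level function of sequence that crosses the core–flank
  boundary, mononucleotide and core-variant features recover only part of
  the shape term; the remainder is the planted margin a shape-augmented
  model should close. Under these defaults the sequence-only model reaches
  R² ≈ 0.55–0.73 and the shape model ≈ 0.82–0.89 across seeds — a gap
  comfortably above the 0.10 the acceptance suite requires — while the
  shuffled control stays within 0.01 of sequence-only. These weights were
  fixed once as a realistic regime (shape and sequence contributions of
  equal magnitude, moderate noise) and are not tuned per run.

## Problem sizes and numerical choices

The test and acceptance workloads use: 10,000 random sequences for the
strand-invariance check (exact equality, not tolerance-based); brute-force
scan enumeration up to width 8 (4⁸ = 65,536 W-mers); 1000 K-S null
replicates at 200 values per group; 2000 sites with 10 outer folds for the
model-pattern check; clustering oracles at n ≤ 12. These sizes make the
full suite run in about a minute and a half on one core while keeping every
statistical margin wide.

Score discretization uses 1/1000 bit; the DP refuses grids with fewer than
100 bins across the score range (a sign of a degenerate, near-uniform PWM).
TSV writers serialize doubles at full precision so matrices round-trip
bit-exactly; the Newick writer uses 12 significant digits.

## Limitations

* Shape values are only as good as the supplied pentamer table; the package
  ships no measured table and the synthetic one is for testing. Real
  analyses should load a simulation- or experiment-derived table.
* The K-S differential analysis treats positions independently; no
  multiplicity correction is applied, matching the per-position reporting
  convention it reproduces.
* The motif scanner supports 0-order backgrounds only; higher-order
  backgrounds and q-values are out of scope.
* Core motifs must be pre-aligned and equal-length; multiple-sequence
  alignment is not provided.
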