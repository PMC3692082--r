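---
title: "Models and methods behind mirset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirset)
```

`mirset` estimates, per gene, the probability of being a functional target
of a *set* of miRNAs at given expression levels.  This vignette explains
the model, the tunable parameters and their defaults, the numerical and
design choices made where several readings were defensible, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## 1. From expression levels to concentrations

Expression input is a miRNA × sample table.  Log-scale input (typical for
arrays) is converted with `log_to_linear()` (base 2 by default; base 10 or
e via the `base` argument — the appropriate base is a property of the
upstream platform, not of this model).  Within each sample the
concentration of miRNA *i* is its fraction of the total,
$c_i = x_i / \sum_i x_i$, so $\sum_i c_i = 1$.

Filtering focuses the analysis on the top-expressed miRNAs.  The retained
set is the **intersection** of (i) the minimal prefix of miRNAs, sorted by
descending concentration, whose cumulative fraction reaches
`coverage_percent`/100 (ties in concentration are ordered lexicographically
by ID so the prefix is deterministic), and (ii) miRNAs with linear level ≥
`min_level`; IDs in `always_keep` are exempt.  Two readings deserve note:

* *Intersection vs union* of the two filters is not dictated by the
  problem; intersection is the stricter and, we judge, least surprising
  reading ("top expressed **and** above the floor"), so it is the
  implementation; both knobs default to no-ops (100 %, 0).
* Retained concentrations are **not re-normalized** after filtering: a
  discarded low-abundance miRNA's mass simply vanishes.  This preserves
  the physical meaning of $c_i$ (fraction of the cellular miRNA pool) and
  keeps scores comparable across filter settings; `renormalize = TRUE`
  offers the alternative.

In *set* mode each sample yields one labelled concentration vector; in
*single-miRNA* mode each miRNA is analysed alone at $c = 1$ regardless of
its level, which ranks each miRNA's individual contribution on a common
footing.

## 2. Site scoring channels

Four channels score individual sites; two are computed from sequence, two
are imported.

**Seed channel.**  The seed is miRNA positions 2–8 (5′ end).  The scanner
reports every occurrence on the target of the reverse complement of
positions 2–7, classified as 8mer, 7mer-m8, 7mer-A1 or 6mer by the match
at position 8 and the A across from position 1 (the canonical taxonomy;
the A1 anchor is an adenosine regardless of the miRNA base).  Each
occurrence is reported once, as the strongest *accepted* class it
qualifies for, so tightening the accepted set can only reduce counts and
an 8mer survives as a 7mer when 8mers are excluded.  The default accepted
set {7mer-A1, 7mer-m8, 8mer} follows the standard efficacy hierarchy in
which plain 6mers are marginal; which classes the original count-based
channel used is not documented, so this is a package choice and
configurable via `seed_definition()`.  Conservation is deliberately not
used.  Coordinates are 0-based half-open over the nucleotides pairing the
seed region (the A1 adenosine is annotated by the class, not included in
the interval).  Windows containing N never match.

**Energy channel.**  A simplified hybridization model stands in for a full
alignment-based scorer: sites are anchored on 6mer seed cores; around each
anchor the miRNA is aligned antiparallel and ungapped, and the energy is a
duplex initiation penalty plus nearest-neighbor stack terms over the most
stable contiguous helix (Watson–Crick stacks from the standard RNA
parameter set at 37 °C; G:U wobble stacks with approximate values; the
symmetric closure of the table is built in code so the energy is exactly
invariant under duplex reversal).  Only sites with negative energy are
emitted.  This captures the two properties the combinatorial model needs —
site strength ordering and additivity over sites — without reimplementing
published alignment tools; imported tables override the built-in scanner
when provided.

**ΔΔG and mirSVR channels.**  Both depend on external machinery (secondary
structure ensembles, a trained regression) and are import-only, via a
5-column TSV (`gene_id`, `mirna_id`, `start`, `end`, `score`); the format
is this package's interchange convention since none is standard.
Unparseable rows are errors, not silent drops, and intervals are validated
against sequence lengths when sequences are supplied.

Sequences are stored in the DNA alphabet (U→T on ingestion): a single
internal alphabet makes complementarity checks uniform.  When several
3′UTR isoforms share a gene ID the longest is kept, ties resolved to the
first encountered (the resolution of equal-length isoforms is unspecified
upstream; first-encountered is deterministic and order-faithful).

## 3. Expression-weighted combination

**Fermi–Dirac channels** (energies, ΔΔG).  Site $j$ of miRNA $i$ on gene
$k$, with energy $E_{ijk}$, is occupied with probability

$$p_{ijk} = \frac{1}{1 + e^{(E_{ijk} - \mu_i)/kT}}, \qquad
  \mu_i = \mu_0 + kT \ln \max(c_i, \varepsilon),$$

and the gene score is $S_k = \sum_i \sum_j p_{ijk}$, the expected number
of occupied sites — bounded by the site count, additive over disjoint site
sets, non-decreasing in every $c_i$ and non-increasing in every $E_{ijk}$.
The logistic is evaluated with `plogis`, which saturates gracefully, and
$\varepsilon = 10^{-9}$ floors the concentration inside the logarithm.

Parameters (all configurable via `fd_params()`):

* `kT = 0.593` kcal/mol, RT at 25 °C — the natural thermal scale for
  free energies in kcal/mol.
* `mu0 = -12` kcal/mol.  The chemical potential at $c = 1$ must sit in
  the range real site energies occupy: seed-anchored duplexes under the
  shipped stack table land around −10 to −18 kcal/mol, so anchoring
  $\mu_0$ at the typical site energy keeps occupancies responsive to both
  energy and concentration.  A $\mu_0$ far above that scale (e.g. 0)
  saturates every occupancy at 1 and silently degenerates the channel
  into site counting.  Both defaults are calibration choices with the
  intended qualitative behaviour, not measured physical constants.

Note that downstream features are *ranks* of $S_k$, which are invariant
to any monotone recalibration of $kT$ and $\mu_0$; the calibration
matters for the interpretability of $S_k$ and for
concentration-sensitivity, not for the classifier.

**Weighted-sum channels** (seed counts, mirSVR).  The per-gene single
score of miRNA $i$ is the site count (seed channel) or the sum of site
scores (mirSVR), and $S_k = \sum_i c_i s_{ik}$.  Concentrations (not raw
levels) are the weights — they are what preprocessing produces, and they
make scores comparable across samples with different sequencing depth.
mirSVR scores keep their native sign (more negative = stronger); the
direction is handled at ranking time.

Sites belonging to miRNAs filtered out upstream contribute nothing; they
are counted in a diagnostics tally rather than silently ignored.

## 4. Rank normalization and SVM integration

Each channel's per-gene scores are replaced by fractional ranks
$r_k = \mathrm{rank}_k / n \in (0, 1]$, most target-like gene at 1, ties
averaged.  Ranks depend only on the ordering, which removes
distributional differences between channels (and between species or miRNA
sets) — this *is* the normalization step, and it is why a model trained in
one setting transfers to another.  $r = \mathrm{rank}/n$ rather than
$(\mathrm{rank}-1)/(n-1)$: the two differ by a monotone affine map (hence
identically ranked SVM inputs after training on the same convention); the
former keeps $r > 0$ and gives the top gene exactly 1.  Ranks are computed
per submission over the supplied gene universe, custom sequences included,
so user sequences are ranked within the same population.  Per-channel
direction defaults: occupancy sums and seed counts higher-is-target;
mirSVR weighted sums lower-is-target.

The integrator is a radial-kernel SVM (`cost = 1`,
`gamma = 1/n_channels`) with probability calibration; the radial kernel
with standard regularization is the conventional default for
low-dimensional, rank-compressed features, and both hyperparameters are
exposed and recorded in the model object.  Training requires both
classes, reports a stratified cross-validated AUROC computed on held-out
decision values, and is deterministic given `seed` (the calibration's
internal cross-validation draws from R's RNG, which the seed controls).
Models save/load bit-identically via `save_model()`/`load_model()`.

No trained model ships with the package: a useful model is fit on
experimentally supported target labels (typically Argonaute-IP-derived),
which the package does not distribute.  `default_model()` trains on the synthetic fixture at run time and
is labelled as such; for real analyses, retrain on your own labelled
genes (e.g. AGO-IP-derived target lists) with `train_target_model()`.
The SVM accepts any non-empty channel subset, so the tool works without
the import-only channels.

## 5. Differential prediction

`wilcoxon_differential()` compares, per gene, its scores (or per-sample
fractional ranks, `use_ranks = TRUE` — both comparisons are meaningful,
probabilities being calibrated and ranks being scale-free; scores are the
default) across two
disjoint groups of ≥3 samples with a two-sided rank-sum test.  For
`min(n, m) ≤ 8` the p-value is exact — via the closed-form null
distribution when values are tie-free, by complete enumeration over all
$\binom{n+m}{n}$ assignments of the pooled midranks when ties are present
(base R has no exact-with-ties path) — and a continuity-corrected normal
approximation otherwise.  The exact small-sample path matters because the
minimum group size is 3, where approximations are unreliable; at $n=m=3$
the smallest achievable two-sided p is 0.1, so no 3-vs-3 comparison can
clear α = 0.05 — a discreteness fact users should know.  Raw p-values are
reported by default (no multiple-testing correction, since the analysis
is exploratory gene screening); a Benjamini–Hochberg column is available
via `adjust = TRUE`, and `alpha` only flags rows, never removes them.

## 6. The synthetic-data generator

`generate_fixture()` produces a complete, seeded study: i.i.d. random
3′UTRs (uniform base composition by default, GC-bias knob available),
random 22-nt miRNAs, a power-law expression profile (level of the $i$-th
miRNA $\propto i^{-1}$, log-normal sample noise, sdlog 0.25) over 2
samples, target-class genes carrying 3 exact 8mer complements of the 5
most abundant miRNAs at non-overlapping positions, decoy genes with
background-only matches, imported-channel tables whose scores scale with
a per-site latent strength plus Gaussian noise, and target/decoy labels.
The defaults (200 genes, 20 miRNAs) are the standard study size used
throughout the tests and the acceptance script — small enough to run in
seconds, large enough for stable AUROC estimates.  `fixture_snp_pair()`
derives a wild-type/variant sequence pair differing by one substitution
inside a planted seed core, emulating a binding-site-destroying SNP.

What the generator does **not** emulate: real 3′UTR base composition and
repeat structure, conservation, isoform structure, AGO-IP noise (labels
are exact by construction), the true distributions of accessibility or
regression-based site scores (the synthetic ones are fixture policy, not
claims about the external tools), and any cooperative or competitive
site interactions.  Passing tests therefore demonstrate that the
machinery is correct and that the pipeline recovers planted signal under
the stated noise — not field performance on biological data.

## 7. Numerical and testing notes

* Oracle tests compare both combiners against naive double-loop
  reimplementations at $10^{-12}$, and the seed scanner against a
  brute-force substring scan on sequences up to 10 kb.
* The null-calibration simulation for the rank-sum test uses two groups
  of 8, where the exact path runs and the test's exact size at α = 0.05
  is 0.0499 (at the paper-minimum group size of 3 the size is 0, see §5,
  which would make a calibration check meaningless).
* Concentration-monotonicity is guaranteed *per score*: doubling one
  miRNA's concentration (holding the others fixed) never lowers any of
  its target genes' Fermi–Dirac scores and never changes genes it has no
  sites on.  The corresponding statement for fractional ranks holds
  against the unchanged competitor genes; genes that all rise by
  different amounts can reshuffle among themselves, so a simultaneous
  rank guarantee for every affected gene is not a theorem and is not
  asserted.
* Degenerate inputs are errors or flagged, never silent: all-zero
  samples, single-class training labels, all-tied scores (midpoint ranks
  plus a warning), empty post-filter miRNA sets (warning), unknown
  miRNA IDs (dropped with notification).

## 8. Known limitations

The energy channel is a deliberately simplified ungapped model: no
bulges, no 3′-supplementary pairing, no accessibility.  ΔΔG and mirSVR
channels are only as good as the imported tables.  The shipped G:U stack
parameters are approximate.  Cooperative targeting and Ago-loading
competition are out of scope.  The default model is synthetic-trained and
must be retrained for biological use.
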