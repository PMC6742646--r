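---
title: "Models and methods behind edgoburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind edgoburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgoburden)
```

# Overview

`edgoburden` chains five analysis stages — clone calling from pooled
sequencing, interaction-perturbation calling, per-genome burden
extrapolation, protein-stability scoring, and evolutionary/structural
context — with a shared statistics layer and a synthetic-data generator
that plants known parameters into every input. This vignette documents
the models, the tunable parameters and their defaults, the numerical
choices made where the underlying procedure is genuinely open, and the
limits of what the synthetic data can show.

# Clone calling from pooled sequencing

A mutagenesis pool contains `TotalMutations` copies of an ORF, each
intended to carry one engineered single-base change. If clones
contribute reads evenly, a true mutation appears in `1/TotalMutations`
of the reads at its position. Sequencing error perturbs this fraction in
both directions: errors in the other clones create mutant-looking reads,
and errors in the mutant clone destroy them, giving the expected
fraction

$$E = \frac{1}{T} + (T-1)\,\epsilon - (A-1)\,\epsilon$$

with $A = 6$ alleles (four bases, insertion, deletion). The call
statistic is the ratio of observed to expected fraction, thresholded at
0.5, **boundary inclusive**.

Parameters and conventions:

* **Coordinates** are 1-based along the ORF nucleotide sequence, protein
  positions 1-based; this matches molecular-biology convention.
* **Sequencing error** $\epsilon$ at a position is the mean non-reference
  read fraction over the *10 nearest non-targeted positions* by absolute
  coordinate distance. Two choices here were open and are fixed as
  follows: (i) equidistant candidates tied at the 10th place are *all*
  included (the neighbourhood may hold 11+ positions) — symmetric and
  deterministic; (ii) the query position itself is always excluded, so a
  genuine off-target mutation cannot inflate its own error estimate.
* **Minimum coverage** (default 10 reads): positions below it are
  excluded from error estimation and skipped in the off-target scan,
  because read fractions at such depths are noise-dominated. A *targeted*
  position with zero coverage makes the call uncallable rather than
  silently failed.
* **Off-target screening** reuses the same per-position $\epsilon$ and
  the same `TotalMutations` in the expected fraction — an unwanted PCR
  artifact arises in one clone exactly like a desired mutation does.
* **Ranking** of accepted clones is lexicographic: desired score
  (descending), maximum undesired score (ascending), mean coverage
  (descending), mean base quality (descending). The combination of these
  four criteria is not prescribed anywhere authoritative; a lexicographic
  order is deterministic and auditable. "Quality" is mean base quality;
  mapping quality is not modelled.
* **ORF mapping validation** requires identity within a 31-aa window
  centred on the variant (truncated at termini) *and* either > 95%
  global identity or an exact substring spanning ≥ 1/3 of the
  transcript. Global identity is an input (from an external alignment
  summary), not recomputed.

Degenerate inputs: an all-uncovered pool raises an error ("unusable
pool"); a pathological $\epsilon$ making $E \le 0$ is refused rather than
scored.

# Interaction perturbation calls

A mutant × interaction test is *disrupted* when mutant growth, relative
to the wild-type interaction (WT = 1.0), is ≤ 0.5 on the **same**
selective medium in all three replicate screens; either of the two media
qualifies. The per-medium formulation is our resolution of an
under-specified reproducibility rule: requiring the drop to reproduce on
the medium where it occurs is the weakest rule that still demands
three-fold reproducibility. Autoactivation of bait or mutant makes the
test *untestable*; untestable records leave both numerator and
denominator of every downstream rate.

Variants tested against ≥ 2 partners fall into non-disruptive / partially
disruptive / null-like; single-partner variants support only the binary
call and are reported `unclassifiable` for the three-way scheme.

For the disease-concordance analysis, same-gene mutation pairs must share
at least one *tested* interaction. Pairs are unordered, each counted
once. Categories (share ≥ 2 disrupted / share ≥ 1 / share none) are
reported both **overlapping** (≥ 2 is a subset of ≥ 1, mirroring how such
pair counts are usually published) and as an **exclusive** partition,
since enrichment tests on overlapping categories are not independent.
Disease labels compare equal after trimming and case-folding only — a
declared, minimal normalization; no ontology mapping is attempted.

# Per-genome burden

Variants are binned by global MAF at 0.1%, 1% and 10%. The lowest bin is
closed on both ends (`[0, 0.001]`), so a variant at exactly 0.1% counts
as "very rare"; the remaining bins are left-open/right-closed. The
per-genome expectation weights per-bin disruption rates by a per-genome
bin composition (an *input*, typically derived from a site frequency
spectrum): $E = \sum_b r_b c_b$. The SEM treats the bin rates as
independent binomial proportions and the composition as a fixed
constant — the standard delta-method choice:
$\mathrm{sem} = \sqrt{\sum_b w_b^2\,se_b^2}$. Correlation between bins
(shared genes, shared screens) is not modelled.

# Protein stability

The stability score is background-corrected GFP over background-corrected
mCherry, both backgrounds estimated from the plate's GFP-negative control
wells (≥ 4 of each control role per plate). Wells whose corrected mCherry
falls below a floor — default 3 SD above the background-control mean —
are *invalid*: a failed transfection is not an unstable protein. The two
classification thresholds are honoured exactly: mutant score < 0 →
unstable; mutant:WT ratio < 0.5 → moderately stable; otherwise stable.
The score is exactly invariant under adding a constant to all GFP
readings of a plate, and classification is invariant under positive
scaling of all fluorescence — both properties are tested.

# Evolutionary and structural context

**Conservation.** Column conservation is the Jensen–Shannon divergence,
equal-weight ($\lambda = 1/2$), base-2, between the column's amino-acid
distribution and a background — uniform over the 20 residues by default,
BLOSUM62 frequencies or a custom vector optional. Gap characters are
excluded from column distributions; columns with > 30% gaps are flagged
low-confidence, all-gap columns score `NA`. Sequence weighting and gap
penalties (as in some conservation-scoring toolkits) are deliberately not
applied; the chosen formulation is fully stated so scores are
reproducible. Tracks from alignments with fewer than 50 homologs are
marked unusable.

**Selection scan.** `H = θπ − θH` over the unfolded SFS of half-open
windows (`[start, start + 1000)`, 0-based; the sliding step defaults to
the window length, i.e. tiling, since a step is not otherwise
prescribed). Windows with fewer than 3 polarized SNPs have no measurable
`H` and are excluded from the percentile computation. The significance
threshold is the within-group 5th percentile taken as the
`ceiling(0.05 N)`-th order statistic, flagging everything *at or below*
it — with all-distinct values exactly `ceiling(0.05 N)` windows are
flagged, and ties at the threshold are all included.

**Duplicate genes.** Pairs below 40% identity are excluded before
scoring; identity and coverages are fractions in `[0, 1]`, so the
weighted score is bounded by 1 (perfect duplicates).

**Interfaces.** Interface residues require a SASA change strictly
greater than 1 Å² between unbound and bound states (1.0 Å² exactly does
not qualify); interacting domains require both the
mediates-protein-interaction annotation and ≥ 5 interface residues
within their bounds.

# Statistics

The two-proportion Z-test uses **pooled** variance and no continuity
correction by default; this is the form whose p-values match published
proportion comparisons reproduced in the test suite, and its square
equals the 2×2 Pearson chi-square (also tested). On binary data the
tie-corrected rank-sum test coincides numerically with this pooled Z,
which is why figure-legend "U-tests" on proportions are reproduced by
`twoPropZ()`; both routes are available. The Mann–Whitney implementation
enumerates exactly when both samples are untied and small (min n ≤ 8)
and otherwise uses the tie-corrected normal approximation; when every
observation is tied the rank variance is zero and the one-tailed p is
reported as 0.5. No multiple-testing adjustment is applied anywhere:
per-comparison p-values are reported as such.

# The synthetic-data generator

The generator's defaults *are* the study conditions the package is
tested under:

* **Pools**: 4 clones, depth 1000×, error rate 0.001, ORF length 300 nt.
  Read errors replace the true allele with probability $\epsilon$,
  uniformly over the five other alleles — insertions and deletions
  receive the same per-allele share as substitutions, since the error
  model being emulated is symmetric and otherwise unspecified.
* **Network**: per-pair disruption probabilities `(0.200, 0.170, 0.130,
  0.096)` across the four MAF bins. The two endpoints are published
  per-bin rates for an edgotyping screen of this design; the two middle
  values interpolate the published decreasing trend. Partner counts are
  `1 + Poisson(mean_partners − 1)`, default mean 2 — most variants in
  such screens are tested against one or two partners. Growth readouts
  are continuous in `[0, 1.05]` relative to WT so that thresholding
  itself is testable; real screens record plate outcomes. Note the
  *variant-level* disruption rate implied by per-pair probability $p$ is
  $1 - (1-p)e^{-\lambda p}$ under this partner model — tests recovering
  planted burden rates use this closed form.
* **Genome composition**: 13,595 missense variants per genome split
  `(0.05, 0.08, 0.15, 0.72)` across the bins — a typical genome is
  dominated by common alleles; the exact split is configurable because
  published per-genome SFS summaries vary.
* **Disease labels** are drawn per gene from two label pools with a
  per-variant probability chosen so any same-gene pair shares a label
  with the planted probability (default 0.7).
* **Plates**: backgrounds 100 ± 5 (GFP) and 50 ± 3 (mCherry) a.u.,
  signals 2000/1000 a.u., 2% CV, planted mutant ratios
  `(1.0, 0.9, 0.4, −0.05)` spanning all three categories.
* **MSAs**: 60 homologs; each column draws the consensus residue with
  the column's conservation parameter, so conservation 1.0 gives an
  invariant column.
* **Window SFS**: n = 20 chromosomes, Poisson segregating-site counts at
  $\theta = 5$ per window; neutral windows follow the `1/i` shape, sweep
  windows mix in a high-frequency-derived component (class probability
  ∝ i) with weight `sweep_skew`.

Each generator seeds its own RNG stream from the master seed plus a fixed
offset, so adding a generator never changes another's output and
identical configs are byte-identical.

What the synthetic data does **not** emulate: raw reads and alignment
(pileups are generated directly), real site-frequency spectra, uneven
clone pooling, batch and plate-position effects, autoactivator
prevalence, or correlated disruption across partners of the same
variant. Passing tests therefore demonstrate the correctness of the
calling, classification and propagation machinery under the stated
models — not robustness to those real-data artefacts.

# Test problem sizes

The property suites run at sizes chosen to keep the full test run near
ten seconds while leaving comfortable statistical margins: 100 seeded
pools (depth 10⁴, ORF length 240 nt) for planted-mutation recovery; 200
seeded replicates of 600 variants for burden recovery within 2×SEM; 100
replicates of 250 variants for disruption-probability coverage; 60
replicates for concordance coverage. Deterministic oracles (closed-form
expected fractions, hand-derived H values, exhaustive pair enumeration,
brute-force nearest-neighbour and sorting checks) run at the sizes shown
in the tests.

# Known limitations

* Clone calling assumes even read contribution across pooled clones; a
  heavily skewed pool shifts observed fractions away from `1/T` and the
  score loses calibration.
* The burden SEM ignores between-bin correlation and treats the genome
  composition as exact.
* The concordance analysis treats disease labels as flat strings;
  synonyms and nested phenotypes are not resolved.
* Fay & Wu's H requires externally polarized derived alleles;
  misorientation biases H upward at high-frequency classes.
* JSD conservation uses unweighted sequences; deep, redundant homolog
  sets overweight crowded clades.
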