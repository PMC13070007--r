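---
title: "Methods: sequencing-based phage display selection and kinetic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequencing-based phage display selection and kinetic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slisy)
```

This vignette documents the models, the statistical rules, and the design
choices behind each stage of the package, and what the synthetic-data
tests do and do not establish about real experiments.

## Site-saturation library design

A selection round is defined by a parent scFv, a set of mutable CDR
positions, and a (possibly empty) backbone of substitutions fixed in
earlier rounds. Each variant differs from the round's backbone sequence
at exactly one position, so a library with $S$ sites and $a_s$ allowed
substitutions at site $s$ has $\sum_s a_s$ variants plus one
zero-alteration "parent" entry. The reference configuration is 74 sites
with all 19 non-parental amino acids allowed: 1,406 variants + 1.

Choices made where the procedure is genuinely open:

- **Which sites and substitutions to include is an input, not an
  algorithm.** Curation of unusual neighboring residues or low-diversity
  amino acids depends on external CDR-frequency resources, so the
  package models it as a user-supplied per-site exclusion map;
  `enumerate_sites()` with no exclusions reproduces the 74 × 19 design.
- **Coordinates.** CDR intervals are 0-based half-open in all external
  tables (TSV), converted to R's 1-based substring arithmetic only at
  the boundary. Display labels of positions are opaque strings (the
  built-in example uses 1-based residue numbers), so no commitment to
  Kabat/IMGT/Chothia numbering arithmetic is made — annotation is out of
  scope.
- **Clone IDs** are comma-joined mutation strings
  `<parent AA><label><new AA>`, cumulative over rounds and ordered by
  CDR (L1, L2, L3, H1, H2, H3) then position, e.g. `V30K,S32R,R27Y`.
- **Reverse translation** uses one fixed codon per amino acid
  (configurable table); library synthesis accepts any valid encoding,
  and a deterministic choice makes the read round trip exact.

## From reads to molecule counts

The sequencing assay observes the CDR-covering windows of the scFv as a
set of segments per cluster, tagged with a sample barcode and a 14-mer
UMI. The pipeline is: demultiplex → collapse UMIs → trim/translate →
classify → tally, with full conservation accounting (demultiplexed +
discarded = input reads; assigned + unassigned + untranslatable +
length-mismatch = molecules per sample).

- **UMI collapse key** is the pair (UMI, full nucleotide sequence) with
  zero UMI mismatch tolerance: identical pairs are PCR duplicates of one
  molecule; the same UMI with a different sequence stays two molecules.
  This is the conservative reading of UMI-based deduplication; with the
  14-mer space of $4^{14} \approx 2.7\times10^8$, collisions are
  negligible at the depths used.
- **Classification rule.** A translated window peptide identical to the
  round's backbone is the parent; exactly one amino-acid alteration that
  matches an enumerated variant assigns that clone; anything else
  (including a single alteration outside the design) is unassigned.
  Treating off-design singletons as unassigned rather than as novel
  clones keeps scoring defined over the designed library; the QC report
  retains their count.
- **Error handling is the ≤1-alteration filter itself.** No
  quality-score filtering is applied and barcode mismatch tolerance
  defaults to 0 (both configurable); a stop codon or non-ACGT base makes
  a molecule untranslatable, which is reported, not dropped silently.
- **Counting unit.** Molecule (UMI-collapsed) counts are the default;
  `count_reads(..., unit = "reads")` switches to raw read counts. At
  duplication rate 1 the two coincide; with PCR duplication, molecule
  counts are the better estimator of bound phage.

## SLISY scoring

For clone $i$ with count $n$, the approximate 95% interval is
$n \pm 2\sqrt{n}$ (normal approximation to a Poisson count; lower bound
floored at 0). Stringency biases both statistics against false
positives: the TRBC2-bound count enters through its lower bound and the
TRBC1-bound count through its upper bound, so the stringent binding
ratio never exceeds the point estimate:

$$B_i = \frac{\max(0,\; n_i^{2} - 2\sqrt{n_i^{2}})}
             {\max(n_i^{1} + 2\sqrt{n_i^{1}},\; \varepsilon)},\qquad
  E_i = \frac{\max(0,\; n_i^{2} - 2\sqrt{n_i^{2}})/N^{2}}
             {\max(n_i^{\mathrm{in}},\; \varepsilon)/N^{\mathrm{in}}}.$$

Numerical and design choices:

- $\varepsilon = 1$ read floors zero-count denominators: a clone never
  seen in the TRBC1 pool gets the largest ratio its TRBC2 count
  supports, scaled consistently with depth, instead of infinity.
- The confidence bound is applied to the bound-pool count only, not to
  the input-library count: sample totals and input counts are
  comparatively deep, where the $2\sqrt{n}$ correction is negligible;
  `score_config(use_ci = FALSE)` switches both statistics to point
  estimates (under which the enrichment ratio is exactly
  depth-invariant).
- **Normalization** is a linear min–max map of each statistic to
  [0, 100], per library and per statistic (all-equal input maps to all
  zeros). Rank-percentile mapping was considered and rejected: it
  discards the magnitude separating a dominant clone from the field.
- **Selection rule.** Clones are ranked by descending
  $\min(B^{\mathrm{norm}}, E^{\mathrm{norm}})$ — a clone must be high on
  *both* statistics — with ties broken by descending binding ratio, then
  clone ID. A `top_k_by_binding` alternative is available; the max–min
  default is the conservative formalization of selecting clones with
  high binding *and* enrichment.

## 1:1 Langmuir kinetics

The forward model per analyte concentration $C$ (association phase of
length $t_c$, then dissociation):

$$R(t) = R_{eq}\left(1 - e^{-(k_a C + k_d)t}\right),\quad
  R_{eq} = \frac{R_{max} C}{C + K_D},\qquad
  R(t > t_c) = R(t_c)\, e^{-k_d (t - t_c)}$$

with $K_D = k_d/k_a$. No mass-transport or bulk-refractive-index terms
are modeled: the model is the pure 1:1 binding isotherm. The default
protocol is multi-cycle: threefold dilutions 1,000 → 4.1 nM (six
concentrations), 60 s contact, 300 s dissociation, 1 Hz sampling.

`fit_1to1()` is a global fit sharing $(k_a, k_d, R_{max})$ across all
curves. Because the model is linear in $R_{max}$, that parameter is
profiled out in closed form ($R_{max}^\ast = \langle g, y\rangle /
\langle g, g\rangle$ for the unit-$R_{max}$ model $g$), leaving a
2-parameter problem in $(\log_{10} k_a, \log_{10} k_d)$ solved by
Levenberg–Marquardt from a 5 × 5 log-spaced multistart grid
($k_a \in [10^3, 10^7]$, $k_d \in [10^{-5}, 10^{-1}]$; the three best
grid points are refined). Noiseless simulations are recovered to well
below $10^{-3}$ relative error; with noise at 1% of $R_{max}$, the
fitted $K_D$ at a true 10 nM stays within 20% across seeds. A single
concentration is rejected as unidentifiable ($k_a$ and $R_{max}$ trade
off).

**Dissociation fraction.** The fraction of antibody–antigen complex
remaining after time $t$ is $e^{-k_d t}$ — the rate constant here must
be the off-rate $k_d$ (units 1/s); writing the exponent with the
equilibrium constant $K_D$ (molar) is dimensionally inconsistent,
although the two are sometimes conflated in informal use. At
$k_d = 0.0013\,\mathrm{s^{-1}}$ and $t = 600$ s the function returns
0.4584 (full precision is reported; quoting 45.7% is consistent with an
unrounded off-rate near 0.00130 s⁻¹).

## Downstream assay summaries

Deterministic arithmetic, kept as functions so they are testable:
quadrant percentages ($100\,c_q/\sum c$), malignant fraction
($100\,\text{cancer}/\text{total T}$, reported at full precision
alongside the conventional rounding), DAR
($\sum \ell_j A_j / \sum A_j$ over integer-labeled chromatogram peaks —
peak identification is a judgment call left to the user), and the 4PL
dose–response model
$y = b + (t - b)/(1 + (x/\mathrm{IC}_{50})^h)$ fitted by
Levenberg–Marquardt with IC50 on the log scale and Hill starts of both
signs, reported in the canonical orientation $t \ge b$. Responses are
assumed normalized upstream (fraction of untreated control); IC50
scales linearly with the dose units. Flat curves are rejected rather
than silently returning an arbitrary IC50.

## What the synthetic generator emulates — and what it does not

`simulate_panning()` draws input counts from a multinomial over the
clone fractions and bound-pool counts from multinomials with
probabilities $\propto f_i\, p_i$, where $p_i$ is the clone's capture
probability on the respective cell line. Capture probabilities are
specified directly (interpretable truth); an equilibrium link
$p = C/(C + K_D)$ is available for affinity-driven scenarios. One
bind–wash–sequence pass per library is modeled — no multi-round
amplification, growth bias, or chimeric PCR artifacts.
`emit_reads()` inverts the read pipeline: one record per molecule with
a fresh random UMI, geometric PCR duplication (configurable mean), and
independent per-base substitution errors (0–5%).

Defaults define the simulated study conditions: depth $10^5$ molecules
per sample (a realistic amplicon depth giving ~70 input molecules per
clone at library size 1,407), error rate 0 unless a test exercises
error handling, duplication mean 1. The end-to-end recovery test plants
one clone whose TRBC2 capture probability exceeds all others 10-fold at
equal TRBC1 capture and requires it to rank first in at least 95 of 100
seeded replicates at that depth.

Passing these tests shows the pipeline's bookkeeping and statistics are
correct under the stated sampling model. It does not show that real
panning obeys multinomial sampling with clone-independent capture, nor
that real sequencing errors are independent substitutions; wash
stringency, nonspecific background, and amplification bias are not
modeled, and measured affinities, DARs, IC50s or donor flow percentages
of real antibodies cannot be reproduced from simulation — those enter
only as reference parameter values (e.g. $K_D$ = 10 nM) whose
*recovery* from synthetic data is what the tests certify.

## Problem sizes and runtime choices

Tests run the full 1,407-clone design where the identity matters
(enumeration counts, read round trip) and a 10-site toy parent (191
clones) where only the rule is under test (classification oracle,
1,000 random peptides). Replicate studies use 100 seeds for ranking
recovery (count-level, depth $10^5$) and for noisy $K_D$ recovery; the
acceptance script reports the median fitted $K_D$ over 25 seeds. The
read-level round trip is exercised at depths up to ~1,500 molecules per
sample — the error-free round trip is exact, so count-level and
read-level analyses are interchangeable at error rate 0.

## Known limitations

- Scoring treats clones independently; no joint selection-coefficient
  model across rounds, and no p-values on enrichment.
- The ±2√n interval is a normal approximation; at very low counts
  (n ≲ 4) its lower bound is 0 and the stringent ratios are
  conservative by construction.
- The 1:1 fit assumes a homogeneous ligand surface and no rebinding;
  heterogeneous or transport-limited data will show structured
  residuals rather than a warning.
- Barcode demultiplexing at tolerance > 0 requires barcode sets with
  adequate pairwise distance (the built-in pool has minimum pairwise
  distance 6).
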