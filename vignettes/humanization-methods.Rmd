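---
title: "Humanness scoring and greedy humanization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Humanness scoring and greedy humanization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abhumanize)
```

## The problem and the model

Antibody variable domains (VH; VL kappa or lambda) are numbered with the
IMGT unique scheme: positions 1–128, with framework regions FR1 (1–26), FR2
(39–55), FR3 (66–104), FR4 (118–128) and CDR loops CDR1 (27–38), CDR2
(56–65), CDR3 (105–117). Numbering aligns sequences of different lengths
onto a common coordinate system, which is what makes a fixed-length
classifier encoding possible. Insertion codes (e.g. `111A`) are part of the
data model and sort in the scheme's order — ascending after their integer
position, except on the inward-counting side of the CDR3 loop at position
112, where they sort descending *before* it.

"Humanness" is modeled as a supervised classification problem: for each
human V-gene family of a chain, a binary random forest is trained with that
family's human sequences as positives and the pooled non-human sequences of
the chain as negatives. Training per V gene avoids a non-physiological
mixed-family representation and yields, for any query, a profile of scores
across families. The classifier's score is the mean per-tree positive-class
probability. A sequence is classified human when its score strictly exceeds
the calibrated threshold of *any* V-gene model of its chain; a VH/VL pair is
human only when both chains are. Light chains are first routed by a
kappa-versus-lambda forest before humanness scoring.

### Feature encoding

The forests see a one-hot encoding over an ordered position universe: 21
indicators per universe position (20 amino acids plus an explicit gap state
for unoccupied positions), exactly one of which is 1. The default universe
is the 128 integer IMGT positions; insertion codes are excluded from
classifier features by default because they are rare in repertoires and
would triple the feature count for negligible signal (any universe can be
passed explicitly). Sequence positions absent from the universe are skipped
silently by default so that the insertion-free universe can encode inserted
sequences; a `strict` flag turns this into an error naming the offending
codes. Encoding is injective over a fixed universe and `decode_sequence()`
inverts it, which the tests exercise as a round-trip property.

### The forest

No decision-tree library is assumed: the ensemble is implemented in the
package's C++ code. Trees are CART-style — Gini impurity, bootstrap
resampling, `sqrt(p)` features examined per node, grown to purity
(`min_split = 2`) — and, because every feature is a 0/1 indicator, a split
is a single counting pass. Defaults follow the common ensemble contract:
200 trees, unlimited depth, impurity splits. Feature importances are
normalized impurity decreases, mapped back through the encoding to
(position, residue) pairs together with the residue's frequency in the
positive and negative training corpora. All randomness is drawn from R's
RNG, so `set.seed()` (or the `seed` arguments) makes training reproducible;
scoring a fixed model is deterministic.

### Threshold calibration

Data are split 0.8/0.1/0.1 into train/validation/test, stratified by label
with largest-remainder allocation (class proportions in every partition are
within one record of global). The decision threshold τ maximizes Youden's J
statistic, J = sensitivity + specificity − 1, over candidate cutpoints
taken as midpoints between adjacent distinct validation scores plus the
sentinels 0 and 1. The decision rule is strict (`score > τ`; a score equal
to τ is non-human). Ties in J break toward the smallest candidate, which
maximizes sensitivity. The MCC-maximizing cutpoint is computed alongside
for comparison and reported, not enforced; on the synthetic benchmark the
two coincide.

## The humanizer

Greedy single-site search: every possible substitution at mutable framework
positions is generated (19 alternatives per position; CDRs never mutated to
preserve binding), all mutants are scored, and the best one is accepted if
it strictly improves the score. The loop repeats from the new sequence
until the target score T is reached, no mutant improves the score
(*plateau*), or `max_iterations` is hit. Design choices where the procedure
was genuinely open:

- **Conserved cysteines.** C23 and C104 are structurally essential; rather
  than merely observing that they are never mutated, the default
  configuration masks them (`immutable = c("23", "104")`), guaranteeing the
  property for arbitrary scoring models. The mask is overridable.
- **Tie-breaking.** Among equally best mutants: lowest IMGT position, then
  alphabetical target residue. Any fixed rule would do; determinism is the
  requirement, and identical calls yield identical trajectories.
- **Plateaus** stop the search rather than accepting score-neutral
  mutations: the objective is as few mutations as possible, and accepting
  neutral moves could wander without bound.
- **Re-mutation** of an already-mutated position is allowed by default
  (forest scores interact across positions, so revisiting can be optimal);
  `allow_revisit = FALSE` disables it.
- **Default target.** When no target is supplied the model's calibrated τ
  is used — the classification boundary is the natural goal when no
  experimentally humanized reference score exists.
- **Gap handling.** Only residue→residue substitutions are generated;
  positions absent from the input are never created and none are deleted.

When the score is additive over positions the greedy trajectory provably
equals the exhaustive best-k mutation set for every prefix length k, which
the tests use as an oracle via a toy consensus-match objective. The
wrong-V-gene negative control scores the input under all supplied models,
humanizes against the *lowest*-scoring one (seeded uniform choice among
exact ties), and on the synthetic benchmark needs more steps than the
matched model or fails to reach the target — the desk-scale analogue of the
matched-versus-mismatched comparison.

## Evaluation metrics

Tool and experimental humanization are compared as framework mutation sets
with final-state semantics: one entry per position (a trajectory may
revisit a position; the set records the precursor-versus-final difference).
With `n_tool` suggested and `n_exp` experimental mutations:

- OR = 100 × |matches| / n_tool, a match requiring the same position and
  the same target residue;
- AOR additionally counts targets in the same amino-acid similarity group
  (defaults: hydrophobic AVLIM, aromatic FWY, positive KRH, negative DE,
  polar STNQC, special GP — a stand-in partition, overridable, since the
  authoritative grouping is not published in the main text);
- mutation ratio = 100 × n_tool / n_exp.

All three round half-up to integer percent, which reproduces the printed
benchmark values (e.g. 14/16 → 88). Aggregation reports half-up-rounded
means and medians per metric. The random baseline draws `n_tool`
substitutions uniformly (positions without replacement over the mutable
set, targets uniform over the 19 alternatives to the precursor residue) and
converges to the analytic expectation — for the benchmark geometry roughly
2% OR and 5–8% AOR, i.e. an order of magnitude below the tool. Note the
baseline needs the precursor residues, not just positions, so `mutable` is
a named residue vector or a numbered sequence. The ADA correlation is the
R² of the OLS regression of ADA percent on min-chain humanness score,
identical to squared Pearson correlation for this simple fit. Default
interface and Vernier position lists are editable stand-ins, not
authoritative structural definitions.

## The synthetic world

The simulator states a fixed benchmark world. Germline templates are
*synthetic*: deterministic per-chain residue patterns with conserved C23,
C104, W41 and W118 and conventional occupancy gaps — not database germlines
(unavailable offline, and irrelevant to the pipeline's correctness). Human
heavy V1/V3/V4 differ from each other at five framework sites each; mouse
and rat templates differ from their human counterpart at exactly the
`signature_positions` (default 12) framework sites, with species-distinct
consensus residues; CDR residues are shared within a chain. Kappa and
lambda use different base patterns so the chain-type classifier has signal.

Somatic hypermutation is a per-position substitution process: default rates
0.02 (framework) and 0.08 (CDR) per occupied position — CDR-biased, as in
affinity maturation — with targets uniform over the 19 alternatives (a
biased 20×20 row-stochastic matrix can be supplied). These defaults make
classes separable in aggregate while individual sequences are not germline
copies. One master seed drives derived per-record streams, so any prefix of
a larger run reproduces exactly. Exact duplicates from sampling collisions
are removed and reported; optional QC-artifact injection (cysteine errors,
truncated FR1, duplicated records) exercises the quality filter, whose
rules are: exact-duplicate removal, cysteine present at 23 and 104, and no
missing conventionally occupied FR1 position (positions 1–26 occupied in
every built-in germline of the chain — the interpretation chosen for
"missing residues preceding CDR1").

What a green benchmark establishes — and what it does not: with 12
signature positions and low framework SHM, near-perfect AUC/YJS is the
*expected* behaviour of any competent classifier, so the benchmark
validates the machinery (encoding, training, calibration, thresholding,
greedy search), not real-world discrimination power. Real repertoires have
V(D)J recombination structure, clonal lineages, indels, allele-level
variation and much subtler species signal; none of that is emulated, and
performance numbers on this benchmark must not be quoted as expected
performance on biological data. One measurement subtlety: duplicate removal
preferentially discards unmutated records, biasing observed SHM rates
slightly upward at the default rates, so the rate-convergence test runs at
rates where germline collisions are vanishingly rare.

## Numerical choices and degenerate inputs

- Scores are averages of per-leaf fractions, always in [0, 1]; candidate
  thresholds always include 0 and 1, so calibration is defined even for
  degenerate score distributions.
- AUC uses midranks, so tied scores count one half.
- Half-up rounding (`floor(x + 0.5)`) for all percent metrics; R's default
  banker's rounding would disagree with the printed benchmark values.
- Model archives are single JSON documents; leaf values and τ are
  serialized as `%.17g` strings because JSON number emission loses the last
  ulp, and the round-trip contract is bitwise-identical scores. Metadata is
  readable without touching the forest payload, and a format/version check
  refuses incompatible archives.
- Empty tool sets make OR undefined (signalled, not returned as 0); empty
  experimental sets likewise for the mutation ratio.
- `train_model` accepts `n_estimators = 1`; single-class inputs are
  rejected everywhere a second class is semantically required.

## Known limitations

- The forest grows trees to purity with no depth cap; on far larger corpora
  a depth or leaf-size control would be worth exposing.
- FASTA input requires a user-supplied numbering callable; the package
  deliberately does not implement HMM-based antibody numbering.
- The similarity grouping, interface and Vernier sets are editable
  stand-ins.
- The CLI is intentionally thin; it wraps the R API one-to-one and adds no
  behaviour of its own.
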