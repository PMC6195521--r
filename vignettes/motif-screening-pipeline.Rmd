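---
title: "Motif-screening models for SUMOylation site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-screening models for SUMOylation site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumoscreen)
library(dplyr)
```

## The problem

SUMOylation attaches a small ubiquitin-like modifier to a lysine residue.
Experimentally verified sites cluster around the consensus ψ-K-x-E(/D) — a
hydrophobic residue immediately before the lysine and an acidic residue two
positions after — but a large minority of real sites (roughly 25–40% in
curated collections) do not follow the consensus at all. A single classifier
trained on everything tends to learn the consensus and neglect the
non-conforming sites. The approach implemented here therefore *screens*
candidate lysines by a consensus grammar first and trains two separate
models: one for motif-conforming sites (CY) and one for non-conforming
sites (CN). At prediction time each candidate is routed to the submodel
matching its own motif class.

## Windows and labels

Every lysine in an input protein becomes a candidate: a 21-residue window,
10 residues either side of the lysine, padded with `-` where the window
runs past a sequence end. The window length follows the observation that
crosstalk between lysine modifications acts within about 21 residues of
the site. Annotated lysines are positives; the remaining lysines are
negatives *only in proteins that carry at least one annotated site*
(`negatives_rule`), because proteins never assayed for SUMOylation provide
no evidence that their lysines are truly unmodified. Lysines in
un-annotated proteins are labelled `unknown` and excluded from training;
the rule can be switched off to treat them as negatives instead.

Coordinates are 1-based and inclusive throughout: annotation positions,
window centres, and window-internal indices (the lysine sits at window
index 11, so window index 13 is K+2). Non-standard residue codes
(B, J, O, U, X, Z) are rejected by default; a permissive mode maps them to
the gap character, which every encoder treats as "no information" (zeros).
Sequence-redundancy reduction is deliberately out of scope: `read_fasta()`
accepts a `keep_ids` list so an external clustering run can be applied as a
filter.

## Consensus grammars

Six grammar variants are built in, differing in the allowed ψ set and in
whether aspartate may stand in for glutamate at K+2:

| id | ψ (K−1) | tail (K+2) |
|----|-------------------------|------------|
| C1 | L, V, M, F | E, D |
| C2 | A, I, P, L, V, M, F | E, D |
| C3 | A, I, P, L, V, M, F, G, Y | E, D |
| C4 | L, V, M, F | E |
| C5 | A, I, P, L, V, M, F | E |
| C6 | A, I, P, L, V, M, F, G, Y | E |

The default is C1 with the CN submodel at a 1:2 positive:negative training
ratio and the CY submodel at 1:1 — the configuration the screening system
settles on when the grammars and the ratio grid {1:1, 1:1.5, 1:2} are
compared by repeated cross-validated MCC. Matching is evaluated on the
padded window, so edge behaviour is uniform; the unconstrained x at K+1
must still be a real residue, because a gap is not an amino acid — a
lysine at the carboxy terminus can never be CY.

## The 903-dimensional encoding

Each window maps to four fixed blocks, concatenated in this order:

| block | positions | content |
|------------|-----------|------------------------------------------|
| binary | 1–420 | 21 × 20 one-hot amino-acid indicators |
| physchem | 421–630 | 21 × 10 physicochemical property values |
| structure | 631–777 | 21 × 7 per-residue structure profile |
| ptm | 778–903 | 21 × 6 PTM confidence codes |

One-hot channels use a frozen alphabetical amino-acid order (A, C, D, …,
Y); the order is arbitrary for learning but must never change once models
are persisted, so it is part of the encoding layout version. Gaps encode
as zeros in the binary block; we extend the zero rule uniformly to the
other three blocks (zero is also the natural "no modification" code), so
padding, gaps, and null providers are indistinguishable from "nothing
known" everywhere.

The ten physicochemical values per residue are five factor-analytic
consensus scores (polarity, secondary-structure propensity, molecular
size, codon diversity, electrostatic charge) and five literature-survey
properties (Kyte–Doolittle hydropathy, side-chain heavy-atom count,
Chou–Fasman helix and strand propensities, codon count). The table ships
as a versioned text file; any same-shaped replacement can be supplied, and
a hash of the table in use is stored inside every model archive so a model
can refuse encodings produced under a different table. No correctness
claim rests on the specific numbers — the tests exercise dimensions and
zero/identity structure, not table values.

Structure profiles (seven values per residue: buried/exposed class,
relative and absolute accessibility, Z-score, helix/strand/coil
probabilities) and PTM profiles (six modification types — acetylation,
hydroxylation, methylation, phosphorylation, sumoylation, ubiquitination —
coded 0/10/50/100 by confidence) come from external predictors via plain
tabular files; the package parses and validates them but never
re-implements the predictors. Passing `NULL` instead of a profile is the
*null provider*: the corresponding block is all zeros. The null PTM
provider is exactly the "No mod" ablation used to measure what the PTM
block contributes. Because upstream tools disagree on whether the
buried/exposed call is a class or a probability, the parser accepts a 0/1
class column; and since a PTM provider may itself predict sumoylation at
the candidate lysine, `mask_center_sumo` can zero that single channel
(default: included).

## Feature selection (FSC)

Two rankings are computed: a Fisher-style F-score per feature (the LIBSVM
`fselect` convention, with 0/0 defined as 0 and a zero within-class
variance with distinct means as +∞), and a greedy mRMR ordering (MID
variant: relevance is mutual information with the label, redundancy the
mean mutual information with already-selected features; continuous
features are discretised at mean ± one standard deviation into three
levels; MI uses empirical frequencies and natural logs). The *combination*
is defined operationally: every top-k prefix of either ranking, over a
configurable size grid (default 25, 50, 100, 200, 400, 903), is scored by
mean cross-validated MCC under the working classifier, alongside the
all-features baseline; the best scorer wins, with ties broken towards
fewer features and then towards the F-score family. Including the baseline
guarantees selection never returns a subset that cross-validates worse
than using everything.

## Training and prediction

Per submodel, all partition positives are kept and negatives are drawn
without replacement at the configured ratio; the draw is repeated
`n_candidates` times (default 500, following the "at least 500 candidate
models" design; a handful suffices for smoke tests), each candidate is
scored by stratified cross-validated MCC on its own draw, and the best
draw is refitted in full. If the requested ratio exceeds the available
negatives the draw clamps with a warning — sampling with replacement would
duplicate rows across CV folds and inflate the score. If a partition is
too small to cross-validate (fewer members of a class than folds) the
first draw is used as is; a partition missing a class entirely is an
error.

The default classifier is a random forest with 100 trees and vote-fraction
probabilities; an RBF SVM (C = 1, γ = 1/p, Platt-scaled scores) is
retained as the alternative the model-selection phase explored. Neither
learner's hyperparameters are tuned per dataset — they are frozen
defaults. Predicted labels use a 0.5 score threshold unless configured
otherwise.

## Evaluation protocol

Metrics are the five standard threshold quantities (Sn, Sp, Precision,
ACC, MCC). MCC with any zero factor in its denominator is defined as 0;
an undefined Sn/Sp/Precision is reported as NA and excluded from means.
Because realistic site collections run near 1:20
positive:negative, headline numbers come from the balanced protocol:
20 cycles, each keeping every positive and a fresh independent draw of the
same number of negatives, metrics per cycle, arithmetic mean over cycles.
Whether a published mean averages per-cycle metrics or pools counts first
is ambiguous in general, so the report carries both (mean-of-metrics
primary, pooled-counts secondary). For the paired system, CN and CY
confusion counts from the same split are summed element-wise before
recomputing metrics — the standard way to quote one figure for two routed
submodels. Cross-validation is stratified by class (unstratified folds at
these imbalances can easily go single-class) and re-randomised each round;
within a round, out-of-fold predictions are pooled into one confusion
matrix. ROC curves use the plain threshold sweep with trapezoidal AUC.

## The synthetic generator

`generate_dataset()` emulates exactly the structure the pipeline exploits,
and nothing else: background sequences from uniform (default) or
Swiss-Prot-like residue frequencies; each lysine promoted to a planted
positive with `positive_rate` (default 0.05, the ~1:20 order of curated
collections); each planted positive rewritten to match the chosen grammar
with probability `motif_conformance` (default 0.75, the conforming share
reported for curated SUMO sites) or rewritten to guarantee a non-match
otherwise; optional planted PTM signal (high-confidence
acetylation/ubiquitination at the site, phosphorylation next to it — a
crosstalk pattern, deliberately not a planted sumoylation channel, which
would make the task trivial) and structure signal (exposed, high
accessibility) at positive sites. Context rewriting locks every touched
position, skipping (with a message) any site whose rewrite would collide
with another planted site or run past a sequence end, so conformance is
exactly controllable; the ground-truth table records each site's realised
conformance re-derived from the final sequence. Setting
`motif_conformance = NULL` disables rewriting entirely — positives then
carry no signal of any kind, the fully null condition used to check the
pipeline does not hallucinate skill.

What the generator does *not* imitate: real substrate composition,
homology between proteins, correlated PTM landscapes, or any
position-specific preference beyond the three motif positions. A high MCC
on synthetic data therefore demonstrates that the machinery recovers
planted signal of the kind it models — not that it attains any particular
accuracy on real proteomes.

## Problem sizes and numerical choices

The shipped checks use synthetic proteomes of 100–250 proteins of 80–250
residues with elevated positive rates (0.18–0.35), sized so that several
hundred positives and a few dozen motif-conforming negatives exist — CY
negatives are intrinsically rare (a background lysine matches C1 about 2%
of the time), which is also why the clamp-with-warning rule matters in
practice. End-to-end recovery uses a 65/35 train/test split, 5 candidate
draws, and the 20-cycle protocol; the ablation comparison uses 10
generator seeds with single candidate draws and 5-cycle evaluation. Under
these conditions the strong-signal pipeline reaches mean MCC above 0.9,
the null pipeline stays within ±0.1 of zero, and the PTM-ablation
direction is recovered in 10 of 10 seeds (see `scripts/acceptance.R`,
which recomputes all of these from scratch).

Other fixed choices: seeds derive child seeds by a fixed affine map inside
the 32-bit range, so every stochastic step (generation, splits, draws,
fold assignment, forest fits) is reproducible from one master seed, and
identical seeds give byte-identical output files; mRMR ties break to the
lower feature index; model archives embed the encoding layout version and
the physicochemical-table hash and refuse to load across mismatches.
Output TSVs carry a header comment with package version, seed, and config
hash; FASTA files carry no header comment because the format has no
portable comment syntax.

## Limitations

Real-data performance depends entirely on the quality of the upstream
structure and PTM predictors and on annotation completeness; the
`negatives_rule` treats unannotated lysines in annotated proteins as true
negatives, which certainly mislabels some undiscovered sites. The WEKA-style
multi-algorithm sweep is not reproduced — the harness is
classifier-pluggable but ships only the random forest and the SVM. No
SUMO-interaction motifs are modelled, and no attempt is made to reproduce
published benchmark figures that depend on third-party databases and
trained models that are not redistributable.
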