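---
title: "Partner-aware interface prediction: models and methods"
author: "pairsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partner-aware interface prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pairsite)
```

## The problem

Most sequence-based predictors of protein–protein interaction sites score
each residue of a single chain for its propensity to sit in *some*
interface, ignoring the identity of the partner protein. `pairsite`
implements the partner-aware alternative: given the sequences of the two
sides of a complex (a "ligand" and a "receptor" in docking-benchmark
terminology, each possibly multi-chain), it scores every ligand × receptor
**residue pair** for being in contact, and compares this pair-trained
approach head to head against the conventional partner-unaware one.

The package covers the full experimental loop: contact labelling from bound
structures, pairing-propensity statistics, the two-stage neural-network
ensemble, pair↔single score conversions, per-complex leave-one-out
evaluation, and the use of prediction/contact agreement as a docking decoy
scoring function.

## Contact definition and data layout

A ligand residue and a receptor residue are **in contact** when the
distance between any atom of one and any atom of the other is ≤ 6.0 Å
(`extract_contacts()`). All (m₁+m₂+…) × (n₁+n₂+…) inter-side pairs of a
complex are labelled; pairs within one side are never considered. The
single-residue view pools all residues of both sides and marks a residue
positive when it participates in at least one contact
(`pool_single_residue_labels()`).

Parsing decisions for crystallographic input (PDB): only the first
alternate location is kept; insertion codes are folded into a sequential
1-based index per chain (window arithmetic requires gap-free indices, and a
`residue_map()` table preserves the author numbering); MSE/SEC/PYL are
mapped to their parent standard residues and other non-standard residues
are dropped with a warning; chain breaks are logged and the observed
residues treated as sequence-adjacent, since coordinates say nothing about
how many residues are missing.

## Pairing propensity statistics

For residue types *i, j*, the candidate-pair count accumulates
N_i(ligand)·N_j(receptor) per complex (both side assignments summed for
heterotypic pairs, homotypic counted once). With N_o total observed
contacts and Σ the total candidate pairs, the expected contacts are

> E_ij = pair_count_ij / Σ × N_o,

the propensity is P_ij = O_ij / E_ij, and significance is assessed by the
one-cell Pearson statistic χ² = (O−E)²/E against a 1-df chi-squared
distribution. Two numerical notes: (1) expectations are computed from the
pooled counts, which conserves Σ E_ij = N_o exactly; (2) the Pearson
denominator is E, the standard choice, which also reproduces published
interface-survey tables bundled with the package
(`benchmark_pair_counts()`) to their printed precision.

## Feature encoding

Each residue is encoded by up to three blocks (`feature_spec()`):

* **sparse window** — one-hot 20-vectors for the residue and its sequence
  neighbours within a window of width 0, 1, 3, 5 or 7;
* **PSSM window** — the corresponding rows of a PSI-BLAST position-specific
  scoring matrix, squashed to (0,1) by the logistic 1/(1+e⁻ˣ). The squash
  is an implementation choice (bounded inputs stabilise small-network
  training); the raw log-odds scale is available by transforming the
  profile before use;
* **chain composition** — the 20-dim amino-acid frequency vector of the
  whole chain, appended once per residue (on by default). The per-chain
  reading is the minimal definition of a "global composition" feature;
  per-complex pooling would blur the two sides.

A pair pattern concatenates the two residues' vectors **in both orders**
with the same 0/1 target, so the network can learn order invariance; at
prediction time the two orders are averaged, making the score exactly
symmetric. During training, positions whose largest window overruns a
chain terminus are excluded; at prediction time missing neighbour slots
are zero-padded instead, so score matrices are complete (downstream
conversions need every residue scored).

## The two-stage ensemble

Stage 1 is a grid of 24 models — all (sparse, PSSM) window combinations in
{0,1,3,5,7}² except the featureless (0,0) (`make_feature_grid()`). Each is
a single-hidden-layer feedforward network with logistic output trained on
0/1 targets. Because non-contacts outnumber contacts by two to three
orders of magnitude, each model trains on **all** positives plus an
independent random negative subsample of min(round(fraction·N), cap)
negatives, with fraction 0.02 and cap 1000 for pair training
(`sample_negatives()`). Single-residue training uses fraction √0.02 ≈ 0.14,
which gives comparable effective coverage at the pair level. Held-out data
are never subsampled. Stage 2 averages the 24 stage-1 scores.

Hyper-parameters the original two-stage design leaves open — hidden-layer
size, training algorithm, cycle count — are exposed in `network_params()`.
Defaults are 5 hidden units and up to 100 training cycles; the fit uses
`nnet` (quasi-Newton BFGS on least-squares loss; cross-entropy available),
the standard single-hidden-layer network in R. BFGS may converge before
the cycle limit, so `epochs` is an upper bound; determinism is guaranteed
by seeding the weight initialisation. Every stochastic step (negative
sampling, weight init) derives its seed from one base seed, so whole
ensembles and whole leave-one-out runs are bit-reproducible.

## Evaluation protocol

Leave-one-out over complexes (`loo_evaluate()`): for each complex, a full
ensemble is trained on all the others and evaluated on the held-out one;
per-complex AUCs are averaged unweighted. The tie-aware rank AUC counts
ties as ½, so a constant predictor scores exactly 0.5, and equals the
trapezoidal area under the ROC curve. Predictions are positive at
score ≥ threshold (the convention is fixed and documented). Complexes
whose held-out labels are single-class have no defined AUC and are dropped
from averages with a warning. Best-F1 operating points resolve ties toward
the lowest threshold. Two models are compared by a two-sided paired
Student's t-test over per-complex values; zero-variance differences are
flagged degenerate rather than silently producing a t statistic.

`loo_compare()` runs the pair-trained and single-trained ensembles on the
same benchmark and reports both tasks: pair prediction (single-trained
scores converted by averaging the two residues' scores,
`single_to_pairs()`) and single-residue prediction (pair-trained scores
converted by the max over a residue's pairs, `pairs_to_single()`).

## Decoy scoring

For a docking pose, the contact set implied by the pose is compared with
the predicted pair-score matrix: the AUC of predictions against pose
contacts is the pose score (`score_pose()`), poses are ranked by it, and a
weighted rank consensus with an external (energy-based) ranking uses 3:1
weights by default (`consensus_rank()`); weights (1,0) reproduce the
external ranking exactly. Hits are poses with native RMSD < 2.5 Å among
the top 2000 (`count_hits()`). Per-pose AUCs use all m×n pairs, including
terminal-padded ones, since prediction-time features are complete.

## The synthetic benchmark

Real benchmarks require curated bound structures and NR-derived PSSMs;
`generate_benchmark()` replaces them with a fully synthetic, self-contained
analogue whose ground truth is known:

* chains carry uniform random sequences and one dummy atom per residue;
* an interface of k one-to-one contact pairs is drawn with probability
  proportional to a planted type-pair multiplier map; geometry places
  contacting pairs at ≈5 Å and everything else beyond 8.5 Å, so the 6.0 Å
  extractor recovers the planted table exactly;
* synthetic PSSMs peak at the true residue (+7 log-odds) with Gaussian
  noise (σ = 2), emulating a conservation profile;
* decoy sets contain near-native poses (contact sets equal to the truth,
  RMSD < 2.5 Å) and shuffled decoys, with external ranks correlated with
  nativeness through a noisy pseudo-energy.

The default preference map plants a multiplier of 150 on six complementary
type pairings with disjoint types (D-R, E-K, W-Y, F-M, N-Q, S-T). Two
deliberate departures from realism deserve emphasis. First, the multiplier
is far above the 2–4× enrichments of real interface surveys: with six rare
pairings (~3% of candidate pairs) a multiplier of 150 is what makes
roughly three quarters of planted contacts carry the pairing signal, which
is what gives a benchmark of only 24 complexes enough signal to measure.
Second, the signal is purely *pair-typed*: because each hot type has
exactly one planted partner, single-residue identity is genuinely less
informative than pair identity — wrong pairings of hot types (D-K, E-R, …)
are frequent negatives that a partner-unaware model cannot demote. This is
the regime the partner-aware design targets, so passing the comparison on
this benchmark demonstrates the machinery and the direction of the effect,
not the effect size on real complexes. Real interfaces add spatial
clustering, non-uniform composition, evolutionary correlation between
partners and much weaker pair signals, none of which the generator
emulates.

A 3× planted enrichment is recovered by the propensity machinery within
sampling error, and with the planted signal removed the held-out pair AUC
collapses to ≈0.5 (see the test suite).

## Problem sizes and numerical choices

The shipped evaluation (acceptance script and test suite) uses 24
complexes of 1–2 chains per side with 16–24 residues per chain and 8–14
contacts each, and trains the full 24-model grid with 3 hidden units and a
40-cycle limit per network — a scale chosen so a complete double
leave-one-out comparison (48 ensembles, 1152 network fits) completes in
minutes on a single core while still separating the two training modes
clearly. The statistical comparison gains its power from pairing per-
complex AUCs, not from large per-network capacity.

Degenerate inputs are handled explicitly rather than silently: empty
negative pools warn and return empty samples; single-class training sets,
featureless specifications, infeasible planted interfaces and unscorable
poses (no contacts) are errors or flagged NAs; AUC ties and best-F1 ties
have fixed, documented conventions.

## Known limitations

* Absolute AUC levels on the synthetic benchmark are not comparable to any
  real-data benchmark; only the within-benchmark contrast between training
  modes is meaningful.
* The predictor is sequence-only; no accessibility, secondary structure or
  docking-energetic features are used, and no repulsive term exists in the
  decoy score.
* PSSMs are consumed, not produced: the PSI-BLAST ASCII dialect is read,
  but running the profile search is out of scope.
* The partner-specific site report ("common" predictions shared by ≥ 2
  partners) uses top-k intersection with k = 30 by default; a
  threshold-based definition would be an alternative reading.
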