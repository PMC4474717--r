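---
title: "Predicting intrinsically disordered regions with conservation profiles and a CRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intrinsically disordered regions with conservation profiles and a CRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intrinsically disordered regions (IDRs) are stretches of a protein chain
that do not adopt a stable tertiary structure. Operationally, a residue is
*disordered* when its backbone C-alpha atom is missing from the deposited
crystal structure, and *ordered* otherwise. Disorder is rare (roughly 5% of
residues in structure-derived datasets) and concentrates at chain termini
and in short internal segments, which makes per-residue prediction a
heavily imbalanced sequence-labeling problem in which most errors cluster
at order/disorder boundaries.

`idrcrf` addresses both difficulties with a three-state label alphabet and
a conservation-based feature:

* **Near-disorder (`N`)**: the `K` residues at each terminus of every
  ordered region are relabeled from `O` to `N` (default `K = 5`,
  `add_near_disorder()`). A maximal ordered run of length `m > 2K` keeps
  its interior `O`; a run with `m <= 2K` becomes entirely `N`, the
  symmetric choice that avoids ambiguous partial overlap of the two
  termini. The rule applies at every run terminus, including runs abutting
  the chain ends. `D` residues are never touched. Near-disorder softens the
  class imbalance and gives the decision layer a probability to threshold
  exactly where boundary errors live. It is a training and inference
  device only: ground truth for every evaluation in this package remains
  the original two-state annotation.

* **Multi-class conservation score (MCS)**: for a query, local-alignment
  hits against a knowledge database of `{O,N,D}`-annotated sequences
  ("MCSbase") are filtered to e-value strictly below a threshold (default
  10), ranked ascending, and truncated to the top `S` (default 10). Each
  selected hit projects its subject's state onto every query position it
  covers (gap columns advance one cursor and contribute nothing); the three
  per-position tallies are normalized to a probability triplet. Covered
  rows sum to one by construction.

## The model

The tagger is a linear-chain conditional random field over `(O, N, D)`.
Each residue carries 12 features: the 3 MCS probabilities and a 9-column
one-hot encoding of externally predicted secondary structure (eight
DSSP-style states plus `-` for "no prediction"; only the cardinality and
ordering of the alphabet are load-bearing, the predictor is pluggable).
State potentials are linear in a windowed expansion of these features: each
column is replicated at offsets `-4..+4` (four upward and four downward
neighbours plus the position itself) with zero padding outside the chain,
plus a constant bias, giving `12 x 9 + 1 = 109` inputs per label. A
`3 x 3` transition matrix couples neighbouring labels. Because the features
are probabilities rather than discrete tokens, potentials are
`weight x value` — the continuous analogue of token-indicator unigram
templates; transitions carry no feature conditioning.

Training maximizes the L2-penalized conditional log-likelihood

$$\sum_i \log P(y_i \mid x_i) \;-\; \frac{\lVert w \rVert^2}{2\sigma^2},
\qquad \sigma^2 = 10 \text{ by default},$$

with L-BFGS and the analytic gradient (observed minus expected feature
counts; expectations and the partition function come from a log-domain
forward–backward recursion). Weights start at zero, so the fit is fully
deterministic; the `seed` argument is recorded for provenance but cannot
influence the optimum. `max_iter = 0` returns the zero-weight model, a
useful null. Convergence uses a relative objective tolerance
(`tol = 1e-6`).

Inference offers exact posterior marginals (`predict(fit, type =
"marginal")`), MAP decoding (`type = "viterbi"`, ties broken toward the
label earlier in `(O, N, D)` order so the all-zero model decodes to the
majority class deterministically), and exact posterior path sampling
(`simulate()`).

```{r}
library(idrcrf)
corp <- generate_corpus(synth_config(seed = 1))
paths <- write_corpus(corp, "corpus")
fit <- run_train(paths["queries"], paths["truth"], paths["mcsbase"],
                 paths["ss"], paths["hits"], model_out = "model.json")
summary(fit)
```

## Decision schemes

Both schemes reduce the three-class posterior of a residue to a binary
order/disorder call; they are alternatives, never composed:

* **Scheme I** (`apply_scheme_I()`): disorder if the base three-state call
  (argmax of the marginals, ties toward `D` then `N`) is `D`, or if the
  call is not `D` but the near-disorder posterior exceeds `tau` (default
  0.4). This reclaims boundary residues without eroding specificity.
* **Scheme II** (`apply_scheme_II()`): disorder if the disorder posterior
  exceeds `tau` (default 0.03 — small because disorder is rare). Sweeping
  `tau` traces the ROC of the disorder posterior.

Both comparisons are strict (`>`), so `tau = 1` yields no calls and scheme
II with `tau = 0` fires wherever the posterior is positive. The base
determination deliberately uses marginals rather than the Viterbi path:
both schemes threshold marginal probabilities, and keeping a single
probability object per residue makes the two rules commensurable. The
default thresholds are the calibration operating points reported for this
architecture; `sweep_threshold()` recomputes the weighted-score-maximizing
grid point (ties to the smallest `tau`, default grid 0 to 1 by 0.01) for
any corpus.

## Evaluation

Disorder is the positive class and truth is always two-state. The measure
set: sensitivity `Sn`, specificity `Sp`, balanced accuracy
`ACC = (Sn + Sp)/2` (all percent), Matthews correlation, the weighted
score

$$S_w = \frac{W_d\,TP - W_o\,FP + W_o\,TN - W_d\,FN}{W_d N_d + W_o N_o},$$

with `W_d` the *ordered* fraction and `W_o` the *disordered* fraction — an
assignment that weights each class by the other's prevalence and makes
`Sw = Sn + Sp - 100` exactly (the test suite verifies the identity on
1,000 random tables), and a tie-corrected rank AUC (equal to brute-force
disorder/order pair counting, also verified). An MCC whose denominator has
a zero factor is reported as 0 with an `undefined` attribute so reports
stay numeric. Standard errors resample *chains*, not residues: each of
1,000 replicates draws 80% of the chains without replacement, pools their
residues, and recomputes the measure.

## The synthetic corpus

`generate_corpus()` produces everything the pipeline consumes, with no
external data: chains, a homolog database, secondary structure and
alignment hits, byte-identical for a fixed `(config, seed)`.

* **Chains** (default 80–300 residues): disordered segments of geometric
  mean length 8 sit at each terminus with probability 0.6 and start
  internally at rate 8e-4 per residue; with these settings the pooled
  disordered fraction lands near the 5% target (the suite checks
  [3%, 7%] over 200 chains). Disordered positions draw amino acids from a
  table enriched in P, E, S, K, G, Q and depleted in W, C, F, I, Y, V,
  mirroring the low hydrophobicity of real IDRs; ordered positions use
  background frequencies.
* **Homolog families** (default 15 per chain): per-residue substitutions
  (0.15), rare single-residue indels (0.01) and per-residue label noise
  (0.05) applied to a copy of the parent's three-stated annotation. Noise
  acts on the three-state copy so that each corrupted label has a
  one-residue footprint; corrupting the two-state labels and re-deriving
  near-disorder would let a single flip rewrite up to `2K + 1` positions,
  destroying the family majority signal the conservation score depends
  on. Indels are kept rare so labels transfer positionally.
* **Secondary structure**: ordered runs emit H/E/T blocks, disordered
  residues emit `-` or C, and each symbol is replaced by a uniformly
  random alphabet symbol with probability 0.2.
* **Aligner**: `toy_align()` performs local alignment (match +2, mismatch
  −1, affine gaps: 5 for a one-residue gap, +1 per additional residue) via
  `Biostrings::pairwiseAlignment`, one best hit per subject, with a cheap
  score-only pass over the whole database before full traceback of
  passing subjects. Scores at or below 10 are dropped. The pseudo e-value
  `m n 2^{-score/4}` is a simplified Karlin–Altschul form: downstream
  selection only uses its ordering, which is monotone in score.

What the corpus does *not* emulate: realistic substitution matrices,
domain architecture, repeats and low-complexity sequence, alignment errors
from distant homology, and correlated annotation errors between database
records. Passing the end-to-end suite therefore demonstrates that the
machinery is correct and that the model recovers a strong homology signal;
it says nothing about accuracy on real proteins, which depends on the
quality and coverage of a real knowledge database and secondary-structure
predictor. In production the hits come from PSI-BLAST tabular output
(`-outfmt "6 qseqid sseqid evalue qstart qend sstart send qseq sseq"`,
documented external run: six iterations, 500 maximum target sequences)
via the same parser the synthetic corpus exercises.

## Numerical and design notes

* All chain recursions run in log space; the backward recursion recomputes
  `log Z` independently and the suite asserts agreement with the forward
  value and with exhaustive `3^L` enumeration for `L <= 6`.
* Query positions covered by no hit emit `(0, 0, 0)` rather than uniform
  `1/3`: the CRF can then distinguish "no homology evidence" from
  "uniform evidence", and the zero-padding of windowed features outside
  the chain carries the same "no observation" semantics.
* Each high-scoring segment pair counts as one matched sequence; several
  HSPs of one subject may all enter the top `S`. E-value ties break by
  `(subject_id, query_start)` for a platform-stable top-`S`.
* The fairness rule (`exclude_matches()`) removes database records whose
  full sequence equals a query's, case-insensitively, with no similarity
  threshold; hits pointing at removed records are dropped with them.
* Model files are versioned JSON with weights printed at 17 significant
  digits, giving bit-exact round trips.
* Test and acceptance problem sizes: property suites use 1,000 random
  confusion tables, 100 random chains of length ≤ 6 against the
  enumeration oracle, and finite-difference gradient checks on ~30-40
  parameters; the end-to-end runs use 20 synthetic families (about 3,700
  residues) for acceptance and 6 families for the pipeline unit tests —
  sizes at which the homology signal is already decisive.

## Limitations

* Prediction quality is bounded by homology coverage: a query with no
  database hits is classified from secondary structure alone.
* The CRF uses unigram feature templates plus label-pair transitions only;
  no bigram feature conditioning or semi-Markov segment modeling.
* The near-disorder width `K` is global; real boundary uncertainty varies
  with resolution and crystal contacts.
* Per-class three-state evaluation is out of scope: predicted `N` is
  always resolved to a binary call before scoring.
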