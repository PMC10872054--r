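---
title: "Reduced amino-acid alphabets: models, scoring, and design notes"
author: "redalph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced amino-acid alphabets: models, scoring, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redalph)
```

This vignette is the package's own account of its methods: the models
and statistics it implements, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the design
decisions taken where more than one reasonable reading existed.

## Alphabets and translation

A reduced amino-acid alphabet is an ordered partition of the 20
standard residue letters into K clusters. The unknown residue `X` is
never a cluster member: it is a reserved 21st symbol, so a K-cluster
alphabet induces a token vocabulary of size K + 1, with clusters
numbered `0..K-1` in listed order and the unknown token at index K.
That convention keeps token ids stable across runs and makes the full
alphabet (UNIPROT20) a strict identity encoding.

Nine published alphabets are bundled. Their names end in the cluster
count, and the parser checks that any user-supplied alphabet whose name
ends in digits is consistent with its own cluster count, warning (not
silently fixing) on mismatch. All nine bundled definitions parse
cleanly, partition exactly 20 letters, and match their numeric
suffixes, WASS14's fourteen clusters included.

Raw sequences are first normalized to the 21-letter vocabulary:
selenocysteine `U` becomes `C`, pyrrolysine `O` becomes `K`, and the
ambiguity codes `B` and `Z` join `X` as unknown. Anything else is an
error that names the offending character and position — silent
coercion of malformed input is worse than failure.

Translation has two modes with different consumers:

* **Token compression** (`tokenize()`) maps each residue to its 0-based
  cluster index; this is what the language model consumes.
* **Representative substitution** (`to_representative_sequence()`)
  replaces every residue by one member letter of its cluster, held
  fixed along the sequence, producing a real amino-acid sequence a
  folding model can accept. The deterministic default (`fixed_first`)
  uses each cluster's first listed letter; `seeded_random` draws one
  member per cluster reproducibly; `explicit` takes a user assignment
  (validated for membership); `per_position_random` draws independently
  at every position, the stochastic variant of the same encoding
  family. `enumerate_representative_assignments()` walks the full
  Cartesian product of per-cluster choices (the product of cluster
  sizes; 81 for GBMR4) in deterministic lexicographic order under a cap.

Both modes preserve length, and representative substitution never
changes cluster identity — `tokenize()` after translation equals
`tokenize()` of the original. These two invariants are property-tested
across all nine alphabets.

Sequence fidelity after translation is summarized per position — no
alignment is performed, since translation is length-preserving and
introducing an aligner would add parameters the analysis does not need.
Identity is the percentage of unchanged letters; similarity is the
percentage of positions whose BLOSUM62 entry is strictly positive (the
EMBOSS convention; the rule is recorded in the output so users can
recompute under a different threshold). Positions involving `X` stay in
the denominator and score through the matrix's `X` row. The bundled
matrix is the canonical NCBI BLOSUM62, shipped as a plain-text file for
bit-exact offline reproducibility; note that different software
distributions disagree slightly in the ambiguity rows (B/Z/X), which is
why the test suite cross-checks only the 20 standard residues against
an independent copy.

## Mutation distinguishability

An alphabet fails to capture a substitution when the wild-type and
variant residues share a cluster: both sequences encode identically, so
no model downstream of the encoding can tell them apart. The error rate
of an alphabet on a substitution set is the percentage of such missed
pairs. Substitutions are counted with multiplicity as they occur in the
variant set, which weighs recurrent mutations the way they occur in a
screening dataset; `unique_pairs = TRUE` deduplicates to unique letter
pairs for the complementary reading, since the choice between the two
conventions is not forced by the definition. Indels are rejected (the
statistic is defined for substitutions), and positions involving `X`
are skipped and tallied.

Two analytic anchors pin the scale: the full alphabet's error rate is
identically 0 and a single-cluster alphabet's is identically 100. A
property test further checks coarsening monotonicity: merging any two
clusters can only keep or enlarge the set of missed pairs.

## The masked language model

The encoder is a three-layer bidirectional LSTM over token embeddings
with a per-position softmax head — deliberately small enough that many
variants can be trained, yet expressive enough to pick up contextual
structure. Two presets exist: `desk` (embedding 32, hidden 64 per
direction; ~250k parameters) for interactive use and testing, and
`paper` (embedding 512, hidden 512 per direction) at the ~14M-parameter
scale of a serious pretraining run. The realized parameter count is
printed at training start, since a stated total is only meaningful
jointly with the architecture.

**Corruption scheme.** There is no designated mask token. Each
non-unknown position is selected independently with probability 0.10;
selected tokens are replaced by draws from a background distribution
(the corpus' empirical token frequencies with the unknown token's mass
forced to zero), renormalized to exclude the original token — the
replacement is a *different* residue. A flag allows self-replacement
for users who read the scheme more loosely, and an `exact_count` option
selects exactly ⌊0.1·L⌋ positions for those who prefer fixed-budget
masking; Bernoulli selection is the default because independence per
position is the simpler null model and the realized fraction
concentrates tightly at scale. Unknown positions are never selected and
never contribute to the loss: `X` carries no evolutionary signal, and
predicting it would distort perplexity. The draw order is fixed and
documented (per sequence: one uniform per position, then one
categorical draw per selected position), so a replay with the same seed
reproduces the corruption exactly — this is tested against an
independent re-implementation.

**Training.** Adam with library-default moments, cross-entropy on
masked positions only, and a learning rate decaying linearly to a tenth
of its initial value at `max_steps`. The "decay to a tenth" is read as
a learning-rate schedule, since that is what the recipe's sentence
modifies; a literal L2 weight-decay switch exists for the other
reading. The reference pretraining rate is 2e-4, tuned for very long
large-batch runs; the desk preset uses 1e-3 for its 2000-step,
batch-16 schedule, the standard proportional adjustment when the step
budget shrinks by two orders of magnitude. Sequences are right-padded
to the batch maximum and padding is excluded from masking, loss, and
pooling via a validity mask; the recurrent state is reset across
padding so the reversed direction sees exactly the sequence it would
see unpadded (a property the tests check bit-for-bit). All randomness
flows from one run seed through named sub-streams (split, init,
shuffling, per-step masking), so identical seeds give identical loss
traces. Training aborts with a diagnostic on non-finite loss. The
sequential recurrence is compiled (Rcpp/RcppArmadillo); the input
projections and weight-gradient contractions are single BLAS calls, and
the backward pass is verified against central finite differences.

**Scoring.** Perplexity is the exponential of the mean negative
log-likelihood per masked token, estimated over `n_draws` random mask
sets; the mean is taken before exponentiating (the printed definition
leaves the average implicit, and the mean reading is the one consistent
with pseudo-perplexity and with the uniform-model limit equal to the
vocabulary size). A Monte-Carlo standard error accompanies the
estimate. Pseudo-perplexity scores each position conditioned on all
others with one corruption per position; because the scheme has no mask
token, the per-position conditional is computed by marginalizing the
model's prediction at position i over background replacement tokens
r ≠ x_i. That marginalization is what makes the measure fully
deterministic — repeated calls agree bit for bit, which the acceptance
suite asserts. Unknown positions are skipped, mirroring their exclusion
from the training loss.

**Embedding trajectories.** Snapshots of the embedding matrix are taken
every `checkpoint_every` steps and projected by per-snapshot PCA
(centered, unscaled). Principal axes are defined only up to sign, so
consecutive snapshots are sign-aligned by coordinate correlation to
keep token trajectories visually continuous; explained-variance
fractions are reported per snapshot. The projection is tested against a
direct covariance eigendecomposition.

**Downstream head.** A learned attention pooling (softmax-normalized
scores over valid positions; equal scores reduce to the arithmetic
mean) followed by an MLP with one hidden layer maps per-position
encoder outputs to classes or a regression output, trained full-batch
with Adam and early stopping on a validation split. The encoder is kept
frozen: at desk scale the handful of head epochs would move the encoder
negligibly, and freezing keeps the head's behaviour attributable.
Accuracy (classification) and Pearson correlation (regression) are the
reported metrics, matching the conventions of the benchmark tasks this
head mirrors.

## LDDT-Cα

The local distance difference test on Cα traces is superposition-free:
the reference defines the set of residue pairs with Cα–Cα distance
below the 15 Å inclusion radius, and a pair is preserved at threshold
t ∈ {0.5, 1, 2, 4} Å if the model reproduces its distance within t.
The global score is the mean preserved fraction over thresholds on a
0–100 scale; the per-residue profile applies the same rule to the pairs
touching each residue. These parameter values follow the test's
standard definition and are overridable. Scoring is Cα-only — no
stereochemistry checks — and pairs touching residues absent from the
model count as not preserved, so incomplete models are penalized rather
than silently rescored on their covered region.

Residue matching is by author residue number plus insertion code, the
target/model convention of blind-prediction assessment, not by sequence
alignment; a mismatch count is reported. Domain cropping retains
residues inside inclusive author-numbered intervals; when a cropped
pair is scored, the inclusion pair set is recomputed on the crop (the
alternative — restricting the full-trace pair set — differs for pairs
that straddle the crop boundary, and recomputing is the convention that
matches scoring a domain as its own target). The implementation is
tested bit-for-bit against a brute-force loop over all pairs and
thresholds on dozens of random instances, and for exact invariance
under rigid rotation + translation.

`compare_alphabet_predictions()` tabulates per-target scores for
predictions made from differently encoded sequences against the
full-alphabet baseline, with the improvement flag at a configurable
margin (default 1 LDDT point). Both per-alphabet deltas and the
best-over-alphabets row are reported, so either aggregation of
"improved by a reduced alphabet" can be recovered.

## Synthetic data: what it does and does not emulate

The generators make every analysis runnable offline and define the
package's standard study conditions:

* **Corpora** (`corpus_spec()`): iid residues from a bundled average
  amino-acid composition (a published knowledgebase-wide frequency
  table, normalized at load), uniform lengths, and an optional motif
  planted verbatim at a random offset. The defaults — 5000 sequences,
  lengths 30–50, a 16-residue motif in every sequence — are the
  package's standard desk-scale training corpus: the motif gives a
  bidirectional model genuinely learnable context (inside the motif the
  next residue is near-deterministic given its neighbours), while the
  background tests that the model at least recovers the unigram
  distribution. What this corpus does *not* emulate: long-range
  covariation between contacting residues, domain structure, length
  distributions of real proteins, or homology between sequences. A
  model that halves its held-out perplexity here has demonstrably
  learned context, but nothing about its performance on real
  evolutionary data follows.
* **Variant sets** (`generate_variant_set()`): a wild type from the
  same composition with variants at exact Hamming distance k and
  substitute letters uniform over the other 19. Real mutational scans
  have strongly non-uniform substitution spectra; the uniform choice
  makes the error-rate statistic's expectation a pure function of the
  alphabet's cluster-size profile, which is the property under test.
* **Structures** (`structure_spec()`): ideal α-helical Cα traces
  (1.5 Å rise, 2.3 Å radius, 100° turn per residue) perturbed by
  isotropic Gaussian noise, optionally rigidly transformed. A helix is
  chosen over a random coil so the 15 Å inclusion radius yields a
  nontrivial pair set at 10–30 residues. Noise of growing scale gives
  strictly decreasing mean scores over replicates, which is the
  monotonicity the tests exercise; real prediction errors (hinge
  motions, register shifts, locally correct but globally misassembled
  domains) are not modelled.

All generators are seed-deterministic, byte-for-byte, via integer
sub-streams derived from the run seed.

## Numerical choices and problem sizes

* Perplexity of an exactly uniform model equals the vocabulary size to
  within 1e-9; this and the perfect-recall limit of 1 are asserted as
  floating-point checks, not approximations.
* The LSTM gradient check uses central differences at 1e-6 with a
  1e-4 relative tolerance, on a 2-layer desk-width-divided model small
  enough for the finite-difference loss to be smooth.
* The test and acceptance suites use these problem sizes: the 10%
  masking fraction is measured over 10^6 positions (1000 × 1000);
  LDDT-Cα oracle agreement over 50 random instances of up to 20
  residues; the training check runs the standard 5000-sequence corpus
  for the full 2000-step desk schedule (a few minutes on one CPU);
  everything else is sub-second.
* Ties in altloc occupancy resolve to file order; PCA sign alignment
  leaves the first snapshot's orientation as computed; the learning
  rate at step t is `lr · (1 − 0.9 t / max_steps)`, hitting exactly
  lr/10 at the final step.

## Known limitations

* The language model is a desk-scale instrument. It demonstrates the
  corruption scheme, the scoring definitions, and trainability; it is
  not a substitute for a pretrained protein language model, and no
  claim about real downstream benchmarks follows from its numbers.
* Encoder fine-tuning during downstream training is not implemented
  (the head trains on frozen features).
* `read_ca_trace()` handles single chains; multi-chain scoring means
  one call per chain.
* Pseudo-perplexity costs L × (V−1) forward passes per sequence
  (batched internally); for long sequences and the full alphabet this
  is the dominant scoring cost.
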