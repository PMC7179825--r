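---
title: "The encoder layer: model, training schedule, and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The encoder layer: model, training schedule, and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`elgram` simulates a cortical patch — the *encoder layer* (EL) — as a grid
of cortical columns, each a two-dimensional lattice of neural units. Every
word of a sentence is one *event*; the layer's response to it is decided by
three input streams:

* **Proximal afferent dendrites** carry distributional-semantic word
  embeddings. Each column samples a fixed random subset of embedding
  components from a rectangular receptive field over the embedding grid
  (9 × 29 of a 10 × 30 grid, 31 components, in the default architecture)
  and models its afferent dendrite as a self-organizing map (SOM): unit
  excitation is the negated Euclidean distance between the sampled input
  and the unit's weight vector. The afferent stream *excites a cluster* of
  `floor(excited_fraction × units)` units per column (22 of 225 by
  default) — a set of plausible lexical hypotheses, not a single winner.
* **Distal dendrites** do not excite; they *partially depolarize*. Each
  unit owns one dendritic branch per linked source column, with
  `synapses_per_branch` (6) weighted *potential synapses* onto random
  units of that column. A branch spikes when at least `branch_threshold`
  of its synapses are simultaneously *established* (weight ≥ 0.5) and
  presynaptically active; branches are independent — active synapses are
  never summed across branches. A unit with any spiking branch is
  *predicted*. Lateral branches listen to the EL's own previous
  activation (sequence context); apical branches listen to a fictitious
  foreign layer broadcasting one of three fixed coarse word-category SDRs
  (content / function / verb), the minimal category signal infants are
  thought to derive from phonology.
* **Inhibition** resolves the event: within each column, predicted units
  that are also excited fire first and shut down their rivals — at most
  `winners_per_cc` (2) units, ranked by (best-branch overlap, afferent
  excitation, lowest unit id). If fewer than `sdr_min_predicted` (1)
  excited units are predicted, the whole excited cluster fires: a
  *massive firing event* (MFE), the layer's prediction-failure signal.

Learning couples the streams: the SOM moves towards each sampled input
(Kohonen rule, Gaussian lattice neighborhood); distal synapses follow an
STDP-like rule — synapses onto firing units potentiate
(`w ← w + lr(1 − w)`) when their presynaptic unit fired at the previous
event, and depress (`w ← w(1 − lr)`) when it fires only simultaneously.
A presynaptic unit active at both times potentiates (past-pairing wins).
Weak synapses (`w < 0.1`) are zeroed every 1,000 learning steps
(homeostatic pruning); the potential slot persists and may relearn.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `excited_fraction` | 0.10 | fraction of units | size of the afferent hypothesis set; 22 of 225 units |
| `winners_per_cc` | 2 | units | SDR sparsity (99% at the default lattice) |
| `branch_threshold` | 1 | synapses | branches hold 6 potential synapses and source columns only 2 active units, so higher thresholds essentially never spike before learning concentrates weight |
| `established_threshold` | 0.5 | weight | boundary between potential and functional synapses |
| `prune_floor`, `prune_period` | 0.1, 1000 | weight, words | homeostatic removal of never-reinforced weights |
| `excitation_beta` | rule-derived | — | temperature of stochastic excited-cluster selection (below) |
| `apical_timing` | `"current"` | — | the category SDR of the *current* word drives apical predictions (the category cue precedes lexical resolution); `"previous"` is available |

**Stochastic excitation.** Afferent excitation biases but does not fully
determine cluster membership: units enter the excited cluster by weighted
sampling without replacement with weights
`exp(β · (e − max e) / sd(e))`. Standardizing by `sd(e)` makes the
temperature scale-invariant; on unit-variance excitation profiles the
expression reduces to the plain `exp(β (e − max e))` form, and that is the
regime in which β is calibrated: the default is the smallest integer for
which the top decile of units carries at least 90% of the total sampling
weight on unit-variance Gaussian profiles at the configured lattice size
(β = 3 for 15 × 15 units, β = 4 for 7 × 7). Stochastic selection is on in
both training and inference; a deterministic top-k mode exists for oracle
tests.

**Initial distal weights** are uniform on `[0, established_threshold/2)`.
The upper bound matters: had initial weights reached up to the established
threshold, a single potentiation event would establish some synapses and
the very first training pass would already be predictive. With the halved
range and the stage-1 learning rate of 0.3, establishment requires at
least two pairings of the same presynaptic/postsynaptic units
(0.25 + 0.3 × 0.75 = 0.475 < 0.5), so established connections always
reflect *repeated* structure, and an untrained layer answers every word
with a full massive firing event.

**Training schedule.** Three stages over the same corpus: two passes with
SOM rate 0.1 → 0.01, neighborhood radius half the lattice width → 1.0 and
distal rate 0.3 → 0.15; two passes at 0.05 → 0.005, 2.0 → 0.5,
0.15 → 0.05; one final pass with everything held at the stage-2 final
values. Within a stage every parameter decays geometrically per word
event. The distal rates are the package's choice (tied to the two-pairing
establishment argument above); the SOM shape follows common SOM practice.
Lateral context is reset at each sentence start; sentence order is as
given (no shuffling), and out-of-vocabulary tokens are skipped and
counted (a zero-vector policy is available).

## The synthetic data generator

Real inputs (large pretrained embeddings, a parsed corpus) are supported
through the word2vec and tag-file readers, but the package ships a
generator that reproduces the *statistical structure the model exploits*
while staying self-contained:

* Semantic classes are centroids on the unit sphere, kept at pairwise
  distance ≥ 4 × the within-class noise sd (0.2 by default); a word
  embedding is its class (or sense-mixture) centroid plus Gaussian noise.
  Defaults (60 nouns, 36 verbs, 18 adjectives, 12 adverbs over 4 + 4 + 2 + 1
  families, plus number-marked determiners, pronouns, prepositions,
  conjunctions, modals) give a token/type ratio of ~14 on the default
  600-sentence corpus — the regime of natural pre-cleaned text.
* Ambiguity is deliberate and mirrors what distributional vectors lose:
  singular/plural noun surfaces share an identical embedding; a verb's
  base and 3rd-person forms share one; 35% of noun lexemes are noun/verb
  homographs whose surfaces carry senses in different coarse categories.
  Tags remain fully determined by (embedding, coarse category, left
  context): determiners and pronouns are always number-marked, agreement
  is enforced (NNS subjects take VBP, NN subjects VBZ), and modals and
  the infinitival marker are always followed by the base form.
* A probabilistic template grammar (`S → NP VP [PP]`, optional
  coordination, adjectives and adverbs, modal/infinitive/past
  alternatives) emits aligned tokens, fine tags and coarse categories.

What the generator does *not* emulate: natural lexical frequency laws
(Zipfian tails), long-distance dependencies beyond the clause, punctuation
and morphology, and the 113-tag granularity of a full parser. Passing
tests on synthetic data therefore demonstrate the *mechanism* — that
fusing sequence context and coarse categories with embeddings recovers
context-dependent tags that embeddings alone cannot — not performance on
any natural corpus.

## Evaluation protocol

Features for classification are flattened binary activation vectors
(active unit → 1) from the EL run in inference mode (weights frozen —
checkpoints hash identically before and after). The classifier is a
linear-kernel SVM (libsvm through e1071) with its cost parameter swept
over `2^{-5, -3, …, 5}`, each candidate scored by five-fold
cross-validated accuracy and the winner refit with pairwise-coupling
probability estimates. Sources are compared per held-out corpus with
two-tailed paired t-tests over the per-corpus accuracies,
Holm–Bonferroni-corrected with factor 3 (the generalised step-down:
the i-th smallest p multiplied by `factor − i + 1`, running maximum,
capped at 1). Per-tag accuracies are disaggregated on the pooled test
predictions, with tags under 10 test occurrences flagged as low-support.

The desk-scale experiment (`el_benchmark()`) uses the scaled
configuration — 5 × 5 columns of 7 × 7 units, 30-component embeddings on
a 5 × 6 grid, proportionally scaled receptive fields — with 600 training
sentences, 10 held-out corpora of 150 sentences and 10 encoder seeds;
one full and one separately trained stripped-lateral encoder per seed.
Problem sizes were chosen so the full experiment runs on a single CPU in
minutes while keeping every mechanism of the full architecture. Two
protocol choices at this scale: the C sweep runs once per feature source
on a stratified subsample of at most 1,500 training tokens and the chosen
C is reused across encoder seeds (the hyperparameter belongs to the
feature type, not the seed); final models are always refit on the full
training features.

## Numerical choices and degenerate inputs

* BMU and top-k ties break towards the lowest unit index; SDR winner
  ranking is (branch overlap, excitation, lowest id) — all deterministic.
* Receptive-field windows wrap toroidally when enabled; a window larger
  than a (toroidal) grid collapses duplicate positions, and a window
  leaving a non-toroidal grid is a configuration error.
* `decay_schedule(a, b, s, 0)` returns `a`; zero-variance excitation
  profiles fall back to uniform sampling; zero-variance paired
  differences return exact p = 1 at mean 0 and a degenerate flag
  otherwise; single-class classification input is an error, classes with
  fewer examples than folds are dropped with a warning.
* All randomness flows through named sub-seeds derived from one run seed
  (`derive_seed()`), so any run is exactly reproducible and adding a new
  random consumer never perturbs existing ones.

## Known limitations

* **Distal sparseness at desk scale.** After full training plus pruning,
  the fraction of non-established potential synapses is about 0.89 for
  the apical table but only ~0.5 for the lateral table (~0.70 overall)
  at the scaled geometry, versus the >0.90 regime expected of the full
  architecture. This is a density effect, not a mechanism difference:
  scaled SDRs activate 2 of 49 units per column (4.1%) against 2 of 225
  (0.9%) at full size, and the recurrence probability of a specific
  presynaptic/postsynaptic pair grows with the square of that density,
  while the past-pairing-wins rule shields persistently active
  presynaptic units from depression. The package reports the honestly
  measured scaled value.
* The model has no backward connectivity into the embedding or category
  layers, no structural plasticity (the potential-synapse pool is fixed
  at initialization), and no batch or growing SOM variants.
* Homograph resolution depends on the category SDRs being supplied at
  inference; with them withheld (or the apical pathway removed) the
  layer degrades to afferent-plus-sequence behaviour.
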