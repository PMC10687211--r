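---
title: "Generative pretraining for longitudinal diagnosis-code sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative pretraining for longitudinal diagnosis-code sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nextvisit)
```

## The problem

A longitudinal electronic health record is, for modelling purposes, a
date-ordered sequence of visits, each visit a priority-ordered list of
diagnosis codes (the primary diagnosis first), attached to a small block of
demographics (gender, age, race, marital status). Clinical risk prediction
from such records is dominated by two facts: outcomes of interest are rare
(a percent or two of patients), and codes are heavily correlated — chronic
conditions recur visit after visit, comorbidities cluster, and some
conditions foreshadow others.

`nextvisit` implements a generative encoder-decoder transformer for these
sequences, pretrained with a *visit-masking* objective: the model sees a
patient's demographics and visits up to some point and must generate the
complete, priority-ordered code set of the *next* visit. The conventional
alternative — an encoder-only model trained to reconstruct a random 25% of
individually masked codes — is implemented as the baseline, and the package
ships the training, evaluation and synthetic-cohort machinery needed to
compare the two designs end to end on a single CPU.

## Input representation

Each patient becomes a token sequence: four demographic tokens
(`gender=male`, `age=50-59`, ...; ages are decade-binned so the vocabulary
stays bounded) followed by the codes of each visit. Every token carries
three features that are summed in the embedding layer:

* a learned **code embedding** (the token identity);
* a learned **visit-index embedding** — all tokens of one visit share an
  index (1, 2, ...); the demographics block has index 0;
* a sinusoidal **time embedding** of the visit's time value.

Two time conventions are supported. `date` feeds days since 1970-01-01
through the standard sinusoidal formula; `daysdiff` (the default) instead
uses the number of days between the visit and the most recent context
visit, so the representation carries no absolute dates — a deliberate
privacy property. A direct consequence, asserted in the test suite, is that
every `daysdiff` pipeline output is invariant under shifting all of a
patient's dates by a constant.

There is no intra-visit positional term in the encoder: within a visit,
order is conveyed to the *decoder* only, as the order in which target codes
are generated. The alternative (a within-visit position embedding) would
presume that encoder-side priority order carries signal beyond what code
identity provides; we keep the encoder permutation-invariant within visits.

Sequences are capped at 512 tokens. Truncation drops the oldest clinical
tokens first and always retains the demographics block; surviving tokens
keep their order.

## Pretraining objectives

An n-visit patient expands recursively into n−1 instances: visits 1..k
predict visit k+1, for k = 1..n−1.

**Visit masking** (the focal objective): the target visit is withheld from
the encoder entirely; the decoder, attending to the encoder states through
cross-attention, generates the target visit's codes autoregressively in
priority order (BOS → primary diagnosis → secondary → ... → EOS). During
pretraining each remaining context visit is additionally dropped with
probability 0.15 (at least one always survives) to discourage memorization;
surviving visits are re-indexed compactly 1..k — the alternative of keeping
original indices would leak how many visits were dropped.

**Code masking** (the baseline objective): each code token is independently
replaced by `[MASK]` with probability 0.25. In the encoder-decoder
architecture the decoder is trained to emit the masked codes in their
original order (so the two objectives are comparable inside the same
architecture); in the encoder-only architecture the model predicts each
masked code from its contextual state (a masked LM). Selection is resampled
if it comes up empty, so every instance has at least one prediction target.

## Architecture

Pre-layer-norm transformer blocks with multi-head attention and ReLU
feed-forward layers; the decoder adds causal self-attention and
cross-attention over the encoder states. The reference configuration in the
literature is 6+6 layers; all desk-scale work in this package uses 2+2 (or
1+1) layers at width 64–128, which the configuration object makes explicit.
For architecture comparisons the encoder-only baseline is configured to
match the encoder-decoder's parameter count within 10% (a 5-layer
encoder-only model matches a 2+2 encoder-decoder of the same width;
`parameterCount()` checks this).

Task heads are single linear layers, zero-initialized (an untrained head
scores 0.5 everywhere). For the encoder-decoder the head reads the
decoder's hidden state at the BOS position — the state that parametrizes
the first-step next-visit distribution, which matches the generative
framing; for the encoder-only baseline it reads a designated pooling token
prepended to the input.

The binary classifier loss is the usual binary cross-entropy. The
multilabel loss is the mean over instances of the *summed* per-output
cross-entropies. With the all-elements mean, per-output gradients shrink
linearly in the panel size, which at desk scale stalls head training; the
per-instance sum keeps gradient magnitudes comparable between binary and
multilabel heads at the same learning rate.

## Optimization

AdamW (decoupled weight decay, applied to weight matrices but not biases or
layer-norm parameters) with the standard recipe: peak learning rate 1e-3,
linear warmup over the first 10% of steps then linear decay, dropout 0.1,
weight decay 1e-3. Finetuning optimizes the whole network (backbone and
head) and, when a validation set is supplied, keeps the parameters of the
epoch with the best validation AUPRC — AUPRC because it is the informative
metric under the class imbalance these tasks have.

Mini-batches are processed as *packed sequences*: the instances of a batch
are concatenated and attention is restricted by a block-diagonal mask (plus
the causal mask in the decoder), so one forward/backward serves the whole
batch. This is purely an engineering device for single-CPU throughput; the
test suite asserts that packed batches reproduce single-instance losses and
logits to 1e-10. The loss of a packed generative batch is the mean token
cross-entropy over all target positions (token-weighted rather than
instance-weighted).

Every source of randomness flows from explicit seeds: weight init from the
model config seed, shuffling/corruption/dropout from the train config seed,
splits from the split spec seed. Stage seeds are derived from one global
seed via `deriveSeed(seed, tag)`. Re-running any stage with its manifest
settings reproduces its outputs bitwise in single-threaded mode.

## The synthetic cohort generator

Restricted clinical data cannot ship with a package, so every downstream
stage is exercised on synthetic cohorts with *planted, recoverable*
structure:

* **Comorbidity clusters.** The code universe is partitioned into clusters;
  each patient draws latent cluster memberships once (probability 0.25 per
  cluster, at least one forced); at every visit each non-chronic member
  code is emitted with the co-activation probability (default 0.5). This
  creates the strong patient-level code correlation that pretraining is
  supposed to exploit.
* **Chronic codes.** The first code of each cluster is chronic, with its
  own two-sided dynamics. *Onset* is a background process: any never-seen
  chronic code onsets with a small per-visit probability (default 0.03)
  for every patient, independent of cluster membership. *Recurrence* is
  recency-driven: present at the previous visit, the code recurs with the
  persistence probability (default 0.8; 0.9 in the stratification
  experiments); lapsed, it is mostly resolved and revives with
  persistence/16. Both choices matter for the new-vs-recurrent
  stratification, which is about an asymmetry of *predictability*: new
  onset must be largely unpredictable (were onset driven by visible
  cluster siblings, predicting it would be easy) while recurrence must be
  predictable from the observable recent history (were lapses i.i.d.
  coin flips, history would carry no signal). The defaults encode the
  clinically familiar version of that asymmetry.
* **Progression rules.** Optional (trigger, consequence, lag, probability)
  rules: when the trigger appears at visit t, the consequence is emitted at
  visit t+lag with the stated probability. Acute triggered events present
  as the leading diagnosis: consequences sit at the front of the visit's
  priority order (after the outcome code, before chronic recurrences), so a
  planted rule is recoverable from the model's *first* decode step.
* **Rare outcome.** A per-visit hazard (eligible from visit 2) with a
  multiplier once any trigger code has appeared in the history. When the
  outcome fires, its code leads the visit and the record truncates there —
  the outcome visit is the final visit, as in case/control cohort designs.
  With base rate 8e-4/visit and hazard ratio 5.5, the patient-level
  prevalence works out near 1.9%: roughly 45% of patients acquire a
  trigger code (cluster-1 membership plus background onset of its chronic
  code), carriers accumulate about 9 × 0.0044 ≈ 3.9% risk over a mean 9
  eligible visits, non-carriers about 0.7%, giving
  0.45·3.9 + 0.55·0.7 ≈ 2.1%, measured nearer 1.8% with the outcome-truncation of case records — the rare-outcome regime of the
  self-harm-scale prediction problems this package emulates.
  `expectedOutcomePrevalence()` gives the closed form for the no-trigger
  case, and the generator is tested against it.
* **Visit counts and gaps.** Discretized normal visit counts (default mean
  10.1, sd 3.3, the shape of the multi-visit clinical cohorts this package
  emulates); discretized lognormal inter-visit gaps (median 30 days); first
  visit uniform over a three-year window.
* Acute noise codes arrive as a Poisson stream (default 2 per visit) from
  the non-cluster part of the vocabulary.

Everything is drawn from one seeded stream per cohort, so identical specs
yield byte-identical cohorts.

What the generator does **not** emulate: real ICD-10-CM marginal
frequencies or hierarchy, coding-practice artifacts (billing-driven code
inflation, site effects), care-seeking dynamics, or any clinical
plausibility of specific code combinations. Tests passing on these cohorts
therefore demonstrate that the machinery recovers structure *of the planted
kinds* — correlation, recurrence, progression, rare triggered outcomes —
not that the model is clinically validated.

## Evaluation

* **AUROC** is computed as the Mann–Whitney rank statistic with mid-rank
  tie handling.
* **AUPRC** is average precision without interpolation (the step-wise walk
  down the ranked list); interpolated variants are biased upward on rare
  outcomes.
* **PPV/sensitivity at top-k%** selects the ⌈kn⌉ highest-scoring
  individuals; ties at the threshold are broken by stable order and
  flagged. At k = 1 PPV equals prevalence, an identity the tests assert.
* Confidence intervals are seeded percentile bootstraps (1,000 replicates)
  over individuals; multi-seed experiments instead report across-seed mean
  ± sd with a one-sided Welch t-test, which is the convention for
  comparing finetuned models across random seeds. Zero-variance arms are
  handled in closed form (equal means give p = 0.5) since the textbook
  statistic is undefined there.
* **New-vs-recurrent stratification** partitions evaluation instances by
  whether the predicted code occurs anywhere in the context; strata that
  are empty or single-class are reported not-evaluable rather than erroring.

All three ranking metrics are verified exactly against brute-force oracles
(all-pairs counting, rank-walk summation, sort-and-count) on hundreds of
randomized instances, and checked to be invariant under strictly monotone
transformations of the scores.

## Desk-scale study conditions

The experiments in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` are sized for a single CPU; these sizes are the
package's study conditions, chosen once:

* *Planted-rule recovery*: 2,000 patients, vocabulary 100 (two 3-code
  clusters plus noise), one deterministic rule A→B at lag 1, d_model 128,
  2+2 layers, visit masking, batch 16, 1,100 optimizer steps, 3 seeds. The
  measured quantity is the gap in mean first-step probability of B between
  contexts containing A and contexts lacking A.
* *Masking-objective ablation*: both arms pretrain on the same 500-patient
  cohort (vocabulary 60, four 4-code clusters) for 4 epochs at d_model 32,
  1+1 layers — a deliberately *partial* pretraining budget: with enough
  pretraining both objectives saturate this small task and the contrast
  vanishes, so the ablation is read in the regime where representation
  quality still differs. Each arm then finetunes a 10-code multilabel head
  with 5 seeds (10 epochs, learning rate 3e-3); the measured quantity is
  mean per-code test AUROC on an independent 500-patient cohort, compared
  with a one-sided Welch t-test.
* *Pretraining benefit*: a visit-masking backbone pretrained on 1,000
  patients (3 epochs, so it has seen enough rare-outcome events) vs fresh
  random initializations; binary head finetuned on a 700-patient labeled
  cohort (~2% outcome prevalence) with 5 seeds per arm; mean AUPRC on an
  independent 2,000-patient test cohort.
* *Stratification*: the chronic code of the ablation cohort (persistence
  0.9), scored on up to 1,500 recursive instances of the test cohort by
  the finetuned multilabel model, stratified into recurrent ("R") vs
  new-onset ("0").

## Known limitations

* The implementation is plain R on BLAS; it is adequate for the desk-scale
  configurations above, not for corpus-scale pretraining.
* Greedy/top-k decoding only; no beam search.
* Codes are atomic tokens: no ICD hierarchy, no subword sharing between
  related codes.
* The generator's demographics are independent of the clinical process, so
  subgroup analyses on synthetic data check invariance machinery, not
  equity properties of any real model.
* Visit re-indexing after visit dropping discards the original indices; the
  alternative (keeping original indices) is a one-line change but was not
  adopted, to avoid leaking the drop pattern.
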