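---
title: "Energy-based post-processing of automatic sleep staging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-based post-processing of automatic sleep staging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepenergy)
```

## The problem

Automatic sleep stagers score each 30-second polysomnography epoch into one
of the five AASM stages — Wake (W), N1, N2, N3 and REM (R) — and most of
them score epochs in isolation or with a small context window. The
resulting hypnograms are noisier than human scorings: isolated one-epoch
stage flips and transitions that essentially never occur in real sleep
(e.g. direct W to N3 jumps). `sleepenergy` is a meta-optimization layer
that takes the per-epoch stage *probabilities* emitted by any such
classifier and re-decodes the night so that the sequence is simultaneously
faithful to the classifier and coherent with empirical stage dynamics. It
consumes no EEG; its inputs are the `T x 5` predicted probability matrix,
a stage-transition matrix estimated from scored training hypnograms, and a
column-normalized confusion matrix estimated from validation predictions.

## The energy model

Every consulted probability `p` contributes a reciprocal error

```
f(p) = 1 / ((1 - eps) * p + eps) - 1
```

which is strictly decreasing and convex, exactly 0 at `p = 1`, and capped
at `1/eps - 1` at `p = 0`. The cap constant `eps` keeps zero-probability
events finitely expensive (zero probabilities are legal inputs, no
flooring is applied) and sets the steepness of the curve. The per-epoch
energy of a candidate hypnogram `s` is

```
E(t) = alpha * [ f(P_trans(s[t-1] -> s[t])) + f(P_trans(s[t] -> s[t+1])) ]
     + (1 - alpha) * [ f(P_conf(s[t] | pred_label[t])) + f(P_pred(t, s[t])) ]
```

and the hypnogram energy is the sum over epochs. Conventions worth
spelling out, because they define comparability of energies:

* **Boundary epochs.** The missing incoming term at `t = 1` and outgoing
  term at `t = T` are omitted — not imputed, not rescaled. End-epoch
  energies are therefore systematically smaller; all comparisons in the
  package use one fixed convention throughout.
* **Double counting of transitions.** Each interior transition appears in
  two epoch energies (outgoing for `t`, incoming for `t + 1`), so the
  total energy counts every transition error exactly twice. The
  incremental update (`delta_energy()`) reproduces this factor of two.
* **Fixed conditioning of the confusion term.** `pred_label` is the
  argmax candidate hypnogram computed once from `P_pred`; the confusion
  term always conditions on it, never on the evolving state. The
  column-normalized confusion matrix answers "given the classifier said
  X, what is the stage really?", which is relabeling evidence about the
  classifier, not about the current optimization state.
* **The exact algebraic form.** The affine-denominator form above is the
  simplest strictly monotone "1/p - 1"-type curve that passes both
  anchors f(1) = 0 and f(0) = 1/eps - 1. It is isolated in
  `reciprocal_error()`, so swapping in an alternative error family is a
  one-line change.

### Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `alpha` | weight of the transition terms vs confusion + prediction terms, in [0, 1] | 0.5 | balanced contribution of sequence dynamics and classifier evidence |
| `eps_t` | cap constant for transition errors, in (0, 1) | 0.1 | worst transition costs 9; never-seen transitions are strongly but finitely penalized |
| `eps_p` | cap constant for confusion/prediction errors, in (0, 1) | 0.1 | same scale as the transition terms |

At `alpha = 1` the energy ignores the classifier entirely (only dynamics
remain — this measurably collapses balanced accuracy, because the global
optimum is then a near-constant hypnogram); at `alpha = 0` it ignores
dynamics and the optimum essentially reproduces the argmax candidate.

## Matrix estimation

`estimate_transition_matrix()` counts consecutive stage pairs within each
recording — never across recording boundaries, so pooling many nights
introduces no spurious transitions — and row-normalizes. The pseudocount
defaults to 0 because structural zeros are informative: a transition that
never occurs in training data should stay maximally expensive. Smoothing
is opt-in for small corpora. Rows of never-observed source stages fall
back to uniform with a warning.

`estimate_confusion_matrix()` counts (true, predicted) pairs and
column-normalizes, estimating `P(true | predicted)`. A predicted stage
never observed carries no evidence, so its column falls back to uniform
0.2 (an uninformative, finite energy term) with a warning. The intended
protocol — transition matrix from training labels, confusion matrix from
*validation* predictions, never from test data — is a workflow convention
enforced by the CLI's separate inputs, not by the estimators themselves.

## The annealer

The whole hypnogram is the optimization variable. Starting from the argmax
candidate, each step

1. **selects one epoch** from the softmax over current per-epoch energies
   at inverse temperature `beta`, and
2. **resamples its stage** from the 5-way softmax of `exp(-beta * deltaE)`
   over all five stages, where `deltaE` is computed from the at most three
   affected epoch energies. The current stage (with `deltaE = 0`) is
   always a candidate, so the proposal *is* the update; there is no
   separate accept/reject test.

Design choices that were genuinely open:

* **Position-selection sign.** A literal Boltzmann weighting over
  positions, `exp(-beta * E(t))`, concentrates proposals on epochs that
  already have *low* energy, which works against minimization. The package
  defaults to `sign_mode = "effective"` (`exp(+beta * E(t))`: revisit the
  worst-explained epochs) and keeps `sign_mode = "literal"` available for
  the strict Boltzmann reading. All correctness tests (incremental-vs-full energy,
  Boltzmann sampling at fixed temperature) are independent of this choice;
  it only changes where the optimizer spends its steps.
* **Schedule.** No cooling law is prescribed by the method itself, so the
  package uses a geometric ramp of `beta` from 0.1 to 10 over
  `K = ceiling(40 * T)` single-site steps: each epoch is proposed about 40
  times in expectation, early steps are near-uniform exploration, late
  steps near-greedy. Convergence was probed by running 5x longer and 20x
  colder schedules on benchmark nights: best energies change by under
  0.2%, so the default is effectively converged at this problem size.
* **Reported state.** The best-visited state, not the final one —
  standard annealing practice, and it guarantees the method never returns
  a hypnogram with higher energy than its own argmax start.
* **Caching.** Per-epoch energies are cached and patched at
  `{t-1, t, t+1}` after each accepted move; the contract (tested) is exact
  agreement with full recomputation. The step loop is compiled (Rcpp) and
  draws all randomness from R's RNG, so a seed makes runs bit-identical.

With uniform position selection and a constant `beta`, step 2 is exactly
the Gibbs conditional of the Boltzmann distribution `exp(-beta * E(S))`
(the normalization of `deltaE` cancels the current state's energy), so the
chain is a random-scan Gibbs sampler. The test suite exploits this: on a
`T = 3` instance the empirical distribution over all 125 hypnograms is
compared against the exactly enumerated Boltzmann distribution.

## Baselines

`viterbi_decode()` is the usual post-hoc HMM smoother: probability rows
are treated as per-epoch emission pseudo-likelihoods (no re-estimation),
decoding in log space with ties broken toward the lowest stage code.
`median_smooth()` replaces each epoch by the modal stage of its centered
window, keeping the original stage on ties. Both exist so the benchmark
compares the energy method against the natural alternatives.

## The synthetic generator

`make_benchmark()` produces fully seeded nights with the statistical
structure the method assumes:

* **Ground truth** is a first-order Markov chain over the five stages. The
  default transition matrix is persistence-dominated (diagonal 0.86-0.92)
  with residual mass on plausible moves (N3 reached through N2, direct
  W-N3 exchanges absent) and nights start awake or drowsy. Defaults are
  configuration, not claims about any dataset.
* **The classifier** is emulated label-then-Dirichlet: per epoch a
  "predicted" label is drawn from the row of a confusion target
  `P(predicted | true)`, then the probability row is drawn from a
  Dirichlet with concentration `sharpness * b`, `b` putting mass 0.8 on
  the drawn label. This gives direct control over the error pattern — the
  quantity the energy model consumes — unlike additive noise on one-hot
  rows. The default target has a prevalence-weighted diagonal around 0.72
  with N1 hardest (recall 0.40), and `sharpness = 20` produces confident,
  deep-network-like rows; realized argmax accuracy is about 70%.
* Transition and confusion matrices are estimated from held-out synthetic
  nights (default 10), never from the test nights, mirroring a
  train/validation protocol.

**What the generator does not emulate.** Two simplifications matter when
reading benchmark results. First, there is no ultradian structure (no
early-night N3 or late-night REM enrichment) and no between-subject
variability; the matrices estimated from held-out nights are therefore
unrealistically well matched to the test nights, which flatters every
matrix-consuming method. Second, the emulated classifier is *equally
confident when right and when wrong* — a single `sharpness` governs all
rows. Real networks are least confident exactly on the epochs they get
wrong. This has a visible consequence: with confidently wrong errors, the
`(1 - alpha)`-weighted classifier terms pin the labels unless `alpha` is
large enough, so accuracy grows steeply between `alpha = 0.25` and
`alpha = 0.5` on synthetic benchmarks; a classifier whose errors come
with low confidence would let smaller transition weights flip them,
flattening that profile. Passing
benchmark tests here demonstrate the direction and significance of the
improvement and the collapse at `alpha = 1`, not the precise robustness
profile over intermediate `alpha` on real recordings.

## Evaluation and testing conventions

* Balanced accuracy averages per-stage recall over stages *present in the
  truth*; absent stages are excluded (their recall is undefined).
* Per-stage F1 defines 0/0 as 0 — stated explicitly because short
  recordings can miss stages — and the macro average runs over stages
  present in truth or prediction.
* The paired Wilcoxon signed-rank test drops zero differences (the
  classical treatment), uses mid-ranks for ties, the exact null for up to
  25 untied differences and the tie-corrected normal approximation with
  continuity correction otherwise; it is two-sided. All-zero-difference
  comparisons are reported non-significant with a warning rather than
  failing. Holm-Bonferroni adjustment is applied across whatever family
  of comparisons is supplied, with significance flagged at adjusted
  p < 0.05.

## Numerical choices and degenerate inputs

* Probability rows are validated with tolerance `1e-6`: tiny deviations
  are renormalized with a warning, larger ones are errors naming the
  offending row — silent rescaling of badly scaled input would mask
  upstream bugs. Validation is idempotent.
* Argmax ties break toward the lowest stage code, deterministically, in
  both the candidate decoder and the Viterbi backtrace.
* Softmax computations subtract the maximum exponent first; at
  `beta = 10` and energies up to the cap this is the difference between
  correct sampling and overflow.
* A `5 x 5` probability file is orientation-ambiguous and is rejected
  unless the orientation is stated explicitly.
* `T = 1` hypnograms are legal everywhere; they simply have no transition
  terms.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run entirely on generated
data at desk scale: 20 benchmark nights of 900 epochs (7.5 h) each with 10
held-out nights for matrix estimation; exhaustive enumeration oracles at
`T <= 6` (15 625 hypnograms); a 200 000-step fixed-temperature sampling
check at `T = 3`; and 50 nights for transition-matrix recovery. These
sizes make every claim checkable by enumeration or law-of-large-numbers
arguments while keeping a full run in the low minutes.

## Known limitations

* Matrices are global: no per-subject, per-age, or time-of-night
  conditioning, and one transition/confusion matrix serves the whole
  night.
* The method inherits the upstream classifier's quality; on recordings
  where the classifier is badly wrong (or its validation-estimated
  confusion matrix is unrepresentative), relabeling evidence is itself
  wrong and little improvement should be expected.
* The energy's confusion term conditions on the fixed argmax label; a
  classifier whose second-choice probabilities are informative is only
  partially exploited through the prediction term.
* Energies are comparable only within the boundary convention described
  above and for a fixed `(alpha, eps_t, eps_p)`.
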