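---
title: "Snow leopard optimization: model, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snow leopard optimization: model, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slopt)
```

## The optimizer

Snow leopard optimization (SLO) minimizes a deterministic objective
`f : [Low, Up]^d -> R` with a population of `pop` candidate solutions
("territories"). Each member carries two fixed attributes assigned at
initialization — a gender (the first `ceiling(pop/2)` members are male) and
a living arrangement (solitary or co-residing, Bernoulli(1/2) per member) —
which only determine *which* move a member performs and *whom* it references;
they carry no objective-function meaning. The member with the smallest
objective value is the *leopard king*.

A deterministic temperature `1 - 2t/(t + MAX_T)` decreases from 1 (iteration
0) to 0 (iteration `MAX_T`) and schedules three phases:

1. **Delineation** (`Temperature > 0.8`): every member generates a candidate
   near an opposite-gender member with the same arrangement (co-residing
   members use their fixed partner; solitary members draw a mate uniformly
   from the opposite-gender solitary pool). The per-dimension step is
   `± 0.5 · ((Up - Low)·rand + Low)` damped by `1/(r + 1)^2` with
   `r = fit(mate)/fit(self)`, so moves toward much-better mates shrink.
   This phase dominates roughly the first 11% of iterations
   (`Temperature = 0.8` at `t = MAX_T/9`) and provides global coverage.
2. **Neighborhood relocation** (low temperature, gate draw below 0.4):
   members step along their offset from a same-gender co-residing rival
   (`± 0.5 · BC · randn · (self - rival)`), males stepping instead from the
   king with probability 1/2 — a local search whose scale shrinks with
   `BC = rand·(1 - Temperature)`.
3. **Dispute** (low temperature, gate draw at or above 0.4): members probe
   around the king with the small constant 0.05; solitary members may
   instead battle a same-gender solitary rival, damped by `1/(q + 1)`,
   `q = fit(self)/fit(rival)`. Because the gate compares
   `rand · rand · (1 - Temperature)` against 0.4, dispute iterations are
   impossible just below the 0.8 threshold and reach probability
   `1 - 0.4 + 0.4·log(0.4) ≈ 0.233` at temperature 0 — exploitation takes
   over smoothly as the run cools.

Every candidate is clipped to the box component-wise and accepted greedily
(strictly better only), so the best-so-far history is non-increasing by
construction. Updates are sequential within an iteration: an accepted
improvement, including a new king, is visible to all later members of the
same iteration, the usual convention in swarm optimizers.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `pop_size` | 100 (benchmarks), 20 (feature selection) | population size; must be >= 4 so all four roles exist |
| `max_iter` | task-dependent | iteration budget `MAX_T`; also sets the temperature scale |
| `c1_explore` | 0.5 | step constant of delineation and relocation |
| `c1_dispute` | 0.05 | step constant of disputes (an order of magnitude finer) |
| `temp_threshold` | 0.8 | temperature above which delineation runs |
| `gate_threshold` | 0.4 | relocation-vs-dispute gate on `rand · BC` |
| `ratio_mode` | `"divide"` | reading of the fitness-ratio damping factors |
| `eps` | 1e-12 | guard added to ratio denominators |
| `seed` | — | single source of all randomness in a run |

All parameters are dimensionless; territories inherit the units of the
decision variables.

## Design decisions

Several parts of the algorithm's published description admit more than one
reading; the package fixes them as follows.

* **Phase gate.** The prose description of when relocation versus dispute
  occurs (a fixed cutoff of 0.1 on `BC`) is inconsistent with the
  pseudocode, which gates on a fresh uniform times `BC` against 0.4 — and
  only the pseudocode direction yields the stated trend that disputes grow
  more frequent as the run cools. The pseudocode gate is implemented,
  with the cutoff exposed as `gate_threshold`. The two gate conditions are
  complementary; one draw per iteration selects exactly one phase, ties
  (`rand·BC = 0.4`) going to dispute.
* **Fitness-ratio factors.** Whether the ratio terms multiply or divide the
  step is typographically ambiguous in the source equations. The default
  `divide` bounds the step factor in (0, 1] for non-negative fitness and
  matches the described behavior of settling *near* the reference member;
  `ratio_mode = "multiply"` retains the other reading for sensitivity
  analysis. For objectives that go negative, the ratio inputs are shifted
  by the population minimum (fixed at the start of each iteration) so the
  factors stay positive.
* **The ± sign** is drawn independently per dimension with probability 1/2;
  the qualitative "weaker members keep their distance" remark suggests a
  deterministic rule but does not define one.
* **Per-dimension draws.** `rand` and `randn` are redrawn for every
  dimension (vector-valued), the common convention; a scalar draw per
  member would collapse moves onto a line through the reference point.
* **Boundary handling** is component-wise clipping; **acceptance** is
  strictly-greedy replacement, which is what makes the published
  monotone convergence curves structural rather than empirical.
* **Roles.** Both genders receive the Bernoulli(1/2) arrangement split
  (the source randomizes males only and is silent on females); empty
  gender x arrangement cells are repaired by flipping one random member so
  every selection pool is non-empty, and co-residing members are paired
  cyclically when the gender counts differ. The relocation rival pool is
  same-gender co-residing members, following the prose (the pseudocode's
  "co-residing male or solitary male" line contradicts it and is treated
  as a typo). A member that draws itself as rival redraws once, then keeps
  the draw — a zero step is harmless under greedy acceptance.
* **Determinism.** One seeded RNG per run; the draw order is fixed (gate
  draws, then members in ascending index; per member: variant uniform,
  rival index, per-dimension signs, then magnitudes) so runs are
  bit-reproducible, which the test suite asserts.

## The feature-selection wrapper

Continuous solutions in `[0,1]^N` are binarized at 0.5 (the boundary
selects); the objective on the *training partition only* is
`0.99·(1 - Acc) + 0.01·n/N`, with `Acc` the mean fold accuracy of a
5-nearest-neighbor classifier under stratified 10-fold cross-validation
restricted to the selected features. Protocol choices:

* **Folds are fixed once per run** (seeded from the optimizer seed plus a
  fixed offset). Re-shuffling folds per evaluation would make the objective
  noisy, and greedy acceptance against a noisy objective systematically
  retains lucky draws. Folds are re-randomized across repetitions.
* **Stratification** (per-class shuffle, round-robin dealing) keeps
  per-class fold sizes within one of each other; with as few as 50 samples
  and up to 9 classes, unstratified folds can lose a class entirely.
  Classes smaller than the fold count simply appear in only some folds.
* **KNN** uses Euclidean distance on raw feature values — no scaling is
  part of the protocol — with fully deterministic tie-breaks: distance ties
  go to the lower training-row index, vote ties to the label with the
  smaller summed neighbor distance, then to the smaller label value. `k`
  is capped at the training-fold size.
* **The empty mask** (no feature selected) is scored at the worst value
  `alpha + beta` instead of crashing the classifier, steering the search
  away from it. Should a degenerate run still return an empty mask, the
  single largest-component feature is reported.
* **Baseline injection.** The all-ones solution (every feature) is placed
  into the initial population, so the returned fitness is provably never
  worse than the all-features baseline under the same folds. Disable with
  `fs_config(inject_baseline = FALSE)`.
* **Hold-out hygiene.** The stratified test partition (20% or 10%) is
  split off before fold construction and never touched until the final
  scoring of the selected subset; the test suite verifies this by
  corrupting the test rows and checking the training-side trajectory is
  bit-identical. Both the training-side CV accuracy and the hold-out
  accuracy are reported, since "accuracy" in wrapper-selection summaries
  can refer to either.

## The synthetic-data generator

`generate_expression_data()` emulates the small-n / large-p regime of
microarray classification benchmarks: `n_features` i.i.d. Gaussian noise
columns of which `n_informative` receive class-specific mean offsets at
equally spaced points spanning `effect_size · noise_sd · (n_classes - 1)`,
symmetric about zero, so adjacent classes differ by `effect_size` noise
standard deviations. `expression_regimes()` reproduces the (features,
instances, classes) shapes of eight published benchmark datasets, with 10
informative features at effect size 2 by default — enough signal that a
5-NN classifier responds monotonically to informative-feature inclusion at
n ≈ 50, while leaving the selection problem genuinely hard (the planted
features are a 0.5% minority).

What the generator deliberately does **not** model: gene–gene correlation,
batch effects, heteroscedastic or heavy-tailed noise, and class-imbalance
pathologies. Passing the planted-feature recovery tests therefore shows the
wrapper machinery is sound and leak-free, not that SLO ranks first on real
microarray data — the published cluster-scale comparisons (100-d official
benchmark suites at 10,000 iterations, eight real gene datasets, seven
competitor algorithms) are outside this package's scope, and the official
benchmark functions can be attached through `register_benchmark()` when
their data files are available.

## Numerical choices and problem sizes

Ratio denominators carry a `1e-12` guard; candidate arithmetic is verified
against a straight-line re-implementation to 1e-12 per component; fitness
bookkeeping identities are asserted to 1e-12. The test suite and the
acceptance script run at desk scale, chosen to finish in minutes on one
CPU while leaving the conclusions qualitative-free: the 30-d sphere at
pop 50 / 300 iterations over 10 seeds for optimizer sanity (median final
best within 1% of the initial best, and better than uniform random search
at the same evaluation budget), the 62 x 2000 two-class regime over 5 seeds
for planted-feature recovery (pooled hypergeometric enrichment p < 0.01),
and 1e5-draw Monte-Carlo estimates for the gate trend. The Friedman
module reports the tie-corrected chi-square statistic alongside the average
ranks; the full-tie table leaves the statistic undefined (`NA`).

## Known limitations

* Greedy acceptance plus a finite dispute constant means the optimizer
  stagnates once the population collapses onto the king; there is no
  restart or diversity-maintenance mechanism.
* The wrapper's objective evaluates one full CV per candidate; at
  thousands of features and hundreds of samples the distance computation
  dominates and run time grows as `O(pop · iter · n² · n_selected)`.
* Only single-objective, box-constrained, continuous minimization is
  supported; no discrete, multi-objective or constrained variants.
* KNN is the only classifier; the fitness weights assume `alpha + beta = 1`
  (warned otherwise).
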