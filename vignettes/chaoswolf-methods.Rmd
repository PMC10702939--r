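---
title: "Chaos-integrated grey wolf feature selection: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaos-integrated grey wolf feature selection: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaoswolf)
```

## The model

`gwo_knn()` fits a wrapper feature-selection classifier for binary
document-term matrices. A population of `N` wolves moves in the continuous
cube $[0,1]^M$ (one coordinate per vocabulary term); a position decodes to
a term subset $S$ by strict thresholding at 0.5, and the subset is scored

$$\mathrm{fitness}(S) \;=\; w_1\,\mathrm{acc}_{KNN}(S) \;+\;
  w_2\,\frac{M - |S|}{M}, \qquad w_1 = 0.9,\; w_2 = 0.1,$$

where $\mathrm{acc}_{KNN}$ is k-nearest-neighbour accuracy (Hamming
distance on the selected 0/1 columns, $k = 5$) on a stratified validation
holdout. Fitness is maximized; at equal accuracy a smaller subset always
wins, which is what makes the fitted model interpretable — the result is a
short word list plus a KNN rule over it.

The search engine is the improved grey wolf optimizer with
dimension-learning-based hunting (DLH). Each iteration every wolf builds
two candidates, a leader-guided move (`gwo_candidate()`) and a DLH
recombination (`dlh_candidate()`), keeps the better, and only replaces its
position on strict improvement. The "NI" modification replaces the random
$r_1$ in $A = 2a r_1 - a$ with the deterministic schedule
$r_1 = \alpha - t\,\alpha/\mathrm{MaxIter}$, $\alpha = 2$
(`gwo_schedule_r1()`). The four chaotic variants substitute a chaotic map
stream for specific uniform draws:

| variant | chaotic injection point |
|---|---|
| `cni1` | population initialization (row-major consumption) |
| `cni2` | the $r_2$ behind $C_1$ (α-leader), one value per wolf per iteration |
| `cni3` | same, for $C_2$ (β) |
| `cni4` | same, for $C_3$ (δ) |

All other draws stay uniform under the run's seed, so a run is reproducible
from `(seed, map)`.

### Assumptions

- Features are binary presence indicators; the Hamming = squared-Euclidean
  identity for 0/1 data is used for exact distance computation.
- Labels are binary with label 1 the positive ("depressive") class.
- A small subset of columns suffices for accurate classification —
  otherwise the feature-reduction term simply trades accuracy away at rate
  $w_2/M$ per column.

## Tunable parameters

| parameter | default | unit / range | rationale |
|---|---|---|---|
| `pop_size` | 30 | wolves | standard budget for this optimizer family |
| `max_iter` | 100 | iterations | ditto; evaluations = $N + 2N\,T$ = 6030 |
| `w1`, `w2` | 0.9, 0.1 | weights, sum 1 | accuracy-dominated multi-objective blend |
| `k_neighbors` | 5 | neighbours | odd (no binary vote ties), robust small default |
| `threshold` | 0.5 | position cut | symmetric decoding of $[0,1]$ positions |
| `val_fraction` | 0.25 | of training rows | fitness holdout, stratified |
| `feature_term` | `"reduction"` | — | see design choices |
| map `z1` | 0.7 | initial value, (0,1] | shared across all three maps |
| circle `y1`, `y2` | 0.5, 0.2 | — | standard chaotic-regime parameters |
| logistic `mu` | 4 | — | the fully chaotic regime |
| iterative `y` | 0.9 | (0,1) | see numerical choices |

## Numerical choices

- **Circle map normalization.** The raw recurrence
  $z' = z + y_2 - (y_1/2\pi)\sin(2\pi z)$ drifts above 1; emitted values
  are reduced modulo 1 (the standard circle-map convention), keeping every
  consumer's $[0,1]$ contract valid. Raw values remain available
  (`chaos_sequence(..., raw = TRUE)`).
- **Iterative map sign and guard.** $\sin(y\pi/z)$ ranges over $[-1,1]$;
  unit values take the absolute value while the recurrence keeps the
  signed state. Since the map is undefined at $z = 0$, a state with
  $|z| < 10^{-12}$ reseeds to $z_1$ instead of dividing by zero.
- **Iterative `y` default.** The reseed guard interacts badly with any
  parameterization where $y/z_1$ is an integer: the first step from $z_1$
  is then $\sin(m\pi) \approx 0$, the guard fires, and the stream freezes
  in a two-cycle at zero. With the shared $z_1 = 0.7$ this rules out the
  otherwise natural $y = 0.7$; the default is $y = 0.9$ and the
  constructor warns when a user-chosen $(y, z_1)$ hits the degenerate
  ratio.
- **Boundary handling.** Candidates are clamped coordinate-wise to
  $[l, u]$ after every move. Clamping (rather than reflection or
  resampling) keeps the threshold decoding meaningful: a coordinate pushed
  hard toward a bound reads as a confident include/exclude.
- **Tie-breaks.** Equal fitness between the two candidates prefers the
  leader-guided move (listed first in the selection rule); equal KNN
  distances resolve by training-row order; an even vote splits to the
  single nearest neighbour's label. All three rules make runs bit-for-bit
  reproducible.
- **Degenerate inputs.** An empty decoded mask falls back to the single
  largest coordinate (first on ties), so fitness is always defined; a
  single-class validation split is allowed (accuracy remains
  well-defined); 0/0 metric ratios are defined as 0.
- **Optimization direction.** The engine maximizes. The selection rule is
  often written for minimization; its comparison is mirrored accordingly.

## Design choices that were genuinely open

- **Feature term direction.** A "features ratio" can be read as $|S|/M$ or
  $(M-|S|)/M$. Under maximization only the latter keeps subset sizes
  small, which is the stated purpose of the term, so `"reduction"` is the
  default; the literal form stays selectable
  (`fitness_spec(feature_term = "literal")`).
- **Leak-free fitness.** Scoring candidate subsets against the final test
  split during the search leaks the test set into model selection. The
  default evaluates fitness on a 25% stratified holdout from the training
  split; passing `x_val`/`y_val` reproduces external-scoring arrangements
  when comparability matters more than hygiene.
- **Leader distance form.** The leader-guided distance is implemented
  multiplicatively, $D_k = |C_k X_k - X|$, consistent with the encircling
  definition; the subtractive variant sometimes seen in print is available
  behind `literal_distance = TRUE` for comparison.
- **Friedman rank direction.** With larger-is-better scores the winning
  algorithm should carry the largest mean rank, so blocks are ranked
  ascending in quality; the $\chi^2$ statistic itself is
  direction-invariant (tested), so this affects reporting only. Ties take
  average ranks with the tie-corrected statistic.
- **Quartiles.** Linear-interpolation quantiles (type 7), the convention
  behind standard box plots; the `type` argument exposes the inclusive /
  exclusive variants.
- **Preprocessing defaults.** Lowercase, URL/handle/digit/punctuation
  stripping, stopword removal (compact English list, replaceable),
  minimum token length 2, document frequency ≥ 2. These are conventional
  choices for short social-media text, not an attempt to reproduce any
  particular corpus's vocabulary size; stemming is deliberately not
  offered.

## What the synthetic generator does and does not emulate

`synth_spec()` produces class-conditional Bernoulli document-term
matrices: informative columns appear with probability `p_pos` (0.9) in
positive documents and `p_neg` (0.1) in negative ones; background columns
are Bernoulli(0.5) everywhere; labels follow the 83.1/16.9 imbalance of
the motivating corpus. Defaults (400 documents, 80 terms, 10 informative)
are sized so that a full-budget wrapper search runs in seconds-to-minutes
on one CPU while leaving the planted subset genuinely hidden among
distractors.

It deliberately does **not** emulate: term-term correlation, burstiness or
document-length variation, near-duplicate posts, label noise, or
vocabulary drift. Passing tests on this generator therefore demonstrate
that the optimizer recovers sparse informative structure under class
imbalance — not that any particular accuracy level transfers to real
social-media corpora, where correlated and redundant features make both
the search landscape and the leak-free validation estimate harsher.

## Problem sizes used by the shipped checks

Unit tests run the optimizer at reduced budgets (populations 6–10, 10–30
iterations) on a separable toy objective with a known optimum, and
cross-check the fast KNN and DLH neighbourhoods against brute-force
oracles on hundreds of small random instances. The end-to-end acceptance
checks use the full study budget — 30 wolves, 100 iterations, five seeds
per variant — on the default synthetic specification, asking each of the
five variants to reach ≥ 0.95 validation accuracy with a strictly
sub-full mask in at least 4 of 5 seeds. `scripts/acceptance.R` repeats
that experiment with 5 seeded runs per variant plus held-out test metrics
and the cross-variant Friedman test.

## Known limitations

- The 20-run, 8-algorithm comparison protocol is implemented, but the
  package ships only the NI-GWO family; comparison metaheuristics (ABC,
  HHO, SCA, ...) and ML baselines are out of scope, so `compare_variants()`
  compares configurations of this family.
- KNN stores the full training matrix in the fitted object; for corpora
  far beyond 10⁴ documents both memory and per-evaluation cost grow
  accordingly.
- Chaotic streams are shared per run and consumed in a documented fixed
  order; changing population size or iteration count therefore changes
  which chaotic value reaches which coefficient (as it must).
- The iterative map's long orbits visit tiny $|z|$, where
  $\sin(y\pi/z)$ is evaluated at very large arguments; values stay
  bounded and deterministic on a given platform, but the low-order digits
  of such steps are not meaningful chaos theory, just IEEE arithmetic.
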