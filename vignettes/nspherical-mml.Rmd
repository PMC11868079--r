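---
title: "The N-spherical minimalist classifier: model, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The N-spherical minimalist classifier: model, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphereMML)
```

## The model and its assumptions

The classifier addresses two-class problems in the microarray regime:
hundreds to thousands of numeric attributes, tens to hundreds of patterns,
imbalance ratios up to roughly four. Its premise is geometric: after
restricting the data to a small, well-chosen attribute subset, the two
classes can be separated by a sphere centred at the origin — one class
inside, one outside. The only component of the N-spherical coordinate system
the decision path uses is the radius; the angular components are computed by
`cartesian_to_nspherical()` for inspection but never consulted when
classifying. (The arccos-based angles live in $[0, \pi]$ and lose the sign
of the last coordinate; a zero tail norm defines its angle as 0 so the
transform is total.)

Learning is a fixed pipeline, not an iterative optimisation:

* **T-means.** Per attribute $j$: $T_j = (m_{1j} + m_{2j})/2$, the midpoint
  of the class means. $E_1[j]$ counts class-1 values strictly above plus
  class-2 values strictly below $T_j$ (class 1 assumed *below*); $E_2[j]$ is
  the mirror. Values exactly on the threshold are errors in neither count.
* **Orientation.** $C1_{IN} = \operatorname{mean}(E_1) <
  \operatorname{mean}(E_2)$, with a strict inequality: a tie orients class 1
  outside. The flag couples the univariate picture to the radial one — class
  1 "below the thresholds" corresponds to class 1 "inside the sphere". That
  correspondence is only coherent when informative attribute values are
  nonnegative, which is the regime the model targets (expression-like
  intensities) and the regime the synthetic generator emulates.
* **Two-stage ranking.** Stage 1 keeps the `att` attributes with the fewest
  univariate errors ($E_1$ if $C1_{IN}$, else $E_2$), ties broken by
  ascending attribute index (stable, deterministic). Stage 2 scores each
  survivor by the resubstitution error of its own one-dimensional spherical
  frontier — radial norms here are absolute values — and re-ranks,
  again stably. Stage 2 is what actually finds radially informative
  attributes; stage 1 is a cheap univariate filter.
* **Progressive boundaries.** For $k = 1 \dots \text{bound}$, every training
  pattern's radial norm over the first $k$ re-ranked attributes is computed;
  the $k$-th boundary is the midpoint of the adjacent class extremes,
  $(\max r_{\text{in}} + \min r_{\text{out}})/2$. Prefix norms are
  non-decreasing in $k$, so the boundary sequence tracks a growing geometry.

The **training error** is the minimum resubstitution error over the
progressive boundary sets. The midpoint-of-extremes frontier makes this a
genuinely open design point: a single attribute separating both classes
yields a zero immediately, but on truly radial class structure (concentric
shells) no single attribute separates, and only the multi-attribute
progressive sets reach zero. Defining the training error over the
progressive sets keeps it meaningful as the fitness the hyperparameter
search minimises — it depends on `bound`, so both hyperparameters are
actually tunable — and makes "separable geometry ⇒ zero training error"
hold. The per-attribute stage-2 errors remain available in the fitted object
(`candidate_errors`).

**Classification** projects a pattern onto the learning attributes (in rank
order), computes progressive norms, and lets each boundary vote: with class
1 inside, a norm strictly below its boundary votes class 1; with class 1
outside, strictly above. A norm exactly equal to its boundary votes class 2
(strict inequalities throughout). Class 1 wins with at least half the votes,
so an even split goes to the positive class. Classification is
deterministic and depends only on the attributes in the learning set.

## Tunable parameters

* `att` (count, $1 \le$ `att` $\le L$): candidate attributes surviving the
  univariate filter. An alternative percentage reading (`att_percent =
  TRUE`, `round(att * L / 100)`) is provided; the count form is the default
  because it is the form under which the model's published worked
  arithmetic is reproducible.
* `bound` ($\le$ `att`): number of progressive sets, hence votes. Out-of-range
  values from the tuner are clamped with a warning rather than rejected, so
  the search loop is total.
* Differential evolution (`de_control()`): population `np = 20`, mutation
  `F = 0.5`, recombination `pR = 0.9`, generations `G = 30`, `bound` searched
  in $[1, 15]$ and `att` in $[1, \min(L, 200)]$ by default — canonical
  DE settings for a two-dimensional integer box this small. Donor
  combinations are rounded half away from zero (deterministic across
  platforms), clamped, and repaired to `bound <= att`. Crossover is binomial
  per coordinate with one guaranteed mutant coordinate; the single-gate
  variant (the whole mutant evaluated with probability `pR`, never mixing
  coordinates) is selectable via `crossover = "gate"`. Replacement is
  greedy *minimisation*: a trial replaces its target only when its training
  error is strictly smaller, which is the reading consistent with sorting
  the population by ascending error and returning its head. Fitness
  evaluations are memoised on `(att, bound)` since learning is
  deterministic.

## Evaluation protocol

Leave-one-out cross-validation is used because it is deterministic. Every
fold excludes the held-out pattern from *all* learning computation,
including the column-mean imputation of missing values (means fitted on the
training fold, applied to the held-out pattern). With self-adjustment,
`mode = "per_fold"` re-runs the DE search inside every fold (fold $f$ seeds
the search with `seed + f - 1`); `mode = "global"` tunes once on the full
data and is flagged as optimistic, since the held-out pattern then
influenced the tuning. Aggregation treats class 1 as positive: balanced
accuracy $(\text{tpr} + \text{tnr})/2$ — exactly $0.5$ for any constant
predictor — and F1 $= 2tp/(2tp + fp + fn)$.

Classifier comparison across datasets uses within-dataset midranks (rank 1
= best, ties averaged), the classic chi-square Friedman statistic
$\frac{12}{Nk(k+1)}\sum_j R_j^2 - 3N(k+1)$ with $k-1$ degrees of freedom and
*no* tie correction — the variant under which the packaged benchmark
table's published ranking arithmetic reproduces (base R's `friedman.test`
tie-corrects, and is used as a cross-check only on tie-free data) — and
Holm's step-down post-hoc against the best mean rank:
$SE = \sqrt{k(k+1)/(6N)}$, $z_i = |R_0 - R_i|/SE$, two-sided normal
p-values, thresholds $\alpha/(k-i)$, rejection stopping at the first
failure.

## The synthetic generators, and what passing tests do not show

`radial_shells()` realises the separability premise directly: the inside
class uniform in the ball of radius `inner_radius` (direction uniform on the
sphere, magnitude scaled by $u^{1/d}$ for uniformity in the ball), the
outside class at radii uniform in $[\text{outer}, 2\cdot\text{outer}]$.
Directions are drawn on the **positive orthant**, for two reasons: the
target domain's informative measurements are nonnegative intensities, and
the orientation criterion's below/above-threshold logic only maps onto
inside/outside radial position when informative values are nonnegative.
Appended noise columns are standard normal and carry no class signal, so
attribute-selection correctness is directly assertable (selected attributes
must lie in the informative block). The default spec — 15 + 15 patterns, 3
informative and 50 noise dimensions, radii 1 and 5 — gives a margin four
times the inner radius.

`gaussian_imbalanced()` emulates the imbalanced tabular regime (two
spherical Gaussians, means `mean_shift` apart; with shift 0 any classifier
sits at chance). `inject_missing()` blanks an exact fraction of cells,
never a whole column, so fold-wise mean imputation always has support.

These generators match the model's own assumptions. Passing their tests
shows the pipeline implements its specification and recovers planted
geometry; it does **not** show that real gene-expression data satisfies the
concentric-shell premise, that the univariate filter is optimal, or that
the reported benchmark ranking would transfer to new datasets. Test problem
sizes (tens of patterns, tens of attributes; 200 random datasets of at most
12 patterns × 6 attributes for the brute-force oracle comparison) were
chosen as the smallest scales that exercise every branch — ties included —
while keeping the full suite near ten seconds.

## Numerical conventions and degenerate inputs

* Strictness everywhere: threshold ties count in neither error vector,
  boundary ties are not resubstitution errors, a norm equal to its boundary
  votes class 2, and an orientation tie sets $C1_{IN} = 0$.
* All sorting is stable with ascending-index tie-break; attribute indices
  are 1-based everywhere a user sees them.
* Model JSON is written with 17 significant digits, the shortest
  representation that round-trips IEEE doubles bit for bit.
* Degenerate inputs fail loudly and name the offending entity: a class
  absent from a training split, a fold that loses a class, non-finite
  vector components (by index), non-numeric CSV cells (by row and column),
  more than two labels (the model is binary by construction), model/data
  width mismatches (both widths named).

## Known limitations

Binary classification only; numeric attributes only (labels may be strings;
categorical features are not supported). The arccos angle convention loses
the last coordinate's sign, which is irrelevant to the radius-only decision
path but matters if the angular output is repurposed. The
midpoint-of-extremes boundary is sensitive to single outlying patterns — it
is a minimalist frontier, not a robust estimator. On data whose classes are
not radially structured around the origin (e.g. zero-centred features), the
orientation criterion approaches a coin flip and performance degrades to
chance; centring conventions are the user's responsibility.
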