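# sphereMML

Binary classification of high-dimensional numeric data — the gene-expression
regime where attributes far outnumber patterns and classes are imbalanced —
with the **N-spherical minimalist machine-learning (MML) classifier**, plus
the evaluation machinery that goes with it: deterministic leave-one-out
cross-validation, balanced accuracy and F1, and Friedman/Holm multi-classifier
comparison.

## The model

The minimalist paradigm separates two classes with a single elementary
geometric frontier built from a small attribute subset. Here the frontier is
spherical: one class is modelled as lying *inside* a radial boundary, the
other *outside* it. Learning proceeds in four fixed steps on a training set
split into class matrices `Y1` (class 1, the positive class) and `Y2`:

1. **T-means.** For every attribute *j*, the threshold is the midpoint of the
   two class means, `T[j] = (mean(Y1[,j]) + mean(Y2[,j])) / 2`. Two error
   vectors count strict threshold violations: `E1[j]` assumes class 1 lies
   below `T[j]`, `E2[j]` assumes it lies above.
2. **Orientation.** `C1_IN = mean(E1) < mean(E2)` decides whether class 1 is
   modelled inside (`C1_IN = 1`, ranking by `E1`) or outside (`C1_IN = 0`,
   ranking by `E2`) the spherical frontier.
3. **Two-stage attribute ranking.** The `ATT` attributes with the fewest
   univariate errors are retained, then re-ranked by the resubstitution error
   of each attribute's own 1-D spherical frontier — the midpoint of the
   adjacent class extremes of the per-pattern radial norms,
   `(max r_in + min r_out) / 2`.
4. **Progressive boundaries.** For k = 1 … `BOUND`, the radial norms of every
   training pattern over the first k re-ranked attributes give one spherical
   boundary per nested attribute set. The training error is the minimum
   resubstitution error over these progressive sets.

A test pattern is projected onto the learning attributes; its progressive
radial norms are compared with the boundaries, each comparison casts one vote
(`C1_IN = 1`: inside votes class 1; `C1_IN = 0`: outside votes class 1), and
the majority — with ties going to class 1 — decides. The two hyperparameters
`ATT` and `BOUND` can be self-adjusted by differential evolution
(`DE/rand/1`, trial `x_c + F·(x_a − x_b)`, greedy replacement on the training
error).

## Worked example

Thirty patterns, three informative dimensions (class 1 uniform in the unit
ball, class 2 on the shell of radius 5–10) and fifty pure-noise columns:

```r
library(sphereMML)
d   <- radial_shells(n1 = 15, n2 = 15, informative_dims = 3, noise_dims = 50,
                     inner_radius = 1, outer_radius = 5, seed = 7)
fit <- mml(d, att = ncol(d$x), bound = 3)
fit
#> N-spherical minimalist classifier
#> Class 1 ('1') lies inside the spherical boundaries (c1_in = 1)
#> Learning attributes: inf2, inf3, inf1
#> Spherical boundaries: 0.6078, 2.1464, 3.0255
#> att = 53, bound = 3, training error = 0 (of 30 patterns)
```

The learner recovers exactly the three informative columns and a zero
training error; the boundaries grow with the nested sets because prefix norms
never shrink. A shell pattern classifies by falling outside every boundary:

```r
predict(fit, d$x[16, ], type = "trace")[[1]]
#>  k   norm boundary    vote
#>  1 5.0765   0.6078 class 2
#>  2 5.1350   2.1464 class 2
#>  3 7.1871   3.0255 class 2
#> votes for class 1: 0 of 3 -> predicted class 2
```

Leave-one-out cross-validation is perfect on this geometry, and the
differential-evolution tuner finds a zero-error setting immediately:

```r
mml_loocv(d, att = ncol(d$x), bound = 3)
#> Leave-one-out cross-validation (30 folds, fixed hyperparameters)
#>   balanced accuracy: 1.0000
#>   F1 (positive = '1'): 1.0000
#>   confusion: tp=15 fn=0 tn=15 fp=0

mml_tune(d, seed = 1)$best
#> $att [1] 4   $bound [1] 4   $fitness [1] 0
```

Comparing many classifiers over many datasets uses the rank-test surface on
the packaged benchmark table (balanced accuracies of seven classifiers on
thirteen two-class biomedical datasets):

```r
fr <- friedman_ranks(read_score_matrix(benchmark_scores_path()))
fr$mean_ranks["NSpherical"]   # 1.5 — first of seven
holm_posthoc(fr)              # all six comparisons rejected at alpha = 0.05
```

A command-line wrapper (`inst/scripts/mml`) exposes `train`, `predict`,
`loocv`, `compare` and `simulate` subcommands over the same functions; see
`?mml_cli`.

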