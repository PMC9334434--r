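---
title: "Decoding stimulus class from peck locations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding stimulus class from peck locations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pecktrack)
```

## The scientific setting

In touchscreen categorization experiments a bird learns to sort images of
two artificial stimulus classes (X and Y) and reports its decision on choice
keys. Because the screen also registers the *location* of every peck on the
stimulus, the peck stream is a second, richer behavioral readout: if the
animal attends to class-specific local features, its pecks should cluster on
those features, and the presented class should be decodable from peck
coordinates alone. pecktrack implements that analysis chain — spatial
statistics, a kNN decoder with a permutation null, and choice-performance
statistics — together with a synthetic generator that emulates the pecking
strategies the decoder is designed to distinguish.

## Data model

Pecks live on a square registration region: the stimulus (4 cm) plus a
border (0.5 cm) on which pecks still register, giving a 5 x 5 cm region.
Coordinates are continuous cm with the origin at the region's bottom-left
corner, x rightward and y upward; the physical-units convention makes logs
portable across screen resolutions. Bounds are closed: a peck exactly on the
region edge is in-bounds (border pecks count), and anything outside is
discarded before analysis (`filter_pecks_in_bounds()`). A valid trial has at
least 5 pecks; trials with fewer pecks but a recorded choice are retained
with a warning rather than dropped, because while a conforming apparatus
aborts them, foreign logs may contain them. `no_choice` trials (the choice
window elapsed) are excluded from every analysis, as are aborted trials.
Only stimulus-period pecks (those preceding the choice) are logged.

## Heatmaps and peck concentration

The region is sectioned into a 15 x 15 grid (225 squares of ~0.11 cm²).
Cells are half-open with the top/right edge folded into the last cell, so
every in-bounds peck lands in exactly one square. Counts are normalized to
*relative pecks* — `100 * pecks_in_square / all_pecks` — so heatmaps are
comparable across subjects with different peck totals; a heatmap therefore
always sums to 100. Class difference maps (X − Y) localize
class-specific pecking.

Peck *concentration* is summarized by ranking the 225 squares by descending
count and accumulating the covered fraction of pecks: focused pecking
saturates within a few squares, dispersed pecking climbs slowly. Ties in the
ranking are broken by cell index; this affects only the plotted curve, never
the comparison statistic on distinct counts. Correct- and error-trial
concentration curves are compared by the KS statistic
`D = max_r |C_correct(r) - C_error(r)|`, each curve ranked by its own
descending order. The p-value uses the asymptotic two-sample KS distribution
with the 225 ranked squares of each curve as the sample sizes; this
curve-based construction is one defensible reading of an ambiguous
convention (the alternative — raw peck events as samples — changes n), so
reports should quote D alongside p. Significance is judged at a
Bonferroni-adjusted alpha, 0.05/8 = 0.00625 by default for a cohort of eight
individually tested subjects.

## The kNN decoder

The decoder asks whether peck coordinates predict the presented class. Per
iteration, 250 training and 250 test pecks are sampled without replacement
and disjointly from the relevant pools; each test peck is labeled by the
majority vote of its k = 15 Euclidean-nearest training pecks (odd, and close
to sqrt(250)); accuracy is the percentage of test pecks matching the
presented class. Ten iterations with fresh samples give the accuracy
distribution; events may recur across iterations since each draws a fresh
split. The chance level is estimated by re-running each iteration with class
labels randomly permuted against coordinates within both the training and
the test sample (shuffling only the training labels is available as an
option but is not the default). A paired t test across the 10 iterations
(df = 9, two-sided) with `d = mean(diff)/sd(diff)` yields the verdict:
above chance, below chance, or at chance at the adjusted alpha.

Three train/test regimes probe different questions: **CC**
(correct/correct) — is pecking class-informative at all; **CE** (train on
correct, test on error) — above chance means errors peck the *same* features
(a choice lapse), below chance means the *opposite* class's features (class
confusion), at chance means error pecking is unrelated; **EE**
(error/error) — internal consistency of error pecking. CE and EE run only
when the error pool holds more than 500 events; smaller pools yield an
explicit "insufficient errors" outcome, keeping the gate auditable.

Two controls address sampling concerns. One peck per trial: pecks within a
trial are dependent, so optionally only one randomly chosen peck per trial
enters the candidate pool before sampling. Peck order: decoding restricted
to the i-th peck of each trial (i = 1..5) probes how quickly pecking reaches
class-informative locations; when a rank has fewer than 500 events the
sample sizes shrink to floor(available/2) (minimum 50, recorded in the
report), and ranks under 100 events are skipped.

Numerical choices: distance ties are broken by training-point insertion
order (with continuous coordinates ties have measure zero, but the rule
makes runs reproducible); with odd k and binary labels vote ties cannot
occur. Train/test draws are class-balanced whenever both classes have
enough events, so shuffled-label accuracy is centered on 50%. All
randomness flows through a single seed; a fixed seed reproduces every
report bit for bit.

## Choice-performance statistics

Percent correct is `100 * correct / (correct + error)` within a grouping
(trial type x class, or pooled). Cohort-level tests are the standard
one-sample t against the 50% binary-choice chance level and the paired t
between groupings, both two-sided (sidedness is not prescribed by
convention here, and two-sided is the conservative choice), with effect
sizes `d = (mean - mu0)/sd` and `d = mean(diff)/sd(diff)`. These formulas
satisfy `t = d * sqrt(n)` exactly, which the tests assert.

## The synthetic generator

Raw peck logs from the motivating experiments are not publicly deposited,
so validation uses synthetic sessions whose generative structure mirrors
the task: balanced two-class trials, ~92% correct choices, at least five
pecks per trial (`5 + Poisson(mean - 5)`, mean 8), a fraction (0.11) of
transfer trials, and class-dependent 2D peck distributions. Correct-trial
pecks are isotropic Gaussians (sd 0.4 cm) around class centers at
(1.5, 2.5) and (3.5, 2.5) cm — 2 cm apart, i.e. well separated at that sd —
truncated to the region by resampling. A Gaussian is the simplest unimodal
model matching observed single-hotspot peck maps; real peck fields can be
skewed or multimodal, which this generator deliberately does not emulate,
so passing recovery tests demonstrates the *pipeline's* correctness, not
distributional claims about real birds. Each trial's first peck (default
one) is an *orienting peck* drawn broadly (sd 1.5 cm, a value chosen once
to make early pecks carry little class information while remaining mostly
on-stimulus) around the region center, reproducing the empirical pattern
that first pecks decode worse than later ones.

Strategy archetypes set the error model and learned classes:

| archetype | construction | decoder signature |
|---|---|---|
| `two_class` | both centers, dispersed errors (sd 1.2 cm) | CC high (≥ 80%), CE/EE above chance |
| `one_class` | class-Y trials peck uniformly | CC intermediate |
| `lateralized` | one shared center | CC at chance |
| `confusion` | errors at the opposite center | CE below chance |
| `lapse` | errors at the correct center | CE above chance |
| `random_error` | errors uniform | CE/EE at chance |

The `one_class` archetype exposes only the class-X variant; by label
symmetry (asserted in the tests) a class-Y learner is equivalent. These
defaults *are* the study conditions for the package's validation targets
and are not tuned per run: the shuffled null must sit within 50 ± 3 points
(binomial sd of the mean over 10 iterations of 250 test pecks is ~1 point),
`two_class` CC must reach the ≥ 80% band, and `confusion` CE must fall at
or below 35%. For CE/EE targets the generator runs at `p_correct = 0.70`
over 600 trials so the error pool clears the 500-event gate.

## Stimulus selection

The pre-experiment screen picks, from candidate grayscale renders, the
`n` exemplars per class least correlated with the other class: each
candidate is scored by the mean (optionally max — the aggregation is not
canonical, and the mean is the less outlier-driven choice) of its pixelwise
Pearson correlations to all other-class members, and the lowest-scoring
exemplars are kept (ties by id, making selection input-order invariant).
Whether to correlate raw renders or binarized silhouettes is left to the
caller — the functions take whatever pixel matrices they are given. A
confound check then verifies the classes are not separable by trivial cues,
t-testing object size (pixels above an intensity threshold, default 10/255
— renders have near-black backgrounds) and background black area between
classes.

## Problem sizes and limitations

The validation suite runs sessions of 400–700 trials (~3,000–5,500 pecks)
and decodings of 10 iterations at 250/250 events — sizes at which every
recovery property is comfortably outside sampling noise while the whole
suite completes in a few minutes on one CPU. Known limitations: the
generator's stationarity (no learning within a session), isotropic
single-cluster peck fields, outcome independence across trials, and the
curve-based KS convention discussed above. Empirical per-subject accuracies
from any particular experiment are not reproduction targets — they depend
on undeposited raw data; the package's claims are the analytic facts and
the recovery of its own generative ground truth.
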