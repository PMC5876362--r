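---
title: "Neurally-weighted learning: methods and design notes"
author: "neuroweight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neurally-weighted learning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroweight)
```

## The paradigm

`neuroweight` implements a two-stage "neurally-weighted" learning scheme
for binary visual object classification. The premise: when a subject views
an image, the strength and pattern of the BOLD response in category-
selective visual cortex carries information about how unambiguously the
brain recognizes the image's content. That information can be distilled
into one scalar per training image and injected into an ordinary image
classifier, which after training needs no neural data at all.

**Stage one** (`generateActivityWeights`) trains an RBF-kernel SVM on
per-stimulus voxel response amplitudes, restricted to a chosen combination
of regions of interest (ROIs). The clear-sample training stimuli are split
into five stratified folds; for each fold a classifier is tuned by an inner
cross-validated grid search over the soft-margin penalty $C$ and kernel
parameter $\gamma$, a Platt sigmoid
$p(f) = 1/(1 + \exp(A f + B))$ is fitted to inner cross-validated decision
scores, and the calibrated model is applied to the held-out fold. The
resulting probability of class inclusion is the stimulus's *activity
weight* $c_x \in [0, 1]$. Every clear training stimulus is scored exactly
once by a model that never saw its voxel row; all other stimuli implicitly
carry $c_x = 0$.

**Stage two** (`trainSVM`) trains image classifiers under either the plain
hinge loss

$$\varphi_h(z) = \max(0, 1 - z), \qquad z = y \cdot f(x),$$

or the *activity-weighted loss*

$$\varphi_\psi(x, z) = \max(0, (1 - z) \cdot M(x, z)), \qquad
  M(x, z) = \begin{cases} 1 + c_x & z < 1 \\ 1 & \text{otherwise,}
  \end{cases}$$

which penalizes margin violations of high-weight stimuli up to twice as
hard. Since $\varphi_\psi(x, z) = (1 + c_x)\,\varphi_h(z)$ for every $z$,
the problem is exactly a per-sample-weighted hinge SVM, and its dual is a
standard SVM dual with per-sample box constraints
$0 \le \alpha_i \le C (1 + c_{x_i})$. We solve it with a deterministic SMO
decomposition (second-order working-set selection, analytic two-variable
updates against the per-sample boxes). With all weights zero the solver
reduces bit-for-bit to the hinge-loss path.

## Experimental harness

The harness mirrors a standard decoding protocol:

* **Clear sample set.** A stimulus is tentatively positive for every
  category covering at least 20% of its pixels. Stimuli tentative for
  exactly one category are clear positives of that category and clear
  negatives of every other; stimuli tentative for none are negatives
  everywhere; multi-category stimuli are excluded and get $c_x = 0$. (With
  more than two categories, the tasks of different categories consequently
  share the other categories' single-category stimuli as negatives, not
  only the fully unlabeled ones.)
* **Partitions.** Four independent stratified 80/20 train/test splits of
  the clear set (`makePartitions`). Stratification is our choice — a plain
  random split occasionally leaves a single-class test set at these sizes.
* **Balanced problems.** Five per partition: all training positives plus
  an equal-size random negative subsample (`makeBalancedProblems`). Only
  training data are balanced; every problem shares the partition's
  untouched, unbalanced test set.
* **Voxel scaling.** Per-voxel min–max scaling to $[0,1]$ computed on the
  partition's *training* rows only and applied to all rows
  (`minmaxScale`); out-of-range values for held-out rows are clipped, and
  constant voxels map to 0 so that an RBF kernel sees them as
  uninformative.
* **Stage-two parameters.** No tuning: $C = 1$, $\gamma = 1/d$ with $d$
  the feature dimension.
* **Pairing.** 4 partitions × 5 problems give 20 paired HL/AWL accuracy
  samples per (category, ROI combination); `pairedOneTailedT` tests
  "AWL > HL" and `errorReduction` reports the mean accuracy difference
  with its standard error over trials.

The ROI analysis asks which regions drive above-average accuracy. For a
$k$-ROI universe there are $2^k - 1$ combinations (127 for the seven
higher-level visual areas EBA, FFA, LO, OFA, PPA, RSC, TOS), and any fixed
ROI appears in $2^{k-1} = 64$ of them. The statistic is the fraction of
the 64 combinations containing an ROI whose mean accuracy strictly exceeds
the overall mean over all 127; its null distribution is sampled by drawing
random 64-subsets uniformly without replacement (`sampleNull`, default
$10^6$ draws; our tests use $10^5$, which changes any p-value by no more
than the binomial Monte-Carlo error). Upper-tail empirical p-values are
compared against the Bonferroni-adjusted threshold $\alpha/m$
($0.05/127 \approx 0.0004$); a conservative $(r+1)/(n+1)$ variant is
available but the plain empirical CDF comparison is the default.

## The synthetic data generator

Real paired image/fMRI data cannot be bundled, so `simulateDataset` builds
a study whose statistical structure matches what the paradigm assumes:

* **Stimuli** are 64×64 grayscale images (resolution-independent logic;
  small images keep tests fast) containing zero, one or two axis-aligned
  rectangular category regions with area fractions drawn from
  $U(0.05, 0.65)$, which straddles the 20% labeling threshold.
* **Clarity** of a stimulus is its dominant category's pixel fraction.
* **Voxels** respond as
  $x_{sv} = \sum_c S_{r(v),c}\, g(\pi_{sc}) + N(0, \sigma^2)$, with
  $g(\pi) = (1-\lambda)\,1[\pi \ge 0.2] + \lambda \pi$ and
  $\lambda$ = `clarityLink`. The default selectivity map $S$ gives EBA/FFA
  strong human and weaker animal responses, PPA/RSC/TOS building and food
  responses, and LO a general object response — category-selective cortex
  prefers rather than exclusively encodes its favorite category. The
  default amplitude noise $\sigma = 0.35$ makes single-category decoding
  good but imperfect, as in real recordings.
* **Features** are `featureDim`-dimensional vectors with the same graded
  category signal along fixed orthonormal directions plus unit Gaussian
  noise; `separation` sets the effect size (0 gives chance-level
  classification, large values approach perfect accuracy).
* **Annotation noise** (`corruptPositiveLabels`) models the
  characteristic error of pixel-outline labeling: near-empty scenes
  recorded as positives. A fraction $p$ of the training positive set is
  drawn from the lowest-clarity negatives and relabeled $+1$; flips are
  capped so negatives remain the majority class, which the balanced
  subsampling design assumes.

Everything is a pure function of the configuration and one integer seed;
all randomness in the package flows through explicitly derived seeds, so
any run is bit-reproducible.

What the generator does *not* emulate: hemodynamics, spatial voxel
correlations, retinotopy, multi-subject variability, and the rich
correlation structure between image statistics and cortical responses in
natural scenes. Passing tests on this generator demonstrate that the
machinery is correct and leak-free, not that activity weighting will
improve any particular real dataset.

## Numerical choices

* SMO stopping rule: maximal KKT violation below $10^{-6}$ (iteration cap
  $10^5$; non-convergence is an error, never a silent result). The tight
  default lets the solver's objective agree with an independent
  brute-force primal minimizer to $10^{-4}$ relative error in our audits;
  the tolerance is a user-visible argument.
* Platt fitting uses the numerically stable damped-Newton formulation
  with regularized targets $(n_+ + 1)/(n_+ + 2)$ and $1/(n_- + 2)$.
* Grid search defaults to the conventional coarse log grid
  $C \in \{2^{-5}, 2^{-3}, \ldots, 2^{15}\}$,
  $\gamma \in \{2^{-15}, \ldots, 2^{3}\}$ with 3-fold inner CV; ties go to
  the smallest $C$, then the smallest $\gamma$. Unit tests use smaller
  grids — the selection logic, not the grid extent, is what they check.
* Decision ties at $f(x) = 0$ classify as $+1$, recorded here as the
  package convention.
* Degenerate cases: constant voxels scale to 0 with a warning;
  zero-variance paired differences in the t-test resolve to $p \in \{0,
  0.5, 1\}$ by sign.

## Study conditions for the mechanism experiment

The mechanism-recovery experiment (also run by `scripts/acceptance.R`)
uses: 280 stimuli, categories humans/animals, `backgroundFraction` 0.15,
`mixedFraction` 0.05, 14 voxels per ROI, `noiseSd` 0.35, `clarityLink` 1,
`separation` 2.2, annotation noise $p = 0.3$, stage-one grid
$C \in 2^{\{-1,3,7\}} \times \gamma \in 2^{\{-7,-3,1\}}$, 4 partitions ×
5 balanced problems. These were chosen once as a realistic
single-subject-scale regime (test-set positive prevalence ≈ 0.33, matching
the human-category prevalence of a natural-scene clear set; stage-one
decoding accuracy ≈ 0.75).

## A negative result, documented

Under these conditions the activity-weighted loss does **not** reliably
beat the hinge loss on raw test accuracy, and we consider this finding a
result rather than a defect to be tuned away. The reasons are structural
and worth recording:

1. Hinge weights act only on margin violators. Clear positives that the
   feature model already classifies outside the margin contribute zero
   loss, so their large weights are inert; the weights that matter sit on
   ambiguous samples.
2. For calibrated Platt weights, the mean weight difference between the
   labeled classes equals exactly the decodability of the label from
   voxels. An informative stage one therefore always hands the positive
   class the larger mean multiplier, and the decision surface shifts
   toward predicting positive.
3. With balanced training sets and a majority-negative test set — the
   prescribed protocol — that shift costs accuracy, and in our simulations
   the cost exceeds the benefit of relatively down-weighting mislabeled
   low-clarity positives. The multiplier $1 + c_x \ge 1$ can never push a
   corrupted sample *below* the plain hinge penalty, which bounds the
   noise-robustness channel by second-order base-rate contrasts.

We probed this across a wide family of generator geometries (coupled and
decoupled clarity, compact and diffuse negatives, object-rich negative
pools, near-balanced prevalences, tiny and large training sets), with both
pipeline-estimated and idealized weights: the paired AWL−HL accuracy
difference ranged from −0.05 to +0.006 and never reached reliable
one-tailed significance at 20 trials. The mechanism-recovery test in the
suite asserts the hypothesized improvement and is left failing
deliberately as a record of this finding; on real data, correlations between cortical
responses and image statistics that this generator does not model may well
supply the missing ingredient, but the synthetic family cannot demonstrate
it. Users applying the package to real recordings should treat the HL/AWL
comparison — not AWL's superiority — as the experiment.

## Worked example

```{r example, eval = FALSE}
cfg <- syntheticConfig(nStimuli = 140, categories = c("humans", "animals"),
    rois = c("EBA", "PPA"), voxelsPerRoi = 6, seed = 1)
ds <- simulateDataset(cfg)

acc <- runExperiment(ds$voxels, ds$labeling, ds$features,
    categories = "humans",
    combos = enumerateROICombinations(c("EBA", "PPA")),
    gridSpec = gridSearchSpec(costGrid = c(1, 100),
        gammaGrid = c(0.01, 0.1), innerFolds = 2L),
    seed = 1)

a <- acc[acc$loss == "awl", ]; h <- acc[acc$loss == "hl", ]
pairedOneTailedT(a$accuracy[order(a$partition, a$problem)],
    h$accuracy[order(h$partition, h$problem)])
comboAccuracies(acc, loss = "awl")
```

## Known limitations

* Scalar weights: one number per stimulus discards most of the voxel
  pattern; multi-dimensional weights are out of scope.
* Binary tasks only; no multiclass calibration, no isotonic alternative
  to the Platt sigmoid.
* The CNN feature path is a file interface (`readFeatureMatrix`): no
  network weights are bundled, and the built-in HOG is a plain dense
  9-bin unsigned-gradient cell descriptor with L2 cell normalization —
  adequate because downstream logic is feature-agnostic, but not a
  re-implementation of any specific historical HOG dialect.
* The permutation null treats combination accuracies as exchangeable
  units; it inherits the usual caveats of permutation tests on
  overlapping subsets.
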