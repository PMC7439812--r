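---
title: "Methods: invariant contour signatures, RBF curve fitting and salp-swarm SVM tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: invariant contour signatures, RBF curve fitting and salp-swarm SVM tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the choices that were genuinely open, and what the test suite does and
does not establish.

## The shape signature

A leaf silhouette enters the pipeline as a binary mask, an integer matrix
in the y-up convention (row 1 is the bottom image row; pixel centers at
integer coordinates). `extractContour()` keeps the largest connected
foreground component, ignores interior holes, and traces the *crack
boundary* — the marching-squares walk along pixel edges with foreground on
the left. The emitted pixels are exactly the foreground pixels that touch
the exterior background through a 4-neighbour side, ordered
counter-clockwise, and the traversal is closed with unit steps. The tests
verify this set equality against a brute-force scan on random blobs. Two
degenerate inputs are rejected with distinct errors: masks without
foreground, and components with no interior pixel (everywhere thinner
than 2 px), whose "contour" would be the whole component.

The centroid is the arithmetic mean of the *boundary* points — not the
area centroid. For nearly convex leaf outlines the two are close, but the
boundary mean is what the distance definition below pairs with, and the
package keeps it consistently. Each boundary point contributes a distance
$D_i$ to the centroid; dividing by $\max_i D_i$ removes scale, and
measuring angles counter-clockwise from the reference axis (centroid →
farthest point) removes rotation. Translation never enters. The signature
is circular: the package stores angles in degrees in $[0, 360)$ and all
curve machinery works on the circle.

**Tie-break.** When several points are within $10^{-9}$ relative tolerance
of the maximum distance, the smallest traversal index wins — an arbitrary
but deterministic rule.

**Reference-axis stability.** The invariance of the signature under
rotation hinges on the farthest point being well defined. A shape whose
radial profile has two nearly tied lobes (for example, a dominant $k = 2$
harmonic perturbed by a weak incommensurate harmonic, leaving the two
lobes a few percent apart) can flip its reference axis between lobes
under rasterization noise, which shifts the whole signature by roughly
the inter-lobe angle. Purely symmetric shapes are immune (a flip maps the
signature onto itself), and shapes with one dominant lobe are safe. The
invariance tests therefore use dominant-lobe and symmetric templates;
this is a real property of farthest-point referencing, not a test
artifact, and users comparing signatures of near-symmetric leaves should
be aware of it.

## Periodic RBF curve fitting

The discrete signature is regressed onto a continuous curve
$\hat d(\theta) = b + \sum_{k} w_k \exp(-\beta_k\, d(\theta, \mu_k)^2)$,
with $d$ the circular angular difference in degrees wrapped to
$[-180, 180)$. Using circular distance in the basis makes the fitted
curve 360°-periodic by construction and avoids endpoint artifacts at
0°/360°, which an open-interval fit of a "circular list" would suffer.

The spread is parameterized directly as $\beta = 1/(2\sigma^2)$ and
optimized on the log scale, which enforces positivity without
constraints. Units: centers in degrees, $\beta$ in degrees$^{-2}$
(initial draws correspond to $\sigma$ between roughly 5° and 70°).

With centers and spreads fixed the model is linear, so the output weights
are never searched: `fitWeights()` solves the ridge-damped least-squares
problem ($\lambda = 10^{-8}$, QR on the augmented system; the damping is
for conditioning only, and the tests confirm agreement with explicit
normal equations to $10^{-8}$).

The genetic algorithm searches what least squares cannot: the number of
centers (3–25), their angles and their log-spreads. Encoding is
real-coded and variable-length; selection is tournament of 3, crossover
mixes the two parents' gene pools, mutation jitters centers by 5° and
log-spreads by 0.1, a structural move adds or drops a unit with
probability 0.1, and one elite survives unchanged — which is why the
per-generation best fitness is non-increasing, a property the tests
assert. Fitness is the RMSE on a held-out 20% of the signature points
(split seeded per shape), mirroring the package-wide target of a held-out
fit error below 1%. The search stops at that target, after 30 generations
without improvement, or at the generation cap (default 1000). The best
model so far is always returned with a `targetMet` flag, so an unmet
target is visible rather than fatal.

On rasterized shapes the achievable RMSE is bounded below by pixel
quantization (roughly $0.5/R$ for base radius $R$) plus whatever radial
noise the shape carries; at the sizes used here (radius 60–100 px, noise
0.5%) the 1% target is comfortably reachable, which the acceptance tests
check.

## Feature vectors

`sampleFeatures()` evaluates the fitted curve at $0, s, 2s, \dots$
degrees from the reference axis; $s \in \{30, 20, 10, 8\}$ gives 12, 18,
36, 45 features. Values are kept as the curve produces them — they may
slightly overshoot 1 near the reference lobe; no clipping or
renormalization is applied, so the feature map stays a linear readout of
the fitted curve.

## Classifiers

**Prototype RBF network.** Every training vector is stored as a hidden
unit; its activation for input $x$ is $\exp(-\beta_k \lVert x - \mu_k
\rVert^2)$, so a prototype activates to exactly 1 on itself. The output
layer is linear with one unit per class. The training procedure for this
output layer is genuinely underspecified in the literature this design
follows; the package's reading is: a GA searches per-neuron log-spreads
(initialized around the inverse median pairwise squared distance), and
for every candidate the output weights are re-solved by damped least
squares against one-hot targets on the training part, with fitness the
score RMSE on a stratified inner validation split. Prediction is the
argmax score, ties to the lexicographically smallest label.

**SVM.** The soft-margin dual with box constraint $0 \le \alpha_i \le C$
is the contract; the quadratic program itself is solved by libsvm
(through `e1071`) at tolerance $10^{-6}$ — the package's contribution is
the pipeline and the tuning, not a new QP solver. The exposed parameters
are exactly $C$ and the kernel width $\sigma$ with $K(x, x') =
\exp(-\lVert x-x'\rVert^2 / (2\sigma^2))$; libsvm's `gamma` is derived as
$1/(2\sigma^2)$ and the $\alpha$-bound is re-verified after every
training. Multiclass is one-vs-one (the standard choice for kernel SVMs;
subproblem size stays bounded). The tests cross-check decision values
against an exhaustive active-set enumeration of the dual on instances
with $n \le 8$, to $10^{-4}$.

## The Salp Swarm Algorithm

`ssaMinimize()` is a generic bound-constrained minimizer. One leader
(agent 1) moves around the best-ever position $F$:
$p_j = F_j \pm s_1((uppb_j - lowb_j)s_2 + lowb_j)$ with $s_2, s_3 \sim
U[0,1]$ drawn independently per dimension and the sign decided by
$s_3 \ge 0.5$; followers update sequentially to the midpoint of
themselves and their already-updated predecessor. All positions are
clamped to the box after every move. $s_1 = 2e^{-(4L_c/L_M)^2}$ decays
from 2 to effectively 0, shifting the swarm from exploration to
intensification. Design points that were open and decided here:

* exactly one leader — the follower rule applies from agent 2 on;
  variants with half the swarm leading exist, but the single-leader form
  matches the update equations implemented;
* the follower chain uses current-iteration predecessor values
  (sequential semantics), since the midpoint rule mixes updated and
  non-updated positions otherwise;
* $F$ is the best-ever evaluated position, never replaced by a worse
  incumbent, so the best-value trace is non-increasing (asserted in the
  tests);
* non-finite objective values are treated as $+\infty$: such agents are
  never adopted as $F$;
* termination: iteration cap, a target objective value, or stagnation
  (default patience 30 iterations without improvement);
* the search runs on the linear scale of the printed bounds.

`ssaSvmTune()` searches $(C, \sigma)$ in $[0.01, 1000] \times [0.01,
100]$ with 20 agents and a default stopping objective of 0.025. The
objective trains an SVM on an inner 80% of the *training* data and
scores the misclassification rate on the remaining 20% (stratified,
seeded, fixed for the run). Tuning on an inner validation split — rather
than on the test set — is a deliberate leakage guard: the held-out test
set is never visible to any tuning objective, and the experiment driver
enforces this by construction. The plain-SVM baseline is tuned by a
20 × 20 log-grid over the same box on the same kind of inner split.

## The synthetic shape generator

Real leaf datasets are large and external; the generator replaces them
with shapes whose ground truth is analytic. A class template is a
star-shaped region $r(\theta) = R(1 + \sum_k a_k \cos(k\theta +
\phi_k))$: the CCD signature of a star-shaped region is exactly its
normalized radial profile, so every downstream stage can be checked
against a closed form. Boundary roughness is injected as Gaussian noise
on the radius *before* rasterization (default sd 0.5% of $R$), emulating
contour-level variability of real leaves rather than pixel salt-and-pepper
noise; masks are post-processed to the largest component with holes
filled so signature preconditions always hold. Within a class, samples
jitter harmonic amplitudes (sd 0.01) and phases (sd 0.05 rad) and undergo
random rotation ($[0°, 360°)$), scaling ($[0.5, 2]$) and translation
within the canvas margin — so only transform-invariant features can
separate the classes. Class templates are validated to be pairwise
distinguishable: the minimum L2 distance between noiseless 36-point
template signatures must exceed 5× the radial noise sd.

What the generator does *not* emulate: petioles and self-occlusions,
non-star-shaped outlines (deeply re-entrant lobes where the boundary
crosses a radius more than once), serrated margins at sub-pixel scale,
and segmentation artifacts. Passing tests on synthetic data therefore
demonstrate the correctness and invariance of the pipeline, not
field-level accuracy on real herbarium scans.

## Experiment protocol

`runExperiment()` fits one curve per shape (shared across angle steps),
then for each step and classifier: an 80/20 stratified train/test split,
hyperparameter tuning on the training part only, stratified 10-fold
cross-validation of the tuned configuration on the training part, and a
final score on the held-out test part. Accuracy is 1 minus the error
rate. UCI-style 64-value signature rows can be used in place of masks;
they are treated as uniform angular samples and refitted by the same RBF
machinery.

## Problem sizes

The package's standing checks use desk-scale instances chosen once: the
curve-fit quality target uses one shape of base radius 100 px (≈ 650
signature points); the tuning target uses 5 classes × 40 shapes at 36
features; the invariance suite uses two dominant-lobe shapes against 4
rotations, 2 scales and a translation; the classifier-ordering check uses
5 classes × 12 shapes over 5 seeds. All stochastic stages are seeded, and
the acceptance script derives every seed from its `--seed` argument.

## Known limitations

* The farthest-point reference axis is unstable for shapes with nearly
  tied radial lobes (discussed above).
* The boundary-point centroid of a strongly non-star-shaped outline can
  fall outside the region; distances remain well defined, but the
  signature is no longer a single-valued function of the angle, and the
  periodic fit will average crossing branches.
* The GA and SSA are stochastic searches with no optimality guarantee;
  the package mitigates this with elitism, best-ever bookkeeping, seeded
  determinism, and oracle cross-checks at small sizes.
* JSON model export of an SVM records the mathematical object (support
  vectors, dual coefficients, biases, $C$, $\sigma$) for interchange, not
  a loadable R object; retrain or keep the in-memory model for
  prediction.
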