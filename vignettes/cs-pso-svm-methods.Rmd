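---
title: "Metaheuristic hyperparameter tuning for clinical SVM classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaheuristic hyperparameter tuning for clinical SVM classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspsosvm)
```

## The problem

Soft-margin kernel SVMs are strong classifiers for tabular clinical data
(disease present / absent), but their generalization hinges on two
hyperparameters the user must supply: the penalty $C$, which trades margin
width against training error, and the kernel parameter (for the radial basis
kernel, the width $\sigma$). Grid search over $(C, \sigma)$ is expensive and
coarse; `cspsosvm` instead tunes them with population metaheuristics, and in
particular with a two-stage hybrid: **cuckoo search** explores the space
globally with heavy-tailed Lévy jumps, then a **particle swarm** refines the
cuckoo stage's solutions. Genetic-algorithm and plain-PSO tuners are included
as the customary baselines, and a comparison runner benchmarks all three on a
shared train/test split.

## The classifier

For labels $y_i \in \{+1, -1\}$ the soft-margin SVM solves, in its dual form,

$$\max_\alpha \; \sum_i \alpha_i - \tfrac12 \alpha^\top H \alpha,
\qquad H_{ij} = y_i y_j k(x_i, x_j),$$

subject to $0 \le \alpha_i \le C$ and $\sum_i \alpha_i y_i = 0$. Points with
$\alpha_i > 0$ are the support vectors; a new point is labeled by
$\mathrm{sign}\!\left(\sum_i \alpha_i y_i k(x_i, x) + b\right)$, with an exact
zero mapped to $+1$ by convention. Available kernels are linear, polynomial
$(x \cdot z + a)^b$, radial basis $\exp(-\lVert x - z\rVert^2 / 2\sigma^2)$,
and sigmoid $\tanh(a\, x \cdot z - b)$. The sigmoid kernel is not positive
semi-definite in general, so training with it warns and falls back to
endpoint evaluation inside the solver wherever the restricted two-variable
problem is non-concave. The RBF kernel is the experiment default: it is the
standard choice in the SVM-tuning literature and makes the search space the
two log-scaled dimensions $(C, \sigma)$.

### The SMO solver

The dual is solved by sequential minimal optimization in compiled code:
repeatedly pick a pair $(\alpha_{i_1}, \alpha_{i_2})$, solve the
two-variable subproblem analytically, and update an error cache. Sweeps
alternate between all examples and the non-bound subset, examining
KKT violations at tolerance `tol` (default $10^{-3}$); the partner index
maximizes $|E_1 - E_2|$ with randomized fallback scans driven by R's RNG, so
a fixed seed reproduces the model exactly. A sweep cap (default 1000)
bounds the worst case — extreme $C$ values proposed by the optimizers on
non-separable data may hit it, which is reported by a warning and, inside
the fitness function, simply scored as-is. On problems of up to six points
the solver is tested against two independent oracles: a coarse-to-fine grid
search of the dual (after eliminating one multiplier through the equality
constraint) and an interior-point QP solve.

The bias is recomputed after convergence by averaging
$y_v - \sum_i \alpha_i y_i k(x_i, x_v)$ over support vectors, preferring the
unbounded ones ($0 < \alpha_v < C$), which lie exactly on the margin;
bounded support vectors only constrain $b$ to one side, so they enter the
average only when no unbounded ones exist.

## The tuners

All four searchers maximize the same fitness (below) over a box in *encoded*
coordinates: log-scaled dimensions are searched in $\log_2$ units, so the
defaults $C \in [2^{-5}, 2^{15}]$ and $\sigma \in [2^{-4}, 2^4]$ become the
rectangle $[-5, 15] \times [-4, 4]$. Every optimizer is elitist (the best
solution ever seen survives), keeps every evaluated position inside the box
by clamping, counts its objective evaluations, and records a per-generation
trace of best fitness, mean fitness, and best position.

**PSO.** Standard global-best particle swarm:
$v \leftarrow w v + c_1 r_1 (p - x) + c_2 r_2 (g - x)$, $x \leftarrow x + v$,
with $c_1 = 1.5$, $c_2 = 1.7$ (the reference settings), velocities clamped to
20% of each dimension's range, and inertia $w$ decaying linearly from 0.9 to
0.4 across the run (a fixed $w$ is available). The decay schedule is the
common default when no value is published: early exploration, late
exploitation.

**Cuckoo search.** Twenty nests, one egg each. Per generation every nest
proposes a Lévy-flight candidate
$x' = x + \alpha \cdot \mathrm{Levy}(\lambda) \cdot (x - g)$ with
$\lambda = 1.5$ and step scale $\alpha$ = 1% of each dimension's range
(Mantegna's algorithm generates the stable variates; when $x = g$ the drift
vanishes and the step is applied directly so the best nest is not frozen).
The candidate replaces its parent nest when strictly fitter — the rule of
the reference implementation of cuckoo search; comparing against a uniformly
random nest instead, as the textbook pseudocode states, is available via
`acceptance = "random"`, but its late-stage refinement is measurably slower
and it fails the known-optimum recovery study below. Then the worst
$\lfloor P_a \cdot \mathrm{pop} \rfloor$ nests (best excluded) are abandoned
and re-seeded uniformly at random, with $P_a = 0.25$.

**GA.** Real-coded baseline: roulette selection on min-shifted fitness,
blend (extended intermediate) crossover with probability $p_c = 0.5$ —
each child gene is $t x_1 + (1 - t) x_2$ with an independent
$t \sim U(-0.5, 1.5)$, so children may fall slightly outside the parents'
span — per-gene Gaussian mutation with probability $p_m = 0.005$ and
standard deviation 10% of the range, and 1-elitism. The blend form matters:
with $p_m$ this small, pure convex recombination collapses the population
to a point within about ten generations and the search stalls far from the
optimum; the extension keeps enough diversity for steady refinement while
remaining a textbook real-coded GA.

**CS → PSO hybrid.** The headline tuner splits one budget of 100
generations (population 20) into a cuckoo stage and a swarm stage,
`cs_fraction = 0.5` by default, i.e. 50 + 50. The swarm starts from the
final nest positions with zero velocities and its global best set to the
cuckoo best, so the concatenated trace is monotone and the final answer can
never be worse than the cuckoo stage's. Whether the cuckoo stage should
hand over its whole population or only its best solution is ambiguous in
the source material; both are implemented (`transfer = "population"`, the
default, and `"best"`). Population transfer preserves the search diversity
the first stage paid for, which is why it is the default.

## The fitness function

The objective the tuners maximize is the mean **stratified 5-fold
cross-validation accuracy** (in percent) of an SVM trained at the candidate
$(C, \sigma)$ on the training split. The original experiments never state
their fitness function; CV accuracy is the standard choice in the PSO-SVM
literature this design follows. Because reported 100% training accuracies
suggest some published tunings scored the training set directly,
`fitness_mode = "train"` offers that (cheaper, leakage-prone) alternative.
Fold assignment is deterministic given the seed, so fitness is a pure
function of the candidate — a requirement for reproducible runs and for the
elitist bookkeeping to be meaningful.

## Data handling

UCI-style `.data` tables (comma- or whitespace-separated, label in a
configurable column) are read with raw labels preserved; the clinical 1/2
coding maps to $+1$ (benign) / $-1$ (malignant) by default, and the metrics
treat the malignant class as positive by default — both configurable, since
the source tables do not state which class their precision/recall treat as
positive. Missing-value tokens (`?`) error by default or drop rows on
request. Features are min-max scaled to $[0, 1]$ **on the training rows
only**, and the stored ranges are applied to the test rows (values outside
$[0, 1]$ are allowed, no clipping): scaling on the pooled data before
splitting would leak test information into training. The original material
says only that attributes are "normalized firstly", so this is a documented,
deliberately conservative reading.

The split takes a stated number of training rows (190 of 270 for the
heart-shaped problem, 549 of 699 for the breast-shaped one) as a stratified
random sample under a seed; `order = "first-n"` reproduces a file-order
split for users who believe the original used one. How the original 190/549
rows were chosen is not disclosed, which is the main reason its exact
accuracies are not reproducible and are treated here as plausibility
anchors rather than targets.

## The synthetic generator

`generate_synthetic()` stands in for the UCI downloads: two spherical unit
variance Gaussians whose means are `separation` apart along the normalized
all-ones direction, so every feature carries equal signal. Its defaults are
frozen to a heart-shaped condition — 150 + 120 samples, 13 features,
separation 2.5 — chosen because the Bayes accuracy of that geometry,
$\Phi(2.5/2) \approx 0.89$, matches the ~80–90% test-accuracy regime of the
clinical benchmarks. What it does **not** emulate: mixed discrete/ordinal
features, class-conditional covariance structure, label noise, and
informative-vs-noise feature splits, all present in real clinical tables.
Passing tests on this generator therefore demonstrate that the machinery
(solver, tuners, pipeline) is correct and competent, not that any accuracy
level will transfer to a particular real dataset.

## Numerical choices and degenerate inputs

* Support-vector threshold: $\alpha_i > 10^{-8} C$.
* SMO step acceptance requires a relative change of at least $10^{-12}$;
  KKT tolerance $10^{-3}$ by default, tightened in tests that compare
  against the QP oracles.
* Constant features min-max scale to 0; empty datasets and single-class
  training sets error.
* Degenerate metric denominators (no predicted or no true positives)
  return 0 with a warning rather than `NaN`, the usual reporting
  convention.
* Ties on equal fitness keep the incumbent everywhere, so constant
  objectives leave optimizer state fixed.
* Exactly-zero decision values predict $+1$.
* Budget accounting is part of the contract and asserted in tests:
  `pop + pop * iters` evaluations for PSO and GA,
  `pop + iters * (pop + floor(pa * pop))` for cuckoo search, and the sum of
  its stages for the hybrid (population transfer re-uses the nest
  fitnesses; best-only transfer re-evaluates the fresh swarm).

## Problem sizes used in the shipped studies

The test suite solves the dual oracle comparisons on 3–6-point problems,
the invariant checks on 15–40-point problems, and the known-optimum
competence study on the 2-D quadratic bowl $f(x) = -\lVert x \rVert^2$ over
$[-5, 5]^2$ with 100 seeded runs per optimizer at the reference budgets
(population 20, 100 generations): PSO, cuckoo search, and the hybrid must
finish within $10^{-2}$ of the origin in at least 95 of 100 runs, the GA
within $0.1$ in at least 90. The acceptance script runs the full three-way
comparison on the default heart-shaped generator output and a separable
sanity check (separation 10), where the hybrid must report 100% train and
test accuracy.

## Known limitations

* Binary classification only; no multi-class scheme, no probability
  calibration, no SVM regression.
* The tuned space is $(C, \text{kernel parameter})$; tuning an
  $\varepsilon$-insensitive loss parameter — regression vocabulary that
  appears in the source material despite the classification task — is
  deliberately not offered.
* Published benchmark accuracies on the real UCI tables depend on an
  undisclosed split and fitness function; this package reproduces the
  method and its internal consistency (e.g. every published F-measure
  follows from its precision/recall pair to the printed precision), not
  those exact numbers.
* Metaheuristics are stochastic: a single run's report is seed-dependent,
  which is why the runner exposes the seed everywhere and the comparison
  holds the split fixed across algorithms.
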