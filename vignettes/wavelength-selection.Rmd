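---
title: "Wrapper wavelength selection with a genetic algorithm and SVM fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper wavelength selection with a genetic algorithm and SVM fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavesel)
```

## The problem

Mid-infrared (FTMIR-ATR) spectroscopy discretizes an absorbance spectrum
into a few hundred variables — here V = 176 wavelengths per sample. For
authentication tasks such as classifying fruit-juice dilutions by
concentration level, most of those variables are redundant (neighboring
wavelengths are strongly correlated) or uninformative (baseline and noise).
Classifying on the full spectrum can even hurt: over-information makes the
classifier generalize poorly. The goal of this package is wrapper feature
selection: find a minimal subset of wavelength indices such that a
classifier trained on the subset alone assigns samples to their
concentration class.

The selector is a hybrid: a genetic algorithm (GA) searches the space of
index subsets, and the score (fitness) of each candidate subset is obtained
by actually training support vector machines (SVMs) on the projected data —
the classifier itself is the evaluation function. Because the SVM dual
problem is convex and the solver is deterministic, a given subset always
receives the same fitness; this repeatability is the central advantage over
neural-network fitness functions, whose stochastic weight initialization
makes selected variables unstable across runs.

## The classifier

Each binary machine solves the soft-margin problem

$$\min_{w,\xi}\ \tfrac12 w^T w + C\sum_{i=1}^N \xi_i,$$

where the slack variables $\xi_i$ absorb non-separable samples and $C$
trades margin width against training error: larger $C$, narrower margin,
fewer training errors. Kernels available are linear
$\langle x, y\rangle$, Gaussian $\exp(-\|x-y\|^2/2\sigma^2)$ (the default;
its width $\sigma$ is the "radial" parameter of chemometric SVM tables) and
polynomial $(\langle x, y\rangle + 1)^n$.

Multiclass problems use one-vs-rest (OVR): one binary machine per
concentration class, that class relabeled $+1$ against all the rest.
Prediction takes the class with the largest decision value
$f_c(x)=\sum_i \alpha_i y_i K(s_i, x)+b_c$ (first class wins ties, for
determinism). Error counting, however, is *strict*: a sample counts as
correct only when **every** machine places it on the correct side — its own
class machine positive, all others negative. Strict correctness implies
argmax correctness, never the converse, so strict error counts are an upper
bound and a deliberately severe yardstick.

### Numerical choices

* **Solver.** A sequential-minimal-optimization (SMO) solver over the dual,
  with second-order working-set selection and lowest-index tie-breaking.
  There is no random element: identical inputs give bitwise-identical
  models.
* **Stopping tolerance.** The `epsilon` hyperparameter is the solver's
  duality-gap tolerance, applied *relative to C*: iteration stops when the
  maximal KKT violation is at most $\varepsilon\max(1, C)$. The dual
  gradient scales with $C$, and an absolute gap of $10^{-6}$ at $C=10^4$ on
  non-separable data is beyond what double precision and any practical
  iteration budget deliver (the reference LIBSVM implementation needs
  $\sim10^7$ iterations on an 86-sample projection of our own fixture).
  A hard iteration cap ($10^7$) turns pathological non-convergence into an
  error rather than a silent bad model.
* **Standardization.** Features are standardized (zero mean, unit variance,
  statistics from the training portion only) before kernel evaluation, and
  the standardizer is stored in the model. The source study is silent on
  scaling, but Gaussian widths of order 2–10 are only meaningful on a
  normalized scale. Constant columns pass through with unit scale.
* **Classification MSE.** The per-machine score is the mean over all
  evaluated samples of $(f(x_i)-y_i)^2$ *restricted to misclassified
  samples* ($y_i f(x_i)\le 0$; correct samples contribute zero). This
  definition is zero exactly on perfect separation, grows with both the
  count and the depth of misclassification, and is deterministic — the
  three properties the GA fitness relies on. The historical WinSVM tool
  that inspired it documents only "a mean squared error measuring the
  distance of incorrectly classified samples", so the precise residual form
  is a design choice of this package.

## The genetic algorithm

An individual is an ordered set of distinct 1-based variable indices; runs
may fix the length (the standard configuration uses pairs, length 2) or
draw lengths from a range at initialization. Defaults follow the canonical
simple-GA configuration: 100 individuals, 100 generations, wheel-roulette
selection, uniform crossover at rate 0.90, uniform mutation at rate 0.10,
generational replacement.

Operator details that the word "uniform" leaves open were fixed as follows:

* **Initialization** redraws a whole candidate combination until its genes
  are distinct, which keeps the distribution uniform over distinct tuples.
* **Roulette scores.** The GA minimizes fitness but roulette needs
  non-negative goodness, so selection uses
  $s_i = (\max_j f_j - f_i) + 10^{-12}$; an all-equal generation degrades
  gracefully to uniform selection. This transform is scale-free and
  introduces no selection-pressure constant to tune.
* **Crossover** exchanges aligned positions (up to the shorter parent's
  length) with probability 1/2, complementary between the two children;
  tails of a longer parent stay with the same-length child, so lengths are
  inherited and no cut-and-splice length changes occur — length diversity
  enters only through initialization. Duplicate genes created by mixing are
  repaired by redrawing uniformly from the indices absent from that child.
* **Mutation** replaces each gene, independently with the mutation
  probability, by an index drawn from outside the individual, preserving
  distinctness and length.
* **Elitism** (on by default) re-inserts the best-so-far individual over
  the worst child, which makes the best-fitness trace monotone
  non-increasing — an invariant the test suite asserts.
* **Stopping**: generation cap; positional convergence (at every gene
  position, 95 % of the population carries the same index; only meaningful
  in fixed-length mode); optional stagnation window (no improvement
  $>10^{-12}$), off by default since the standard configuration fixes 100
  generations.
* **Reproducibility.** One master seed derives named substreams
  (initialization, selection, crossover, mutation), so each operator is
  reproducible in isolation and a whole run — trace included — is
  bitwise repeatable.

## Fitness

Two variants connect the GA to the classifier, both computed after
projecting the data onto the individual's variables and training a full OVR
model on the projected training partition:

* `mse_train`: the sum over classes of the binary training MSE;
* `mse_train_plus_test`: the training sum plus the same sum on the test
  partition (the commercial partition is never used in fitness, only in
  reporting).

Per-class MSEs are summed unweighted even under class imbalance. SVM
hyperparameters are fixed for the whole run — chosen beforehand by
`random_parameter_search()`, which draws 100 (C, epsilon, sigma) triples
(log-uniform in $C\in10^{[-1,5]}$ and
$\varepsilon\in10^{[-7,-2]}$, uniform in $\sigma\in[0.5,20]$, spanning the
values reported for this family of problems), ranks them by summed OVR
training MSE, and keeps draw order among ties. Fitness evaluations are
cached by sorted gene tuple; since fitness is deterministic and
order-invariant, the cache changes cost, never results.

## The synthetic generator

Real FTMIR juice spectra are not publicly deposited, so the package ships a
generator that emulates their statistical structure and provides planted
ground truth. A sample of concentration $c$ (percent juice) is

$$x_v = \mathrm{baseline}(v) + \sum_{j\in\mathcal I} a(c)\,g_j\,[v=j]
 + \text{redundant copies} + \varepsilon_v,$$

with $\mathcal I$ the informative indices (default $\{94, 95\}$, the pair a
Procrustes-rotation analysis of the original data found sufficient),
$a(c) = 0.01\,c + 0.1$ an affine Beer–Lambert-like concentration-to-
absorbance map, $g_j$ a Gaussian band profile across the informative
indices, and $\varepsilon_v$ white noise (default sd 0.01 absorbance
units). Neighbors within `redundancy_spread` (default 2) of an informative
index receive a scaled copy of its signal (factor 0.8 per index step, plus
independent jitter), so the selector must cope with correlated decoys;
recovery is accordingly scored as hitting the planted indices ±
`redundancy_spread`. The baseline is one fixed low-order polynomial shared
by all samples, so it cannot leak class information.

Default class designs mirror the two dilution studies: a high-concentration
set (20/25/50/70/100 %, 86 train / 44 test / 21 commercial samples) and a
low-concentration set (2–20 %, 134 / 39 / 2). With `noise_sd = 0` and
`redundancy_spread = 0` the construction is exactly separable at the
planted indices and every other variable is class-constant — the fixture
used by the exactness tests.

Chosen-once realism defaults (not revisited after seeing test outcomes):
noise sd 0.01 reflects the high signal-to-noise of FTMIR absorbances while
leaving adjacent levels (20 % vs 25 %, gap 0.05 absorbance at the planted
index) genuinely confusable; amplitude slope 0.01 per percent keeps
absorbances in a realistic 0.1–1.2 range over 2–100 %.

### What a green test does and does not establish

The generator plants a *point* signal in index space with known ground
truth; real spectra have many overlapping bands, multiplicative scatter
effects and instrument drift, none of which are modeled. A green recovery
test therefore establishes that the selector finds concentrated class
information among correlated and noisy decoys — not that it would single
out the same two wavelengths on any real instrument's data.

## Design choices on genuinely open points

* **"Radial" = Gaussian σ** and the Gaussian kernel as default: it is the
  only listed kernel with a radial width, and parameter tables pair
  (C, epsilon, radial).
* **"Epsilon" is a solver tolerance, not a regression tube** — the task is
  pure classification.
* **Test partition in `mse_train_plus_test` is the test role only**; the
  commercial role is a held-out check that never influences search.
* **Class labels are opaque categories**: no ordinal structure of the
  concentration scale is exploited, matching the pure-classifier design.
* **Variable indexing is 1-based at every interface** (files, reports,
  genes), as in the field's own reporting of "variable 94 and variable 95".

## Known limitations

* The directional claim that `mse_train_plus_test` yields no worse strict
  test-error rates than `mse_train` is *not* reproduced on the synthetic
  fixture under hyperparameters chosen by the prescribed random search:
  ranked only by full-spectrum training MSE, the search ties at zero on the
  separable fixture and its draw-order winner (wide σ) underfits
  two-variable projections, where depth-weighted MSE and strict error
  counts decouple. The corresponding acceptance test is left failing by
  design, with the measured means in its output, rather than weakened.
* Strict OVR error counting is harsh under class imbalance; a subset can
  have excellent argmax accuracy while most samples fail strict
  correctness.
* The SMO solver targets dataset sizes of this problem family (tens to a
  few hundred samples); it computes the full kernel matrix and does not
  implement shrinking or caching for large N.
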