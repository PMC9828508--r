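---
title: "Atomic GPR potentials by MEPE active learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atomic GPR potentials by MEPE active learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atomgpr)
```

## The modelling problem

`atomgpr` builds per-atom Gaussian process regression (GPR, kriging) models
of atomic energies for a single molecule in vacuum. Every atom gets its own
model: inputs are geometric descriptors of the whole system expressed in that
atom's local frame, the output is the atom's energy contribution (kJ/mol),
and the molecular energy is recovered as the sum of the atomic predictions.
Because labelling a configuration with per-atom energies is the expensive
step in real pipelines (ab initio calculation plus a quantum-topological
energy partition), training sets are grown frugally by active learning:
starting from a small seed design, each iteration adds the sample
configurations the current model expects to predict worst.

## Atomic local frame features

An atom's local frame (ALF) is defined by three atoms: the origin (the atom
itself), an x-axis atom, and an xy-plane atom. Partner atoms are chosen once,
on a reference geometry, by a deterministic rule: neighbours in the
covalent-radius bonding graph (cutoff 1.2 times the radius sum) are ranked by
a Cahn–Ingold–Prelog-like priority — descending atomic mass, ties resolved by
recursively comparing substituent masses level by level, final ties by lowest
atom index — and the two highest-ranked become the x-axis and xy-plane atoms.
Terminal atoms with a single bonded partner extend the candidate list with
the nearest atoms by distance. Freezing the ALF on the reference frame keeps
the feature map identical across all frames of a trajectory.

The feature vector of an atom is

1. the origin-to-x-axis distance (Å),
2. the origin-to-xy-plane distance (Å),
3. the valence angle between those two vectors (rad), then
4. spherical-polar triples (r, θ, φ) of every remaining atom in ascending
   index order, in the frame x̂ ∥ origin→x-axis,
   ẑ = x̂ × (origin→xy-plane) (normalized), ŷ = ẑ × x̂, with θ ∈ [0, π]
   measured from ẑ and φ ∈ (−π, π].

This gives 3N − 6 dimensions for N atoms, is invariant under rigid motion,
and is invertible: `features_to_config()` rebuilds the Cartesian geometry (up
to rigid motion) and is used by the test-suite as a uniqueness oracle. Every
third dimension (1-based: the valence angle and each azimuth φ) is angular
and is marked in a cyclic mask; differences on those dimensions are wrapped
into (−π, π]. Wrapping the valence angle too is harmless — it lies in
[0, π] — and keeps the "every third dimension" rule uniform.

## The kriging model

With training features $x_i$ and outputs $y_i$ ($i = 1..n$), the covariance
kernel is the squared-exponential with per-dimension scales and the cyclic
correction,

$$k(x, x^*) = \exp\Big(-\sum_d \theta_d\, r_d(x_d, x^*_d)^2\Big),$$

where $r_d$ is a plain difference on linear dimensions and the wrapped
difference on cyclic ones. The mean is the constant $\mu = \bar y$, weights
are $\alpha = R^{-1}(y - \mu)$, the prediction is
$\hat f(x^*) = \mu + r^\top \alpha$, and the predictive uncertainty is the
ordinary-kriging variance

$$s^2(x^*) = \sigma^2\Big(1 - r^\top R^{-1} r +
  \frac{(1 - \mathbf{1}^\top R^{-1} r)^2}{\mathbf{1}^\top R^{-1}\mathbf{1}}\Big),$$

whose last term accounts for the estimated constant mean. The process
variance uses the maximum-likelihood plug-in
$\hat\sigma^2 = (y-\mu)^\top R^{-1} (y-\mu)/n$ for the fixed constant mean;
it is recorded in the model file for reproducibility. Hyperparameters
$\theta_d$ are trained by maximizing the marginal log-likelihood

$$\mathcal{L} = -\tfrac12 (y-\mu)^\top R^{-1} (y-\mu)
  - \tfrac12 \log|R| - \tfrac n2 \log 2\pi .$$

### Numerical choices

* **Nugget.** The GP is noise-free; a jitter of 1e-10 is added to the
  diagonal of R purely for conditioning, escalated tenfold (to at most 1e-4)
  if the Cholesky factorization fails, and an ill-conditioned-model error is
  raised beyond that. The nugget actually used is stored on the model.
* **No explicit inverses in prediction.** All $R^{-1}v$ products go through
  the stored Cholesky factor; `predict()` never refactorizes, so prediction
  cost is linear in the training-set size once the model is fit. The
  closed-form cross-validation errors (below) form the full inverse once via
  `chol2inv`, which is intended for the active-learning regime of at most a
  few thousand points.
* **Variance clamping.** The predictive variance is clamped at zero against
  floating-point round-off.

## Hyperparameter training: particle swarm optimization

The likelihood surface is multimodal, so a particle swarm maximizes it over
the box $[\theta_{\min}, \theta_{\max}]^{d}$. Velocities follow
$v \leftarrow \omega v + \phi_p r_1 (p - x) + \phi_g r_2 (g - x)$ with
$r_1, r_2$ uniform per particle and per dimension, and per-particle/global
bests updated once per cycle. Defaults: $\omega = 0.729$,
$\phi_p = \phi_g = 1.490$, bounds $[0, 3]$, and a stall criterion that stops
the swarm once the relative change of the global best stays below 1e-7 for
20 consecutive iterations. Positions and velocities are both initialized
uniformly on $[\theta_{\min}, \theta_{\max}]$ — the all-positive initial
velocities are a deliberate part of this swarm parameterization, kept over
the more common symmetric velocity initialization. Particles are clamped at the box
bounds with the velocity zeroed on the clamped dimension, which keeps
$\theta \ge 0$ as the kernel requires. Swarm size defaults to
$\max(4d, 50)$ and the iteration cap to 1000; the active-learning loops use
a desk-scale swarm (12 particles, cap 40) since they refit every iteration.
A particle whose likelihood evaluation fails scores $-\infty$ for that cycle
and the swarm continues.

## MEPE active learning

The available frames are split into a training set, a sample set (the
acquisition pool) and a validation set. The seed training design takes, for
every feature dimension, the frames attaining the minimum and maximum and
the frame closest to the dimension mean (duplicates removed), so it scales
linearly with dimension with an upper bound of three times the number of
dimensions. Sample and validation sets are drawn randomly from the remaining
frames with target sizes 10,000 and 500; smaller trajectories shrink both
proportionally.

Each iteration scores every sample point $x$ by the expected prediction
error

$$\mathrm{EPE}(x) = \alpha\, \mathrm{PE}^2_{CV}(x) + (1-\alpha)\, s^2(x),$$

an exploitation/exploration blend of a cross-validation error estimate and
the kriging variance. The CV term is the leave-one-out (LOO) error of the
nearest training point: sample points inherit the squared LOO error of their
Voronoi cell's training point, with nearness measured by unweighted
Euclidean distance in feature space (cyclic wrap applied). The unweighted
metric was chosen over a θ-weighted one so that cell assignment does not
jump discontinuously when hyperparameters are refit; the metric is a
configurable design point.

### Closed-form LOO errors

Refitting n models per iteration is too slow, so LOO errors come from the
closed form
$e_i = [R^{-1}(d + H_{:,i} d_i/(1-H_{ii}))]_i / (R^{-1})_{ii}$ with $H$ the
hat matrix of the constant basis ($H = J/n$). Two residual conventions are
implemented. The default forms $d$ with the model's own mean $\bar y$; under
that convention the formula is *algebraically identical* to the exact
retrain-LOO of this constant-mean GP, because deleting point $i$ shifts the
left-out mean by exactly $(y_i - \bar y)/(n-1) = H_{:,i} d_i/(1-H_{ii})$.
The test suite verifies agreement with the exact retrain oracle on random
instances to a documented tolerance of 1% relative (deviations are
floating-point conditioning only; the observed median is at machine
precision). The alternative `residual = "gls"` uses the
generalized-least-squares constant of universal kriging, the convention of
the MEPE literature; it is a close approximation rather than an identity here,
since the package's models carry the simple mean.

### The balance factor

$\alpha$ starts at 0.5 and thereafter compares how wrong the model actually
was about the previously added point(s) with what the CV estimate claimed:
$\alpha = 0.99 \min(0.5\, \mathrm{PE}^2_{true}/\mathrm{PE}^2_{CV},\, 1)$,
so $\alpha \in [0, 0.99]$ always leaves at least 1% weight on exploration. A
zero CV estimate is treated as an infinite ratio (α = 0.99). With
multi-point batches each added point contributes its own α and the batch
uses their arithmetic mean. The realized error of a batch is evaluated with
the model that selected it, at the newly computed true outputs.

### Per-atom and per-system modes

In per-atom mode every atom runs an independent loop — its own training,
sample and validation indices, its own hyperparameters and α — and only that
atom's energies are ever requested from the oracle for selected frames.
Runs share nothing but the read-only trajectory and oracle, so any execution
order gives identical per-atom results (the tests permute atom order). In
per-system mode all atoms share one training set; CV errors, variances and
realized errors are summed over atoms before forming EPE and α. For a
one-atom system the two modes reduce to the same point sequence, which the
tests check exactly. The shared seed design in per-system mode is the union
of the per-atom seed designs, since one training set must serve every model.

Each iteration ends by adding the batch with the largest EPE values (ties:
lower sample index) to the training set; the loop stops at a configured
training-set size, an exhausted sample pool, or a validation-RMSE target.
Hyperparameters are refit by PSO every iteration by default (`refit_every`
relaxes this); GPR weights are refit every iteration regardless.

## The synthetic oracle

The package replaces the ab initio stages with two synthetic components so
the whole loop runs at desk scale:

* **Sampler.** Normal-mode-style sampling: a random orthonormal basis of
  3N − 6 internal directions (net translation and rotation projected out),
  Gaussian per-mode amplitudes of standard deviation
  $0.002\sqrt{T}$ Å — the equipartition amplitude $\sqrt{k_B T/k}$ for the
  stiffness scale of the built-in surfaces ($k \approx 2000$ kJ/mol/Å²,
  $k_B T \approx 2.5$ kJ/mol at T = 300) — plus two rejection rules: a
  minimum feature-space distance between accepted frames (the anti-clustering
  cutoff; a helper suggests 1% of a pilot trajectory's median
  nearest-neighbour distance) and a steric-clash filter discarding frames
  with any pair distance below 0.4 times the covalent-radius sum, since
  physically based samplers never emit overlapping atoms. "Temperature" is a
  monotone distortion control, not thermodynamic Kelvin; tests assert only
  monotonicity of the spread.
* **Toy PES with exact partition.** Harmonic bonds and angles plus
  Lennard-Jones-like nonbonded terms, with half of each pair term and a
  third of each angle term assigned to the participating atoms. The total is
  *defined* as the sum of the atomic energies, so the partition is
  conservative to machine precision — mirroring the property that a
  quantum-topological partition's atomic energies sum to the molecular
  energy. Built-in systems (`water`, `ammonia`, a 12-atom chain surrogate)
  derive every equilibrium parameter from their idealized geometry, so each
  geometry is exactly a stationary point of its surface.

What this emulates: temperature-controlled geometric diversity, rejection
sampling, smooth per-atom labels that sum to a total. What it does not:
anharmonicity patterns of real PESs, electronic effects, the heavy-tailed
label noise of real partitions — so green tests demonstrate correctness of
the machinery, not chemical accuracy on real systems.

## Evaluation tools

Per-configuration total prediction errors are summarized as S-curves (error
versus percentile, convention $100k/m$ for the k-th of m sorted errors) in
two modes: summing absolute atomic errors (no cancellation) or the magnitude
of the signed sum (cancellation, never larger). Learning curves track
validation RMSE and maximum error against training-set size. Kabsch
superposition (proper rotation, determinant +1, via SVD) aligns trajectory
frames for spread inspection, by default on the heavy-atom subset.

## Problem sizes and study conditions

The end-to-end suites run on the synthetic water system (3 atoms, 3
features): a 1000-frame trajectory at nominal temperature 300, models grown
to 59 training points — a size at which the acquisition choice still matters
on this domain — with batch sizes 1 and 5, validation pools scaled
proportionally from the 10,000/500 sample/validation targets, and 5 seeds
per comparison. MEPE runs are compared
against random acquisition at equal oracle budget; medians over seeds are
compared. These sizes keep the full suite within a couple of minutes on one
CPU while leaving the acquisition problem non-trivial.

## Known limitations

* Feature scales are used raw (Å and radians) with θ bounded in [0, 3];
  for very stiff, low-temperature domains the optimal θ can sit at the
  bound. Rescaling features or widening the box is a one-line configuration
  change but is not the default, which follows the published swarm box.
* The Voronoi CV propagation is a zeroth-order approximation; sample points
  far from all training points lean entirely on the variance term.
* `chol2inv`-based LOO is quadratic in memory; the intended regime is
  ≤ a few thousand training points per atom.
* Per-atom runs are independent but executed serially here; the contract
  (identical results under any execution order) is what a parallel driver
  needs, and is tested.
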