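---
title: "Neural cellular automata as trainable lattice dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural cellular automata as trainable lattice dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncadyn)
```

## The model

A neural cellular automaton (NCA) is a lattice dynamical system: an
S × S grid of cells, each carrying a real vector of C channels, updated
synchronously by a local rule that is itself a small neural network.
The first `C_obs` channels are *observable* — they are what the model is
fitted to — while the remainder are *hidden* channels the dynamics may
use as latent memory or an environment encoding (in a biological
reading: unmeasured species that the fitting procedure is free to
invent).

One update has four stages:

1. **Perception.** A fixed bank of 3×3 kernels — identity, local
   average, the two Sobel gradients, and a nine-point Laplacian — is
   applied depthwise (per channel, no mixing) to produce, at every
   cell, a C·K vector of local differential-operator responses.
   Kernels are hard-coded, not learned: they keep the model
   interpretable as a finite-difference stencil, and at most nine 3×3
   kernels can be linearly independent anyway.
2. **Per-cell network.** A single-hidden-layer perceptron, identical at
   every cell, maps the perception vector to a C-vector of increments:
   `f = W1 u(W2 z) + v`, hidden width H = 4C, activation `u` one of
   relu (`(|z|+z)/2`), linear, or tanh.
3. **Stochastic mask.** Each increment is gated by an independent
   Bernoulli variable that is 0 with probability `p`, which breaks
   global synchrony between cells (a dropout-like regulariser).  Both
   per-element gates (one per `(i,j,c)` entry) and per-pixel gates
   (one per cell, broadcast over channels) are implemented; the two
   appear interchangeably in the NCA literature and the package
   records which one a run used.  The default is per-element.
4. **Residual add.** `x' = x + σ·f`.  The residual form matters: a
   zero output layer makes the map exactly the identity, which is also
   the initialisation (`W1 = 0`, `v = 0`, `W2` random uniform scaled by
   `1/sqrt(C·K)` so hidden pre-activations are O(1) for any channel or
   kernel count).  "Do nothing" is the right starting point for
   learning dynamics: information from the initial state is preserved
   by default rather than forgotten.

With `p = 0` the update is precisely an explicit Euler step of a PDE
`∂t x = F(x, ∇x, ∇²x)` discretised with the kernel stencils; the
package's tests exploit this by hand-building diffusion weights and
checking the rollout against an independently coded Euler integrator.

Boundary handling is either periodic (reads wrap) or fixed-zero (reads
outside return 0, and the outer ring of cells is clamped to zero after
every step, so "vanishes at the boundary" holds exactly rather than
approximately).  State values are not clamped to any interval by
default; nothing in the model requires it, and clamping is left to the
caller.

## Training

`nca_fit()` learns the update rule from snapshots `y(0..M)` separated
by `t` NCA steps, over R trajectory copies.  The objective is the
per-transition Euclidean distance on observable channels, averaged over
all (time, batch) pairs.  Per epoch:

* the M·R transition grid is shuffled and split into B mini-batches
  (sizes differing by at most one, so no transition is discarded);
  gradients of the mean loss are accumulated across mini-batches —
  because every transition is visited exactly once per epoch, the
  accumulated gradient equals the full-batch gradient when states are
  not propagated, a property the test suite asserts;
* the accumulated gradient is normalised to unit global L2 norm (a
  global rather than per-tensor normalisation — the package picks one
  convention and documents it) and applied in a single Nadam step
  (Adam with Nesterov momentum; β₁ = 0.9, β₂ = 0.999, ε = 1e-8);
* stored intermediate states are replaced by the epoch's predictions
  (state propagation — this is what lets hidden channels learn
  long-term structure), except for one designated batch that is
  re-initialised from the data, a cheap data augmentation that speeds
  early training.  The re-initialised batch takes its observable
  channels from data; hidden channels are never overwritten by data
  (the data has none), and the m = 0 state always carries zero hidden
  channels.

The learning rate is not something the source formulation pins down;
the default is the Adam-family standard 1e-3, and the heat-equation
recovery experiment below validates it.  The returned model carries the
parameters of the epoch with minimal training loss, not the final ones.

All gradients are computed by an analytic backpropagation-through-time
implementation written for this package: every stage of the update is
a linear map or an elementwise nonlinearity, so the reverse sweep is a
short sequence of matrix products and the exactness is testable.  The
contract is `gradient_check()`, which compares the analytic gradient
with central finite differences on a tiny instance; the suite requires
agreement to 1e-4 relative (observed: ~1e-6–1e-9), including with a
frozen stochastic mask stream.  Transitions within a mini-batch are
rolled out in parallel as vertically stacked lattices (the kernel
bank becomes one sparse matrix per kernel acting on the flattened
lattice), which is why training runs at practical speed in R.

Training supports only the Euclidean loss; the probability-mass
(Hellinger, Bhattacharyya) and Fourier-magnitude losses are provided
as evaluation metrics, since the Euclidean loss is the one that works
best in practice for both task families and it is the one all the
package's experiments use.  Mass-based losses need a convention for
real-valued fields: each observable channel is shifted by its minimum,
floored at 1e-9, and normalised to unit mass before the textbook
definitions apply — a documented choice, not canon.  The spectral loss
compares magnitude (not complex) spectra; a phase-sensitive version
would collapse onto the Euclidean loss by Parseval's theorem.

## Task generators

**Gray-Scott.** `simulate_gray_scott()` integrates the two-species
reaction-diffusion system with cubic autocatalysis A + 2B → 3B
(feed rate α, kill rate γ) by explicit Euler with time step 1.  The
Laplacian is the same nine-point kernel the NCA perceives with, so the
PDE and the learned rule share one discrete operator — a deliberate
choice that makes "the NCA can represent the integrator exactly" a
meaningful statement.  At `D_A = 0.1, D_B = 0.05, α = 0.06230,
γ = 0.06268` the system forms maze-like Turing patterns.  A stability
guard rejects `dt·max(D) > 1/4` (the nine-point operator's spectrum
lies in [−6, 0], so this keeps the scheme comfortably inside the
explicit-Euler stability region).  Initial conditions are seeded
patches — discs or squares of (A, B) = (0.5, 0.25) on the (1, 0)
background — and a `high_frequency` kind adds Nyquist-band
checkerboard patches plus broadband noise for generalisation probes;
the patch generators are this package's stand-ins, since only figures
of such fields exist to imitate.

**Measurement noise.** `corrupt_with_noise()` interpolates data
towards uniform noise, `ỹ = (1−ξ)y + ξη` with `η ~ U(min y, max y)`;
the extremes are taken globally over the whole trajectory (per-channel
extremes would be an equally defensible reading; the global one is
implemented and recorded here).

**Image morphing.** `make_morph_sequence()` builds the fixed-boundary
task: RGBA images (licence-free programmatic shapes from
`synthetic_shapes()` — disc, ring, cross, star, glider) are
area-average downsampled to 60×60 by default, embedded in a lattice
padded by 16 zero cells, shifted randomly by up to ±8 cells per batch
copy (R = 4 copies by default), with the final image repeated so the
end state is trained as an attractor, and uniform ±0.005 noise added
to every frame.  The pad, shift, copy-count and noise amplitude are
package defaults — the construction needs *some* value and these are
small relative to the 60-pixel content — and all are configurable.
The noise is not cosmetic: training the stable final transition
without it makes gradients diverge, because the loss gradient of a
perfectly reproduced frame is a zero-over-zero direction; noise keeps
the target transition informative and builds a basin of attraction
around the final state.

## Stability analyses

`local_perturbation_map()` perturbs each pixel of an initial state in
turn, rolls out n deterministic steps, and counts final-state pixels
whose observable-channel maximum change exceeds 0.1 (the cutoff that
absorbs stochastic-mask fluctuation).  Counts are bounded by the
locality cone (2n+1)² — with 3×3 kernels information moves at most one
cell per step — and the suite asserts the bound.  The perturbation
magnitude and its channel scope are parameters (default: +1 on all
observable channels), since only the counting threshold is canonical.

`kappa()` scores a perturbation of the initial condition by
`κⁿ = ‖x̃⁰‖ − ‖Φⁿ(x⁰+x̃⁰) − Φⁿ(x⁰)‖`: large positive values mean big
perturbations with small future consequence; negative values mean
small perturbations with outsized consequence.  Both rollouts share
one determinism convention (p = 0, or a frozen mask stream used by
both), otherwise the difference term would be dominated by mask noise.
`adversarial_search()` optimises κ by gradient ascent/descent using
the same backpropagation engine, from a small uniform start
(norm 1e-2), accepting only improving steps and halving the step on
rejection — so the reported trace is monotone and the search cannot
diverge.  The tests require the optimised perturbation to beat 20
equal-norm random perturbations in the chosen direction.

`symmetry_eval()` rolls the model from transformed initial conditions
and scores against the equally transformed target.  On-lattice
transforms (90° rotations, axis flips) are exact index permutations;
45° uses bilinear interpolation with zero fill, the simplest scheme
that keeps a centred disc's mass within 1%.  A model built from
symmetric kernels (identity, average, Laplacian) commutes with the
on-lattice transforms exactly — an equivariance theorem the suite
checks to 1e-8 — while gradient-kernel models do not, which is the
trade-off between isotropy and expressiveness that the kernel choice
controls.

## Problem sizes, numerics, and what the tests do and do not show

The package's experiments are desk-scale by design and state their
sizes explicitly:

* *Heat-equation recovery*: S = 16, C = 2, identity+Laplacian,
  linear activation, t = 1, M = 8, 300 epochs.  Passing means the
  trainer drives the loss below 10% of its initial value and the
  learned one-step impulse response matches the Euler diffusion
  stencil within 5% — i.e. the optimiser genuinely recovers an
  exactly-representable dynamics.
* *Gray-Scott generalisation*: S = 32, C = 6 (2 observable + 4
  hidden), t = 16, N = 512 PDE steps (32 transitions), 500 epochs,
  printed kinetic rates, learning rate 3e-3 (for this short epoch
  budget the default 1e-3 converges too slowly and its late-epoch
  iterates can destabilise long unseen-IC rollouts; 3e-3 was the most
  reliable setting in a small sweep and is recorded here as the
  experiment's configuration).  The acceptance check compares the
  fitted rule against the untrained identity model on a seeded-blob
  initial condition it never saw, asking for at least a 2×
  improvement in mean Euclidean loss over the 32 test frames.  This
  is a deliberately hard, scaled-down analogue of the full-size
  experiments (S = 64, N = 1024–2048, thousands of epochs at GPU
  scale): a few hundred CPU epochs buy a clear but not dramatic
  margin over the baseline, so this check probes the limit of what
  desk-scale training achieves rather than a comfortable pass.
* *Noise robustness*: the same run repeated at corruption ξ = 0.8
  must generalise strictly worse than the clean run.  Only the
  qualitative direction is asserted; the interesting intermediate
  regime (incorrect-but-Turing-like patterns at moderate ξ) needs
  full-scale training to reproduce and is out of scope here.

The synthetic generators emulate the *structure* of the study
conditions — PDE snapshot trajectories, image sequences with fixed
boundaries and augmentation — but not properties of real experimental
data: no spatially correlated measurement noise, no drift, no missing
frames, no non-square or non-stationary domains.  A green suite
therefore certifies the machinery (exact kernels, exact gradients,
conservation laws, equivariances, learnability of representable
dynamics at small scale), not performance on any particular real
system.

Numerical conventions collected in one place: relu's subgradient at 0
is taken as 0; the zero-gradient guard leaves an all-zero gradient
unnormalised (so a perfectly fitted model stays put); a non-finite
increment, loss, or gradient raises an error carrying the step, epoch
and chunk indices rather than propagating NaNs — training
instabilities are a finding, not something to clip away silently;
ties in "best epoch" resolve to the earliest; and every random draw
(initialisation, shuffling, masks, generators) flows from explicit
integer seeds, so identical configurations reproduce bit-identically
on the same platform.

## Known limitations

Hand-derived gradients cover the Euclidean training loss only.  The
per-pixel perturbation map is O(S²) rollouts and is meant for modest
lattices.  Off-lattice rotations use bilinear interpolation, which
slightly blurs mass at patch edges.  The Nadam implementation is the
plain published update without learning-rate schedules.  Training
runs on one CPU thread per BLAS configuration; the stacked-lattice
batching keeps this practical at the scales above but full-size
replication (S = 64, thousands of epochs) is better done on
accelerator-backed implementations.
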