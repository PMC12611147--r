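---
title: "Cellular-Potts vasculogenesis and its U-Net surrogate: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular-Potts vasculogenesis and its U-Net surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `cpmunet`: the mechanistic model
and its energy functional, the coupled chemoattractant field, the rendering
and pairing of training data, the convolutional surrogate, the evaluation
metrics, and — importantly — the places where the design was genuinely open
and the choices this package made there.

## The mechanistic model

Endothelial cells seeded in a gel spontaneously organize into a network of
cords enclosing acellular "lacunae" — in-vitro vasculogenesis.  The package
simulates this with a two-dimensional Cellular-Potts (Glazier–Graner–Hogeweg)
model on a periodic square lattice: each cell is the set of lattice sites
holding its integer id, the medium is id 0, and the configuration evolves by
single-site copy attempts biased by the change of an effective energy

\[
H = \sum_{(i,j)\ \text{neighbors}} J_{\tau(\sigma_i),\tau(\sigma_j)}
      \bigl(1-\delta_{\sigma_i \sigma_j}\bigr)
  + \lambda_{vol}\sum_{cells}(V-V_t)^2
  + \lambda_{surf}\sum_{cells}(S-S_t)^2 ,
\]

plus a per-attempt chemotaxis contribution described below.  A copy attempt
replaces the id at a random site with the id of a random 4-neighbor and is
accepted with probability \(\exp(-\max(0,\Delta H/H'))\); one Monte-Carlo
step (MCS) is `latticeSize^2` attempts.  Cells are a single motile type with
contact energy 8.2 per cell–medium face and 6 per cell–cell face, volume
constraint 5 toward 50 sites, surface constraint 1 toward 16.8, chemotaxis
strength 2000 with saturation 0.5, field decay 0.6 per MCS, and temperature
\(H'=8\) — the vasculogenesis parameter set shipped as `cpmParams()`
defaults.

The secreted chemoattractant obeys
\(\partial c/\partial t = D\nabla^2 c - k c + s(\mathbf{x})\),
with secretion at every cell-occupied site, integrated by an explicit
5-point finite-difference scheme on the same periodic lattice, one call per
MCS (`pdeSubsteps` Euler substeps).  We enforce the positivity-preserving
bound \((4D+k)\,dt \le 1\) — the center-point weight of the update stencil
must stay non-negative — which is slightly stricter than plain von-Neumann
stability and guarantees the field never goes negative; violations are
refused with a diagnostic rather than integrated.

## Conventions the energy does not fix

Several aspects of a Potts model are conventions rather than equations, and
the model's published description leaves them open.  Each is a constructor
argument; the defaults are:

- **Contact neighborhood** (`contactNeighborOrder = 2`): contact energy is
  summed over unordered Moore (8-neighbor) pairs, the common practice of the
  major CPM frameworks; copy-attempt candidates and surface counting always
  use 4-neighbors.
- **Surface measure** (`surfaceMeasure = "perimeter"`): the surface entering
  the constraint is the in-plane 4-neighbor boundary face count \(P\).  The
  alternative `"voxel"` measure, \(2V+P\), counts the out-of-plane faces a
  unit-thickness 3-D voxel representation exposes — the behavior a 3-D
  framework exhibits when running a 2-D simulation.  Cached statistics
  always store \(P\), so the lattice bookkeeping invariants are independent
  of this choice.
- **Chemotaxis convention** (`chemotaxisMode = "advance"`): the saturated
  chemotactic term
  \(-\lambda\bigl[\frac{c_d}{s c_d+1}-\frac{c_s}{s c_s+1}\bigr]\)
  applies when a *cell* copies into the destination site; the medium does
  not chemotax.  This is the convention of the major frameworks.  It breaks
  detailed balance — the lattice feels a sustained active drive rather than
  relaxing to a Boltzmann equilibrium — which is what keeps a chemotactic
  tissue remodeling indefinitely.  `"both"` selects the antisymmetric
  conservative variant in which a retraction is penalized with the opposite
  sign.  Because the term depends on a source *and* a destination it is
  intrinsically per-attempt; the static total energy excludes it.

## Calibrating the field constants

The diffusion constant \(D\) and the secretion rate have no published
values.  `calibrateFieldParams()` is the reporting tool used to choose
them: it runs short simulations over a candidate grid and summarizes
lacunae counts, vessel fraction, and field levels.  The shipped defaults
(\(D = 2\) sites²/MCS, secretion 0.05 per MCS, i.e. a saturation scale
\(c^* = r/k \approx 0.083\)) were selected on the morphology gate — at
MCS 2000 on the 256² lattice the model forms a connected vascular mat with
on the order of 80 distinct lacunae of area ≥ 50 sites, rather than one
compact aggregate or dispersed cells — and on desk-scale runtime (a
2100-MCS full-size run takes about 90 s on one CPU core).

**A documented discrepancy.**  The published evaluation of this model
reports, for the frozen MCS-2000 configuration against the true MCS-2100
state, a Dice overlap near 0.77, a normalized-field MSE near 0.038 and a
lacunae-area EMD near 21.  A Dice of 0.77 at vessel fraction
\(1000\times50/256^2 = 0.763\) is numerically the overlap of two
*independent* masks at that coverage — it implies the network rearranges
almost completely every 100 MCS.  Under the printed energy scale
(temperature 8 against face-counted contact and surface energies) this
package's dynamics are far more rigid: across every combination of
\((D,\ \text{secretion})\), both surface measures, both chemotaxis modes
and both contact orders we explored, the 100-MCS self-overlap stays at
0.97–0.995 and the Dice-vs-lag curve plateaus near 0.90, and even
quadrupling the noise scale leaves it near 0.98.  We therefore read the
published reference-baseline magnitudes as reflecting an energy-unit or
surface-counting convention of the original simulation framework that the
description does not state.  The acceptance suite asserts the published
bands as documented and reports the discrepancy rather than tuning printed
constants away from their stated values; all structural and algorithmic
properties (energy bookkeeping, acceptance law, conservation, metrics) are
verified independently of it.

## From lattice states to training data

`renderFrame()` turns a state into the surrogate's two-channel image: a
binary vessel mask and the field divided by a recorded normalization
constant — by default the analytic saturation scale \(c^* = r/k\), the
fixed point of the field equation under blanket secretion, which puts
typical concentrations on an O(1) scale.  `buildPairs()` pairs each saved
MCS \(t\) with \(t+100\) under a half-open window convention (the pair
whose target would be the final snapshot is excluded); on the standard
protocol — unit cadence over MCS 200 to 20,000 — this yields exactly
19,700 pairs per simulation.  (The closed window would yield 19,701; the
half-open convention is adopted deliberately and tested.)  `splitPairs()`
draws a seeded 80/20 split over pairs, the literal protocol; a
by-simulation mode avoids temporal leakage between splits and is off by
default.

## The surrogate

`buildSurrogate()` constructs a classic U-Net — encoder levels of two 3×3
convolutions with PReLU activations and 2×2 max pooling, a bottleneck, and
a mirrored decoder with nearest-neighbor upsampling and skip
concatenations — in which *every* convolution uses circular padding, so the
network lives on the same torus as the lattice and is exactly equivariant
to translations divisible by \(2^{depth}\) (a property the tests assert).
The mask head emits logits (sigmoid applied at prediction time); the field
head is linear, clipped at zero on output.  The published architecture
figure is schematic, so depth 4 with base width 32 doubling per level is a
reconstruction; every number is configurable.  Forward and backward passes
are built from compiled im2col+GEMM convolution primitives; gradients are
verified against numerical differentiation in the test suite.

Training minimizes binary cross-entropy on the mask channel plus ten times
the mean-squared error of the field channel, the published weighting, with
seeded minibatch Adam (defaults: learning rate 1e-3, batch 16; both
exposed, plus an optional per-epoch learning-rate decay).  A non-finite
loss aborts with a diagnostic.

Two further choices are ours:

- **Residual parameterization** (`residual = TRUE`): the network predicts
  the *change* from the input frame — the input mask (rescaled to ±4
  logits) and field are added to the output heads, and the head convolution
  starts at zero, so the untrained network is the identity map.  This is
  standard practice for learned time-steppers: the 100-MCS update is a
  small correction to a largely persistent state, and learning it as a
  residual is far better conditioned than relearning the identity.
- **Rollout feeding**: `rolloutSurrogate()` feeds continuous mask
  probabilities back by default (the compounding smoothing this causes is
  the surrogate's documented long-horizon failure mode); a
  `binarize` flag thresholds between iterations instead.

## Evaluation metrics

`diceScore()` is \(2|A\cap B|/(|A|+|B|)\), defined as 1 for two empty
masks; probability inputs are thresholded at 0.5.  `fieldMSE()` is the
per-site mean squared error on the normalized field.

`lacunaeAreas()` extracts the areas of the enclosed medium regions.  Medium
uses 4-connectivity (8-connected medium would leak diagonally through
vessel walls).  The default `"torus"` method labels components directly
with wraparound adjacency — the exact semantics, cross-checked in the tests
against an independent union-find oracle.  The `"tiled"` method implements
the plus-shaped tiling procedure: pattern the mask above, below, left and
right, label the canvas in the plane, deduplicate wrapped copies by a
signature of (area, inertia-tensor eigenvalues, canonical footprint modulo
the lattice), and discard frame-touching fragments the plus arrangement
cannot close.  The footprint term in the signature is our choice of
matching rule: eigenvalues alone would merge distinct lacunae that merely
share a shape.  The tiled procedure cannot close a lacuna that wraps both
periodic axes at once; the torus method is authoritative, and the two are
tested to agree whenever no region does so.  Regions under 3 sites are
dropped in both methods — 1–2-site holes are transient lattice noise, not
lacunae.

`areaEMD()` is the 1-D Wasserstein-1 distance between the two empirical
area distributions with equal total mass, computed from the closed form
\(\int |F_a - F_b|\,dx\) (checked against an independent implementation in
the tests).  Normalized rather than count-weighted mass is a deliberate
choice, recorded because the two frames' lacunae counts generally differ.
An EMD against an *empty* area set is undefined and raised as an error;
`evaluateRollout()` records `NA` for such steps.

`evaluateRollout()` is the harness: from a true MCS-2000 frame it rolls the
surrogate forward and, at every step, scores both the prediction and the
frozen initial frame (the "do-nothing" reference the surrogate must beat)
against ground truth, plus the divergence diagnostics (vessel area and
un-normalized field sum) that expose how recursive predictions drift.  The
published evaluation used 25 simulations in one place and 20 in another;
the harness takes any number.

## Problem sizes in the shipped tests and scripts

The test suite and the acceptance script run everything at sizes chosen for
a single desk CPU: the reference-baseline pilot uses 3–5 full-size (256²,
1000-cell) simulations to MCS 2100; the learning check trains a depth-2,
base-12 surrogate for 15 epochs on ~120 pairs from four 64² simulations at
the full model's cell density and compares single-step predictions on two
held-out runs; the end-to-end pipeline smoke test is smaller still.  The
full published protocol (20 training simulations to MCS 20,000, 19,700
pairs each, 100 epochs at 256²) is expressible with the same functions and
configuration, but is a multi-day CPU computation and is not exercised by
the shipped tests.  At desk scale the mechanistic dynamics are so rigid
(see the discrepancy note above) that the frozen reference is very nearly a
Bayes-optimal single-step predictor; the trained surrogate converges to it
from its identity initialization, and the margin by which it can exceed the
reference is within seed noise.  The acceptance suite states the
directional expectation and reports the measured outcome.

## Known limitations

- Two-dimensional lattices only; a single motile cell type; no
  connectivity constraint (cells may fragment, and a cell whose volume
  reaches zero is removed).
- The explicit field solver requires \((4D+k)/\text{substeps} \le 1\);
  large diffusion constants cost proportionally many substeps.
- Simulation artifacts (runs, datasets, checkpoints) serialize as RDS
  containers with format stamps.
- The published headline wall-clock comparison is hardware-bound;
  `benchmarkSurrogate()` reproduces the *harness* (medians and standard
  deviations over identical configurations) but its numbers are
  machine-dependent by nature.
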