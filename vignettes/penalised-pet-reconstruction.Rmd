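---
title: "Penalised-likelihood PET reconstruction and convergence benchmarking with petrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalised-likelihood PET reconstruction and convergence benchmarking with petrec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrec)
```

# The reconstruction problem

PET image reconstruction is an inverse problem: histogrammed coincidence
counts `y` are related to the unknown activity image `x` through an affine
Poisson model, and the image is recovered by maximising a penalised
likelihood (MAP) objective

    Psi(x; y) = L(y; ybar(x)) - beta * R(x),    x in C,

where the constraint set `C` requires nonnegativity inside a support mask
and exact zeros outside it. The expected data are

    ybar(x) = m * (A x + a),

with `A` a line-integral projector, `m` bin-wise multiplicative factors
(detection efficiency times attenuation), and `a` a strictly positive
additive background modelling randoms and scatter. Bins with `m = 0`
("virtual crystals") are structurally empty: their data are zero and their
log-likelihood terms are defined as exactly zero. The Poisson
log-likelihood, up to image-independent terms, is
`L = sum_k y_k log(ybar_k) - ybar_k`.

`petrec` implements this model at desk scale on synthetic phantoms, together
with the reference solver, challenger algorithms and the timing/ranking
protocol used to benchmark how quickly an algorithm reaches the converged
solution. Everything runs in seconds to minutes on one CPU, so the entire
pipeline is testable end to end.

## The projector

The projector is 2D parallel-beam with exact voxel-intersection lengths
(Siddon-style parametric ray tracing); 3D volumes are projected plane by
plane. The system matrix is assembled once per geometry as a sparse matrix
and back-projection applies its transpose, so the forward/adjoint pair is
matched to machine precision by construction. A matched pair is not a
nicety: the sensitivity images, EM-type preconditioners and gradient
formulas below are only mutually consistent when the adjoint is exact. The
test suite asserts the inner-product identity `<Ax, g> = <x, A'g>` at
1e-10 relative on random pairs.

This parallel-beam operator is an explicit simplification: it reproduces
the mathematical structure (linearity, matched adjoint, subset
partitioning) of a clinical scanner geometry, not any particular scanner.

## The smoothed relative difference prior

The roughness penalty is the smoothed relative difference prior

    R(x) = 1/2 sum_i sum_{j in N_i} w_ij k_i k_j
           (x_i - x_j)^2 / (x_i + x_j + gamma |x_i - x_j| + epsilon)

over the 8 (2D) or 26 (3D) nearest neighbours. The weights `w_ij` are the
in-plane ("horizontal") voxel pitch divided by the Euclidean inter-voxel
distance, so direct in-plane neighbours have weight exactly 1 and in-plane
diagonals 1/sqrt(2). The 2D neighbourhood is the dimensional restriction of
the 3D rule. Parameters, with defaults:

* `beta` — global regularisation strength; trades data fit against
  smoothness. A config input (default 1 for the bundled phantoms); no
  cross-scanner auto-calibration is attempted.
* `gamma = 2` — edge preservation: large differences are penalised
  approximately linearly rather than quadratically.
* `epsilon` — smoothing constant making the penalty differentiable at
  equal neighbours; derived as `1e-4 * max(OSEM image)`. The organisers'
  exact rule is not published; a small fraction of the reconstruction
  scale is the natural choice and the factor is configurable.
* `kappa` — voxel-wise weight image, the square root of minus the row-sum
  of the log-likelihood Hessian at the initial OSEM image,
  `kappa = sqrt(A' (m^2 y / ybar^2 * A 1))`. This makes the effective
  regularisation approximately uniform across the object. The test suite
  checks it against an explicitly assembled dense Hessian.

`R(x)` is zero exactly on images that are constant on every neighbourhood
component with positive `w k k`, and with `epsilon = 0` it is positively
homogeneous of degree 1 — both used as test properties.

One consequence of the full-neighbourhood sum deserves note: voxel pairs
that straddle the support boundary (inside voxel vs structurally zero
outside voxel) are penalised too, since kappa is generally positive there.
At very large `beta` those boundary terms dominate and pull the optimum
towards zero — the prior is edge-preserving, not edge-transparent. The
"constant phantom stays constant" solver test therefore sets `kappa` to the
object indicator, making a constant disc exactly prior-compatible.

# Solvers

All solvers operate on angular subsets: subset `j` of `n` contains the
views congruent to `j` mod `n` (maximally interleaved). The subset
gradient is upscaled, `n * grad L_s(x) - beta * grad R(x)`, so the average
over subsets equals the full gradient exactly — the prior gradient is
carried in full at every update.

* **OSEM** (initialiser): the classical multiplicative update
  `x <- x / (A_s' m_s) * A_s'(m_s y_s / ybar_s)`, with 0/0 defined as 0 at
  voxels of zero subset sensitivity. With one subset this is MLEM, whose
  monotone likelihood ascent is asserted over 200 iterations.
* **BSREM** (reference): the relaxed preconditioned update

      x <- P_C( x + alpha_k * (x + delta) / S * grad_s Psi(x) ),

  with `S` the average of the subset sensitivity images `A_s' m_s`,
  `delta = 1e-6 * max(OSEM)` a stabiliser that lets zero voxels re-enter,
  and `alpha_k = alpha0 / (1 + eta * epoch)` the relaxed step. The
  preconditioner divides by `S`: it is the EM preconditioner
  `(x + delta) / S`, which is what makes the update EM-like (the printed
  form of the update in the source protocol is ambiguous on this point;
  the division reading is the one under which the scheme reduces to
  scaled EM steps and converges in our tests).
* **SVRG** (challenger): stochastic variance-reduced gradients with a
  full-gradient snapshot per epoch, the same preconditioner and
  projection, seeded random subset order without replacement, and a
  constant-then-relaxed step. With snapshot period 1 it collapses exactly
  to preconditioned projected gradient ascent — a structural identity used
  as a test.

## Reference reconstruction and restarts

`reconstruct_reference()` runs the full pipeline: OSEM warm start, kappa /
epsilon / delta derivation, then BSREM in rounds until convergence. The
convergence check combines a preconditioned KKT residual (interior
gradient magnitude, positive-part gradient on active voxels) with an
objective-stall test. Two numerical facts shaped the defaults:

* The KKT residual floor scales with the current step size — the subset
  limit cycle — so it cannot reach machine precision for any finite
  schedule. The default tolerance (5e-3 relative to the image maximum)
  sits where the objective is already within ~1e-8 relative of the
  optimum found by an independent projected-gradient-with-line-search
  oracle on test problems.
* Restarting the schedule every round prevents tight convergence (steps
  stay large). The schedule therefore continues across rounds, and a
  restart (step index back to 0, iterate kept) fires only when the
  objective has stalled while the residual is still above tolerance —
  i.e. when the step has become too small to make progress. The
  organisers' exact trigger is not published; this one is a stand-in with
  the same purpose. Because a restart can leave the final round
  mid-transient (fresh large steps), the returned reference is the best
  round-end checkpoint by objective value, not necessarily the last
  iterate.

The BSREM objective is compared against the oracle at 1e-6 relative
tolerance in the acceptance tests, together with first-order optimality of
the iterate (interior gradients bounded by a small multiple of the final
step size times the initial gradient scale).

# The evaluation protocol

Candidate images `theta` are compared with the converged reference `r`
through three normalised metrics, all divided by the reference background
mean `MEAN(r; B)`:

1. whole-object `RMSE(theta; r; W) / MEAN(r; B) < 0.01`,
2. background `RMSE(theta; r; B) / MEAN(r; B) < 0.01`,
3. per target VOI `|MEAN(theta; R_i) - MEAN(r; R_i)| / MEAN(r; B) < 0.005`,

where `W` is the marginally eroded whole-object VOI (one pass of 3x3 box
erosion by default; "marginally" is not quantified in the protocol, so the
iteration count is configurable), `B` the uniform background VOI and `R_i`
the target VOIs. An algorithm passes at the first update from which all
criteria hold for 10 consecutive updates; runs that never achieve this
within the time cap are censored at the cap. The recorded pass time is the
timestamp of the first of the 10 passing updates — the earliest defensible
reading, applied uniformly. Timestamps are taken after the update and
before metric evaluation, so metric cost never pollutes algorithm timing.

Ranking: for every (dataset, metric) cell the median pass time over the
repeated runs (censored runs counting at the cap) is ranked from worst
(rank 1, slowest) to best (rank N, fastest); cells with a censored
majority rank strictly worse than every uncensored cell; ties share
averaged rank positions. An algorithm's score is its mean rank over all
cells, reported with its standard error. The tie and censoring conventions
are not specified by the protocol and are fixed choices here; the ranking
is invariant to relabelling and to monotone time transforms (tested).

## Clocks and reproducibility

Pass times are read from a pluggable clock. The default for the pipeline
is a deterministic pseudo-clock (one unit per update), which makes full
challenge runs bit-reproducible — traces, images and leaderboard are
asserted identical across reruns in the tests. Wall-clock timing
(`timing: "wall"`) is available when real run times are wanted; since the
ranking is invariant under monotone transforms of time, the choice of
clock changes reported units, not ranks, whenever update cost is roughly
constant per algorithm (as it is for the bundled solvers).

# The synthetic data generator

`generate_phantom()` builds three scene families: `nema_like` (warm
ellipse at activity 1.0, four hot disc inserts at the `contrast` level,
one target VOI per insert), `hoffman_like` (interleaved high/low activity
bands emulating grey/white matter, band-interior target VOIs), and
`constant_disc`. The attenuation map is water-like (0.0096/mm) on the
support. Insert sizes and positions are fixed deterministic fractions of
the grid; the seed jitters insert positions by at most one voxel, so VOIs
are reproducible by construction. The background VOI is carved from the
uniform warm region at least two voxels from any insert and from the
object boundary. The default acquisition scales activity so the expected
true counts hit 1e6 (a realistic 2D slice count level), with a strictly
positive additive background at 10% of mean trues and attenuation factors
from the mu map.

What the generator does *not* emulate: scanner-specific geometry and
normalisation structure, time-of-flight, detector blur, realistic scatter
physics (the additive term is a flat positive sinogram, not a scatter
estimate), anatomical texture, or multi-bed acquisitions. Passing tests
therefore demonstrate correctness of the model, solvers and protocol
mechanics — not clinical image quality, and not performance claims that
transfer to any particular scanner.

# Numerical choices

* Double precision throughout; gradients validated against central finite
  differences (step `1e-4 *` image scale, tolerance 1e-5).
* Ratios involving `ybar` exclude `m = 0` bins before division; live bins
  are guaranteed `ybar > 0` by the positivity of `a`.
* `kappa` is clamped at zero against negative round-off before the square
  root.
* OSEM voxels with zero subset sensitivity are set by the 0/0 := 0
  convention; BSREM freezes voxels with zero average sensitivity.
* Step tuning is per algorithm, as in the protocol being modelled: the
  reference and BSREM challenger default to `alpha0 = 1, eta = 0.1`; the
  SVRG challenger uses a smaller constant step (0.1, relaxing after a
  20-epoch warm-up) because larger preconditioned variance-reduced steps
  diverge at the default noise level.
* Problem sizes used by the test-suite and the acceptance script: 8x8 and
  16-voxel instances for gradient/Hessian oracles, 16x16 scenes for
  solver-optimality checks, 32x32 for the full challenge recomputation and
  64x64 for the end-to-end determinism run. These sizes keep every check
  well-conditioned while the whole suite runs in minutes.

# Worked example

```{r example, eval = FALSE}
cfg <- run_config(size = 32L, n_views = 32L, n_subsets = 8L,
                  reference_max_updates = 8000L,
                  challenger_max_updates = 2000L, runs = 3L,
                  time_cap = 1e6, seed = 1L)
res <- run_challenge(cfg, out_dir = "petrec_demo")
print(res$ranking)
```

The output directory is self-describing: the resolved YAML config, the
Interfile-style dataset (activity, mu, counts, factors, one mask file per
VOI), the OSEM and reference images, per-run trace and metric CSVs, the
pass-time table and the leaderboard. `petrec score` and `petrec rank` can
be re-run from those files alone.

# Known limitations

* The projector is parallel-beam 2D (slice-stacked in 3D); no scanner
  geometry, arc correction, or resolution modelling.
* `beta` is an input; the organisers' cross-scanner calibration procedure
  is out of scope.
* The additive background is simulated, never estimated from data.
* Kappa variants that include prior curvature are not implemented; the
  row-sum-of-the-likelihood-Hessian reading is the literal one.
* Wall-clock pass times depend on hardware and are never asserted by the
  tests; only protocol mechanics and determinism are.
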