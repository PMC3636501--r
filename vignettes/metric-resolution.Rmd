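---
title: "Measuring the metric resolution of a self-organized CA3 spatial map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the metric resolution of a self-organized CA3 spatial map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the model

Hippocampal CA3 develops place-selective activity in a new environment
through a self-organizing process driven by sparse, effectively random
input from the dentate gyrus (DG). `ca3metric` simulates this process in a
minimal rate model and asks a quantitative question: how much of the
Euclidean metric of the environment survives in the resulting population
code?

The model has three ingredients.

**The environment and behaviour.** A virtual rat explores a 1 m² square
arena realized as a torus (periodic boundaries), moving 2.5 cm per 125 ms
time step (one theta period, 20 cm/s) along a persistent random walk: the
heading performs a Gaussian random walk with a per-step standard deviation
of 0.35 rad. That value is a package choice (the magnitude of the heading
noise is a free behavioural parameter); it is small enough for realistic
path persistence and large enough that 10,000 steps reliably visit all 64
analysis bins. For analysis, the arena is discretized into an 8 × 8 grid
of 12.5 cm bins; the trajectory itself is continuous.

**The DG input.** Each granule cell is active in the environment with
probability `p_DG = 0.033`. An active cell carries `Q ~ Poisson(q)`
firing fields at uniformly random positions; its rate at position `x` is a
sum of isotropic Gaussians of peak `beta0` and width `sigma_f` evaluated
with minimum-image (torus) displacements. `q = 1.7`, `beta0 = 1` (rates
are in arbitrary units throughout) and `sigma_f = 0.1` m are package
defaults chosen as a typical granule place-field scale; the analysis layer
is agnostic to them. Minimum-image evaluation truncates the periodic image
sum; the error is negligible for `sigma_f <= side/6`.

**The CA3 network.** `N_CA3` threshold-linear units receive the DG rates
through fixed, binary mossy-fibre (MF) connectivity (expected in-degree
`C_MF = 50`, uniform weight `J^MF`) and each other through binary
recurrent-collateral (RC) connectivity (`C_RC = 900` at full scale) with
plastic weights. The rate of unit *i* solves

    eta_i = g [ sum_j c^MF_ij J^MF beta_j(x)
              + sum_k c^RC_ik J^RC_ik eta_k + delta_i - T ]_+

where `[.]_+` is rectification, `delta_i` is a small fast noise
(SD 0.002, redrawn each time step), and the threshold `T` and gain `g`
stand in for pooled inhibition: at every relaxation sweep they are
re-adjusted so that the population sparsity `a = <eta>^2 / <eta^2>` equals
0.1 and the mean rate equals 0.1.

## Numerical choices in the dynamics

*Relaxation scheme.* The rate equation is implicit in `eta`. We relax it
by damped synchronous iteration: each sweep computes the controlled
rectified response `F(eta)` to the total drive and updates
`eta <- (1 - kappa) F(eta) + kappa eta` with `kappa = 0.3`. Pure
synchronous updates (`kappa = 0`) cycle indefinitely — the sparsity
control makes each sweep a winner-take-all step, and the winning set
churns with period ~2 — while damping preserves the fixed points and
converges geometrically. Fifteen sweeps per time step (matching the
input-removed protocol below) bring the state within a few percent of the
fixed point; states warm-start from the previous time step.

*Threshold and gain.* Sparsity of the rectified rates is independent of
`g`, so `T` is solved first (bisection on the drive range; the sparsity of
`[drive - T]_+` decreases monotonically from ~1 to `1/N` as `T` rises) and
`g` then follows in closed form from the mean-rate target. A flat drive,
or a sparsity target below the `1/N` floor, is an error, not a silent
fallback.

*MF/RC balance.* Only the ratio of the MF to the RC drive matters (the
gain control absorbs the overall scale). After learning, incoming RC
weights are normalized to sum to 1, which pins the mean RC drive at the
mean rate (0.1). The pipeline therefore sets
`J^MF = target_mean / (C_MF * mean DG rate)`, so the mean MF drive equals
the mean RC drive and the external input competes with, rather than being
swamped by, the recurrent feedback. (With the naive choice
`J^MF = 1/C_MF`, the RC drive is ~20× stronger; the learned network then
collapses onto a couple of global attractors and decoding is at chance
even with the DG input on.) `dg_mean_rate()` supplies the analytic mean,
`n_fields * beta0 * 2 pi sigma_f^2 / (A * N_DG)`.

## Learning

While the rat explores for 10,000 steps (~20 min), the RC weights change
by a trace-based Hebbian rule,

    dJ_ij = gamma * eta_i * (eta_j - Lambda_j),

where `Lambda_j` is the mean of unit *j*'s rates over the preceding
`tau = 14` steps (1750 ms; early steps average whatever history exists).
Weights are clipped at zero whenever an update would make them negative,
activity during the session is computed with the RC contribution frozen at
the uniform initial weight (plasticity does not feed back within the
session), and at the end each unit's incoming weights are normalized to
sum to 1 and installed. The learning rate `gamma = 0.01` is a package
default chosen so the accumulated increments have the same order of
magnitude as the initial uniform weight; the normalization removes the
overall scale. The accumulator starts at the uniform initial weight, so
`gamma = 0` returns exactly the uniform normalized network.

## Decoding and the confusion matrices

A template (training) run assigns each bin the mean population vector over
all visits (100,000 steps). A test run (400,000 steps at full scale)
decodes, at every step and for unit samples of size 1–256 (10 independent
samples per size), the current sub-vector by nearest template in Euclidean
distance, ties to the lowest bin. Events accumulate in a 64 × 64 confusion
matrix `P(decoded | actual)`; averaging all events with the same
decoded-minus-actual displacement on the torus gives the 8 × 8 *reduced*
matrix `Q(x - x0)`.

Two conditions are simulated. With the DG **on**, every relaxation sweep
receives the full MF drive: the representation is externally driven. With
the DG **off**, each step runs the reverberation protocol — full MF drive
on the first sweep, 1/3 on the second, none on the remaining 13 — and the
final configuration is the step's state: the representation is whatever
the recurrent attractors retain. Templates are rebuilt under the same
condition they decode.

From each confusion matrix we take the fraction correct and the plug-in
mutual information (bits, `0 log 0 = 0`, no limited-sampling bias
correction — the long test phases keep the bias small relative to the
quantities compared, and no correction is applied to the reference
constructions either). The reduced matrix's information is
`log2(S) - H(Q)`: it is a translation-invariant channel, so this equals
the full formula under a uniform prior. The information of the reduced
matrix is always below that of the full matrix on the same events; the gap
is the location-specific, non-translation-invariant error structure.

Information and percent correct versus sample size `n` are fitted with
`I(n) = I_sat / (1 + (n0/n)^b)` and its percent-correct analogue
(least squares via Levenberg–Marquardt, multi-start over `b` and `n0`
initials; a constant series is a reported degeneracy, not a fit).

## The metric resolution index

The reduced matrix is fitted with an isotropic Gaussian at the origin plus
a uniform baseline. We tie the baseline to the normalization,
`Q(d) ~ pc exp(-|d|^2 / 2 w^2) + (1 - a)/S` with
`a = pc * sum_d exp(-|d|^2 / 2 w^2)`, leaving two free parameters: the
peak `pc`, the width `w` (bin units), and the implied single-location
volume `a`. A free baseline can push `a` below the chance floor `1/S` on
flat small-sample matrices; the tied form cannot.

Reference information curves bracket what a code with bump volume `a` and
dispersion `sigma` could convey:

* **minimum**: one Gaussian (volume `a`, width `sigma`) on the correct
  bin, the rest uniform — all remaining errors at chance;
* **maximum**: `round(1/a)` such Gaussians, one correct, the others on
  random distinct bins (50 Monte-Carlo placements, uniform prior) — no
  random errors at all. At `sigma = 0` the bumps are point masses: the
  spatially exact limit. The same placements are reused for every `sigma`
  during root finding, so the curve is deterministic and monotone.

For each sample size the dispersion `sigma` is found by bisection so the
maximum-mode reference equals the measured full-matrix information (from
the fitted curve, which is smoother than the raw points), and the metric
resolution is `chi = 1 - sigma / w`: 0 when the whole apparent bump width
is genuine decoding dispersion, 1 when the code is spatially exact and the
bump is pure averaging artefact. Sizes whose fitted `a` is at or below
`1/S`, or whose measured information falls outside the reference band by
more than 5% of its range, are reported as `NA` with a warning — the
index is unidentifiable there; small excursions are clamped to the nearest
endpoint (which can only drag `chi` towards 0 or 1, not towards any
intermediate target).

For the DG-off condition the same procedure is run with the bump
parameters still taken from the DG-on reduced matrices (the DG-off bump
conflates drift with dispersion and is unreliable) and with each reference
bump replaced by two half-height copies in adjacent bins — the drift
adjustment: removing the input lets the state relax deterministically to
an attractor a short distance away, so part of the error mass sits one bin
off even for an otherwise exact code. The neighbour direction is drawn
uniformly from the four axis neighbours per bump and draw.

## Global topology

The 64 full-population templates give a similarity structure:
`d_ij = 1 - r_ij` with `r` the Pearson correlation between template
vectors (clipped at 0). Sammon mapping to 3-D (classical-MDS
initialization, up to 500 iterations) quantifies how faithfully a
low-dimensional Euclidean configuration can reproduce those distances; the
reported stress is the standard Sammon criterion, and an adjacency summary
checks that torus-neighbouring bins sit closer in the embedding than
maximally separated ones.

## Scales, presets and runtime

The `paper` preset is the full protocol (45,000 DG / 1,500 CA3 units,
C_RC = 900, 400,000 test steps). The `desk` preset divides the network by
5 (4,500 / 300, C_RC = 180, preserving the connectivity ratios), keeps the
learning and template phases at full length (10,000 and 100,000 steps) and
tests for 50,000 steps; it completes in minutes on one CPU and is the
scale at which the package's replication tests run. The `tiny` preset
(1,000 / 100) is a smoke-test scale only.

What the desk scale does and does not show: the DG-driven condition
reproduces the full-scale phenomenology — information and percent correct
saturate sigmoidally with sample size, the reduced matrix carries visibly
less information than the full one, and the solved metric resolution is
low (chi of order 0.1) and roughly size-independent. The input-free
condition is much more scale-sensitive: attractor capacity falls with
network size and recurrent in-degree, so the 300-unit network retains far
less positional information after input removal than a 1,500-unit one, and
`chi` is identifiable at fewer sample sizes there. The Sammon stress of
the template embedding is also higher at reduced scale (roughly 0.1-0.15
across desk seeds): with fewer units the local distortions of the
template manifold are relatively larger, and the stress criterion weights
the smallest distances most heavily, even though torus adjacency is
cleanly preserved. Conclusions about the input-free regime or the
absolute embedding stress at full scale should not be read off the desk
preset.

The synthetic trajectory also idealizes behaviour — constant speed, no
walls, no rests — so passing tests certify the analysis pipeline and the
model's internal consistency, not agreement with any experimental
recording.

## Known limitations

* Plug-in information estimates are uncorrected; at the desk test length
  (50,000 events over a 64 × 64 table) the residual upward bias is a few
  hundredths of a bit, largest for the smallest samples.
* The relaxation damping (`kappa = 0.3`) is a numerical device; the model
  itself does not specify a within-theta relaxation scheme, and results at
  the fixed points do not depend on `kappa`.
* The drift adjustment uses exactly two half-height bumps in one random
  axis direction — an average description; real drift varies in strength
  and direction across locations.
* Memory scales with `N_CA3 x n_steps` doubles per phase (~240 MB at the
  desk preset's template phase).
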