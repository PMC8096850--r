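---
title: "Methods: pore profiling, umbrella-sampling PMFs, and map validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore profiling, umbrella-sampling PMFs, and map validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptk)
```

cptk implements the desk-scale computational layer of a full-length ion
channel structure study: geometric profiling of the conduction pathway of a
homo-heptameric (C7) channel model, estimation of the free-energy profile an
ion experiences along the pore from umbrella-sampling trajectories, density
tracing for main-chain building in mid-resolution cryo-EM maps, and the
standard map/model validation battery. Because the cluster-scale inputs
(all-atom membrane MD, raw particle stacks) are not desk-reproducible, the
package ships synthetic-data generators whose ground truth is known
analytically, and every method is validated against that truth or against an
independent oracle. This vignette records the models, the tunable parameters
and why their defaults are what they are, and the numerical decisions the
implementation takes where the design was genuinely open.

## Pore profiling

At an axial position $z$ the pore radius is the radius of the largest sphere
centred on the plane normal to the channel axis that overlaps no atom:

$$ R(z) \;=\; \max_{c \in \mathbb{R}^2} \; \min_i \big( \lVert c - x_i
\rVert - r^{\mathrm{vdW}}_i \big), $$

the classic maximum-inscribed-sphere construction used by pore-tracing tools
such as HOLE. The inner minimisation is exact; the outer maximisation is a
multi-start Nelder–Mead ascent seeded from the channel axis, from the
previous plane's optimum (which gives path continuity along the profile),
and from a ring of perturbed starts. If every start lands inside an atom a
seeded simulated-annealing sweep (fixed seed, hence deterministic) is
polished by a final Nelder–Mead pass. On analytic ring and cylinder
constructions the profiler is exact to well under 0.05 Å, and it agrees with
an exhaustive 0.05 Å grid search everywhere it has been checked.

Parameters that matter:

* `r_cap` (30 Å): planes whose nearest atom is beyond reach are reported at
  the cap and flagged `"unbounded"`, which bounds the search in vestibule
  regions that open into bulk.
* `step` (0.5 Å): plane spacing of the profile; lining-residue assignment is
  per plane, ties broken by the smallest atom index.
* constriction `prominence` (0.5 Å): a local minimum of the radius profile
  counts as a constriction only if it is at least this deep relative to the
  lower of its enclosing ridges, which suppresses noise minima on rough
  profiles.

The channel axis is estimated from the chain-centroid covariance: for a
ring-like Cn assembly the centroids spread in the plane perpendicular to the
symmetry axis, so the smallest-variance eigenvector is the axis direction;
it is then refined by minimising the variance of centroid-to-axis distances.
With fewer than three chains the most isolated eigenvalue of the atomic
covariance decides, which is the right answer for tubes and sheets but can
be ambiguous for globular single chains — a documented limitation.

Open/closed classification compares the minimum pore radius against hydrated
ion radii (Ca²⁺ 4.12 Å, Cl⁻ 3.32 Å, K⁺ 3.31 Å; Stokes radius 1.21 Å kept for
Cl⁻ where the distinction matters). The convention is strict: a channel is
closed for an ion when the minimum radius is *strictly below* the hydrated
radius; exact equality counts as open. The margin (hydrated minus minimum
radius) is always reported so the caller can judge borderline cases.

Residue bookkeeping: the deposited full-length construct carries an
eight-residue affinity tag (WSHPQFEK) inserted after native residue 172, so
model numbering runs eight ahead of native numbering from there on. The
package adopts the +8 offset throughout (the tag occupies model residues
173–180); conversions reject model indices inside the tag span, and reports
print the dual `native(model)` form, e.g. `414(422)`.

## Umbrella sampling and WHAM

The reaction coordinate $q$ is the ion's displacement along the channel axis.
Each umbrella window constrains the ion with a harmonic bias
$U_i(q) = \tfrac{c}{2}(q - q_i)^2$ with a uniform force constant
$c = 20\ \mathrm{kcal\,mol^{-1}\,\text{Å}^{-2}}$; anchors run from +55 to
−55 Å every 1 Å with five replicas per anchor in the full protocol
(replicas are pooled before analysis). Thermal energy is computed from the
Boltzmann constant at 310 K: $kT = 0.61603$ kcal/mol, and $\beta = 1/kT$ is
the inverse thermal energy that appears in all Boltzmann weights.

WHAM estimates the unbiased bin probabilities $P_k$ and window offsets
$A_i$ from the self-consistent equations

$$ P_k = \frac{N_k}{\sum_i n_i\, e^{\beta A_i - \beta U_i(q_k)}},
\qquad e^{-\beta A_i} = \sum_k P_k\, e^{-\beta U_i(q_k)}, $$

and the potential of mean force is $A(q_k) = -kT \ln P_k$, anchored so its
minimum is zero (profiles are only defined up to a constant). Three
implementation decisions deserve explanation:

1. **Solver.** Direct fixed-point iteration of these equations converges
   extremely slowly when window overlap is thin (tens of thousands of
   iterations at these settings). The package instead minimises the
   equivalent convex log-likelihood in the offsets with BFGS and an analytic
   gradient, which reaches the same fixed point in under a hundred
   evaluations. The test suite verifies bin-by-bin agreement with a
   brute-force fixed-point iteration to $10^{-6}$ kcal/mol on small
   problems.
2. **Within-bin bias treatment.** The protocol's windows are much narrower
   (sd $\sqrt{kT/c} \approx 0.18$ Å) than its 0.5 Å reporting bins, so the
   bias varies by many $kT$ *inside* one bin and the textbook bin-centre
   evaluation distorts the profile by up to ~1 kcal/mol. The solver
   therefore works on an internally refined grid — each reporting bin split
   into `refine = 5` sub-bins with the bias evaluated at sub-bin centres —
   and aggregates the unbiased sub-bin probabilities back onto the
   reporting grid. This estimator converges to the correct profile as the
   sub-bins shrink; `refine = 1` reproduces the textbook behaviour and is
   kept for oracle comparisons.
3. **Connectivity.** Windows must overlap for the offsets to be
   identifiable; disjoint groups raise an error that names the unbridged
   $q$ interval rather than silently returning garbage.

The discrete profile is smoothed by moving-window quadratic least squares
(Savitzky–Golay, default five bins), which is exact on globally quadratic
input; a window wider than the profile degrades to a single global
quadratic fit. Convergence is monitored by re-solving on cumulative
trajectory blocks and reporting the maximum bin-wise deviation from the
full-data profile. Barriers are local maxima of the smoothed profile above
a prominence threshold, with heights relative to the anchored minimum, and
are mapped to the residues whose side-chain centroids fall in a ±2 Å axial
slab around each peak.

Statistical behaviour worth knowing: with 1 Å anchor spacing and these
narrow windows, adjacent histograms overlap only in their tails, so the
chained offsets perform a random walk along the window ladder. At the
shipped sampling budget (five pooled replicas of 10⁴ samples per anchor)
this leaves roughly ±0.3 kcal/mol of seed-to-seed scatter in a peak height
15 Å from the profile's anchor region. Recovery claims are therefore made
about means over several seeds (six for the two-peak profile), a sample
size chosen so the standard error is comfortably inside the ±0.3 kcal/mol
claim being tested.

## The synthetic trajectory generator

The generator replaces cluster-scale biased MD with a one-dimensional
surrogate: the ion coordinate evolves on
$U(q) = A^*(q) + \tfrac{c}{2}(q - q_i)^2$, where $A^*$ is an analytic
ground-truth profile (flat, harmonic, double-well
$h((q/w)^2 - 1)^2$, a sum of Gaussian barriers mimicking a channel with a
5 kcal/mol intracellular and a 4 kcal/mol pore-funnel peak, or a tabulated
spline). Dynamics are Metropolis-adjusted overdamped Langevin (MALA):
an Euler–Maruyama proposal followed by a Metropolis accept/reject step, so
the stationary distribution is *exactly* $e^{-\beta U}$ at any stable step
size. The adjustment matters: the unadjusted integrator biases each
window's mean by $O(\mathrm{d}t)$, and through the stiff bias those shifts
accumulate into PMF errors of order 1 kcal/mol — larger than the effects
being measured. At zero temperature the update degenerates to plain
gradient descent, so the coordinate relaxes monotonically to the biased
minimum.

Defaults: $\mathrm{d}t = 0.002$, damping $\gamma = 1$ (so
$c\,\mathrm{d}t/\gamma = 0.04$, safely below the 0.1 stability rule for the
stiffest shipped case), 2000 burn-in steps (80 bias relaxation times),
recording stride 20. All randomness is drawn through R's RNG, so a seed
fixes the entire trajectory. Steered seeding — a moving-anchor harmonic
pull that snapshots the coordinate as the anchor crosses each window
position — provides window initial conditions, as in the original
steered-MD protocol.

What the surrogate does *not* model, and hence what passing tests do and do
not show: there is no explicit solvent, membrane, or ion–protein coupling;
trajectories are one-dimensional and memoryless apart from the coordinate
itself. Recovery results validate the *estimation pipeline* (windowing,
histogramming, WHAM, smoothing, barrier reporting) under Boltzmann
statistics with the paper-scale protocol — they say nothing about
force-field or sampling adequacy of real MD.

Toy channel models place rings of pseudo-atoms (element X, configurable
van der Waals radius) along z following a prescribed radius function, with
atoms partitioned into `symmetry` chains by angular sector and residue
indices increasing along z. The construction makes the true pore radius
available in closed form (ring radius minus pseudo-atom radius, on ring
planes) and lets PMF peaks be mapped onto known waist residues.

## Density maps, LDPs, and validation

**Map container and I/O.** Maps are 3-D scalar grids with per-axis voxel
size and an origin in Å (first-voxel-centre convention). The MRC/CCP4
reader/writer covers the common single-volume case — mode 2 (float32),
orthogonal axes, P1, axis order XYZ — and raises explicit unsupported-format
errors otherwise; round-trips preserve grids to stored (single) precision.

**Model-derived maps.** Each atom contributes an isotropic Gaussian of
width `blur_width`, interpreted as σ (the study's 3.15 Å blur is taken as
σ, a documented and configurable choice), truncated at 4σ and normalised to
unit mass, so the grid integral equals the atom count up to truncation
loss. The kernel is separable, which keeps synthesis fast in pure R.

**Mean-shift LDPs.** Local dense points are the convergence points of
Gaussian-kernel mean shift on the map: each voxel at or above a threshold
(absolute, or "kσ above the mean" contour notation) is iterated to
convergence (step < 10⁻³ Å or 200 iterations; kernel truncated at 3σ;
negative densities clamped to zero so they carry no mass), and converged
positions within one voxel are merged into density-weighted points. Strings
of LDPs follow density ridges and expose main-chain trails; a distance
graph over them supports trail visualisation. The 3σ truncation can break
exact monotone ascent of the kernel-smoothed density at the 10⁻⁴ relative
level, which the property tests allow for. For trail tracing in
mid-resolution maps, the helix fixture is blurred to 3.15 Å *resolution*
(Gaussian FWHM = 3.15 Å, σ ≈ 1.34 Å) and traced with a 1.5 Å bandwidth —
narrow enough to resolve the helical pitch; blurring with σ = 3.15 Å would
melt a 2.3 Å-radius helix into a featureless tube whose ridge is the
helical axis.

**FSC and resolution.** Fourier shell correlation uses shells one
reciprocal voxel wide up to Nyquist, with the conjugate cross-power
normalised by per-shell powers; an optional real-space mask (clamped to
[0, 1]) is applied before transforming. Zero-power shells are recorded as 0
and flagged. Resolution at a threshold (0.143 for half-map comparisons, 0.5
for map-model) is the reciprocal of the first crossing, linearly
interpolated between shells; a curve that never crosses returns a
better-than-Nyquist sentinel, and a threshold above the whole curve returns
the coarsest shell. The transform itself is checked against a
direct-summation DFT on 8³ grids to 10⁻¹⁰.

**Perturbation cross-validation.** The overfitting check displaces every
atom by an independent uniform random vector of norm ≤ 0.5 Å (seeded,
reproducible), then compares FSC of the test model against each half map
and of the final model against the full map; the overfitting indicator is
the maximum shell gap between the two half-map curves, which is exactly
zero when the half maps are identical.

**Per-residue local fit.** Each residue's fit is a Manders-style overlap
between the model-derived and experimental densities over the residue's
voxel footprint (voxels within 2.5 Å of any residue atom), optionally
averaged over a sliding residue window (default one residue), then
Z-scored against the mean and standard deviation pooled over all residues.
Residues with empty footprints are excluded from pooling and flagged; a
degenerate pooled sd (all scores equal, as when the map was generated from
the model itself) forces Z = 0 with a flag rather than dividing by zero.

**Local amplitude scaling.** A deliberately simplified single-pass variant
of reference-based local sharpening: the experimental map is processed in
overlapping cubic windows (default 30 Å side, stride half a window,
triangular blending); within each window the radial Fourier amplitudes are
rescaled shell-by-shell to match the model-derived reference, with a
scale-1 fallback for zero-amplitude reference shells. Per-voxel sliding and
reference B-factor handling of the full algorithm are out of scope.

## Numerical choices and degenerate inputs

* Histogram bins are half-open `[lo, hi)`; a sample exactly on an edge
  counts right.
* The window grid is inclusive of both end anchors (+55 to −55 every 1 Å
  gives 111 anchors; the quoted count of 110 windows corresponds to one
  exclusive endpoint, and inclusivity is the convention adopted).
* Lining-atom ties break to the smallest atom index; LDP merge order is by
  decreasing density with deterministic coordinate tie-breaks, so extraction
  is reproducible.
* Empty models, empty profiles, disconnected window sets, zero-weight
  mean-shift neighbourhoods, and atoms outside a synthesis grid all produce
  explicit errors, warnings, or flags rather than silent propagation.
* Identical pipeline configurations produce byte-identical TSV outputs
  (fixed numeric formatting; every random stage consumes an explicit seed).

## Problem sizes used by the shipped validation

The test and acceptance runs are sized to finish on one CPU in minutes:
flat-null and double-well recoveries use 23 windows × 10⁴ samples
(ten seeds for the double well); the two-peak channel-like recovery uses 51
anchors × 5 pooled replicas × 10⁴ samples over six seeds; pore oracles run
on 7×2-atom-per-ring toy channels; FSC oracles on 8³ grids; LDP checks on
~30-voxel-cube maps. These sizes are the package's validation conditions,
chosen so Monte-Carlo error is small against each tolerance being checked.

## Known limitations

* The pathway is assumed straight along the symmetry axis; curved-pore
  tracing is not implemented (appropriate for this channel family).
* The WHAM layer implements histogram WHAM only — no MBAR, no
  autocorrelation/statistical-inefficiency correction — matching the
  analysis it reproduces.
* The MRC reader intentionally rejects axis permutations, non-orthogonal
  cells, and non-P1 spacegroups rather than attempting conversion.
* `local_scale` is a simplified variant (see above) and should not be
  expected to match full reference implementations voxel-for-voxel.
* Map-space methods hold the whole grid in memory; they target the
  ≤ few-hundred³ grids typical of single-particle maps.
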