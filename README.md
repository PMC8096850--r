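# cptk — channel pore profiling, umbrella-sampling free energies, and cryo-EM map validation

cptk is an R toolkit for the desk-scale computational analyses that
accompany a cryo-EM structure of a homo-heptameric (C7) ion channel:

* **Pore profiling** — HOLE-style maximum-inscribed-sphere radius along the
  channel axis, constriction detection with lining-residue assignment, and
  open/closed classification against hydrated ion radii
  (Ca²⁺ 4.12 Å, Cl⁻ 3.32 Å, K⁺ 3.31 Å). The pore radius at axial position
  *z* is

  *R(z) = max over in-plane centres c of min over atoms i of
  (‖c − xᵢ‖ − rᵢᵛᵈᵂ)*.

* **Umbrella sampling / WHAM** — bookkeeping for harmonic bias windows
  *Uᵢ(q) = c/2 (q − qᵢ)²* (uniform c = 20 kcal mol⁻¹ Å⁻², anchors every
  1 Å, five pooled replicas), and a WHAM solver for the potential of mean
  force *A(q) = −kT ln P(q)* at 310 K (kT = 0.616 kcal/mol), with quadratic
  smoothing, block-wise convergence analysis, and barrier-to-residue
  mapping.

* **Density tracing** — mean-shift extraction of local dense points (LDPs)
  from density maps, exposing main-chain trails in mid-resolution regions,
  plus a distance graph over the LDPs.

* **Map/model validation** — model-to-map Gaussian synthesis, masked and
  unmasked Fourier shell correlation with resolution-at-threshold (0.143 /
  0.5), perturbed-model half-map cross-validation against overfitting,
  per-residue Z-scored local fit, and simplified windowed local amplitude
  scaling.

* **Synthetic data** — analytic free-energy profiles, an exact
  (Metropolis-adjusted) Langevin sampler for biased windows, steered-pull
  window seeding, toy channel models with known radius profiles, noisy
  half-map generation, and r.m.s.d./r.m.s.f. utilities — so every method
  can be validated against known ground truth on a laptop.

It is aimed at structural biologists and simulation scientists who want
these analyses as composable, tested R functions: every user-facing
function takes a data frame (or map object) first and returns a tibble, so
pipelines chain with the pipe, and fitted results support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Profile a two-waist toy channel (C7, pseudo-atom vdW 1.5 Å, waist ring
radii 3.5 and 4.1 Å at z = ∓10 Å), then recover a 5 kcal/mol double-well
barrier from synthetic umbrella windows:

```r
library(cptk)

channel <- build_toy_channel(
  channel_profile_two_waist(r_open = 8, waist_radius = c(3.5, 4.1),
                            waist_z = c(-10, 10)),
  z_range = c(-16, 16), ring_spacing = 2, atoms_per_ring = 14,
  vdw = 1.5, symmetry = 7)

out <- run_pore_pipeline(list(model = channel, step = 0.5, index_map = NULL))
cat(out$report, sep = "\n")
#> pore profile: 65 planes, z in [-16.00, 16.00] A, step 0.50 A
#> minimum pore radius: 2.00 A
#> constrictions (prominence >= 0.50 A): 2
#>   z = -10.00 A, radius 2.00 A, lined by A:4, excludes: Ca2+,Cl-,K+
#>   z = +10.00 A, radius 2.60 A, lined by A:14, excludes: Ca2+,Cl-,K+
#> state per ion: Ca2+ closed (margin +2.12 A); Cl- closed (margin +1.32 A); K+ closed (margin +1.31 A)
```

The two constrictions sit at the construction waists with pore radii equal
to ring radius minus pseudo-atom radius (3.5 − 1.5 = 2.0 Å and
4.1 − 1.5 = 2.6 Å); both are narrower than every tabulated hydrated ion
radius, so the toy channel is closed for all three ions, with the reported
margin saying by how much.

```r
pmf_run <- run_pmf_pipeline(list(
  pmf = analytic_pmf("double_well", height = 5, width = 10),
  q_start = -11, q_end = 11, interval = 1, replicas = 1,
  n_samples = 5000, seed = 4, barrier_prominence = 2))
glance(pmf_run$pmf)
#> # A tibble: 1 × 7
#>   n_windows n_bins bin_width temperature iterations converged barrier
#>       <int>  <int>     <dbl>       <dbl>      <int> <lgl>       <dbl>
#> 1        23     48       0.5         310         79 TRUE         5.03
pmf_run$barriers
#> # A tibble: 1 × 4
#>       z height prominence residues
#>   <dbl>  <dbl>      <dbl> <chr>
#> 1  0.25   5.03       4.05 ""
```

The generating profile has a 5 kcal/mol barrier at q = 0 between wells at
±10 Å; the pipeline samples 23 biased windows, unbiases them with WHAM, and
reads the barrier back within the Monte-Carlo scatter of the run.
`autoplot(pmf_run$pmf)` and `autoplot(out$profile)` draw the standard
figures for each result.

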