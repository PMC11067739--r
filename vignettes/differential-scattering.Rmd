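---
title: "Differential solution total scattering: model, decomposition and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential solution total scattering: model, decomposition and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvscat)
```

## The problem

A total X-ray scattering measurement of a dilute solution is dominated by the
solvent: the solute contributes in proportion to its volume fraction, which
at millimolar concentrations is of order $10^{-2}$ or less.  The standard
remedy is differential: measure the solution (sample A) and an otherwise
identical solvent reference (sample B), and subtract.  At high momentum
transfer ($Q \le 25$ Å$^{-1}$), where the data support sub-Ångström
real-space analysis through the pair distribution function (PDF), the naive
view that the subtraction isolates the solute signal is wrong in two ways:
the local ordering of solvent around the solute (the solvation cage)
contributes, and the reference contains *excess* solvent — the liquid that
in the solution is displaced by the solute's own volume.  `solvscat`
implements a complete bookkeeping for this experiment on atomistic
ensembles, so that every term can be computed, transformed to real space and
ranked by explanatory weight.

## The model

Coherent elastic scattering from $N$ atoms with tabulated form factors
$f_i(Q)$ is evaluated with the Debye equation for isotropically averaged
samples,

$$I(Q) \;=\; \sum_{i,j} f_i(Q) f_j(Q)\,
  \frac{\sin Q r_{ij}}{Q r_{ij}}
  \;=\; N\langle f^2\rangle(Q) + I_d(Q),$$

where the $i = j$ terms give the structureless self scattering
$N\langle f^2\rangle$ and the remainder is the distinct (interference)
intensity $I_d$.  The reduced structure function and reduced PDF are the
sine-transform pair

$$F(Q) = \frac{Q\, I_d(Q)}{N \langle f\rangle^2}, \qquad
  G(r) = \frac{2}{\pi} \int_{Q_{min}}^{Q_{max}} F(Q) \sin(Qr)\, dQ.$$

Splitting the solution's atoms into solute ($u$) and solvent ($v$) sets and
the reference's solvent into an excluded-solvent droplet ($x$) plus its
bulk complement ($v'$), the ensemble-averaged differential distinct
intensity decomposes exactly:

$$\Delta I_d = I_{uu} + 2 I_{uv} + \left(I^A_{vv} - I^B_{vv}\right),
  \qquad I^B_{vv} = I_x + I_{v'v'}, \quad I_x = I_{xx} + 2 I_{xv'}.$$

Normalizing to the scattering power of the solute,
$N_u \langle f\rangle_{uu}^2$, and weighting by $Q$ gives the differential
reduced structure function and its four-term parameterization

$$\Delta F = \tilde F_{uu} + 2\tilde F_{uv}
  - \tilde F_x + \Delta\tilde F_{vv'},$$

where the tilde marks solute-power normalization.  The four terms are,
respectively: the intramolecular solute structure; the solvation cage; the
scattering of the displaced ("excluded") solvent, an artifact of the
differential approach that must be subtracted before interpretation; and
solvent restructuring — the genuine change of solvent–solvent correlations
outside the excluded region, which vanishes by definition in an
ideal-dilute solution.  The linearity of the sine transform carries the
same decomposition into real space, and `model_ladder()` scores the nested
models $\tilde G_{uu}$, $+2\tilde G_{uv}$, $-\tilde G_x$,
$+\Delta\tilde G_{vv'}$ against the exact $\Delta G$ with the coefficient
of determination $r^2$ and the crystallographic $R$ factor
($100\sum|\mathrm{ref}-\mathrm{model}|/\sum|\mathrm{ref}|$; an unweighted
$L_2$ variant is also reported, since published tables rarely state which
convention they use).

The restructuring term is obtained as the framework defines it: the
excluded-solvent term $I_x$ is computed directly from per-frame droplet
labels, and $\Delta\tilde F_{vv'} = \Delta\tilde F_{vv} + \tilde F_x$ *by
definition*, so both closure identities hold to machine precision for any
labelling whatsoever.  This mirrors the operational character of the
excluded volume itself: it is an imposed, algorithm-dependent partition,
not an observable, and the package reports the labelling parameters with
every result.

## Worked example

```{r example, eval = FALSE}
fix <- make_reference_fixture(seed = 1)       # matched A/B ensembles
dec <- decompose_dF(fix$a, fix$b, fix$droplet)
dec_r <- transform_decomposition(dec, transform_spec(0.5, 25, 20, 0.01))
model_ladder(dec_r)
restructure_null_test(dec, n_perm = 400, seed = 1)$p_value
```

## Parameters that matter

**Q grid** — default $0.5$–$25$ Å$^{-1}$ in steps of $0.01$ Å$^{-1}$.  The
upper limit matches both high-energy total-scattering practice and the
validity range of the shipped form-factor parameterization; the lower limit
retains the region where solute–solvent and excluded-volume features are
strongest.  `Q_max` of a transform is a *required*, explicitly echoed
parameter of every real-space output, because truncation ripples of spacing
$\approx 2\pi/Q_{max}$ are part of what the data mean.

**Form factors** — the four-Gaussian-plus-constant analytic coefficients of
the International Tables (Cromer–Mann), neutral atoms, real-valued.
Anomalous terms are neglected (high-energy work far from edges) and neutral
atoms are used throughout, including for the Ru$^{2+}$/Cl$^-$ fixture: at
$Q \gtrsim 1$ Å$^{-1}$ the valence-electron difference between an ion and
its neutral atom is a sub-percent effect, and a custom table can be supplied
as plain text where ionic factors are wanted.

**Radii sets** — two plain-text tables ship. `vdw_radii("ff")` (default)
holds Lennard-Jones $R_{min}/2$ values of the kind used by Amber-family
force fields; `vdw_radii("bondi")` is the classic Bondi contact set.  The
choice is the single largest sensitivity of every excluded-volume quantity:
for the 63-atom metal-complex fixture the fused-sphere volume is
$\sim 650$ Å$^3$ (ff) versus $\sim 490$ Å$^3$ (Bondi), i.e. 22 versus 16
excluded waters under the $N_x = n_B V_{vdW}$ heuristic.  The force-field
set is the default because the excluded volume is meant to describe where a
simulated (or real) liquid cannot reach, and liquid-state packing is set by
the interaction minima, not by crystallographic contact distances; under
the ff set the heuristic, the droplet census and the simulated deletion
count agree to a few percent, which is the self-consistency the framework
relies on.  Both numbers are always reported side by side in the tests.

**Droplet criterion** — a solvent atom belongs to the excluded droplet when
it lies within *the van der Waals radius of a solute atom* (so the droplet
region is exactly the fused-sphere volume and the uniform-solvent
expectation of the droplet count is exactly $n_B V_{vdW}$); the
sum-of-radii alternative is a config switch.  Granularity is atom-wise by
default, with a molecule-wise option for multi-site solvents.  The solute
is embedded at the box centre with a fresh uniform random rotation per
frame (seeded); a fixed-orientation mode exists for reproducibility tests.
Counterions are part of the solute set: the differential experiment removes
the whole electroneutral unit.

**Normalization** — $N_u \langle f\rangle_{uu}^2$, the per-solute-atom
convention that reduces to the standard $F(Q)$ definition when the "solute"
is the whole sample.  The convention is recorded in every curve's metadata
because published work typically states only "normalized to the solute".

## The synthetic solvent, and what it does not emulate

The generator's solvent is a single-site hard-sphere fluid at the atomic
number density of liquid water, $n_B = 0.1$ atoms Å$^{-3}$ (see
`atomic_number_density()`), with $\sigma = 1.9$ Å giving packing fraction
$\eta \approx 0.36$ — a liquid-like density on the stable fluid branch.  It
is sampled by seeded single-particle Metropolis moves (maximum displacement
$0.35$ Å, acceptance $\approx 1/3$) from an fcc start.  Equilibration is
500 sweeps and frames are recorded every 100 sweeps; at these settings a
particle travels $\approx 0.9$ Å rms between frames (half a diameter), and
the per-frame scattering curves behave as independent draws, which the
resampling tests require.  A rigid three-site water-like template is
available to exercise molecule-granularity logic.

The matched pair is built the way an ideal-dilute solution is defined: the
solution ensemble inserts the rigid solute (random orientation, seeded)
into one solvent run and deletes solvent — either exactly the heuristic
count, nearest first (`count_matched`), or every molecule inside the vdW
region (`overlap`) — leaving all surviving solvent untouched; the reference
is a second, *independently seeded* run of the same box, as in the real
experiment where A and B are separate samples.  Under this construction
solvent–solvent correlations are identical in law between the ensembles,
so the restructuring term is zero in expectation, and
`restructure_null_test()` (paired sign-flip resampling of per-frame
curves, $L_2$ statistic) should fail to reject at its nominal level — this
is the package's operational definition of ideality.

What the surrogate does **not** reproduce: hydrogen-bond network structure
(no tetrahedral O–O correlations, no 2.8 Å peak), molecular form-factor
weighting of a real multi-site solvent, electrostriction, or any genuine
solute-induced restructuring.  Consequently the desk-scale fixture's
*magnitudes* — the ladder's intermediate $r^2$/$R$ values, the position of
the solute–solvent cage peak, the solvation-shell radii, and the roughly
hundred-fold intensity contrast of a true 15 mM experiment — are not those
of a force-field MD study of an aqueous complex; the fixture's effective
concentration is far higher (volume fraction $\approx 0.13$) so that every
term is resolved in minutes of sampling.  What passing tests *do*
establish is exact bookkeeping (closure, limits, normalization),
correctness of each estimator against independent oracles, and the
statistical behaviour of the restructuring null under enforced ideality.

The 63-atom solute fixture is an idealized tris-bidentate geometry
(Ru–N 2.06 Å, aromatic rings with all bonds 1.39 Å, C–H 1.08 Å, planar
chelates on octahedron edges, two outer-sphere chlorides); it is a
synthetic surrogate with fixed intramolecular distances, not a
quantum-chemically optimized structure.

## Numerical choices

* **Histogram acceleration.** Pair distances are binned at 0.01 Å; each
  bin stores its count, mean and variance, and the Debye kernel is
  evaluated at the bin mean with a Gaussian damping
  $\exp(-Q^2\sigma_b^2/2)$.  Plain bin-centre evaluation has a second-order
  error $\sim Q^2 w^2 / 24$ — a few $10^{-3}$ at $Q = 25$ Å$^{-1}$ —
  whereas the moment-corrected form stays below $10^{-6}$ relative of the
  brute-force double sum on the packaged test clusters.  One consequence:
  set-pair histograms recompose the all-atom estimator only to binning
  precision when an element pair spans two sets, so decomposition totals
  are defined as the component sums (closure exact by construction) and
  the independent all-atom estimate is reported as
  `estimator_consistency`.
* **Periodicity.** One liquid cell is evaluated with minimum-image
  distances to $r_{max} = L/2$; scattering between cells is treated as
  incoherent, and the isotropic uniform-density contribution
  $\frac{N_a N_b - \delta_{ab} N_a}{V}\,
  \frac{4\pi\left[\sin Q r_{max} - Q r_{max}\cos Q r_{max}\right]}{Q^3}$
  is subtracted in closed form per element pair.  The correction is
  additive over set pairs, which is what makes the decomposition exact.
  A cluster mode (no cell) performs raw sums for analytic tests.
* **$Q = 0$** is always the analytic sinc limit, never a division.
  Coincident atoms across sets are handled the same way, with a warning.
* **Quadrature.** Transforms use the trapezoidal rule on the stored grids
  (the dense default grid makes higher-order schemes unnecessary; the test
  suite cross-checks against Simpson's rule).  No window by default —
  truncation ripples are shown raw — with a Lorch window as an option.
* **Rounding.** The excluded-atom count $N_x$ is kept fractional
  internally; whole-molecule counts round half-up only at reporting
  boundaries.
* **Volumes.** Fused-sphere volumes integrate on a 0.1 Å grid by default;
  a Monte Carlo integrator with standard errors cross-checks it (they
  agree to $\sim 0.02\%$ on the 63-atom fixture).
* **Determinism.** All stochastic steps (sampler, rotations, Monte Carlo
  integration, resampling tests) draw from R's RNG under explicit seeds,
  and ensembles record their seeds; pipeline reruns are checksum-identical.

## Problem sizes

The shipped reference fixture uses 512 solvent molecules and 24 frames per
ensemble on the full default grids; the decomposition, transform and
ladder complete in well under a minute on one core, and the unit-test
systems are smaller still (128 molecules, 8 frames, coarser grids).  These
sizes were chosen so that every statistical test retains clear resolution
of the terms it checks while the whole suite stays quick to run.

## Known limitations

* Orthorhombic (cubic, in practice) cells only; no triclinic support.
* No Compton (incoherent) scattering, anomalous dispersion or instrument
  resolution corrections; comparisons with experiment require externally
  reduced data.
* `scale_and_subtract()` is a plain least-squares utility for differencing
  raw curves; it is *not* an absolute-normalization data-reduction scheme
  and makes no claim of equivalence to one.
* The excluded volume is an imposed construct: all downstream
  "restructuring" statements are relative to the stated labelling
  algorithm and radii set.
* Binary trajectory formats (DCD/XTC) are out of scope; convert externally
  to extended-XYZ.
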