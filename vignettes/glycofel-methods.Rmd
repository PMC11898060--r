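---
title: "Methods: puckering landscapes, well-tempered reconstruction, and catalytic observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: puckering landscapes, well-tempered reconstruction, and catalytic observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycofel)
```

## Scope

glycofel is the analysis layer for enhanced-sampling studies of glycoside
hydrolase catalysis: it turns deposited metadynamics bias records and
enzyme--substrate structures into puckering free-energy landscapes, reaction
paths with activation energies, and geometric/solvation descriptors of the
Michaelis complex.  It performs no electronic-structure or molecular-dynamics
computation itself; a seeded synthetic sampler provides ground-truth inputs
so that every stage is testable without a QM/MM engine.

## Cremer--Pople puckering coordinates

A six-membered ring's out-of-plane distortion is described by the amplitude
$Q$ (A) and spherical angles $(\theta, \phi)$.  Displacements $z_j$ of the
six atoms perpendicular to the mean plane through the geometric centre are
condensed into

$$q_2 \cos\phi = \sqrt{1/3}\sum_j z_j \cos(4\pi (j-1)/6), \quad
  q_2 \sin\phi = -\sqrt{1/3}\sum_j z_j \sin(4\pi (j-1)/6),$$
$$q_3 = \sqrt{1/6}\sum_j (-1)^{j-1} z_j, \qquad
  Q = \sqrt{q_2^2 + q_3^2}, \qquad \theta = \operatorname{atan2}(q_2, q_3).$$

Conventions that the formulae do not fix were settled once:

* **Ring walk**: atoms are ordered O5, C1, ..., C5 with O5 first -- the
  dominant glycoscience convention, under which the ${}^4C_1$ chair of an
  $\alpha$-D-pyranose sits at the north pole ($\theta = 0$).
* **Degeneracy**: for $Q < 10^{-4}$ A (below coordinate noise) the angles
  are undefined and flagged, not errored.
* **Units**: degrees at every user-facing interface, radians internally and
  on FES grids (hills widths are deposited in radians).

The inverse map (`invert_cremer_pople()`) places atoms on a reference
hexagon whose circumradius is shrunk so the mean squared bond length matches
the requested bond length, and adds the $z_j$ pattern reconstructed from
$(Q, \theta, \phi)$.  Because the prescribed $z$ patterns contain only the
$m = 2, 3$ Fourier modes, the mean-plane construction recovers them exactly,
and forward$\circ$inverse round-trips to better than $10^{-6}$ (this is a
tested invariant).

The 38 canonical conformers (2 chairs, 6 boats, 6 skew-boats, 12 envelopes,
12 half-chairs) are placed on the sphere by projecting idealized
displacement sign patterns through the same sums, which makes the reference
table self-consistent with the forward map by construction.  The layout
reproduces the field's standard wheel: $^1S_3$ at $\phi = 210^\circ$,
$B_{2,5}$ at $300^\circ$, $^O S_2$ at $330^\circ$ on the equator, $E_5$ at
$(\theta \approx 54.7^\circ, \phi = 300^\circ)$.  Classification is
nearest-reference by great-circle distance with a fixed-order tie-break.

## Reactive/nonreactive partition and $\Delta G_{r/nr}$

Conformations north of a boundary polyline $\theta_b(\phi)$ (toward
${}^4C_1$) count as reactive, those south of it (toward ${}^1C_4$) as
nonreactive.  The exact transition-state-mimetic boundary is not available
in closed form, so the **default is the equator** ($\theta_b = 90^\circ$,
boundary owned by the nonreactive side): it is the simplest boundary that
separates $E_5$ (reactive) from $^1S_3$ (nonreactive), and it is fully
overridable by any periodic polyline via `partition_spec()`.

The partition statistic is, in the default `"boltzmann"` mode,

$$\Delta G_{r/nr} = -kT\ln\!\!\sum_{\mathrm{reactive}}\! e^{-F/kT}\Delta A
  \;+\; kT\ln\!\!\sum_{\mathrm{nonreactive}}\! e^{-F/kT}\Delta A,$$

at $kT = 0.596$ kcal/mol (300 K), with a uniform node area element in
$(\phi, \theta)$ -- matching the flat 2D projection in which these
landscapes are conventionally drawn (a spherical $\sin\theta$ weighting
would be a different, defensible choice; the projection treatment was kept
because the landscapes themselves are constructed and published in that
projection).  A `"minimum"` mode reports the difference of region minima
instead; both are returned by the pipeline because the aggregation
underlying published values of this statistic is not standardized.
Negative values mean reactive conformations are favored.

## Well-tempered FES reconstruction

A HILLS record is the time series of deposited Gaussian bias terms.  The
accumulated bias at a grid node $s$ is
$V(s) = \sum_k w_k \exp(-\sum_i \Delta_i^2 / 2\sigma_{i,k}^2)$ with
minimum-image differences on the periodic $\phi$ axis, computed as one
separable outer product per hill.  Two **height dialects** exist in the
wild: the default `"tempered"` dialect assumes stored heights are the
as-deposited (already damped) heights, giving
$F = -\frac{\gamma}{\gamma-1} V$; `"prescaled"` assumes the factor is
already folded in, giving $F = -V$.  The bias factor is treated as the
dimensionless well-tempered $\gamma$ (values quoted in energy units in
simulation write-ups are read as the dimensionless factor).  Surfaces are
shifted so the global minimum is zero.  The default grid is
$144 \times 72$ ($\phi$ periodic, $\theta$ clamped); reconstruction equals
a brute-force double-loop summation to $10^{-10}$ in the tests.

Reconstruction never truncates hills; `glance()` flags when the surface
range exceeds 14 kcal/mol, the conventional stop criterion for these runs.

## Minimum free-energy paths

`find_mfep()` returns the **global minimax path**: among all 8-connected,
periodic-aware grid paths it minimizes the highest node energy, with ties
broken by minimal accumulated energy and then by node count.  The
bottleneck level is found exactly by growing connected components over
nodes in increasing energy order; the tie-break path is then the shortest
path (edge weight = mean of the two node energies, plus an infinitesimal
per-edge cost) inside the admissible subgraph.  Tests verify minimax
optimality against an independent Floyd--Warshall closure on random grids.
$\Delta G^\ddagger$ is the path maximum minus the first node,
$\Delta G$ the last minus the first; the transition state is the first
argmax, reported with a $\pm 1$-node window.

Basins come from `find_minima()`: strict 8-neighbour local minima filtered
by basin depth, computed by a persistence sweep (the depth of a minimum is
the lowest saddle connecting it to any deeper basin, minus its own level).

## Reaction collective variables

For the glycosylation step of a retaining glycosidase the two CVs are
distance differences: $\mathrm{CV}_1 = d_1 - d_2$ tracks the proton
transfer from the acid/base carboxylate (midpoint of the two oxygens --
equal masses make the centre of mass their midpoint) to the glycosidic
oxygen; $\mathrm{CV}_2 = d_3 - d_4$ tracks glycosidic bond cleavage versus
nucleophilic attack at the anomeric carbon.  Both are negative in the
Michaelis complex and positive in the covalent intermediate.  Atom naming
in deposited structures varies (protonated aspartate and substrate atoms
especially), so `catalytic_selection()` makes every atom name and residue
number overridable.

## SASA and the substrate-positioning index

`shrake_rupley()` uses a deterministic Fibonacci-spiral point set (no RNG,
bit-stable results) with probe radius 1.4 A and 960 points per sphere by
default -- conventional values for water-accessible surface area.  The SPI
is SASA(substrate)/SASA(pocket), with per-atom areas computed in the
context of the full complex so that every atom occludes.  Hydrogens are
used as given by default; a united-atom option drops them and inflates
heavy-atom radii by 0.1 A.  Tests check isolated-sphere closed forms, a
high-resolution quadrature oracle (independent latitude--longitude
integration), occlusion monotonicity, and point-count convergence.

## The synthetic sampler: what it emulates and what it does not

`sample_wt_metad()` runs overdamped Langevin dynamics in the
two-dimensional CV space of an analytic Gaussian-well potential (periodic
$\times$ reflective domain), depositing well-tempered hills
$w_k = w_0 e^{-V(s_k)/((\gamma-1)kT)}$ every `pace` steps.  Defaults mirror
a puckering production run: $w_0 = 0.75$ kcal/mol, widths 0.1 rad,
$\gamma = 15$, deposition every 75 steps, stop once the implied surface
range reaches 14 kcal/mol.  The friction default (120, with $kT = 0.596$
and $dt = 1$) gives a thermal step of about 0.1 rad.

This is deliberately **not** an atomistic emulator: there is no molecular
force field, no multidimensional hidden coordinate, no CV distortion.  A
passing parameter-recovery test therefore shows that the reconstruction and
path machinery is correct for data of this form, not that any particular
enzyme simulation was converged.

Two built-in landscapes provide phenomenology-matched fixtures, one
parameter apart (`pucker_landscape(delta)`):

* **wild-type-like** (`delta = -4`): northern $E_5$-like basin 4 kcal/mol
  deeper than the southern basin, so the global minimum is reactive and
  $\Delta G_{r/nr} < 0$;
* **D74E-like** (`delta = +10`): southern basin strongly favored, global
  minimum nonreactive, $\Delta G_{r/nr} > 0$, and a much larger barrier to
  reach the northern region.

The southern well is centred at $\theta = 100^\circ$, just south of the
equator rather than exactly at the equatorial $^1S_3$ point: the true
reactive/nonreactive boundary passes north of $^1S_3$, so that basin is
wholly nonreactive, and a basin centred exactly on the default equator
boundary would split its Boltzmann mass between the regions and wash the
statistic out.  Because the Gaussian wells are 0.45 rad wide, the region
statistic of these landscapes is smaller in magnitude than the well-depth
difference (the analytic values are about $-3.6$ and $+1.7$ kcal/mol); the
sampler-reconstruction chain recovers those analytic values, which is the
meaningful test.

The standard parameter-recovery fixture is a symmetric double well along
$\theta$ whose depth is solved at construction so the analytic barrier is
exactly 5 kcal/mol.  The documented recovery run uses 120,000 steps,
deposition every 50 steps, widths 0.35 rad, $\gamma = 8$, seed 42 in the
test suite (the acceptance script derives the seed from its `--seed`
argument); the barrier read from the reconstructed surface via
`find_minima()` + `find_mfep()` lands within 0.5 kcal/mol of 5.

## Numerical choices and degenerate inputs

* Hills with zero records reconstruct a uniformly zero surface; empty
  region masks, degenerate (planar) puckers, zero-length angle vectors and
  a zero pocket area raise descriptive errors (the SPI reports `NA` with a
  warning for a zero denominator, as a degenerate ratio rather than a
  failure).
* Equal-energy ties: conformer classification breaks ties by the fixed
  table order; the minimax path tie-break is deterministic (accumulated
  energy, then hop count via an $10^{-9}$-scaled per-edge cost).
* The Euler--Maruyama integrator has a systematic variance bias of order
  $\mu k\,dt/2$ in a harmonic well of stiffness $k$; the equipartition test
  chooses friction so this bias is well below its tolerance.
* Problem sizes in the routine test runs are scaled down (36--72 node
  grids, 15,000--40,000 sampler steps) relative to the documented
  production-style runs (144 x 72 grids, 80,000--120,000 steps used by the
  acceptance script); the scaling only affects statistical precision, and
  every deterministic check runs at full precision.

## Known limitations

* The equator partition is an approximation to the transition-state-mimetic
  boundary; analyses sensitive to the boundary should supply their own
  polyline (and can flip boundary ownership).
* `profile_along_path()` assigns observations to their nearest path node;
  observations far from the path are still assigned (no distance cutoff).
* The minimax path is grid-based: no continuous-space refinement (string
  method, NEB) is attempted, and node energies are used without
  interpolation.
* SASA is point-sampled, not analytic; accuracy is set by the point count
  (default 960 per sphere, < 0.5% change when quadrupled).
* The phi-origin convention of external puckering data may differ from the
  package's; `cremer_pople()` output can be shifted by a fixed offset
  before classification if a deposit uses another origin.
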