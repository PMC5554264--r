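---
title: "Growing and exciting virtual cardiac monolayers: models and methods"
author: "CardioLattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing and exciting virtual cardiac monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

CardioLattice couples two models: a cellular Potts
(Glazier--Graner--Hogeweg, GGH) model that grows virtual monolayers of
neonatal-rat cardiomyocytes (CM) and fibroblasts (FB), with or without an
aligned nanofibre scaffold, and a monodomain reaction--diffusion solver
that propagates electrical waves over the grown tissue through a
heterogeneous, per-face conductance map. This vignette explains the
models, the numerical choices, and the reasoning behind every decision
that the published description leaves open.

## The tissue-formation model

Each biological cell is a 4-connected set of lattice subcells (2.5 um
per subcell) sharing an integer index. Dynamics are Metropolis copy
attempts: a random target site and a random Moore-neighbour source; the
copy is accepted with probability 1 if it lowers the Hamiltonian and
with probability $e^{-\Delta H/T}$ otherwise. One Monte-Carlo step (MCS)
is $N$ attempts, $N$ the number of lattice subcells.

The Hamiltonian contains:

* **Adhesion**: $\sum J_{\tau_i \tau_j}(1-\delta_{\sigma_i \sigma_j})$
  over neighbour pairs. The neighbourhood order is configurable
  (`adhesionNeighbourhood`); the default is the Moore (8-neighbour)
  convention common in GGH work.
* **Elasticity**: $\sum_\sigma \lambda_\tau (v_\sigma - V^t_\tau)^2$,
  areas in subcells.
* **Protrusion**: each cell owns up to $N_{protr}$ focal-adhesion sites;
  a site at distance $\rho$ from the cell's centre of mass carries
  potential $G/\rho$, so configurations with adhesions farther out have
  lower energy. On a nanofibre subcell the potential becomes
  $G/(\rho\cos\alpha)$, $\alpha$ the angle between the fibre axis and
  the direction from the centre of mass to the site: displacement along
  the fibre feels the full outward force, displacement across it is
  penalised, which is what elongates cells along the scaffold.
* **Event penalties** folded into $\Delta H$: $P_{detach}$ when a copy
  lands on an existing focal adhesion (destroying it), $P_{unleash}$
  when an adhesion tip moves from a fibre subcell onto the isotropic
  substrate (fibre-to-fibre and substrate-to-fibre moves are free), and
  a nucleus-protection penalty $P_N = 2 P_{detach}$ whenever medium or a
  foreign cell invades within 7 um of a cell's centre of mass.

Three copy rules are enforced outside the energy: a copy may not make a
cell disappear, may not break a cell's 4-connectivity (checked by a
ring-neighbourhood fast path and, when inconclusive, a flood fill
restricted to the cell's bounding box), and may not place any protrusion
site beyond $L_{MAX}$ of the (post-copy) centre of mass.

### Focal-adhesion life cycle

Cells are seeded as squares of side $\sqrt{V^t/10}$ with no adhesions.
When an accepted copy expands a cell whose adhesion count is below
$N_{protr}$, the newly added subcell becomes an adhesion. When the copy
source is itself an adhesion site, the adhesion relocates to the target:
this is the protrusion tip advancing, and its energy change
$G/\rho_{new} - G/\rho_{old}$ is the protrusive force. An adhesion
destroyed by an invading copy is simply removed (with the $P_{detach}$
penalty); we deliberately do not credit the $-G/\rho$ of the destroyed
site, because that windfall would make attacking adhesion sites
energetically attractive and neutralise $P_{detach}$ entirely. Newly
established adhesions are likewise free at creation time; charging the
full $G/\rho$ on establishment would forbid early cell spreading (the
first adhesion of a fresh seed would cost more than any thermal
fluctuation can pay). The test-suite oracle reconstructs exactly these
conventions from before/after states, so the incremental energy
bookkeeping is verified against a from-scratch evaluator including the
centre-of-mass shifts.

### Units and the contact-energy scale

The published parameter table mixes unit families (protrusion constants
in mm, elasticity in mm$^{-4}$, penalties in mm$^{-1}$, adhesion
energies and $T = 1$ dimensionless), and no single conversion makes all
of them dimensionally consistent. The conventions adopted, fixed once
and used everywhere:

* $G/\rho$ is computed with both quantities in the same length unit, so
  it is invariant to that choice; the loader stores
  $G_{lattice} = G_{mm}/0.0025$ with $\rho$ in subcells.
* $\lambda$ is an energy per subcell$^2$ as printed. (Reading the
  printed mm$^{-4}$ literally with areas in mm$^2$ yields energies of
  order $10^{-9}$ — elasticity would never act, cells would balloon to
  $L_{MAX}$ stars, and measured areas would not match the published
  per-condition areas, which they do under the adopted reading.)
* $P_{detach}$, $P_{unleash}$ are plain energies as printed.
* The adhesion-energy column is in a different internal unit from the
  temperature: taken as printed (values 300--1150 at $T = 1$) the
  dynamics freezes into its nearest local minimum and every cell relaxes
  to a convex blob (simulated FB convex coverage 0.94 against the
  published 0.66). The secondary gap-junction model's printed energies
  ($G = 25$, $J_H = 2$, $J_B = 10$ at $T = 1$) *are* order-one
  consistent, which points the same way. We therefore convert the
  morphology $J$ column with a contact-energy factor
  (`loadPreset(jScale = )`), calibrated against the published per-type
  convex coverages of the isolated no-fibre condition (0.035) and
  cross-validated, unchanged, on the isolated on-fibre and isotropic
  monolayer conditions (coverages, elongations and areas within one
  experimental SD). The anisotropic monolayer parameter set — fitted
  independently in the source, like each condition — only reproduces its
  published coverages (CM 0.81, FB 0.60) at the printed scale
  (jScale = 1); at 0.035 its ten-fold larger protrusion constant makes
  cells hyper-protrusive (CM coverage 0.45). The default is therefore
  per-condition (0.035 / 0.035 / 0.035 / 1.0), each value validated
  against that condition's published shape table only, and frozen before
  any electrophysiological quantity was computed.

Unprinted cell--cell adhesion energies of the isolated-cell presets are
set to the neutral value $J_{XY} = J_{X,MD} + J_{Y,MD}$ (zero cell--cell
surface tension), so the rare contacts in low-density seeding neither
cluster nor repel.

Two numerical floors protect the $1/\rho$ potential: $\rho$ is floored
at half a subcell, and $|\cos\alpha|$ at 0.1. The cosine enters through
its absolute value because fibres are undirected (angles live in
$[0,\pi)$), and the floor keeps the energy finite and the force from
reversing at $\alpha \to 90^\circ$, where the projection argument that
derives the term no longer applies.

### Seeding and presets

Four presets name the four culture conditions (`isolated_iso`,
`monolayer_iso`, `isolated_fibres`, `monolayer_fibres`) with the
published per-type parameters, lattice sizes (400x400 for isolated
conditions at 1.0x1.0 mm, 320x320 for monolayers at 0.8x0.8 mm),
seeding grids (17x7, 26x26, 5x10, 17x68) and MCS budgets (900, 2000,
2000, 3000). The sample is divided into the grid of seeding areas and
one square seed is placed uniformly at random inside each; cell types
are a random permutation matching the requested FB fraction by largest
remainder. Simultaneous seeding is used (the alternative, sequential
seeding, is indistinguishable here because seeds cannot overlap by
construction). The fibre scaffold is a set of parallel 1-subcell fibre
rows; the published description fixes one (unstated) fibre density, and
the default pitch of 4 subcells (10 um) places several fibres under
every cell. The digit-level readings of two ambiguous table entries
(a monolayer $L_{MAX}$ of 81.41 um rather than 1.41 um, and the G
column split) follow the only parses consistent with the remaining
conditions; 1.41 um would freeze monolayer cardiomyocytes at their
seeds, producing no confluent tissue at all.

### What the generator does and does not emulate

The generator reproduces the mean cell of each condition: areas near
the per-type targets, convex polygonal shapes with protrusions, CM/FB
shape separation (isolated CM coverage ~0.88 vs FB ~0.63), fibre-driven
elongation, and confluent monolayers at the published densities. It
does not model per-cell parameter variability (every CM shares one
parameter set, so simulated shape SDs are narrower than experimental
ones), cell division or death, migration-phase dynamics, or 3-D
effects. Passing shape tests therefore says the *average* morphology is
right, not that the population spread matches real cultures.

## Gap-junction labels and the conductance map

A secondary lattice model distributes "more-GJ" membrane labels on the
frozen tissue: labels start on the one-subcell dilation of each cell's
focal adhesions (the more-GJ quota; configurable), and label-swap
Metropolis moves between neighbouring subcells of the same cell
conserve per-cell counts while the energy
$\sum J^{\sigma}_{\tilde\sigma} + \sum_{moreGJ} G/\rho$ (with $G = 25$,
side-to-side contact cost $J_H = 2$, within-cell more-GJ contact cost
$J_B = 10$, end-to-end cross-cell more-GJ contact cost 0) pushes them
outward and spreads them along borders. The published description does
not validate this sub-model against connexin imaging and neither do we;
it is the mechanism that concentrates coupling at cell ends.

The conductance map assigns one diffusion level per lattice face:
$D_{in}$ within a cardiomyocyte, $D_{end}$ on CM--CM faces flanked by
more-GJ labels on both sides, $D_{side}$ on other CM--CM faces, zero on
anything touching a fibroblast or medium. Fibroblast interiors also get
zero: FBs are unexcited obstacles in this study. With
$D_{side} = D_{end} = D_{in}$ the map degenerates to a homogeneous
CM-phase map, the published minimal-anisotropy control.

## The monodomain solver

$\partial V/\partial t = \nabla(D \nabla V) - (I_{ion}+I_{stim})/C_m$
is integrated by the alternating-direction implicit scheme: each
half-step treats one axis implicitly (independent tridiagonal systems
per row or column, solved exactly by the Thomas algorithm with per-face
conductances) and the other explicitly, with the reaction current
evaluated at the previous full step entering both right-hand sides;
gates advance once per full step from the step-$n$ potential (the
half-step gate timing is not fully specified in the source scheme; the
once-per-step forward update is the simplest consistent reading and is
what the order-of-accuracy test exercises). Closed (no-flux) boundaries
arise naturally from zero boundary-face conductances, and pure
diffusion conserves total $V$ to solver precision — a tested invariant.
At $h = 2.5$ um and $D = 1$ cm$^2$/s the diffusion number
$D\,\Delta t/h^2$ is 1600 at $\Delta t = 0.1$ ms and 16000 at 1 ms;
an explicit scheme would need nanosecond steps, the ADI scheme is
unconditionally stable in its implicit axes and is verified against a
dense linear-algebra reference to $10^{-10}$.

### The ionic surrogate

The full neonatal-rat ionic model that the conductance map was designed
for lives in external code; the package exposes an `IonicModel`
contract (current, gate update, resting state, threshold) and ships a
two-variable excitable surrogate with Aliev--Panfilov kinetics
($k = 8$, $a = 0.15$, $\epsilon_0 = 0.002$, $\mu_1 = 0.2$,
$\mu_2 = 0.3$). The one tunable that matters is `tScale`, the
milliseconds-per-time-unit mapping. The classical mapping (12.9 ms)
gives an upstroke of ~10 ms; in junction-limited discrete tissue that
is fatal — charge injected into a cell leaks on to its strongly coupled
neighbours faster than the slow upstroke can regenerate it, and waves
die at the source. The default `tScale = 1` ms sharpens the upstroke to
the sodium-current scale and restores propagation; the classical scale
remains available and is the configuration used to demonstrate solver
stability at the printed 1-ms operating point (at that step size the
explicit reaction update of the fast variant would be the unstable
element, not the ADI diffusion).

Stimulation is a depolarising current in a disk. Because the tissue is
strongly coupled, a sub-cellular electrode cannot launch a wave
(source--sink mismatch); the default electrode radius is 14 pixels
(35 um, about one cell) at amplitude 1 amplitude-unit/ms for 3 ms.

### Activation maps and velocity measurement

Activation time is the first upward crossing of half the
action-potential amplitude. Velocities are inverse slopes of
least-squares fits of activation time against distance. On discrete
tissue a single-pixel sampling line is dominated by cellular texture
(a line of isopotential cell interiors is a staircase), so the
estimators average it out: segment fits pool parallel lines within a
configurable band; the L-shaped arm fit averages activation times over
the central portion of the arm width before regressing on the along-arm
coordinate; and the point-stimulation estimator fits the whole
activation annulus with an elliptical front model
$t^2 = x^2/v_x^2 + y^2/v_y^2$, which uses every activated pixel and is
robust to the local conduction detours that can distort single-ray
estimates (per-direction sector fits are retained as diagnostics). The
L-shaped protocol stimulates the junction of two arms (fibres parallel
to one arm) and fits each arm's centreline band over its quasi-planar
middle stretch; the longitudinal-to-transversal ratio is the
anisotropy ratio. An optical-mapping-style Gaussian smoothing
(`opticalSmoothing`, physical kernel converted to pixels) is available
for rendering frames the way experimental recordings are processed;
velocity measurements in the package operate on raw activation maps.

With `D_side = 0` a 35 % fibroblast tissue sits near the percolation
threshold of its end-to-end contact network, and an occasional sample
develops a conduction block in one arm. The velocity ratio is undefined
for such a sample (experimentally, a non-conducting sample cannot be
mapped), so the arm fit refuses maps whose fit window is less than 60 %
activated, and ensemble protocols draw further seeds until the required
number of conducting samples is measured. Because ratios are scale
quantities, ensemble averages are taken on the log scale.

## Problem sizes

Formation runs use the published lattice sizes and MCS budgets; the
wave-propagation studies in the acceptance script run the isotropic
monolayer at its native 320x320 (0.8x0.8 mm; three seeds) and the
anisotropic L-shaped sample on a 400x400 domain with 110-pixel arms
(four conducting samples), arms narrow relative to their length so the
plane-front stretch is not contaminated by fast-axis shortcuts inside
the arm. These are the desk-scale analogues of the published multi-mm
optical-mapping samples; the within-sample velocity estimates are
noisier at this size, which is why several seeds are averaged and the
sector/band estimators are used.

## Known limitations

* The contact-energy conversion (`jScale`) is a calibrated constant, not
  a derived one; all adhesion-energy *ratios* are as published, but the
  absolute thermal scale of the morphology model is identified from one
  published validation target.
* Simulated shape variability underestimates experimental variability
  (single parameter set per type, as in the source model).
* In confluent monolayers the simulated CM/FB convex-coverage ordering
  can invert relative to isolated conditions; the isolated-condition
  ordering (CM more convex than FB) is reproduced robustly.
* The anisotropy ratio on 0.8-mm domains fluctuates noticeably between
  seeds because transversal conduction is percolation-like through
  sparse end-to-end contacts; means over seeds are the stable quantity.
* The GJ label sub-model is unvalidated against imaging, as in the
  source description.
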