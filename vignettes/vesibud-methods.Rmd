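---
title: "Models and methods behind vesibud"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vesibud}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vesibud simulates coarse-grained lipid nanovesicles exposed to small
adsorbing solutes with dissipative particle dynamics (DPD), and analyses
the resulting trajectories for adsorption, membrane elasticity and
morphology. This vignette explains the model, the estimators, the
numerical choices, and what the package's own tests do and do not
establish.

## The molecular model

Four bead species build every system: lipid head (H), lipid chain (C),
water (W) and solute (S) beads, all of diameter $d$ (the unit of length,
about 0.8 nm). A lipid is 15 beads: three H beads and two chains of six
C beads, held together by harmonic bonds
$U = \tfrac{k}{2}(r - \ell_0)^2$ with $k = 128\,k_BT/d^2$,
$\ell_0 = 0.5\,d$, and stiffened by a bending potential
$k_b(1 - \cos\phi)$ with $k_b = 20\,k_BT$ on consecutive chain triples
and the head--chain junctions. These bonded constants are standard
values for this family of DPD membrane models; the pair-force table is
the model's published parameter set, and deleting the solute row and
column recovers the solute-free model it extends. All bonded and
thermostat constants are configurable on `dpd_forcefield()`.

Non-bonded beads interact through the soft linear DPD repulsion
$F(r) = f_{ij}(1 - r/d)$ for $r < d$, zero beyond. The water–solute
parameter selects the solvent condition: $f_{WS} = 32$ (good solvent)
or $f_{WS} = 40$ (poor solvent), corresponding to solubilities
$\zeta = 25/32$ and $25/40$. We quantify the solubility as
$\zeta = (f_{WW} + f_{SS})/(2 f_{WS})$, the arithmetic-mean form natural
for the regular-solution demixing criterion of soft repulsive fluids;
at the published parameters ($f_{WW} = f_{SS} = 25$) it reduces to
$25/f_{WS}$.

The thermostat is the standard DPD pair: dissipative force
$-\gamma \omega_D(r) (\hat r \cdot v_{ij}) \hat r$ with
$\omega_D = (1 - r/d)^2$ and random force
$\sigma \omega_R(r) \theta_{ij} \hat r / \sqrt{\Delta t}$ with
$\omega_R = (1 - r/d)$, tied by fluctuation--dissipation
($\sigma^2 = 2\gamma k_BT$; default $\gamma = 4.5$). The noise
$\theta_{ij}$ is symmetric in the pair, so momentum is conserved to
rounding. Unit-variance uniform noise is used, a standard and valid
choice for DPD.

## Integration and ensembles

The integrator is the DPD-adapted velocity-Verlet scheme with velocity
prediction parameter $\lambda = 0.65$ and default timestep
$\Delta t = 0.01\,\tau$ ($\tau = d\sqrt{m/k_BT}$). At these settings the
long-run kinetic temperature stays within 1% of the target. Published
descriptions of this model family do not fix $\Delta t$, $\lambda$ or
$\gamma$; these defaults are documented assumptions chosen for
stability at the given force amplitudes.

NPT is implemented as isotropic weak-coupling (Berendsen-type) box
rescaling toward a target total pressure (default
$23.7\,k_BT/d^3$, the bulk-water value at density $3/d^3$), with
coupling time $10\,\tau$ and a per-step rescale clamp. Its only role is
to set the bulk density before production NVT runs; it is not a
rigorous isothermal--isobaric sampler and is documented as such.

At density $\rho = 3/d^3$ and $f_{WW} = 25$ the engine reproduces the
excess (virial-only) bulk pressure of $20.7\,k_BT/d^3$; the acceptance
script recomputes this from scratch.

## System builders

`build_vesicle()` places $N_{il}$ and $N_{ol}$ lipids on concentric
spherical shells with the heads facing interior and exterior water and
chains meeting at the bilayer midplane. Leaflet head-shell radii follow
from an initial area per lipid of $1.25\,d^2$, the relaxed value for
this lipid; for the published leaflet numbers (4000/6100) this gives a
leaflet separation close to the bilayer thickness
$\ell_{me} \simeq 5\,d$, so the assembled membrane relaxes quickly. The
interior is filled with exactly $N_W^{in}$ water beads and no solute;
the exterior receives the remaining solvent budget at mole fraction
$\Phi_S$. Deflation/inflation (`set_volume()`) relocates interior
waters to the exterior compartment (and back) rather than deleting
them, so the global bead totals stay fixed while the volume parameter
$\nu = N_W^{in}/N_W^{isp}$ varies; the published bead budgets list
fixed totals across $\nu$ protocols, which relocation preserves
exactly. Solute titration (`set_solute_fraction()`) converts exterior
bead identities in place.

Because the bilayer is $\sim 5\,d$ thick, there is a hard lower bound
on vesicle size: the desk-scale `mini_vesicle` fixture (180/810
lipids, midsurface radius $\approx 6.9\,d$, $\sim$59k beads in a
$(27\,d)^3$ box) is about the smallest vesicle this lipid admits. It
is far more curved than the published 36 nm vesicle and serves for
trend and invariance checks, not for reproducing full-scale numbers.

`build_planar_bilayer()` budgets its solvent against the $5\,d$
excluded slab so the far-field solvent relaxes to $3/d^3$;
`build_slab()` seeds all solute in the central third of an elongated
box to nucleate two liquid--liquid interfaces.

## Adsorption observables

Radial profiles are shell histograms about the per-frame centre of mass
of the lipid beads (robust to solvent asymmetry), bin width $0.25\,d$
by default. The midsurface radius $R_{mid}$ is the chain-density peak
refined by a three-point quadratic fit; the membrane thickness is the
full width at half maximum of the membrane density.

The solute coverage is the excess-profile integral
$\Gamma = A_0^{-1} \int_{V^{ex}} \Delta\rho_S\, dV$ with
$A_0 = 4\pi R_{mid}^2$ and $\Delta\rho_S(r) = \rho_S(r) - \rho_{S,b}$.
Two equivalent routes are provided. `coverage()` integrates the binned
excess profile over $r > R_{mid}$, which is exact within the largest
inscribed sphere and is validated against closed-form synthetic shells.
`vesicle_coverage()` evaluates the same integral as a mass balance,
$\Gamma = (N_S - \rho_{S,b} V^{ex})/A_0$ with
$V^{ex} = V_{box} - \tfrac{4}{3}\pi R_{mid}^3$, which also accounts for
the corner regions of a cubic box that radial bins cannot reach; at
desk scale, where the box is only a few adsorption-layer widths wider
than the vesicle, this is the preferred estimator. The bulk density
plateau is taken over the outer 20% of the radial range by default
(the full-scale plateau rule, $r \gtrsim 28\,d$, scaled to the box).
Contact-counting coverage via an S--H contact length is deliberately
not offered: the excess-profile route avoids the arbitrary contact
scale.

## Stress, tension and spontaneous curvature

The spherically resolved pressure tensor is computed by the
Irving--Kirkwood construction: each pair force is spread along the
straight segment between the two beads, each piece assigned to the
radial shell of its midpoint and resolved into normal ($P_N$) and
tangential ($P_T$) components along the local radial direction; the
kinetic part is binned per bead. Bending (three-body) forces are
decomposed into two bond-segment pair forces before deposition. Only
conservative and bonded forces enter the configurational stress:
dissipative and random forces average to zero by construction.
The volume-averaged shell pressure reproduces the global virial
pressure to better than 1% on homogeneous fixtures. Stress bins are
$0.2\,d$, finer than density bins.

The display-equation forms used here (the source renders them as
images) are the standard mechanical expressions for a spherical
interface, adopted as this package's definitions and validated
analytically against single-bin spike profiles:

* bilayer tension
  $\Sigma = \int dr\, (r/R_{mid})^2 \, s(r)$ with
  $s = P_N - P_T$, the droplet-analogy form;
* first stress moment
  $\langle s \rangle_0 = \int dr\, (r - R_{mid})\, s(r)$, evaluated at
  (near-)vanishing tension;
* spontaneous curvature
  $m = 1/R_{mid} - \langle s \rangle_0 / (2\kappa)$, so a vanishing
  moment pins $m$ at $1/R_{mid}$, and solute adsorption onto the outer
  leaflet (which lowers the moment) increases $m$, the physically
  required sign.

Both integrals run over a window $R_{mid} \pm 5\,d$ by default
(configurable); the bilayer's stress lobes are localized within about
$\pm 3\,d$ of the midsurface, and the window trades a small bias for
bulk-noise rejection. The zero-tension tolerance is
$|\Sigma| < 0.1\,k_BT/d^2$.

`find_tensionless()` scans the tension over at least three interior
water counts and interpolates the zero crossing, mirroring the
relaxed-state protocol used to define the reference state for elastic
measurements. The area compressibility $K_A$ is the least-squares slope
of $\Sigma$ against relative area dilation near zero, and the bending
rigidity follows $\kappa = K_A \ell_{me}^2 / 48$ with the 1/48
prefactor.

## Phase behaviour

Coexistence is measured from slab runs: the z-resolved local mole
fraction in $1\,d$ slabs, interfaces at the extreme periodic gradients,
an exclusion zone of $3\,d$ on either side of each interface to avoid
interfacial broadening bias, and plateau averages for the dilute and
dense branches. The system counts as phase separated when the branch
difference exceeds five combined standard errors. A solvent is
classified poor when any scanned overall fraction separates; the
binodal estimate is the dilute branch of the lowest separating point.
Desk-scale slab boxes ($10 \times 10 \times 30\,d$, a few times
$10^4$ steps) are small enough that the dilute branch carries a
finite-size uncertainty of order 10--20%.

One model-fidelity finding deserves emphasis. For the poor-solvent
parameters ($f_{WS} = 40$), equilibrated slab runs of this Hamiltonian
— at $10 \times 10 \times 30\,d$ and $12 \times 12 \times 36\,d$, run
until the dilute branch (filling from below by evaporation) and the
water fraction dissolved in the dense phase (draining from above; the
symmetric mirror of the dilute branch for $f_{WW} = f_{SS}$) meet —
converge on a coexistence mole fraction of about 0.013. That value is
what regular-solution theory predicts for this force contrast
($\chi \approx 0.286\,(f_{WS} - f_{WW}) \approx 4.3$ gives
$x_{coex} \approx 0.014$), so we take it as the true binodal of the
binary fluid as parameterised here, while noting that a binodal near
0.0275 has been reported for these parameters. An onset-of-separation
estimate on an upward concentration scan — which in finite systems
sits above the true dilute branch because separation requires
supersaturation — would land in that region. The package reports the
faithfully measured dilute branch and does not adjust it.

## Morphology

The neck diameter orients the lipid cloud along the principal gyration
axis, slices it into $1\,d$ axial slabs, takes twice the 95th
percentile of the head-bead radial distance as the per-slab outer
diameter (robust against single protruding beads), and minimises over
the region between the two bud maxima. A neck below $10\,d$ counts as
closed. Near-spherical shapes (relative asphericity below 0.15) are
flagged as neckless rather than assigned a spurious neck. Division is
detected by single-linkage clustering of lipid beads at a $1\,d$
cutoff, ignoring components below 1% of the lipids. The contact-area
estimator — outer-leaflet head beads with an opposing-segment head bead
within $3\,d$, converted to area by the mean area per head bead — is
this package's own construction; the published time courses do not
state their estimator, so the full-scale plateau value is treated as
indicative rather than as a validation gate.

## Scale, noise, and what the tests show

The published production systems (1.6 million beads, tens of
microseconds) are far beyond a desk run; the package supports but does
not test that scale. The test suite instead works at sizes chosen to
finish in minutes on one core:

* equation-of-state and thermostat checks on a $(10\,d)^3$ water box
  ($5\times 10^4$ steps);
* a 128-lipid planar bilayer for thickness and solvation checks;
* the 59k-bead mini vesicle, relaxed for 400 steps at
  $\Delta t = 0.005$ and run for 3000 production steps, with the last
  2000 steps analysed (the full-scale protocol discards the first half
  of much longer runs; the scaled-down window is a documented
  deviation);
* slab coexistence at $10 \times 10 \times 30\,d$ with $2\times 10^4$
  steps.

At these sizes the solute coverage is a robust observable, but the
first stress moment of a single short run carries sampling noise of
order $1\,k_BT/d$, and consecutive stress frames are autocorrelated,
so run-mean uncertainties are estimated by batch means over 400-step
blocks. Moreover, each concentration point is an independently
assembled vesicle whose residual tension differs slightly, and the
measured moment couples strongly to that tension; the good-solvent
curvature signal sits below this between-run noise floor. Trend
checks on the spontaneous curvature therefore compare the end points
of the concentration range within twice the sampling error, and
reserve strict inequalities for the well-resolved comparisons: the
poor-solvent rise and the poor-versus-good slope ordering. The
mini-vesicle series is run at fixed $\nu = 1$ (the same slightly
compressed state for every condition) rather than re-relaxing each
point to zero tension, which full-scale work does but which desk-scale
noise does not reward. A nominal bending rigidity
($\kappa = 10\,k_BT$, the order of magnitude this lipid's $K_A$ and
thickness imply) converts moments to curvatures in those trend checks;
monotonicity is unaffected by the constant.

Passing desk-scale tests establishes internal correctness (oracle
equivalence, conservation laws, closed-form analysis checks) and the
direction and ordering of the physical trends (adsorption grows with
$\Phi_S$; poor solvent adsorbs and curves more strongly than good). It
does not certify the full-scale published coefficients, which require
cluster-scale runs.

## Known limitations

* No electrostatics, charged lipids, mixed-lipid membranes, or explicit
  proteins; no Lees--Edwards shear or GPU path.
* The NPT mode is a density-setting device, not a rigorous ensemble.
* The neck and contact-area estimators are geometric constructions;
  absolute values at high curvature depend on the slab width and
  percentile choices (both configurable).
* Trajectory formats store positions (and velocities for the dump
  dialect) at finite precision; topology travels separately.
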