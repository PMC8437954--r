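---
title: "Models and methods behind dynhelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dynhelix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynhelix)
```

`dynhelix` analyses the mechanics of dynamin helical collars: how the
discrete cryoEM symmetry of a filament relates to its continuous shape,
what the stalk filament's elastic energy says about preferred helical
geometries (in particular the one-start versus two-start question), how
the underlying Helfrich membrane tube responds, and how rigid-body
domain motions between two conformations are measured on coordinates.
This vignette documents the models, the parameters and their defaults,
the numerical choices, and the limits of what the synthetic test data
can show.

## Helical geometry

A helical assembly is described discretely by a per-subunit axial rise
and azimuthal twist, a start number n (number of intertwined strands)
and a cyclic point-group order relating the strands. One strand,
regarded as a continuous space curve, is a circular helix with radius
$r$ (helical axis to the filament centerline, which for dynamin we place
at stalk interface 2) and pitch $p$; with the reduced pitch
$h = p/2\pi$ its curvature and twist density are

$$\kappa = \frac{r}{h^2+r^2}, \qquad \tau = \frac{h}{h^2+r^2},$$

with the exact inverse $r = \kappa/(\kappa^2+\tau^2)$,
$h = \tau/(\kappa^2+\tau^2)$. Both maps are implemented and tested as
mutual inverses to $10^{-10}$ relative error, together with the identity
$\kappa^2+\tau^2 = (h^2+r^2)^{-1}$. The degenerate planar ring
($p = 0$) is supported; the straight-line case ($\kappa = 0$) is
rejected in the inverse because its radius is infinite.

Units: lengths are nm internally. Rise values and atomic coordinates are
accepted in Å (the cryoEM and PDB conventions) and converted at the
boundary. The two-start dynamin helix (rise 13.58 Å, twist 24.43°) has
$360/24.43 \approx 14.7$ subunits per turn and a strand pitch of
$1.358 \times 360/24.43 \approx 20$ nm; with two strands the rung
spacing is half that, ~10 nm. Handedness is a flag (default
right-handed, positive twist advancing counterclockwise viewed down
+z): the handedness of the dynamin filament is not fixed by the symmetry
parameters alone, so we do not guess it.

## Stalk-filament elasticity

The filament is modelled as an elastic rod with energy per unit length

$$E = \alpha_\kappa(\kappa-\kappa_0)^2 + \alpha_\tau(\tau-\tau_0)^2,$$

quadratic about spontaneous values. Defaults (all configurable through
`FilamentElasticParams()`):

| parameter | default | units | meaning |
|---|---|---|---|
| $\alpha_\kappa$ | 3000 | nm·kJ/mol | bending modulus |
| $\alpha_\tau$ | 2700 | nm·kJ/mol | twist modulus |
| $\kappa_0$ | 0.058 | nm⁻¹ | spontaneous curvature |
| $\tau_0$ | 0.041 | nm⁻¹ | spontaneous twist density |
| dimer length | 5.6 | nm | converts E to energy per dimer |
| $g_0$ | 0 | kJ/mol/nm | inter-rung GG free energy |

The moduli and spontaneous values derive from molecular dynamics of the
stalk tetramer (prior work); the model assumes a long helix with uniform
$\kappa, \tau$, which is exactly the regime of helical reconstructions.
Energies are reported per dimer ($E \times 5.6$ nm) to match how such
landscapes are usually plotted; per-length values remain available.
When rungs bind through GG dimers an additional free energy per length
$g_0$ applies ($E_{total} = E + g_0$). Its magnitude is unknown; because
the GG interface is essentially identical in one- and two-start
helices, $g_0$ cancels from every comparison, so it defaults to 0 and is
carried only as a constant shift (a property test asserts it moves no
argmin).

The quadratic form gives the global minimum in closed form:
$r^* = \kappa_0/(\kappa_0^2+\tau_0^2) = 11.50$ nm,
$p^* = 2\pi\tau_0/(\kappa_0^2+\tau_0^2) = 51.1$ nm — the filament
intrinsically prefers large pitches (~50 nm). Tests verify the closed
form against a dense (0.05 nm) grid search. Landscapes default to
$r \in [5, 25]$ nm, $p \in [5, 80]$ nm on a 400×400 grid, chosen to
cover the physiological range of dynamin helices with margin around the
minimum. The 1-D minimal-energy curve uses `stats::optimize` (bounded
golden-section/parabolic search); a boundary minimum triggers a warning
rather than a silent clamp.

The multi-start comparison works at fixed radius and fixed rung spacing
$d$ (default 10 nm, the pitch of a one-start dynamin helix): a k-start
helix gives each strand pitch $kd$ without changing the rung spacing
that supports GG contacts. At $r = 13.5$ nm the per-dimer energies are
19.67 (one-start) versus 11.53 kJ/mol (two-start), and the advantage
grows monotonically as the radius shrinks — the elastic argument for the
two-start super-constricted state. By the same logic three- and
four-start helices would be lower still; whatever excludes them
(entropy, GG geometry at high pitch angles) is outside this model.

The mapping from filament radius to the inner lipid-lumen diameter is a
single radial offset, diameter $= 2(r - \delta)$ with $\delta = 11.5$ nm
by default, calibrated so the two-start structure radius (13.5 nm) maps
to its ~4 nm lumen. The true mapping (PH domain plus bilayer) is not
published and need not be a constant offset, so quantitative
lumen-threshold claims are deliberately not asserted in tests.

## Membrane tube

The membrane is an axisymmetric Helfrich surface with bending stiffness
$\chi$ (default 24 $k_BT$) and tension $\gamma$ (default 0.03
$k_BT$/nm²). We use the convention that the bending energy density is
$(\chi/2)(2H)^2$ with $2H = 1/r$ for a cylinder, giving per-length
energy $\pi\chi/r + 2\pi\gamma r$ and equilibrium radius
$\sqrt{\chi/2\gamma} = 20$ nm (diameter 40 nm) at the defaults; this
convention is adopted precisely because it reproduces that equilibrium
diameter from those constants. For a general periodic profile $r(z)$,

$$E = \int 2\pi r\sqrt{1+r'^2}\Big[\tfrac{\chi}{2}(2H)^2 + \gamma\Big]dz,
\qquad 2H = \frac{1}{r\sqrt{1+r'^2}} - \frac{r''}{(1+r'^2)^{3/2}},$$

discretised with central differences on a uniform periodic grid; tests
verify second-order convergence and consistency with the cylinder form.
Membrane energies are kept in $k_BT$ and bridged to kJ/mol (factor
2.494, i.e. 300 K — the temperature is not dictated by the model, so it
is configurable) only when combined with filament energies. No Gaussian
curvature term (constant topology), no spontaneous membrane curvature,
no fission.

## Constriction simulator

The simulator represents each strand as a bead chain, one bead per
dynamin dimer (spacing 5.6 nm), built on an ideal helix with the
angular step solved (to $10^{-14}$) so consecutive-bead chord distances
equal the spacing exactly. Discrete differential geometry: curvature at
a bead is the Menger curvature of its triple; twist density at a bond
is the signed dihedral between consecutive bond planes divided by the
mean of the three bond lengths. At 5.6 nm spacing these track the
continuous relations to within ~0.1% (curvature) and ~3% (twist) for
the helices of interest; the convergence is second order in spacing.

The total energy is the sum of (i) the elastic term,
$\sum \alpha_\kappa(\kappa_i-\kappa_0)^2 \Delta s_i +
\sum \alpha_\tau(\tau_j-\tau_0)^2 \Delta s_j$ with local arc weights;
(ii) stiff harmonic bonds ($k_{bond} = 1000$ kJ/mol/nm²) maintaining
the spacing — a soft-constraint choice that keeps the energy smooth and
differentiable; (iii) the membrane profile energy; and (iv) a soft
radial coupling $(k_c/2)(\rho_i - r(z_i))^2$ per bead
($k_c = 100$ kJ/mol/nm²), with bead axial positions wrapped into the
periodic tube domain. The bead-to-membrane radial offset defaults to 0
(beads ride on the tube surface); it is not published and is left
configurable. Beads do not set the tube radius; filament and tube relax
jointly.

Relaxation is deterministic energy descent: L-BFGS-B (via
`stats::optim`) with central-difference gradients (step $10^{-5}$ nm),
run in chunks of 100–200 iterations; a frame is recorded after each
chunk and accepted only if its energy did not increase, so the recorded
energy sequence is non-increasing by construction, and the endpoint's
maximum absolute numerical gradient is reported as a stationarity
check. A quasi-Newton line-search descent was chosen over plain
steepest descent because the stiff bond term makes the problem badly
conditioned — steepest descent needs orders of magnitude more
iterations for the same endpoints. There is no thermal noise; the seed
slot exists so that stochastic initialisations (e.g. perturbed
fixtures) are recorded in outputs.

The endpoint shape of a free filament is measured with the same
discrete operators that define the energy, then mapped through the
exact inverse $(\kappa,\tau) \to (r,p)$. Measuring a geometric radius
by axis-fitting instead would fold the $O(\Delta s^2)$ discretisation
bias of the bead representation into the comparison with the continuous
optimum; the discrete measurement asks the sharper question — did the
relaxation reach the energy model's own minimum?

Standard runs: a free 20-bead strand started at $(r, p) = (20, 20)$ nm
reaches the closed-form optimum to ~$10^{-6}$ relative; a bare tube
(32 grid points over 100 nm) started at $r = 30$ nm reaches 20 nm; a
coupled two-start system (2 × 12 beads, 16 grid points over one 20 nm
period) started at the 40 nm membrane equilibrium constricts the tube
below 20 nm within 800 iterations. These sizes were chosen as the
smallest systems that cleanly exhibit each behaviour; larger systems
relax to the same endpoints, only more slowly. Passive relaxation
demonstrates only the downhill part of constriction — the active,
GTP-driven regime (rung sliding, ~8 nm lumen in ~300 ms) requires the
full motor model from prior simulation work and is deliberately not
reimplemented; an optional constant inter-strand axial force hook
exists, disabled by default.

## Structure comparison

Superposition is least-squares rigid-body (Kabsch, SVD-based) with the
determinant constrained to +1, so a reflection is never returned even
on near-planar selections. Atoms are paired by chain (optionally
mapped), residue number, insertion code and atom name — no sequence
alignment fallback; mismatched numbering is an error rather than a
silent partial pairing. Cα-only by default. Rotation angles are
reported in [0°, 180°], with the axis sign fixed so the screw
translation is non-negative; near 180° the axis is taken from the
eigenvector of the rotation matrix.

The hinge-angle protocol mirrors how dynamin's hinge swings are
measured: superpose structure 2 on structure 1 using the align domain
(e.g. the BSE), then superpose the measure domain (e.g. the G domain)
of the aligned copy onto its counterpart and report that second
rotation. Aligning on the BSE and measuring the G domain probes
Hinge 2 (the ~46° swing between the two GG-dimer monomers); aligning on
the Stalk and measuring the BSE probes Hinge 1 (~12°). Property tests
assert exact recovery of constructed hinges across 1–179°, 1° accuracy
under 0.2 Å coordinate noise with 100 atoms per domain, and invariance
of the measured angle under arbitrary global rigid motions of either
structure.

Interface conservation: contacts are residue pairs across a chain pair
with any Cα–Cα distance within 10 Å (configurable); two structures are
compared by the Jaccard similarity of their contact sets and by the
RMSD over the union of contacting residues after superposition on the
first chain of the pair. An empty interface reports Jaccard as NA
rather than forcing a number.

The shipped dynamin 1 domain ranges (G domain 33–293; BSE 1–32, 294–320,
711–746; Stalk 321–499, 643–710; PH 500–642; author numbering, JSON
config in `inst/extdata/`) are approximations assembled from the domain
architecture, not published measurement masks; hinge angles measured on
deposited models with these defaults should be expected to agree only
to a few degrees, and the ranges are easy to override.

## Synthetic fixtures, and what passing tests do not show

All tests run on generated data: helical Cα traces at exact lattice
positions (plus optional isotropic Gaussian noise), two-domain hinge
pairs (random points in two 15 Å spheres 40 Å apart, one domain rotated
by a recorded angle about a recorded axis), and perturbed bead
filaments. Every fixture embeds its full generating spec including the
seed, and regenerates bit-identically from it. These fixtures validate
the *operators* — symmetry arithmetic, superposition, hinge recovery,
relaxation — under known ground truth. They do not emulate real
structural data: no side chains, no correlated noise, no partial
occupancy, no domain flexibility within a "rigid" domain, no density
map. Agreement on fixtures therefore demonstrates correctness of the
measurement machinery, not that the shipped domain definitions
reproduce any particular published angle; that check requires the
deposited coordinates and is kept separate.

## Known limitations

* The elastic model is quadratic and uniform; it cannot describe
  localised defects, pitch heterogeneity, or the entropic terms that
  may penalise higher start numbers.
* The lumen mapping is a calibrated constant offset.
* The simulator is passive (no GTPase cycle, no thermal fluctuations,
  no membrane fission) and its membrane is axisymmetric — it cannot
  break cylindrical symmetry even where a real tube might.
* The filament-membrane coupling is a phenomenological soft harmonic;
  its stiffness is a modelling choice, not a measured quantity.
* mmCIF/PDB handling covers ATOM records, altloc selection by
  occupancy and insertion codes; exotic records are out of scope.
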