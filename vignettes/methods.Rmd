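---
title: "Methods: torsional interconversion of a stacked beta-sheet dimer"
author: "BetaTwist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: torsional interconversion of a stacked beta-sheet dimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BetaTwist)
```

## The system and the question

Amyloid fibrils of the amyloid-β peptide grow by stacking monomers into
parallel in-register β-sheets with a ~4.8 Å repeat along the fibril axis.
`BetaTwist` models the smallest unit that captures a fibril end: a *double
layer* of two Aβ(20–34) peptides (`FAEDVGSNKGAIIGL`, positions 20–34 of
Aβ(1–42)), the upper stacked on the lower through a ladder of intermolecular
mainchain hydrogen bonds. The question it addresses is kinematic and
energetic: when a single backbone dihedral (ψ about Cα–C, or φ about N–Cα,
at residue *i* of the upper monomer) rotates so that the chain N-terminal of
the axis lifts off the lower layer — a *twisted conformation* — which bonds
break, how much less stable is the result, and how easily does it revert?

All geometry is exact and testable: hydrogen-bond censuses, broken-bond
counts (ΔN_HB), interlayer and contact distances. The energetics are a
deliberately coarse surrogate: orderings and barrier structure are
meaningful, absolute numbers are not.

## Synthetic structures

`buildStrand()` constructs an ideal peptide chain by internal-coordinate
(NeRF) chaining: standard bond lengths and angles, every residue at the same
(φ, ψ), ω fixed at 180°, L-chirality enforced through the +123° N–C–Cα–Cβ
improper, hydrogens placed explicitly, sidechains in one extended rotamer,
and neutral termini/acid groups (NH₂, COOH) since no protonation modelling
is in scope. The defaults are:

* **(φ, ψ) = (−119°, +113°)** — the flat (twist-free) parallel pleated-sheet
  geometry. This is a real constraint, not a taste: a generic β value such
  as ψ ≈ +130° twists the strand by ~25°/residue, and two pure translates of
  a twisted strand can neither stack at 4.8 Å without steric overlap nor
  form an in-register bond ladder. Only on (or near) the twist-free line do
  the amide N–H vectors alternate along a common stacking normal.
* **layer separation 4.8 Å** — the experimental inter-sheet repeat of
  in-register amyloid stacks.
* **jitterSigma = 0 Å** (optional seeded Gaussian jitter, applied to the
  monomer *before* duplication so the two copies stay exact translates; used
  to generate test ensembles).

`buildParallelDimer()` duplicates the strand along the stacking normal. The
raw build carries 14 intermolecular mainchain hydrogen bonds over residues
21–34 — alternating residues donate downward from the upper monomer and
upward from the lower, which is how a ~one-bond-per-residue ladder arises
from two exact translates.

What the builder does **not** emulate: the meandering (β-arch-like) bends of
the crystal-derived monomer, sidechain rotamer diversity, solvent, and the
slightly irregular bond pattern of the DFT-optimised flat state (12
mainchain bonds of 13 total, with one N27 sidechain–sidechain bond). Tests
passing on the synthetic sheet therefore validate the *operations* —
detection, ledgers, kinematics, path relaxation — not any claim that the
fixture reproduces the deposited coordinates. Published distances
(4.7783 Å → 2.9932 Å carbonyl O–O, the 3.1348 Å G25 Hα contact, the
13/12 census) are only measurable on the deposited ensemble, which the
package reads but does not ship.

`makeHbFixture(n)` provides controlled truth for ledger tests: a polyalanine
double layer whose full ladder is reduced to exactly *n* detected bonds by
rotating surplus amide hydrogens on their covalent sphere to point away from
their acceptors (covalent topology untouched, bonds removed in decreasing
donor–acceptor distance; fully deterministic).

## Hydrogen-bond model

A bond is a donor–H···acceptor triple with d(D···A) ≤ 3.6 Å and
∠(D–H···A) ≥ 120°, both bounds inclusive. Donors are N/O bearing at least
one hydrogen; acceptors any O, plus N with no bonded hydrogen; sulfur is
irrelevant for this fragment. Same-residue triples and acceptors within two
covalent bonds of the donor are excluded — this keeps trivial intra-amide
contacts out while leaving the chemically meaningful *intramolecular*
bonds detectable (e.g. a serine hydroxyl donating to the preceding mainchain
carbonyl, the bond that stabilises the φ-S26 twisted state). A bond is
classed *mainchain* only when both heavy partners are mainchain atoms;
glycine's second α-hydrogen counts as its sidechain (the glycine "sidechain"
is that hydrogen), and mainchain is {N, amide H, Cα, Hα, C, O} plus the
terminal groups.

`deltaHB()` keys bonds by donor/acceptor atom identity, so ΔN_HB — the
count of intermolecular mainchain bonds present in the reference and absent
in the comparison — is stable under coordinate changes and atom reordering.

`interlayerDistance()` is defined as the mean over residue positions of the
in-register Cα–Cα distances. The literature quantity has no stated
operational definition; this is the simplest registry-respecting choice, and
the acceptance check on the deposited flat state carries a ±0.15 Å band for
exactly that ambiguity.

Upper/lower labels are geometric, never trusted from chain identifiers: the
stacking axis is the normal of the least-squares plane through the lower
monomer's Cα atoms (deterministic sign), falling back to the inter-monomer
centroid direction when the Cα set is too small or collinear for a stable
plane; coincident projections are an error, not a silent choice.

## Torsion kinematics

For ψ at residue *i* the axis is Cα(i)→C(i) and the moving set is everything
N-terminal of the axis by bond connectivity: residues < *i* plus residue
*i*'s amide group, Cα, α-hydrogen(s) and sidechain. For φ (axis N(i)→Cα(i))
only the amide group of *i* joins the N-terminal residues. Rotation is a
rigid Rodrigues rotation of the moving set about the bond line; the measured
dihedral changes by exactly the applied δ (the moving set contains the
*first* atom of the four-atom dihedral, so the implementation rotates by −δ
about the N→C axis vector). Rigid-body fidelity (10⁻⁹ Å on all intra-set
distances), composition, inversion and exact-δ behaviour are enforced by
property tests against an independent dihedral oracle.

`generateTwisted()` performs a *driven* torsion scan: 10° stages over
(0°, 180°], lifting sign chosen automatically as the direction that moves
the lifted chain away from the lower layer, with a short step-capped (FIRE)
relaxation after every stage. The interleaved relaxation is essential: a
rigid sweep of a long N-terminal tail about a tilted bond axis jams almost
immediately for near-terminal axes (the tail grinds through its own layer),
whereas a driven scan lets obstructing atoms move aside — the same reason
torsion-driven conformational scans are standard practice. Stages whose
relaxed geometry retains covalent heavy-atom clashes (< 1.8 Å non-bonded)
are rejected. Among the survivors the selected candidate is the
lowest-energy stage that (a) has broken all the moving segment's reference
intermolecular mainchain bonds and (b) lies in a basin separated from the
flat state — the staged energy profile must already have descended from a
preceding maximum by at least the bond-well depth. Criterion (b) matters:
with a narrow bond well *every* angle trivially "breaks" bonds, and without
the basin test the subsequent minimisation simply slides the candidate back
into the flat minimum. The selected candidate is then relaxed further with
the same capped-step descent (a quasi-Newton line search can hop the shallow
col and revert the twist; the capped descent cannot).

## Surrogate energy

Three terms, all with analytic gradients:

* **Steric 12-6**, over non-bonded pairs (1-2, 1-3 and 1-4 excluded),
  Lorentz–Berthelot combining, cutoff-shifted to zero at 12 Å so that
  separated fragments are *exactly* additive. Distances are clamped at
  0.8 Å, which turns atom overlap into a large finite penalty instead of an
  overflow. Per-element σ (H 2.3, C 3.2, N 3.05, O 2.95 Å) is deliberately
  compact: the surrogate has no electrostatics, so sheet packing at the
  4.8 Å repeat must sit near the steric minimum rather than against a hard
  wall. ε is small (0.02–0.09) so that packing is a gentle background to the
  bond term. 1-4 pairs are excluded because with full 1-4 repulsion the
  ideal strand is internally strained and minimisation destroys the sheet;
  torsional stiffness is not the steric term's job here.
* **Hydrogen-bond well**: −D₀ · exp(−(d−d₀)²/2w²) · max(0, −cos θ)ᵖ per
  donor–H/acceptor triple (same exclusions as detection), with D₀ = 2.0,
  d₀ = 2.9 Å, w = 0.35 Å, p = 4. D₀ and w were chosen once so that the flat
  double layer is a true local minimum that *keeps* its bond ladder under
  minimisation (with a 1.0/0.30 well the relaxed sheet lost most of its
  ladder); the closed form makes "breaking one ideal bond costs D₀"
  directly testable.
* **Covalent restraints**: harmonics on 1-2 bond lengths (k = 100) and on
  1-3 distances (k = 30) to the reference topology. The 1-3 distance
  harmonic stands in for a bond-angle restraint — equivalent near
  equilibrium and with a simpler exact gradient. Dihedrals are deliberately
  unrestrained: the studied motion *is* a torsion.

Minimisation is L-BFGS-B on all coordinates with the analytic gradient;
convergence is declared at a maximum gradient component ≤ tol. For molecular
systems the practical tolerance is 0.05 unit/Å (the strict 10⁻³ default is
reachable on small/analytic systems; on the 424-atom dimer the minimiser is
run to a fixed iteration budget and the convergence flag reports honestly).

## Minimum-energy paths

`interpolatePath()` initialises a band either by sweeping the axis dihedral
linearly with rigid torsions (covalent geometry preserved exactly along the
path; the default) or by Cartesian interpolation (documented contrast: bond
lengths contract mid-path). Endpoints are kept exactly as supplied.

`nebRelax()` implements the nudged elastic band with the improved
(energy-weighted) tangent, spring force along the tangent (k = 1.0
unit/Å²), optional climbing highest image, and a FIRE optimiser with a
0.2 Å per-coordinate step cap. Endpoints never move. The same core runs on
arbitrary potentials (`nebRelaxGeneric`), which is how the analytic
double-well benchmark V(x, y) = (x²−1)² + 5y² — saddle energy exactly 1 —
validates the implementation to ±0.01 with 11 images.

`barrierReport()` defines: top = argmax of image energies;
twisted→flat barrier = E(top) − E(last); flat→twisted barrier =
E(top) − E(first); endothermic energy = their difference, computed as that
difference so the identity holds exactly in floating point as well. The
"local minimum" of a pathway is taken to be its final image (twisted states
are optimised minima).

Near-axis contacts follow the steric analysis of the return transition: the
residue adjacent to the axis (the pivot itself for ψ, its predecessor for φ)
contributes its characteristic atoms — carboxyl oxygens for an aspartate
(against lower-monomer carbonyl oxygens), α-hydrogens for glycine, sidechain
hydrogens otherwise (against lower-monomer hydrogens) — reported as minimal
distances at the barrier top and at the local minimum.

## Problem sizes and reproducibility

The default study conditions are the full 15-residue dimer (424 atoms).
The test suite exercises the heavy operations on 2–5-residue dimers and
validates properties (oracle equivalence on 100 random ≤100-atom fixtures,
exact fixture bond counts for n = 0…12, rigid-torsion fidelity, the
double-well saddle, the barrier identity, bond-count monotonicity of the
endothermic energy, and the bulky-sidechain barrier ordering on a
matched pair of full-size double layers differing only by a valine in
place of the glycine-25 pivot). `scripts/acceptance.R` runs the full-size system: flat
relaxation at 1500 L-BFGS iterations, all six studied axes for ΔN_HB, and
8-image NEB at 400 FIRE iterations for ψ-G25 and φ-S26 — a few minutes on
one CPU. Every stochastic step (jitter only) is governed by one seed;
builders, detection, minimisation and NEB are otherwise deterministic, and
`runPipeline()` with a fixed config and seed reproduces its reports
byte-identically.

## Known limitations

* The surrogate has no electrostatics, no solvent, no torsional potential;
  barrier *magnitudes* are not comparable to first-principles values
  (which for this system are electronic-structure results), only orderings
  and the barrier/endothermicity structure are.
* The ideal builder's bond ladder is denser than the meandering deposited
  flat state (14–15 vs 12 mainchain bonds), so segment-wise ΔN_HB values on
  synthetic sheets differ from the published ones by construction; the
  φ-exceeds-ψ-by-one relation per segment is a property of that specific
  deposited bond pattern and is only asserted there.
* Layer assignment assumes two layers along one stacking axis; helical or
  laterally associated assemblies are out of scope.
* NEB convergence on the full dimer is budget-limited; the convergence flag
  is reported and the relaxed band is still an upper bound on the true
  minimum-energy-path barrier.
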