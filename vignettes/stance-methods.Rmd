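---
title: "Methods: muscle-force-loaded FE analysis of the lower limb at stance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle-force-loaded FE analysis of the lower limb at stance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters, numerical choices and
limitations of `stancelimb`. The package is a desk-scale, fully synthetic
reimplementation of the standard two-stage workflow for physiological FE
loading of the lower limb: muscle forces from a rigid-body (RB)
recruitment analysis of the stance phase of gait, applied to a deformable
bone model whose validity is established by reaction-force consistency.

## Units and conventions

All lengths are mm, forces N, moduli MPa (1 MPa = 1 N/mm²), masses kg,
accelerations m/s², so an inertial force is directly `m·a` in N. The frame
is: y vertical (distal→proximal, up positive), z postero-anterior
(anterior positive), x medio-lateral (lateral positive, right limb).
Tetrahedral connectivity is 1-based in memory; the VTK (0-based) and Gmsh
MSH v2 (1-based) dialects are converted at the I/O boundary.

## The synthetic anatomy

Bones are hollow tubes or frustums — a cortical shell only, since
trabecular bone is not modelled. The default geometry flares at the knee
(outer radius 26 mm at the metaphyses against 12–16 mm elsewhere), which
matters mechanically: a uniform slender tube would be far too compliant in
bending and the elastic deflections would mask the rigid-rotation
behaviour that the validation logic relies on. Femur and tibia are bonded
to a 10 mm soft "knee layer" (articular-cartilage modulus) through
node-conforming interface annuli generated with a shared cross-section
discretisation; the tie is realised by merging coincident nodes (tolerance
10⁻⁶ mm). The fibula and patella are non-conforming tubes joined to their
neighbours by webs of stiff axial spring members (below).

The 29 hip/knee-bridging muscles are subdivided into 122 line elements
(the adductores magnus and brevis into three slots each, so recombination
yields 33 applied forces). Each slot has an attachment patch cut from the
boundary facets in a cylindrical window (default half-extent 10 mm axial,
50° angular) centred on its attachment point; element attachment points
scatter around the slot centre (±6 mm axial, ±2°, seeded). Muscle
strengths default to physiologically ordered values per muscle, split
equally over a muscle's elements; the min/max solution is
strength-normalised, so the validation metrics do not hinge on their exact
values.

The gait table holds the five analysed stance instants: beginning and end
of stance plus the three extrema of the knee-joint load. Defaults: GRF
magnitudes (253, 592, 483, 644, 15) N — the first peak is of the order of
body weight for the 62 kg subject; knee flexion 14° at position 4 and 38°
at position 5 (positions 1–3 are free choices of typical gait values: 5°,
20°, 10°); COP travelling heel→toe; segment inertial forces of a few tens
of newtons, so the quasi-static premise (inertia/GRF ≤ 0.10 over the
loaded positions) holds by construction and the analysis may drop inertial
terms. Gravity is likewise excluded: the limb hangs from the grounded
femoral head and the GRF enters at the distal end, so body weight is
implicit in the GRF, not applied as a volume load. Knee flexion is carried
as gait metadata only — the synthetic limb stays geometrically straight at
every position, which keeps the RB and FE stages sharing one geometry.

### The donor mismatch

In the study design this package follows, the RB model and the FE geometry
come from *different donors*, aligned by a rigid 3-point registration on
the femur (femoral-head centre, middle of the transepicondylar axis,
medial epicondyle), after which the two tibiae still disagree (malleoli
not aligned; frontal-plane tibia-axis angle under 3°). The generator
emulates this residual mismatch explicitly: the RB stage's attachment
coordinates are rotated by a small residual angle about the femoral head
(default 0.5° about the mediolateral axis) and the leg-segment attachments
are offset antero-posteriorly (default 12 mm). Muscle forces recruited in
the RB frame and applied on the unperturbed FE patches then leave a net
*moment* about the femoral head (the net *force* stays exactly consistent),
which is what drives the reference regime: distal displacements of
millimetres to tens of millimetres that are almost pure rigid rotations
about the head, and stabilisation-spring forces of a few to a few tens of
newtons. Setting the mismatch to zero gives the identical-geometry
configuration used for the consistency checks. These defaults were chosen
once, from the mechanics of the regime to be emulated, and are
configuration values, not fitted quantities.

## Rigid-body recruitment

The linkage is thigh + (leg+foot), with a spherical hip, a revolute knee
(axis x — its own-axis moment row carries no reaction, so muscles alone
balance it) and a rigid ankle. Twelve equilibrium rows (force and moment
balance of each segment) face the muscle-force magnitudes and eight
reaction unknowns (hip force, knee force, two knee constraint-moment
components). Elements inserting on the patella or at the calcaneus are
assigned to the leg+foot segment — the patella with its tendon is treated
as part of the extensor mechanism; in the FE stage the same forces reach
the tibia through the tendon springs and the calcaneal remote point, so
global equilibrium is consistent between the stages.

The min/max criterion minimises the peak activation `beta = max f_i/N_i`
subject to equilibrium and `f ≥ 0`. Numerically, the free reactions are
first projected out (the muscle forces are constrained only through the
null space of the reaction matrix — this also diagnoses genuinely
infeasible toys, e.g. a single knee-spanning muscle that cannot balance a
GRF moment about the hip), rows are max-scaled, sign-flipped to the
non-negative right-hand-side convention of the simplex implementation, and
zero rows pruned. Among beta-optimal solutions a second LP minimises the
total force at fixed `beta` (relaxed by 10⁻⁹ against vertex degeneracy),
making the reported solution solver-independent; the tie-broken vertex is
accepted only if its equilibrium residual stays within 10⁻⁸·max(1, |d|).

## From recruitment to FE loads

Element forces are summed vectorially per slot (when a muscle's
subdivisions have different lines of action, the resultant is the vector
sum — its direction is no longer exactly along any single element).
Muscles with both attachments on modelled parts are applied as two equal
and opposite loads (third law); pelvis-origin muscles contribute their
insertion load only, their reaction reaching the model through the hip.
Each load is a *uniform traction* over its attachment patch — not a
centroid point load — integrated against the linear shape functions
(each facet node receives a third of the facet's share), which conserves
the total force exactly.

## The FE model and its boundary machinery

The element is the 4-node constant-strain tetrahedron (the 10-node option
is out of scope; constant-strain elements keep the model small and are
exact for the patch test). Materials: cortical bone E = 17 000 MPa,
menisci 120 MPa, articular cartilage 15 MPa, tendon 900 MPa; ν = 0.3 for
bone, 0.45 for soft tissue.

**Remote points.** The COP and the calcaneus are remote points coupled to
the distal tibia end; the femoral head is a remote point on the proximal
femur cap. The default coupling is *distributing*: a load at the remote
point is transferred as the statically equivalent nodal load set
`f_i = w_i (λ + μ×r_i)` (area weights `w_i`, the six parameters fixed by
exact force and moment transfer), and the remote point's displacement is
read back as the weighted least-squares rigid motion of the patch
evaluated at the remote location. Both operators share the same 6×6
normal matrix, so load transfer and motion recovery are energy-consistent,
and a spring attached at an offset remote feels the patch's rotation —
essential for torsional stability. A *rigid* coupling (patch slaved to six
remote degrees of freedom) is available by flag; distributing is the
default to avoid artificially stiffening the coupled surface.

**Springs.** Three 10⁹ N/mm springs along x, y, z ground the femoral-head
remote point: a spherical joint (translations pinned to within ~10⁻⁵ mm
under kN loads, rotations free). Three weak 1 N/mm springs along x, y, z
are attached at *each* of the two distal remote points. One point would
not suffice: with every internal connection a central-force member, a
structure grounded translationally at only two points retains an exact
mechanism — rotation about the line joining them — for *any* geometry.
Anchoring the weak springs at both the COP and the calcaneus (two
separated points, neither on the head–other-anchor line) closes that
mechanism and makes the stabilised system positive definite. The original
validation logic carries over unchanged: the criterion checks the
*resultant* of all stabilisation springs.

The patellar tendon is three parallel springs between the patellar base
and the tibial tuberosity with `k = E·A/L` in total. With E = 900 MPa and
A = 160 mm², the printed total of 2880 N/mm (960 N/mm per spring) implies
L = 50 mm, which also matches the synthetic patella-to-tuberosity
distance; the implementation therefore defaults to L = 50 mm and treats L
as configuration. (A nominal tendon length of 5 mm circulates with this
dataset but is inconsistent with its own printed stiffness.)

**Bonded interfaces.** Conforming interfaces (femur/knee-layer/tibia) are
merged node-to-node; declared ties with orphan nodes beyond tolerance are
an error. The non-conforming fibula and patella are attached by webs of
*axial* spring members (each picked node connected to several nearest
neighbours on the facing patch, stiffness 10⁵ N/mm split per member). The
members are central-force pairs: collinear equal-and-opposite forces carry
no net moment, so the webs cannot corrupt the global moment balance —
an isotropic point-to-point spring, by contrast, transmits shear as
non-collinear force pairs and silently injects internal moments. Shear
and torsion are carried physically by the obliquity of the web members.

**Solver.** Direct sparse Cholesky factorisation (no iterative solver is
needed at this scale), with a few iterative-refinement steps; the solution
must reach a normwise backward error `‖Ku−f‖/(‖K‖‖u‖+‖f‖) ≤ 10⁻¹⁰`.
Strains are reported as the full per-element tensor plus the maximum
absolute principal value and maximum component per part, so "maximum
strain" comparisons are explicit about the measure. Where rigid rotations
reach several degrees, linearised strains contain the usual second-order
rotation artifact (of order θ²/2); this is inherent to any linear analysis
with large rigid motion and affects reported strain magnitudes, not the
force balance.

## Validation criteria

1. **Deformation**: the distal-tibia displacement must be dominated by
   rigid rotation about the femoral head. The split is computed by a
   weighted least-squares fit of a rotation about the head centre over the
   femur+tibia chain; the criterion accepts an elastic remainder of at
   most 5% of the total displacement *or* at most 5 mm absolute (~0.6% of
   limb length — "nearly zero" at limb scale, covering positions whose
   total displacement is itself small). The 5%-of-total property is
   asserted at the largest-displacement position, which is how the
   original claim is framed.
2. **Springs**: the stabilisation-spring resultant must stay below 5% of
   the reference force, taken as the larger of the GRF magnitude and the
   RB hip-reaction magnitude. The GRF alone would be the wrong reference
   at the end of stance, where it is nearly zero while the joint loads are
   not.
3. **Reaction match**: the relative difference
   `100·|‖FE‖−‖RB‖|/‖RB‖` between the femoral-head reaction and the RB
   hip reaction must stay below 16%.

All thresholds are configuration with these defaults. On identical RB/FE
geometry the only force-path inconsistency is the weak springs, so the
relative difference is a small fraction of a percent and decreases
monotonically as the stabilisation stiffness is swept 1 → 0.01 N/mm; the
acceptance suite checks exactly this.

## Problem sizes and determinism

The default limb uses a 10 mm element size (≈11 000 tetrahedra, ≈13 000
degrees of freedom across the five parts), chosen so the full
five-position study — recruitment LPs with 122 elements and one sparse
factorisation per position — runs in well under a minute, and the
cantilever verification (three refinement levels against `PL³/3EI`, within
15% at the default density and monotonically converging) in a few seconds.
Everything stochastic (attachment scatter) is seeded; regeneration with
the same seed is bit-identical, and mesh writes round-trip exactly
(`%.17g`).

## What the synthetic study does and does not show

The generator emulates the *mechanical structure* of the real study —
load magnitudes, muscle bookkeeping, boundary scheme, the donor mismatch
and the resulting rigid-rotation regime — not anatomical shape: tube bones
have no femoral neck (hip and knee centres are coaxial), no condyles, no
menisci as separate parts, and muscle paths are straight lines without
wrapping. Passing tests therefore establish the correctness of the
machinery (equilibrium identities, recruitment optimality, load mapping,
solver exactness) and the internal consistency of the validation logic;
they do not certify subject-specific strain magnitudes, which depend on
real geometry. Nonlinear contact, ligaments, biphasic cartilage and
trabecular bone are out of scope by design, as in the modelling choice the
package follows (all interfaces bonded, linear elasticity throughout).
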