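---
title: "Modeling the invertasome: assembly geometry and recombination topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the invertasome: assembly geometry and recombination topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invertasome)
```

# The system

Hin-family serine invertases flip a chromosomal DNA segment between two 26-bp
recombination sites (*hix*).  The reaction is licensed by a 65-bp
*recombinational enhancer* carrying two binding sites for the DNA-bending
protein Fis, whose centers lie 47 bp apart.  On negatively supercoiled DNA
the two Hin-bound *hix* sites and the Fis-bound enhancer co-assemble at the
base of a plectonemic branch into a tripartite complex (the *invertasome*).
The two *hix* segments cross the enhancer there with two negative nodes.
After cleavage of all four strands, one pair of synapsed subunits rotates
180° relative to the other, carrying its covalently attached DNA ends;
ligation in the rotated register inverts the intervening segment.  A single
exchange releases four supercoils and leaves the circle unknotted; when the
rotation is not arrested after one step, further half-turns produce a ladder
of knots with node counts increasing by one per step.

This package implements that picture as three connected layers: (i) DNA
model construction from base-pair step parameters, (ii) constraint-guided
rigid-body assembly of coarse-grained protein units on the enhancer, and
(iii) an explicit DNA-topology simulation of the subunit-rotation mechanism.

# DNA models from step parameters

A duplex is represented by one orthonormal frame per base pair.  Successive
frames are related by the six rigid-body step parameters (shift, slide,
rise; tilt, roll, twist) through the standard mid-step-triad composition:
the bend `Gamma = sqrt(tilt^2 + roll^2)` is applied about the roll–tilt
hinge with half the twist on either side, and the translations act in the
mid-step frame.  `build_duplex()` composes steps from a canonical first
frame; `analyze_duplex()` inverts the construction exactly (round trips are
accurate to ~1e-12).  One numerical subtlety is worth recording: when the
recovered twist is wrapped into (−180°, 180°], the bend phase must be
shifted by 180° at the same time, because the two parameterisations are
conjugate descriptions of the same rotation.

Each base pair also carries one pseudo-phosphate *backbone proxy* per
strand, at cylindrical offsets of 8.9 Å and ±77° from the base-pair x axis.
All footprinting and contact logic runs against these proxies; no sugar or
base atoms are modeled.

The enhancer table is assembled by `compose_enhancer_params()`: a 21-bp
bent block at each Fis site (centers at positions 10 and 57 of the 65-mer)
and mean B-DNA parameters (twist 34.2°, rise 3.4 Å) elsewhere.  Because a
21-bp block centered 9 bp from the duplex end cannot fit completely, the
block is clipped at the ends; the layout invariant is enforced on the 15-bp
core sites instead.  The per-site bend of the packaged synthetic block is a
configuration value (default 65°); its amplitude is calibrated numerically
(by root finding on the measured entry/exit tangent deflection) rather than
analytically, because roll/tilt components distributed over a twisting
helix do not sum linearly.  The resulting 65-mer is a strongly non-planar
S: the two bend planes are rotated relative to each other by the twist of
the intervening turn and a half.

# Assembly of the three invertasome states

Protein units are coarse-grained to one point per landmark residue
(Fis 16/19/20/21/22/71/98; Hin 28/47/48/51/54/101/107 in the catalytic
domain and 146–160 in the DNA-binding domain).  Fis dimers are docked onto
their sites by least-squares superposition (`superpose()`, a proper-rotation
Kabsch fit) of a *reference pose* — a mapping from landmarks to offsets in
site base-pair frames — so a real structural template with the same
landmark vocabulary could be substituted for the toy coordinates without
code changes.

The Hin tetramer frame is derived from the two docked Fis arms: the
two-fold axis passes through the arm midpoint perpendicular to the
arm-to-arm direction, and the tetramer center sits on it at a
state-dependent height (12/16/22 model units for cleaved, pre-cleaved and
dimer-docked).  The two enhancer-proximal subunits are anchored each to its
own Fis arm (DBD residues 151/154/155 within the 6 Å contact cutoff of arm
residue 21) and to its own stretch of enhancer backbone between the two
core sites (helix-B residues 47/48/51 at 4 Å in the cleaved state, 9 Å
pre-cleaved, 16 Å dimer-docked; the offsets are radial from the helix axis
so the design distance equals the minimum distance to the whole backbone).
The rotating-pair subunits are generated by the tetramer two-folds, which
places their DBDs on the distal *hix* half-sites and their helix-B surfaces
away from the enhancer.  The single subunit template is the average of the
two proximal target sets expressed in their arm-local frames, so each
placement has sub-Ångström residual and all states satisfy the same
contract: arm contact only at *hix1L*/*hix2R*, helix-B–enhancer contact
only in the cleaved state, no steric overlap, and the two-negative-node
branch topology on the attached substrate path.

Crosslink consistency uses landmark-to-landmark distances against the
spacer panel (SIA 1.5, AMAS 4.4, GMBS 7.3, BMOE 8, EMCS 9.4, SMPH 14.2,
KMUS 16.3 Å) with a 3 Å tolerance for side-chain flexibility; negative
observations use the same tolerance.  Tethered-nuclease (FeBABE) footprints
report every backbone proxy within `tether_length + radical_radius`
(12 + 10 Å by default) of the tether landmark; the radical radius is a
declared free parameter, and scission intensity is modeled as inverse
distance rank only.  On the cleaved fixture the Hin-54 tethers print
between the two 15-bp Fis cores and the Fis-98 tethers print within their
own core sites, mirroring the expected geometry.

`refine_by_constraints()` replaces manual docking with a reproducible
seeded hill climb over per-component rigid perturbations; the score (total
positive constraint violation) never increases, and identical seeds give
identical trajectories.

# Recombination topology

The substrate is a closed, labeled 3D polyline: enhancer at the branch
base, the two *hix* duplexes paired side-by-side at the synapse with their
cleavage points facing, a short enhancer-proximal loop, an inner loop, and
the vector domain drawn as an explicitly interwound (left-handed, negative)
plectoneme of four turns.  The branch weave follows a plectonemic crossing
pattern: the *hix1* arm passes over the enhancer and the enhancer passes
over the *hix2* arm, both crossings negative.  This alternation is what
topologically traps the synapse — with both crossings on the same side the
complex would be isotopic to an untangled one and no product could knot.
The routing of the connecting loops was chosen, among arrangements
consistent with the schematic architecture, as the one whose computed
topology reproduces the reaction's recorded outcomes (unknotted substrate,
two negative nodes, supercoil loss of four, knot ladder); the base-pair
spacings themselves (99-bp native spacer, 65-bp enhancer, 26-bp sites) are
carried as segment metadata.

Writhe and linking numbers are computed with the exact per-segment-pair
solid-angle form of the Gauss integral; node counts and knot diagrams come
from generic planar projections, with the knot determinant |Δ(−1)|
evaluated from the Alexander relations of the diagram (three projections
must agree).  Reduced crossing counts apply Reidemeister I/II moves to the
Gauss code and minimise over projections.

Subunit rotation is simulated by direct construction of the relaxed
product: both *hix* sites are cut at their centers and the two
synapse-proximal strands are replaced by an interwound collar of *n*
half-turns about the synapse axis, resealed in the recombinant orientation
for odd *n* and the parental one for even *n*.  The construction is direct
rather than a continuous sweep because a smooth rotation of the rotor by an
even number of half-turns is isotopic to the identity — without cutting,
the accumulated winding simply relaxes away, so a one-shot deformation
cannot model processive exchange.  (We verified this numerically; it is the
reason even-round products of the naive sweep were always unknotted.)

The linking-number change is computed as the change in the *self-linking
number* of the modeled axis: writhe plus the closure twist of a
parallel-transported framing, an exact integer.  Under the rigid-axis
approximation (duplex twist unchanged by the reaction) this equals the
topological ΔLk recorded between closed-circular topoisomers.  Writhe alone
is not integer-valued on these curves, which is why the self-linking form
is used.  On the default substrate the model yields, per number of
half-turns *n*: ΔLk = +4 (inversion, unknot), −1 (parental, trefoil), +3
(inversion, 5-determinant knot), −1 (parental, 7-determinant knot) — the
first exchange releases four supercoils and leaves the DNA unknotted, and
each further half-turn adds one node to the product.  The sequence is
dominated by reconnection parity (odd rounds invert the enhancer-containing
domain, flipping the sign of every crossing between the two domains), so
ΔLk after *n* rotations is *not* n-fold the single-rotation value; the
packaged tests assert the computed behavior.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `fis_bend` | 65 | degrees | per-site bend of the synthetic Fis block (configuration, not a literature value) |
| `contact_cutoff` | 6 | Å | landmark contact distance absorbing side-chain reach of the point model |
| crosslink `tolerance` | 3 | Å | side-chain flexibility allowance |
| `tether_length` | 12 | Å | cysteine-to-Fe distance of the tethered nuclease |
| `radical_radius` | 10 | Å | effective hydroxyl-radical action radius (free parameter) |
| `loop99_bp` | 99 | bp | enhancer-to-*hix* spacer (696 for the long-spacer substrate) |
| `plectoneme_turns` | 4 | — | explicit superhelical turns drawn in the vector domain |
| `rotation_sense` | −1 | — | rotation direction driven by negative supercoiling |

The substrate model is a *shape* model: segment lengths in base pairs are
metadata validated for consistency (they must sum to the plasmid size), not
geometric lengths of the polyline, and changing the spacer length does not
change the trapped topology.  Simulations use a few hundred to ~1500 curve
vertices (refined near the synapse, more finely for higher rotation
counts), at which the Gauss integrals are converged to well below the
integer-rounding tolerance (residuals < 0.2 are enforced, typical values
are < 0.05).

# What the synthetic system does and does not show

The generators emulate the *architecture* of the system: the S-shaped
two-site enhancer, the landmark vocabulary of the crosslinking and
footprinting experiments, and the branch topology of the supercoiled
substrate.  They do not reproduce crystallographic coordinates, all-atom
sterics, sequence-dependent DNA mechanics, crosslinking chemistry or
reaction kinetics; passing tests therefore demonstrate the internal
consistency of the geometric and topological model, not agreement with any
particular measured structure.  Real structure templates can be introduced
through the PDB reader and the landmark sidecar without touching the
assembly code.

# Numerical choices and degenerate inputs

Projections for diagram analysis are slightly oblique views; the crossing
detector rejects near-parallel segment pairs and near-endpoint
intersections, and the determinant is required to agree across three
directions.  `linking_number()` and `delta_linking()` verify that the raw
integrals sit within 0.1–0.2 of an integer and fail loudly otherwise.
Superposition uses the SVD form of the least-squares fit with an explicit
reflection guard; collinear point sets are rejected.  Degenerate step
parameters (non-positive rise, bends ≥ 90°, twists ≥ 180°) are rejected at
validation.  The tapered-helix collar keeps the two product strands
antipodal at every height, so products are embedded by construction; the
reseal is checked against an 8-unit gap bound.

# Known limitations

The model has no elastic energy: loop lengths do not resist winding, so
the arrest of rotation after one exchange in the native short-spacer
system is *represented* (by simulating a chosen number of half-turns), not
*predicted*.  Knot identification is by determinant and reduced crossing
count, which separates the unknot/trefoil/figure-eight-class products but
does not name knots beyond that.  The assembly is a landmark model; it
supports distance logic, not energetics or electrostatics — the basic-patch
analysis counts residue contacts rather than computing surface potentials.
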