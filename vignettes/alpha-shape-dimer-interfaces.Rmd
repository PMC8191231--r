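---
title: "Weighted alpha-shape descriptors of protein dimer interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted alpha-shape descriptors of protein dimer interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphadimer)
```

## The model

`alphadimer` characterizes the interface of a protein–protein dimer by
geometry alone. Every heavy atom is a weighted point $p = (p', p'')$: a
center $p'$ in 3-D and a weight $p''$ equal to the square of the atom's van
der Waals radius. Two weighted points are *orthogonal* when the squared
distance between their centers equals the sum of their weights — the
condition under which the two atom spheres intersect at right angles — and
*sub-orthogonal* when they are farther apart. The regular (weighted
Delaunay) triangulation generalizes the empty-circumsphere condition of the
Delaunay triangulation to an empty-*orthosphere* condition: each
tetrahedron's orthosphere (the sphere orthogonal to all four vertex
spheres) has non-negative power distance to every other point.

The *alpha complex* at value $\alpha$ keeps the tetrahedra whose
orthosphere has signed squared radius $\le \alpha$. At the default
$\alpha = 0$, with weights equal to squared van der Waals radii, a
tetrahedron survives exactly when its four atom spheres have a common
orthogonal point with imaginary radius — i.e. when the four atoms mutually
overlap or touch. The union of surviving tetrahedra is the package's
molecular shape model; *surface atoms* are the vertices incident to a
boundary facet (a facet of exactly one complex tetrahedron) or to no
complex tetrahedron at all.

### Interfacial atoms

For a dimer with chains $A$ and $B$, three surfaces are computed at the
same $\alpha$ and weights: $M$ for the dimer, and $A$, $B$ for each chain
alone in its dimer-frame coordinates (no re-minimization). The interfacial
set is

$$X = (A \cup B) - M, \qquad X_A = X \cap A, \qquad X_B = X \cap B$$

— the monomer-surface atoms buried upon dimerization. The cross-chain
*interacting pairs* are the edges of the dimer complex joining an atom of
$X_A$ to an atom of $X_B$ (any tetrahedron containing such an edge
necessarily connects the two chains). An interfacial atom may legitimately
have no partner: it can be buried by the encounter without sharing a
complex edge across the chain boundary.

### Solid-angle curvature and the matching rate

For each complex tetrahedron incident to an atom, the solid angle
subtended at the atom equals the sum of the three dihedral angles along
the edges through it, minus $\pi$ (the spherical excess). The total
subtended angle $S$ — 0 for a fully exposed atom, $2\pi$ on a flat
surface, $4\pi$ when fully enclosed — is rescaled to

$$\Omega = \cos(S / 4) \in [-1, 1],$$

so positive $\Omega$ is convex and negative concave. The implementation
uses the dihedral route; the test suite cross-checks it atom-by-atom
against the independent Van Oosterom–Strackee closed form for the solid
angle of a triangle.

$\Omega$ is evaluated on each monomer's *own* complex (not the dimer's):
complementarity compares the shapes the two surfaces present to each
other, and in the dimer complex every interfacial atom is buried by
construction, which would erase exactly the signal of interest.

A pair $(a, b)$ is *matched* when $\Omega_a \Omega_b < 0$ — a convex atom
facing a concave one; a product of zero is unmatched (strict inequality).
The per-frame *matching rate* is the matched fraction over all pairs, and
the *mean interfacial COM distance* is the mean Euclidean distance between
the paired atoms' centers of mass (a single atom's center of mass is its
position; masses come from a packaged standard-atomic-weight table).
Frames with no pairs report both quantities as undefined (`NA`), never as
zero — zero-filling would bias trajectory means toward tighter-looking
interfaces.

Applied per frame of a multi-model PDB trajectory, with centered
moving-average smoothing and per-series means, these two series summarize
how tightly and how complementarily two chains interact along a
simulation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0 Å² | alpha-complex filtration value; 0 keeps tetrahedra of mutually overlapping atoms |
| radius table | Bondi (1964) | element → van der Waals radius (Å); weights are its squares; replaceable via CSV |
| `hydrogen_policy` | `"drop"` | the shape model is built from heavy atoms |
| `window` | 51 frames | centered moving-average width, truncated at the series edges |
| `flat_tol` | 0.02 | $|\Omega|$ below this is snapped to 0 (flat) |
| `jitter` | 1e-3 Å | deterministic tie-break perturbation in the triangulation |

## Numerical choices

**Predicates.** Conflict tests are evaluated as translated $4 \times 4$
in-orthosphere determinants rather than as $|p - c|^2 - r^2$ against a
stored orthosphere. Near-coplanar inputs produce sliver tetrahedra whose
orthoradii reach $10^{12}$ Å²; the determinant's error scales with the
local coordinate differences instead of the orthoball size, which keeps
tie decisions consistent at the jitter scale.

**Degeneracy handling.** Exact cospherical and coplanar configurations
(every ideal lattice) are broken by a deterministic jitter — splitmix64
keyed by seed and atom index — of magnitude $10^{-3}$ Å, applied once to a
copy of the coordinates; the jittered coordinates are kept in the result
so that any independent check sees the exact point set that was
triangulated. The magnitude matches PDB coordinate precision and is far
below any inter-atomic scale; smaller magnitudes ($10^{-6}$–$10^{-4}$ Å)
push the margins of the most degenerate predicates (collinear lattice
rows) to the level of double-precision determinant noise, where tie
decisions become inconsistent. Jitter can be disabled for generic inputs,
which the precision-critical closed-form tests do.

**Insertion and cavities.** The incremental construction locates the cell
containing the new point (best barycentric margin), declares the point
hidden if that cell is not in conflict, and carves the facet-connected
conflict region around it. With exact arithmetic that region is the whole
conflict set; numerically, a distant sliver with a huge orthoball can
register a grazing conflict that is disconnected from the local region,
and such tetrahedra are deliberately left in place. They carry
$r^2 \gg 0$, so they can never enter the $\alpha = 0$ complex; the
concession affects optimality of the far triangulation, never validity of
the shape model.

**Flatness.** On an atomically flat surface the incident tetrahedra tile
the half-space exactly, so $S = 2\pi$ and $\Omega = 0$ up to coordinate
noise, with a sign that is pure noise. Values with $|\Omega| <$
`flat_tol` are therefore snapped to exactly 0, and the strict inequality
in the match indicator classifies flat-against-anything as unmatched.
The default 0.02 corresponds to a total angle within ~0.08 rad of $2\pi$,
well above the noise induced by the fixtures' 0.01 Å coordinate jitter
and well below the magnitudes of genuinely curved atoms (lattice edges
$\Omega \approx 0.7$, knob and socket atoms $|\Omega| > 0.8$).

## What the synthetic generator emulates

The generator produces four fixture families whose ground truth is known
by construction, written as real PDB files (carbon pseudo-atoms, one per
`LIG` residue) so they exercise the same I/O path as real structures:

- **Lattice blocks** — the surface set is exactly the boundary lattice
  sites: $m^3 - (m-2)^3$ atoms for an $m^3$ block.
- **Slab dimers** — two face-to-face slabs. In the contact regime (every
  gap-spanning lattice box passing the $\alpha = 0$ test, i.e.
  $\mathrm{gap} \le \sqrt{4r^2 - 2s^2}$ for radius $r$ and spacing $s$)
  the interfacial set is exactly the *interior* of the two facing layers.
  The facing layers' perimeter atoms sit on the dimer's lateral hull,
  remain on the dimer surface, and are never interfacial — burial by
  $X = (A \cup B) - M$ requires full enclosure, not mere contact.
- **Knob-hole dimers** — chain A carries octahedral knobs (a center atom
  and its six lattice neighbours) that register exactly into matching
  vacancies carved from the chain-B block. The buried knob atoms are
  strongly convex on A's own surface and the socket-wall atoms they pair
  with strongly concave on B's, so the designed matching rate is 1. A
  single protruding atom over a flat face cannot realize a rate of 1
  under the burial definition: its cross-chain pairs would include
  flat-face and convex rim atoms, which the indicator counts as
  unmatched. The flattened control replaces the knobs by a flat slab at
  contact distance; flat faces give $\Omega = 0$ on both sides and a rate
  of essentially 0.
- **Separation trajectories** — the slab dimer rigidly translated apart
  along a strictly increasing gap schedule, reusing the same jittered
  monomer coordinates in every frame, so the mean interfacial COM
  distance increases with the programmed gap for as long as pairs exist
  and becomes undefined when they vanish.

Fixtures default to spacing 1.5 Å, radius 1.7 Å (the Bondi carbon
radius), coordinate jitter 0.01 Å and a fixed seed; identical
specifications reproduce byte-identical files.

What passing these fixtures does *not* show: real proteins are not
lattices. The fixtures probe the combinatorial and metric machinery —
surface extraction, burial, pair enumeration, curvature signs, series
plumbing — under known truth; they make no claim that the matching rate
of a real kinase dimer is biologically meaningful at any particular
value, nor do they validate force fields, simulation protocols or
binding-energy estimates, which are outside this package's scope.

## Problem sizes

The shipped tests and the acceptance script run the brute-force oracle on
100 random weighted sets of up to 30 points, lattice fixtures up to
$5^3$ atoms, slab dimers of 100 atoms, knob-hole dimers of ~1,100 atoms
and separation trajectories of 5–6 frames. The kernel itself handles
structures of a few thousand heavy atoms in seconds per frame; full
kinase-domain dimers (~9,000 heavy atoms) are minutes per frame on one
core, dominated by the three triangulations.

## Known limitations

- The triangulation kernel is floating-point with deterministic jitter,
  not exact arithmetic. Validity is extensively property-tested, but
  adversarial inputs (coordinates engineered at the $10^{-3}$ Å tie
  scale) could still produce inconsistent predicates.
- Near-threshold tetrahedra ($r^2 \approx \alpha$) flip complex
  membership under coordinate noise; descriptors of structures whose
  interfaces hinge on such tetrahedra are correspondingly sensitive. The
  fixtures are designed away from the threshold.
- Binary trajectory formats (DCD/XTC) and mmCIF are not read; multi-model
  PDB is the trajectory carrier.
- Solid angles are summed over alpha-complex tetrahedra only. Summing
  over the full triangulation would make every convex-hull-interior atom
  appear buried and was rejected by design.
- The pair definition requires both endpoints interfacial and a shared
  complex edge; an alternative reading that restricts pairs to tetrahedra
  on the complex boundary would only shrink the pair set and is not
  implemented.
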