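---
title: "Consensus elastic networks for stacked protein rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus elastic networks for stacked protein rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringenm)
```

## The scientific problem

Vipp1/IM30, PspA and the ESCRT-III proteins assemble into closed
circular polymers ("rungs") that stack axially into rings. In the
cyanobacterial Vipp1 rings solved by cryo-EM (C11 through C17
symmetries, deposited as PDB 6ZVR-6ZW7), the rungs do not stack as a
straight cylinder: each rung is progressively more tilted than the one
below it, producing a dome — constricted at top and bottom, widest at
the equator. The orientation of the C-terminal helix α5 indexes this
tilt: it lies roughly 40° from the horizontal in the bottom rung and
rotates up to roughly 80° in the uppermost complete rung. The
mechanistic question is whether this dome shape follows from the
*local* inter-rung interfaces alone, together with the geometric
constraints of being a closed ring.

`ringenm` answers that question computationally. It reduces a ring
model to one bead per residue at the Cα position, builds a consensus
elastic network for an idealized "average rung", measures the
inter-rung contact map from one adjacent rung pair, stacks 2-10 copies
of the average rung into a perfect cylinder, relaxes the stack to its
elastic equilibrium, and quantifies the curvature that emerges.

## The model

Every residue is a bead at its Cα position. Beads closer than a cutoff
(default 10 Å) are joined by harmonic springs of uniform stiffness
$k$:

$$E = \sum_{(i,j)} \tfrac{k}{2}\,\bigl(\lVert r_i - r_j\rVert - d^0_{ij}\bigr)^2 .$$

Because every spring shares one stiffness, the equilibrium geometry is
independent of $k$ (this is asserted as a test); $k$ defaults to 1
energy/Å² and all energies are reported in units of $k\cdot$Å².
Springs never break and never form during relaxation: strain that a
real polymer might relieve by unbinding is retained, which is exactly
the constraint whose consequences the model probes.

### Consensus ("average rung") network

Subunits within one rung are crystallographically identical, but
subunits in different rungs differ slightly in conformation. The
intra-rung network therefore uses a consensus rule over *monomer
environments*: one environment per subunit of every complete rung in
the comparison range, comprising the subunit's internal contacts plus
its contacts to same-rung neighbours up to five azimuthal positions
away (the polymer contacts its first and third neighbours; five gives
margin). A contact, expressed in canonical coordinates (residue A,
residue B, slot offset), is kept when it occurs in strictly more than
half of the environments. Contacts lost at this step concentrate at
the flexible hinge regions of the monomer, which is the intent of the
rule: the consensus network encodes the shared architecture, not any
one rung's curvature state.

The natural length of each consensus spring is the unconditional
average of that pair's distance over all environments (the distance is
defined in every environment, including those where it exceeds the
cutoff). An alternative averaging over supporting environments only is
available via `length_mode = "supporting"` for sensitivity analysis.

The average rung itself is produced by relaxing the coordinates of one
complete, well-resolved rung (rung 3 by convention) under the
consensus network to a local minimum.

### Inter-rung network

The contacts between one adjacent rung pair — by default rungs 3 and 4,
the complete equatorial pair (the bottom rung of the C11 ring is
incompletely built) — define the inter-rung map. Natural lengths are
averaged over the n symmetry-related copies of each canonical pair. The
same slot-offset registry is applied identically between every adjacent
rung pair of a stack, which implements the modeling assumption that
every rung interacts with its neighbours through one and the same
interface.

### Relaxation

Stacks are initialized as perfect cylinders of average-rung copies and
relaxed in three phases: (1) a short overdamped Langevin phase whose
Gaussian noise (amplitude `temperature_factor`, default 10⁻³ k·Å²)
provides basin exploration and breaks accidental saddle symmetries;
(2) a monotone limited-memory quasi-Newton (L-BFGS) descent with Armijo
backtracking; (3) backtracking steepest descent to the reported
convergence criterion, a gradient max-norm below `force_tolerance`
(default 10⁻⁴ k·Å). Phase 2 exists because the interesting deformation
modes of a multi-rung ring are collective and two orders of magnitude
softer than the bond-scale springs: pure first-order relaxation crosses
this stiffness gap so slowly that runs of several CPU-minutes per stack
were still sign-unstable in their apparent inter-rung rotations, while
the quasi-Newton phase reaches the same fixed points (equilibria are
protocol-independent, which the test suite asserts through stiffness-
invariance, rigid-motion equivariance, and equivalence with a tiny-step
pure gradient-descent oracle) in seconds. All phases accept only
finite energies; phase 2 and 3 accept only decreases, and the energies
reported in a trajectory are monotone by construction.

Randomness enters only through the Langevin noise, drawn from R's RNG
under a caller-supplied seed; a fixed seed reproduces trajectories
bitwise.

### Geometry readouts

The helix-α5 direction of a subunit is the unit vector between the
centers of mass of two anchor residue intervals (194-202 and 211-219
in Vipp1 author numbering). Because the vector's sign is arbitrary,
angles to the ring axis are folded into [0°, 90°] (acute convention);
the horizontal-referenced angle is the complement, and both are
reported. The per-interface rotation Δφᵢ is the mean horizontal angle
of the upper rung minus that of the rung below (positive when the
upper rung is more vertical, matching the experimental bottom-to-top
40° → 80° progression), and Δφ is their sum, which telescopes exactly
to the top-rung minus bottom-rung difference.

Diameters are reported in two conventions: per-rung (twice the mean
radial distance of a designated α1 N-terminal residue, highlighting
hairpin constriction) and per axial slab (internal diameter twice the
5th-percentile radial bead distance, external twice the
95th percentile, one slab per inter-rung boundary with the central one
the equator; slab half-width 10 Å). The percentile operator is this
package's choice — no published measurement operator exists for
"internal lumen diameter" — so accession-based diameter checks carry a
±1 nm tolerance.

## The synthetic test system

Everything above is testable without downloads through a generator of
Cn-symmetric stacked rings with exact ground truth. Design choices,
made once:

* **Subunit**: an "L" of two helical bead beams — a vertical post
  (axial stacking, like helix α0) and a tangential track whose last
  twelve residues are the "α5-like" arm. Both beams are 4-residue-per-
  turn helices with exact 3.8 Å bead steps; off-axis beads give the
  beams first-order bending stiffness under a distance-cutoff network
  (a straight bead chain resists bending only at second order and
  simply folds instead of transmitting rotation — measured, not
  conjectured), and the centers of consecutive 4-residue turns lie
  exactly on the beam axis, so the arm direction is exactly known.
  The subunit is deliberately schematic: tests need exact ground
  truth, not a Vipp1 replica.
* **Placement**: the body is wrapped along the ring arc (straight
  chords leave both symmetry neighbours and adjacent rungs outside any
  reasonable cutoff — a ring of straight rods at these symmetries is
  simply not in contact), while the arm continues straight. The
  scheduled tilt is applied as an exact rigid rotation of the whole
  subunit about the radial axis through the arm junction: rungs at
  different tilts are therefore congruent, the interface between two
  rungs genuinely encodes their relative orientation, and the arm's
  horizontal angle equals the schedule entry exactly.
* **Defaults as study conditions**: C11 symmetry, 5 rungs, radius
  80 Å, tilt schedule 80° → 40° top-to-bottom (the experimental
  helix-α5 span), 64 residues per subunit, zero noise. The rise is
  12 Å rather than the experimental 30.5 Å hairpin repeat: the
  40-to-64-bead schematic subunit is far thinner than the 258-residue
  monomer, and the rise is scaled so adjacent rungs stay within the
  10 Å cutoff across the whole tilt range, as the real rungs do.
* **Noise** is Gaussian, added after placement under a single seed, so
  ground truth always refers to the noise-free geometry and recovery
  tolerances scale with the noise level.

The tilt-encoding experiment mirrors the ring-stacking study: the
intra-rung map and average rung come from a ring generated at the
uniform mean tilt of the schedule's central interface, the inter-rung
map from a two-rung ring generated at that interface's two tilts, and
cylindrical stacks of 2-10 average rungs are relaxed under both maps.
Minimization then has to *develop* inter-rung rotation from a strained
cylinder, exactly as in the source experiment.

What the synthetic system does **not** emulate: real secondary
structure and side-chain packing, the j+3 staggered interface of the
experimental polymer (the schematic subunit contacts only its first
neighbours), conformational heterogeneity between subunits of one
rung, and map-derived coordinate error beyond isotropic Gaussian
noise. Passing synthetic tests therefore validates the machinery —
decomposition, consensus rule, relaxation, geometry — not any claim
about real Vipp1 energetics.

## Numerical choices and degenerate inputs

* Contact cutoffs are closed (`distance <= cutoff`); the consensus
  boundary is strict (`support > consensus`), so support exactly at
  the threshold is excluded.
* Alternate locations resolve to the highest-occupancy copy, ties to
  the alphabetically first altloc; insertion codes are rejected
  outright rather than silently renumbered.
* Frame detection in `inertia` mode picks the covariance eigenvector
  whose eigenvalue is most separated from the other two. Under Cn
  symmetry the two in-plane eigenvalues are degenerate, which makes
  this criterion robust for both tall and squat rings, where "largest
  variance" or "smallest variance" rules each fail on one of the two.
* Rung clustering splits the sorted chain-centroid axial coordinates
  at the m-1 largest gaps (m = ceiling(chains / n_sym)) and errors
  unless the smallest split gap exceeds twice the largest within-rung
  gap. "Top" (rung 1) is the more constricted terminal rung when the
  two ends' mean radii differ by more than 2%, otherwise the higher
  end along the axis.
* Beads coincident across a spring (zero distance, positive natural
  length) receive a deterministic fallback direction so the gradient
  stays finite; this is reported and never occurs on sane inputs.
* Output files embed the full flattened configuration and seed in
  their headers (strictly more reconstructible than a hash, and free
  of extra dependencies).

## Problem sizes

The test suite exercises relaxation on reduced rings (C5-C8, 24-32
residues per subunit) and the full default system for geometry-only
operations; the acceptance script relaxes the default C11 system at
stack sizes 2, 4, 6 and 8 under the default protocol and tolerance
(10⁻⁴ k·Å), sizes chosen so a complete run stays in the CPU-minutes
range on one core. Full convergence matters here: at a tenfold looser
tolerance the soft collective modes are not yet settled and the
cumulative rotation of the larger stacks is still several degrees from
its equilibrium value. The larger stacks also have nearby metastable
curvature states, so their relaxed cumulative rotation varies by a few
degrees with the Langevin noise seed; the growth of the rotation with
stack size, its saturation, and the zero-drive control do not.

## Known limitations

* The consensus rule needs identical residue coverage across the
  compared monomers; partially built rungs must be excluded from the
  comparison range (the terminal rungs of the deposited models are
  handled this way, matching the source protocol).
* The removed-contact set at the hinges depends on the deposited
  coordinates; the package reports it but asserts no target value.
* Only adjacent-rung coupling is modeled. Rungs that interpenetrate
  deeply enough to touch second neighbours (high tilt, small rise)
  have those contacts ignored by construction.
* The elastic network is harmonic and unbreakable: it cannot model
  the weakening of terminal interfaces that the experimental maps
  suggest, only the strain that would drive it.
* Because the schematic subunit engages its neighbours asymmetrically
  (the tilt-carrying arm binds only the rung below), relaxed synthetic
  stacks concentrate their per-interface rotations toward one end of
  the stack but place the single largest rotation one interface inside
  it, rather than strictly on the first or last interface as the
  experimental rings do. The cumulative rotation, its growth and
  plateau with stack size, and the zero-drive control are unaffected.
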