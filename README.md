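# ringenm

Consensus elastic-network models of Cn-symmetric stacked protein
rings, built for the membrane-remodeling polymers of the ESCRT-III
superfamily (Vipp1/IM30, PspA, CHMP proteins), whose rings are stacks
of 5-7 circular rungs that tilt progressively into a dome.

`ringenm` is aimed at structural biologists who have a stacked-ring
coordinate model (or want a synthetic one with exact ground truth) and
want to ask: *do the local inter-rung contacts, plus ring geometry,
suffice to produce the observed dome-shaped curvature?*

## The model

Each residue is one bead at its Cα position. Beads within a cutoff
(default 10 Å) are joined by harmonic springs of uniform stiffness k:

    E = Σ_springs (k/2) (|r_i − r_j| − d0_ij)²

- **Consensus intra-rung network**: the contact maps of all monomers in
  the complete rungs are compared in canonical (residue A, residue B,
  slot-offset) coordinates; a spring is kept when its contact exists in
  strictly more than 50% of the monomer environments, with natural
  length d0 the average of its distances over the monomers. Relaxing
  one rung under this network yields the **average rung**.
- **Inter-rung network**: the contacts between one adjacent rung pair
  (by default the complete equatorial pair, rungs 3-4), applied
  identically between every adjacent pair of a stack.
- **Simulation**: stacks of 2-10 average rungs start as perfect
  cylinders and are relaxed (noisy overdamped phase, then monotone
  quasi-Newton and steepest descent) to their elastic equilibrium.
- **Readout**: per-rung helix-α5 tilt angles (axis- and
  horizontal-referenced), per-interface rotations Δφᵢ and their
  cumulative sum Δφ, diameter profiles, and Kabsch superposition
  RMSDs.

A synthetic-ring generator (`synthetic_ring_spec()`, `make_ring()`,
`make_tilt_encoding_system()`) produces Cn-symmetric stacked rings
with configurable radius, rise, per-rung tilt schedule and noise, and
exact geometric ground truth, so the entire pipeline is testable
without downloading any structure.

## Worked example

Build the tilt-encoding experiment on the default synthetic C11
system (tilt schedule 80° → 40° top-to-bottom; the inter-rung map
encodes the 10° rotation of the schedule's central interface), relax a
4-rung cylindrical stack, and measure the emergent curvature:

```r
library(ringenm)

spec <- synthetic_ring_spec()            # C11, 5 rungs, 80 A radius
enc  <- make_tilt_encoding_system(spec)  # average rung + both maps
st   <- assemble_stack(enc$average_rung, enc$intra_map, enc$inter_map,
                       n_rungs = 4, rise = spec$rise)
stack_energy(st)                         # strained cylinder
#> [1] 20220.97

fit <- minimize(st, minimizer_params(temperature_factor = 0, md_steps = 0))
fit$trajectory$converged
#> [1] TRUE

dp <- delta_phi(fit$system, params = geometry_params_for(spec))
round(dp$delta_phi_i, 2)                 # per-interface rotations, top first
#> [1] 10.24  9.64  9.79
round(dp$delta_phi, 2)                   # cumulative helix rotation
#> [1] 29.67
```

The initially cylindrical stack (all rungs at 65°, Δφ = 0) relaxes
into a dome: every interface develops a rotation close to the encoded
10°, the largest at a terminal interface, and the cumulative Δφ grows
with stack size — the same qualitative behavior the experimental rings
show, produced purely by local interfaces plus ring geometry.

The same pipeline runs from the shell:

```sh
inst/scripts/ring-enm synth --n-sym 11 --n-rungs 5 --seed 1 --out-dir demo
inst/scripts/ring-enm decompose --input demo/synthetic_ring.pdb --n-sym 11 \
    --monomer-mass 28.7 --out-dir demo
inst/scripts/ring-enm simulate --input demo/synthetic_ring.pdb --n-sym 11 \
    --rung-range 1,5 --inter-pair 3,4 --sizes 2,4,6,8 --seed 1 --out-dir demo
```

Deposited ring models (e.g. PDB 6ZVR, C11) run through the identical
functions — `read_model()`, `extract_calpha()`, `assign_rungs()`,
`build_intra_map()` on rungs 2-5, `build_inter_map()` on rungs 3-4 —
once the coordinate files are available locally under
`inst/extdata/deposited/`.

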