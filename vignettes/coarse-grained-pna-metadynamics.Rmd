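---
title: "Coarse-grained dynamics and metadynamics of PNA:RNA hybridization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained dynamics and metadynamics of PNA:RNA hybridization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnadyn)
```

## Scope and model

`pnadyn` studies three linked questions about peptide nucleic acid (PNA)
strands at coarse-grained resolution: how a single strand balances base
stacking against chain entropy, how a backbone modification at the
gamma position shifts that balance toward a hybridization-competent
("pre-organized") conformation, and how an antiparallel PNA:RNA duplex
melts and re-anneals.  The package supplies the full toolchain — domain
bookkeeping, a Langevin simulator, collective variables, a well-tempered
metadynamics engine with reweighting, and melting/re-annealing analyses —
so that every result it reports is recomputed from its own simulations.

Each monomer is four beads: one backbone bead and a three-bead triplet
spanning the aromatic base plane.  The base center is the triplet
centroid, and the plane normal comes from the triplet cross product, so
both the stacking score and its force are smooth functions of bead
positions.  Units are nm, ps and kJ/mol throughout; kcal/mol appears
only via `convert_units()`.  All site masses are 1 (reduced units).

Bonded terms (bonds, backbone bending, the optional gamma bias) take
their reference values from the ideal starting geometry, which makes
that geometry the minimum of the bonded part of the potential by
construction.  Non-bonded terms reuse the collective variables'
switching functions as their single source of geometric truth:

* stacking well, all intra-strand base pairs:
  `-eps_stack * f(d) * cos^2(theta)` with the stacking switch
  (`r0 = 0.4` nm, n = 6, m = 12);
* pairing well, Watson-Crick partner bases only:
  `-eps_hb * hbonds * f(d)` on the centroid distance with a
  longer-tailed switch (`r0 = 0.35` nm, n = 4, m = 8), `hbonds` = 3 for
  G:C and 2 for A:U/T — so the GAACTC hexamer duplex carries 15 H-bond
  units, 7 in the N-terminal half and 8 in the C-terminal half;
* soft harmonic excluded volume between backbone beads and between
  base-plane sites of different bases within a strand.  Paired bases
  across strands are exempt so the pairing contact can form.

There is no solvent and no electrostatics; solvent effects are implicit
in the effective well depths, and the RNA backbone charge enters only
through the counterion bookkeeping (`counterion_count()`).

## Geometry choices

Single strands start from a twisted ideal helix (rise 0.32 nm, twist 30
degrees) — the single-strand stand-in for a duplex-derived structure.
Duplex systems use an untwisted "ladder": straight parallel backbones
with paired base planes facing across the duplex axis at 0.14 nm.  The
ladder was chosen so that all distorted starting geometries for the
re-annealing study are exact rigid motions of the RNA strand (fan
openings about a terminal pair, a central X-cross, a uniform 0.55 nm
separation), which keeps every bonded term at its rest value in the
distorted state.  The twist matters only where backbone dihedrals are
biased (single strands); the ladder's collinear backbone would make
those dihedrals ill-defined.

## The gamma bias

The gamma-serine modification is represented by a single knob,
`kappa_gamma` (kJ/mol), applied only to `gamma_pna` strands;
`kappa_gamma = 0` reproduces the unmodified model exactly.  It acts as a
set of restraints toward the helical reference geometry: backbone
dihedrals and the base-register dihedral between consecutive monomers
(`1 - cos(phi - phi0)` terms), a backbone bending stiffness increment,
and base-arm orientation restraints.  A bias on backbone dihedrals alone
proved insufficient in this model: dihedrals can stay at their helical
values while the chain bends and the bases swivel, so the strand still
collapses into a compactly stacked globule.  Locking the base register
is what actually preserves the extended, sequentially stacked helix.
The default `kappa_gamma = 100` was fixed, once, as the weakest value at
which unbiased 300 K runs of the gamma strand show a clearly higher
sequential-stacking score and more population in the extended
helix-like region than the unmodified strand across ten paired seeds.

## Collective variables

* `ht_distance()` — distance between the centers of mass of the first
  and last monomers (folded vs extended).
* `pair_stacking()` — `f(d) cos^2(theta)` per base pair; the squared
  cosine keeps the score face-agnostic and differentiable, which the
  bias forces require.  `stk()` sums all unordered pairs (sequential
  pairs included), `sstk()` the sequential ones, `nstk()` the remainder,
  so `stk = sstk + nstk` holds identically.
* `coordination()` — a smooth contact count with the common rational
  switch (default `r0 = 0.3` nm, n = 6, m = 12), used as a
  differentiable hydrogen-bond count.
* `dihedral()` — signed IUPAC dihedral, degrees at the interface,
  radians internally.

The melting/re-annealing analyses evaluate per-pair coordination with a
wider switch (`r0 = 0.45` nm) than the generic coordination default.
The pairing wells are flat near contact, so a bound pair breathes with
centroid distances up to ~0.4 nm; a switch matched to that contact
width records a bound pair as bound instead of flickering, while a
dissociated pair still falls to zero quickly.

## Metadynamics and reweighting

The bias engine deposits Gaussian hills (default height 2.5 kJ/mol,
one hill per ps, bias factor gamma = 30) whose heights decay as
`W0 exp(-V/kB (gamma-1) T)`; the first hill therefore has height `W0`
exactly and no hill can exceed it.  During a run the bias and its
gradient live on a grid (spacing sigma/4, hill cutoff 6 sigma, error
bound `exp(-18) W0` per hill), so the per-step cost is independent of
the number of hills.  Hills are logged and written in a COLVAR/HILLS
text dialect readable next to common metadynamics tooling.

The FES estimator from hills is the final-bias form
`F(s) = -(gamma/(gamma-1)) V(s, t_end)`, min-normalized to zero.
Reweighting uses time-dependent-offset frame weights
`w_t \propto exp((V(s_t, t) - c(t)) / kBT)` with

```
c(t) = kBT * log[ sum exp(-F_t/kBT) / sum exp(-(F_t + V_t)/kBT) ]
```

evaluated on a grid over the biased CVs from the running hill sum
(recomputed every 20 hills; between checkpoints `c(t)` is held
constant).  Correctness is established against quadrature oracles on
analytic benchmark potentials rather than against any particular
reference implementation: on a tilted 1-D double well the hills-based
basin free-energy difference lands within 0.5 kBT of the quadrature
value, and on a 2-D two-well channel the reweighted surface agrees with
quadrature within 1 kBT over both wells.  The single-strand studies
bias (HT, Stk) with widths (0.05 nm, 0.1) — scaled to this model's CV
fluctuations — and reweight onto (HT, SStk).

## Study conditions and their calibration

The effective well depths are not observable from first principles at
this resolution; they were calibrated once, against the package's own
acceptance conditions, and then frozen: `eps_stack = 7`, `eps_hb = 5`
kJ/mol give a duplex that is stable at 300 K over multi-ns runs (so
re-annealed duplexes can be classified "full") yet dissociates
completely within ~2 ns between 340 and 400 K, with end fraying
significantly stronger than central fraying and the 8-H-bond C-terminal
half outliving the 7-H-bond N-terminal half.  The integration step
`dt = 0.002` ps was chosen for energy stability of the stiffest modes
(the frictionless integrator drifts by less than 1e-4 relative energy
over 1e4 steps at dt/2 from a relaxed start); friction 5 1/ps gives
efficient sampling while remaining clearly underdamped on bond
timescales.

Desk-scale problem sizes used by the tests and the acceptance script:
melting, 3 temperatures (370, 385, 400 K) x 7 seeds x 1,000,000 steps
(2 ns); re-annealing, 5 scenarios x 10 seeds x 400,000 steps (0.8 ns);
metadynamics benchmarks, 4-6 million steps on the analytic potentials
and 1 million steps per strand run; the pre-break averaging window is
100 ps, which preserves the ratio of window to dissociation timescale
of the original 0.5-ns-window protocol at these run lengths.

## What the synthetic systems do and do not capture

The simulator reproduces the statistical structure the analyses assume:
competition between stacking enthalpy and chain entropy, Watson-Crick
pairing weighted by H-bond multiplicity, temperature-dependent fraying
that starts at the duplex ends, and a gamma knob that shifts the
single-strand ensemble toward extended sequentially stacked states.  It
does not claim quantitative correspondence to atomistic energetics:
there is no solvent, no electrostatics, no sequence-dependent stacking
strength, and temperatures map to kelvin only through the calibrated
well depths.  Two consequences are worth naming.  First, in vacuum two
free 6-mers diffuse and re-encounter each other quickly, so the
disordered stretched-strand re-annealing scenario (scenario 5) fails in
the consensus of seeds rather than in every seed — a minority of runs
finds a productive collision within the budget.  Second, without
sequence-dependent stacking the fraying asymmetry between the duplex
halves rests entirely on the 7-vs-8 H-bond difference.  Passing tests
therefore demonstrate that the machinery recovers the right qualitative
physics under the model's assumptions, not that real PNA:RNA kinetics
are reproduced.

## Numerical choices and degenerate inputs

The rational switch `(1 - x^n)/(1 - x^m)` is evaluated through a linear
expansion inside `|x - 1| < 1e-6`, making it and its derivative
continuous at `r = r0` (value `n/m`).  Degenerate base planes (collinear
triplets) raise an error rather than returning a garbage normal; in
practice the stiff triangle bonds keep `|v1 x v2|` far from zero.
Persistence bookkeeping uses trailing windows of 5 stored frames with
thresholds 0.5 (formation) and 0.2 (disruption) of each pair's
fully-formed reference coordination; single-frame dips are never counted
as disruption, and "complete disruption" requires every pair to stay
below threshold for a full window.  Ties for the nucleation pair are
broken toward the pair with the strongest mean coordination up to the
tie time.  Melting averages weight each disrupted run equally;
undisrupted runs are reported separately rather than silently dropped.

## Known limitations

* The 6-mer scale makes global strand reorientation fast; kinetic
  orderings (which scenario anneals first) are robust, absolute times
  are not transferable.
* The bias grid clamps outside its range: hills deposited at the edge
  of the declared CV range are truncated, so the range must cover the
  explored region (the defaults do, with margin).
* `anneal_run()` classifies "full" as a sustained persistent pairing
  fraction of at least 0.9, which for a hexamer means all six pairs;
  transient full pairing during breathing counts once sustained for a
  persistence window.
* PDB ingestion maps residues by named atom groups and does not attempt
  chemical perception; unmapped residues are an error by design.
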