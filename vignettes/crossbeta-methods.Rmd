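---
title: "Models and methods behind crossbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crossbeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbeta)
```

crossbeta studies how short functional-amyloid fragments template the
fibrillization of the Alzheimer's peptide A&beta;42: which subsequences of a
bacterial amyloid protein bind the monomer (hotspot scanning), which of them
self-assemble (aggregation), and how a preformed cross-&beta; seed fibril
captures a diffusing monomer (cross-seeding). Around the simulations sit the
two quantitative assays of the field: sigmoidal thioflavin-T (ThT) kinetics
and AFM-style fibril morphometry. This vignette explains the models, the
tunable parameters, and the design decisions, in that order.

## The coarse-grained model

Each residue is two beads: a backbone bead (56 amu; 57 for glycine, which
has no sidechain bead) and a sidechain bead carrying the residue's remaining
mass. Bonds are the standard discrete-molecular-dynamics (DMD) construct, an
infinite square well with hard walls: backbone–backbone in [0.36, 0.40] nm,
backbone–sidechain in [0.24, 0.28] nm. All beads carry a 0.17 nm hard-core
radius, so non-bonded beads contact at 0.34 nm.

Non-bonded attraction has two channels:

* **Hydrophobic sidechain wells.** A single square well from hard-core
  contact out to 0.65 nm whose depth maps the Kyte–Doolittle hydropathy of
  the pair onto energy:
  `depth = epsilon_hp * max(0, (h_i + h_j)/2 + 4.5) / 9`,
  so the scale's range [-4.5, 4.5] maps onto [0, epsilon_hp]. Ile–Ile pairs
  feel the full `epsilon_hp`; pairs whose mean hydropathy is -4.5 or below
  feel nothing. Depths are monotone in the pair's summed hydropathy by
  construction.
* **Directional backbone hydrogen bonds.** A square well [0.44, 0.56] nm of
  depth `epsilon_hb` between backbone beads of residues at least three
  apart in sequence (or on different chains). A bond forms only at the
  moment the pair crosses 0.56 nm inward *and* the two local chain tangents
  (the unit vector from backbone bead i-1 to i+1) are within 30&deg; of
  parallel or antiparallel *and* each partner currently holds fewer than
  two bonds — the donor/acceptor capacity of a peptide unit. A formed bond
  behaves as a reversible bond: the pair is confined between an inner hard
  wall at 0.44 nm and the escape radius at 0.56 nm, where separation
  requires paying `epsilon_hb` out of the radial kinetic energy. Because
  the energy bookkeeping is tied to the bond state rather than to the
  instantaneous geometry, the dynamics conserve total energy exactly.

There are no electrostatics: charge enters only through the (low)
hydropathy of charged residues. The consequences are discussed under
*Limitations*.

Units are nm, kcal/mol and amu, which fixes a reduced time unit of about
0.49 ps. A single constant, `time_scale` (default 3 reduced units per
"ns"), maps the nanosecond durations in which protocols are expressed onto
reduced time. The mapping is nominal — a coarse-grained chain explores its
configuration space far faster than an all-atom one — so configured
"nanoseconds" should be read as protocol bookkeeping, not as physical time.

### Default parameters

| parameter | default | units | role |
|---|---|---|---|
| `epsilon_hp` | 1.2 | kcal/mol | sidechain well-depth unit (~2 kT at 300 K for Val/Ile pairs) |
| `epsilon_hb` | 1.4 × `epsilon_hp` | kcal/mol | hydrogen-bond depth; favours β-sheet at 300 K |
| hb window | [0.44, 0.56] | nm | backbone pairing distance |
| alignment | 30 | degrees | tangent alignment for bond formation |
| capacity | 2 | bonds/bead | donor + acceptor per peptide unit |
| `contact_cutoff` | 0.65 | nm | analysis contact distance |
| `ghost_rate` | 0.004 | 1/bead/reduced-time | Andersen thermostat collision rate |
| `temperature` | 300 | K | thermostat target |
| `time_scale` | 3 | reduced units per ns | protocol time mapping |

`epsilon_hp` was calibrated once, by the criterion the force field exists
for: at 300 K a hydrophobic Val/Ile 10-mer must aggregate into
hydrogen-bonded clusters while a fully polar/charged control stays
essentially monomeric over the aggregation protocol. The thermostat rate is
deliberately weak: Andersen ghost collisions destroy momentum correlations,
so the rate sets the diffusivity of whole chains
(D &asymp; kT/(M&nu;)), and 0.004 per bead per reduced time gives a 4.5 kDa
monomer realistic mobility relative to the protocol durations. The rate is
a free parameter of the ensemble, not of the physics: static averages are
unaffected.

## The event-driven engine

Between potential discontinuities beads fly ballistically, so the engine
advances from event to event exactly: hard-core bounces, well
entries/exits (transmission with radial speed change when the step energy
can be paid, reflection otherwise — all conserving momentum and energy),
bond-wall reflections, hydrogen-bond captures/escapes, thermostat ghosts
and sampling ticks. Velocities update along the pair unit vector with the
reduced mass; a static partner (the frozen fibril) is treated as infinite
mass, and a collision with it leaves the static bead's pending events
untouched since its state cannot change.

Numerical choices that matter:

* Event times come from the quadratic of relative ballistic motion under
  the minimum-image convention; roots within 10⁻⁹ nm of the current
  boundary are disambiguated by the sign of the radial velocity, so a pair
  sitting exactly on a boundary after processing cannot re-fire the same
  event.
* Simultaneous events process in increasing (time, type, bead-pair id)
  order — deterministic across runs.
* Neighbour search uses per-bead Verlet lists (interaction range + 0.3 nm
  skin). Each bead schedules its own list rebuild before it can have moved
  half the skin, and rebuild times are recomputed at every velocity change,
  so no collision can be missed; every sampling tick additionally rebuilds
  all lists and the event queue from scratch. For the package's system
  sizes (&le; ~800 beads, &le; ~250 mobile) this is as fast as cell lists
  and considerably simpler.
* Positions propagate lazily (per-bead last-update times), which keeps NVE
  energy drift at rounding level: the test suite requires < 10⁻⁸ relative
  drift over 10⁵ events and observes ~10⁻¹³.
* An event cascade exceeding a safety bound within one sample interval
  aborts with an "inelastic collapse" diagnostic.
* All engine randomness (thermostat schedule, bead picks, velocity draws)
  comes from a self-contained splitmix64 + Box–Muller generator seeded from
  the run seed, so campaigns are reproducible bit-for-bit and independent
  of R's RNG state.

## The nanofibril model and its saturated interior

The seed fibril is an ideal double-layer cross-&beta; model: two parallel
in-register sheets of extended strands, adjacent strands offset 4.7 Å along
the fibril axis (the meridional, hydrogen-bonding repeat) and the sheets
offset 9.6 Å laterally (the equatorial, sidechain-packing repeat) — the two
canonical diffraction spacings, recoverable from the built coordinates by
`measure_fibril_geometry()` to 10⁻⁹ Å. Whether such a fibril is parallel or
antiparallel and in or out of register is a modelling decision here
(parallel, in-register), not a measured fact.

In cross-seeding systems the fibril's internal hydrogen bonds (residue i of
strand k to residue i of strand k+1, per sheet) are registered in the
initial bond state. Interior strands therefore enter with their two-bond
capacity saturated and cannot accept monomer hydrogen bonds; only the
terminal strand of each sheet retains a free valence. This is the concrete
form of the seeding mechanism the experiments point to — template ends with
exposed donors/acceptors — and it is what makes a sonicated seed, which is
mostly ends, special.

## Campaign design

* **Hotspot scan**: one fragment copy and one free target monomer in an
  8 nm box, 200 ns-equivalent runs with the trailing 150 ns analysed,
  replicated with independent random placements, orientations and
  velocities. Binding frequency averages frames within a replicate first,
  then replicates with equal weight, so replicates of different lengths
  contribute equally.
* **Aggregation**: 10 copies of a 10-mer (7 of a 25-mer) in a 12 nm box,
  350 ns-equivalent with the last 100 ns analysed; single-linkage clusters
  (connected components of the chain-level contact graph) summarised by the
  mass-weighted mean size &Sigma;n²/&Sigma;n.
* **Cross-seeding**: the 34-strand static fibril at the centre of a
  10.5 nm box and one free monomer initially placed uniformly at random at
  least 1.5 nm from any fibril bead. The campaign runs 900 ns-equivalent —
  twice the nominal protocol — with the trailing 50 ns analysed, because at
  the chosen time mapping the coarse-grained monomer's diffusive search for
  the fibril is slower than its all-atom counterpart; the doubled duration
  lets every replicate reach its bound steady state. Monomers start
  extended (an unfolded chain), as do scan peptides; aggregation runs start
  from compact self-avoiding coils.

Starting conformations matter: a collapsed A&beta;42 globule buries its
hydrophobic sidechains and binds the fibril markedly more slowly, which is
physically sensible and was the reason to standardise on extended starts
for binding campaigns.

Windows in which a sequence length is not `window + k*step` get a final
fragment anchored at the C-terminus, so no residue is ever dropped from a
scan.

## Secondary structure without DSSP

DSSP needs backbone atoms a two-bead model does not have. The stand-in
keeps DSSP's logic at bead resolution: a residue is a strand residue when
its backbone bead has at least one geometrically satisfied hydrogen bond
(partner in the [0.44, 0.56] nm well, tangents aligned within 30&deg;) and
its local segment is extended (backbone i-1 to i+1 distance > 0.70 nm).
Terminal residues and chains shorter than three residues cannot be tested
for extension and are flagged on the hydrogen-bond criterion alone.

## Kinetics and morphometry

The ThT model is the standard four-parameter sigmoid
y(t) = y₀ + (y_max − y₀)/(1 + e^{−(t − t₁/₂)k}), fitted by bounded
Levenberg–Marquardt least squares with data-driven starts (y₀ from the
minimum, y_max from the maximum, t₁/₂ from the half-range crossing, k from
the maximum slope). The lag time is the tangent construction
lag = t₁/₂ − 2/k, reported unclamped — seeded curves can legitimately have
negative lag. A curve whose range is under five times the lag-1-difference
noise estimate is rejected as degenerate rather than fitted. Replicates may
be fitted jointly by stacking points. Fits are invariant to affine
rescaling of fluorescence up to optimiser tolerance.

Fibril pitch is the lag of the first significant off-origin maximum of the
mean-removed height autocorrelation along arclength, refined by parabolic
interpolation through the peak and its neighbours; "significant" means
clearing max(0.2, 3/&radic;n), well above the O(1/&radic;n) fluctuations of
an aperiodic trace, and a flat or aperiodic trace raises a no-periodicity
error instead of returning a number. Population statistics use per-fibril
means, n−1 standard deviations, and Welch's unequal-variance statistic for
two-population comparisons.

## What the synthetic generators do and do not emulate

`gen_fragment_set()` supplies the study's sequence contrast: a strongly
amyloidogenic Val/Ile 10-mer, a fully polar/charged control (D/E/K/N/Q
only, so its sidechain wells are essentially zero-depth and any association
is hydrogen-bond-only), and a mixed 25-mer. They are designed inputs with
known character, not natural sequences. `gen_tht_curve()` inverts the
sigmoid fit model plus i.i.d. Gaussian noise — real plate-reader curves
carry drift, heteroscedastic noise and evaporation artefacts it does not
model. `gen_fibril_trace()` models helical twist as a pure cosine height
modulation with Gaussian tracing noise — real fibrils have variable twist,
crossovers and polymorph mixtures. Passing the recovery tests therefore
shows the estimators are correct on their stated signal models, not that
they are robust to every artefact of real data.

## Problem sizes used by the test-suite

The suite exercises the full campaigns at the protocol boxes and windows
with the desk-scale time mapping: the cross-seeding acceptance campaign is
10 replicates of the 34-strand fibril plus monomer (~760 beads, ~10⁶ events
per run); discrimination uses 20 scan replicates per fragment and one
aggregation run per fragment; engine validation uses 2–24-bead systems, a
40 000-reduced-time dimer for the Boltzmann-occupancy check and ~10⁵-event
NVE runs. Everything is seeded and reproduces bit-for-bit.

## Known limitations

* **No electrostatics.** Charged-pair repulsion and salt effects are
  absent; the polar control is inert because its wells are shallow, not
  because it is repelled. Sequences whose solubility is charge-dominated
  will be misranked.
* **Lateral-surface binding dominates final binding modes.** With a fully
  hydrophobic model seed fragment the fibril's lateral surfaces are large
  and attractive, and at desk scale most runs end with the monomer bound
  laterally rather than at the fibril ends, even though only the ends offer
  free hydrogen-bond valences. The experimental picture — surface diffusion
  funnelling the monomer to the ends — needs longer exploration and
  all-atom energetics than this surrogate resolves. The binding-mode
  classifier is exact on geometric fixtures; campaign-level mode counts
  should be read with this bias in mind.
* **Nominal timescales.** The ns labels on protocols are a bookkeeping
  convention through `time_scale`; no attempt is made to reproduce absolute
  kinetic rates.
* **Two-bead resolution.** No sidechain rotamers, no backbone dihedral
  preferences beyond the extension criterion, one bead class per residue
  type.
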