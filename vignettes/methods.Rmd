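---
title: "Methods: conformation inference and damage simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformation inference and damage simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`chromodamage` couples two models. The first infers 3D genome
conformations from Hi-C-derived TAD contact constraints: each TAD is a
spherical bead holding a known bp interval, chained per chromosome, and
a Markov-chain Monte Carlo optimiser arranges the chains inside a
nuclear volume so that contact-constrained bead pairs become spatially
proximal. The second converts radiation energy depositions inside those
beads into DNA strand breaks, clusters them into double- and
single-strand break (DSB/SSB) sites, and quantifies the spatial pattern
of damage with clustering statistics and an edge-corrected 3D Ripley-K.

This vignette records the model assumptions, the tunable parameters and
their defaults, the numerical choices made where the design was open,
and what the synthetic-data generator does and does not emulate.

# The genome model

A genome is a table of bead specifications (`bead_specs()`): chromosome
label, 0-based half-open bp interval, unique id, optional
lamina-periphery flag, and contact-edge partners. Homologous copies use
the `"_A"`/`"_B"` label suffix convention; the homolog key
(`homolog_key()`) strips it, which drives the homolog rule in the
clustering statistics. Files are read and written in the Chrom3D-style
gtrack dialect; an optional per-edge `=weight` suffix is parsed and
ignored, since the solver treats all contacts equally.

Bead radii follow from a single occupancy parameter: bead volume is
proportional to bp content and the total bead volume is
`occupancy * V_nucleus`, with the default occupancy 0.15. A single bead
holding the whole genome in a 5 um sphere therefore has radius
`5 * 0.15^(1/3) = 2.657` um, a useful closed-form check.

Nuclei are spheres or ellipsoids (`nucleus_shape()`), stored as three
semi-axes in micrometres. The study shapes are a 5 um-radius sphere and
a flattened `1.0 x 11.8 x 11.8` um ellipsoid of equal DNA content.
Membership is `(x/a)^2 + (y/b)^2 + (z/c)^2 <= 1`. The distance of an
outside point to the boundary uses the scaled-radial approximation
(`||x|| (1 - 1/u)` along the centre ray), which is exact for spheres;
the true point-to-ellipsoid distance has no closed form and the
approximation errs modestly for very flat ellipsoids, which we accept
for the boundary cost term.

Initial conformations grow each chromosome as a random walk of touching
beads (consecutive centre distance exactly the radius sum), redrawing a
direction up to 1000 times until the centre falls inside the nucleus.
Overlap with non-adjacent beads is tolerated at initialisation — it is
penalised by the solver — because full self-avoiding placement at 0.15
occupancy frequently dead-ends. The pseudo-random reference geometry
(`generate_pseudo_random()`) instead places every centre i.i.d. uniform
in the nuclear volume; it is the territory-free baseline used to
normalise clustering values and to check the Ripley-K statistic, which
must vanish for it.

# The solver

The objective is a weighted sum of four hinge terms, each zero at
satisfaction:

* **contact** — for each constrained pair, `max(0, d - (r_a + r_b))`:
  the surface gap beyond touching;
* **boundary** — distance of each bead centre outside the nucleus, zero
  inside, active only under `constrain_nucleus`;
* **lad** — for periphery-flagged beads, the radial distance inward of
  the shell at fraction 0.8 of the normalised radius. The shell
  fraction is configurable; 0.8 puts the target region comfortably in
  the outer half-volume while leaving room inside the boundary;
* **overlap** — pairwise interpenetration `max(0, (r_i + r_j) - d)`.

The functional forms are package choices: hinge losses are continuous,
have a well-defined zero, and make "satisfied" constraints cost-free.
All weights default to 1 and are configurable.

Five move types operate on one chromosome at a time: crankshaft
(rotate the beads between two fixed pivots about the pivot axis), arm
rotation (rigidly rotate one arm about a pivot bead), arm wiggle
(re-grow one arm as a fresh touching-bead walk inside the nucleus),
whole-chromosome translation (per-component uniform in [-1, 1] um,
the symmetric version of a 0-1 um step so the chain is reversible),
and whole-chromosome rotation (axis uniform on the sphere, angle
uniform on [0, 2pi)). Types are drawn uniformly by default; moves
infeasible for a chain's length are resampled.

Iterations are counted as *accepted* moves ("successful movements");
the production target is 2 million with an attempted-move cap of 50x
the target so the loop always terminates. Acceptance is greedy
(strict improvement only), metropolis (accept worsening moves with
probability `exp(-delta/T)`), or simulated annealing (metropolis with
geometric cooling per accepted move; the default factor 0.999995 is
chosen to decay slowly over 2e6 acceptances). Cost changes are
evaluated incrementally over the beads a move touches, and the
incremental bookkeeping is checked against a from-scratch evaluation
in the tests to 1e-8.

Temperature and the boundary weight matter jointly. At equilibrium the
typical boundary penetration scales like T divided by the boundary
weight, so a unit-weight boundary term at T = 0.5 tolerates ~0.5 um
excursions — far too permissive for an encapsulated nucleus. Runs that
must end confined therefore raise the boundary weight relative to the
other terms (the confinement demonstrations here use weight 10 at
T = 0.3, giving a ~0.03 um penetration scale); this mirrors the role
of the nuclear-boundary constraint as a hard encapsulation objective
rather than one traded off against contacts. The scaled demonstration
used throughout the tests is a ~200-bead diploid genome solved for
50,000 accepted moves, which ends with under 1% of beads outside the
nucleus and a contact cost well below the pseudo-random reference;
problem sizes were chosen so the whole suite stays comfortably
runnable on a laptop core.

# Spatial statistics

*Clustering* counts, for every object (bead or DSB centroid), the other
objects within the cluster radius, then averages over objects.
Distances are centre-to-centre; membership is `<= radius`.
Interchromosomal counts exclude pairs on homologous copies; so do
intrachromosomal counts (same label only). Homolog pairs are available
separately so `total = inter + intra + homolog` is auditable per
object. The inter/intra ratio is flagged undefined (not an error) when
the intra mean is zero.

*Ripley-K* in 3D with nuclear edge correction:

$$K(CR) = \frac{V_{nuc}}{n^2} \sum_i \sum_{j \ne i}
  \frac{I[D(i,j) \le CR]}{V_s(i)}$$

where `V_s(i)` is the fraction of the CR-sphere around point i inside
the nucleus — analytic (sphere-sphere lens volume) for spherical
nuclei, seeded Monte Carlo (10,000 samples) for ellipsoids. The
normalised statistic is `K / ((4/3) pi CR^3) - 1`, zero in expectation
under complete spatial randomness; the normalisation formula is a
package choice consistent with that requirement. Without edge
correction K converges instead to the exact CSR closed form
`V * P(D <= CR)` with
`P = x^3 - (9/16) x^4 + (1/32) x^6`, `x = CR/R`; at `CR = 0.5` um in a
5 um sphere the deficit is 5.6%, which the tests verify against the
closed form rather than against the uncorrected ideal.

*Radial positioning* halves the nuclear volume: a bead is central iff
its normalised radius is at most `2^(-1/3)` (the ellipsoid inner
region is the axis-preserving scaled copy, same factor), and
central/peripheral fractions are bead-bp-weighted within 10 Mbp bins,
homolog copies pooled.

*Chord adjacency* reports chromosome pairs (different homolog keys)
sharing at least one interchromosomal bead pair closer than 500 nm
(strict `<`) in at least a threshold fraction (typically 40% or 50%)
of an ensemble of geometries.

*Proximity score* is the mean, over beads with constraints, of each
bead's mean centre distance to its contact partners — a
boundary-agnostic measure of contact satisfaction; lower is better.

# The damage model

Energy depositions inside beads become strand breaks through two
independent filters: a Bernoulli draw with the sensitive fraction
0.141 — implemented i.i.d. per deposit, which is statistically
equivalent at the bead level to a fixed sensitive sub-volume and keeps
the model geometry-free — and a linear energy ramp from probability 0
at 5 eV to 1 at 37.5 eV (the linear shape between the stated endpoints
follows the PARTRAC-style convention). Surviving deposits are assigned
strand 1 or 2 with equal probability and a uniform bp position within
the host bead. Deposits inside several overlapping beads are
attributed to the deepest relative containment (smallest d/r); the
choice is arbitrary but deterministic.

Breaks cluster per chromosome by transitive chaining: two breaks link
when they are within 10 bp genomically *or* within the equivalent
3.2 nm in their recorded 3D positions. Both criteria are needed
because a bead has no internal structure tying bp to position: the
genomic window handles breaks whose sampled bp collide (and is what
the photon pathway and the bp-window sweep exercise), while the
spatial window is what lets densely deposited track energy form DSBs
— with genomic-only clustering, two deposits nanometres apart in one
~1 Mbp bead almost never collide in bp, and ion DSB yields would be
essentially zero. A chain containing both strands is one DSB whose
complexity (backbone count) is its member count; every other break is
a singleton SSB. Duplicates at identical (chromosome, strand, bp) are
merged first, and sorting on (chromosome, bp, strand) makes the result
order-independent.

Photon exposures bypass track structure: the DSB count is Poisson with
mean 25 DSB/Gy, each DSB landing on a chromosome with probability
proportional to bp, on a bead within it proportional to bead bp, at a
uniform position inside the bead sphere. Photon DSBs are emitted
directly as complexity-2 sites and never re-clustered.

Damage is written in a compact SDD-style dialect: `key, value;` header
lines closed by `***EndOfHeader***;`, then per-site records
`kind; x, y, z; chromosome; bp; backbones;` in micrometres at full
precision, so the paired reader round-trips exactly.

# The track surrogate

Ion exposures use a declared amorphous-track generator, not a physics
transport code. Its only contract is an LET-correct energy budget with
spatially concentrated deposition: straight tracks enter uniformly
over the projected disc of the nucleus, deposit a Poisson number of
point energies (exponential with mean 60 eV, a typical
ionisation-scale quantum) uniformly along the chord with 5 nm Gaussian
lateral jitter, so the expected energy per track is LET times the
chord length. The track count for a dose follows from the mean chord
length 4V/S (Cauchy) and the water-density nucleus mass; for a 5 um
sphere at 10 keV/um, 1 Gy needs 49 tracks. Parallel-beam geometry
mirrors broad-beam irradiation; an isotropic option exists for
spherical nuclei.

Because the surrogate is not a transport code, absolute ion yields
are out of numeric scope. What it reproduces are directional trends
at fixed dose: DSB yield rises with LET, SSB yield falls (breaks
joining DSB clusters), and intrachromosomal DSB clustering rises
(damage localises along tracks). The trend study runs 10 LET points
from 5 to 100 keV/um, 10 exposures of 20 Gy each, on a territorial
chain-walk conformation — a higher dose than a single fraction, for
the same reason the damage-versus-geometry analyses elsewhere use
high-dose exposures: clustering statistics on a handful of DSBs per
exposure are dominated by shot noise. Yield trends are tested on the
break-partition fractions (DSB sites and SSBs as fractions of all
breaks), since total break production per Gy is LET-independent by
construction and carries the track-geometry sampling noise. One trend
the surrogate does *not* reproduce is the falling inter/intra
clustering ratio: real track structure yields near-constant DSB
counts across LET (low-LET secondary-electron spurs still cluster
locally), whereas the surrogate's DSB yield grows roughly sixteen-fold
from LET 5 to 100, so the pooled DSB density — and with it
interchromosomal clustering — rises with LET and cancels the
localisation effect on the ratio. The corresponding check is left
failing by design as a documented limitation rather than papered
over.

# Ensemble comparison

Per-geometry metric values of two groups are compared cell-by-cell
over a LET-by-cluster-radius grid with the two-sided two-sample
Kolmogorov-Smirnov test (asymptotic p-values, the usual choice at
~200 geometries per group), adjusted by Benjamini-Hochberg across the
whole grid of one comparison pair (the family boundary is a package
choice; adjusting across comparison pairs as well is possible by
concatenating grids). Cells carry the group mean difference and a
significance class: red (p > 0.05), purple (0.05 > p > 0.01), yellow
(0.01 > p > 0.001), green (p < 0.001).

# The synthetic genome generator

`synth_config()` defaults emulate the study conditions: a diploid
6 Gbp genome over 46 chromosomes (23 haploid chromosomes with a
human-like decreasing size profile, duplicated as `"_A"`/`"_B"`),
mean TAD size 1 Mbp (the TAD scale of the input data; lognormal sizes
with CV 0.5), 0.5 contact edges per bead of which 80% are short-range
intra-chromosomal (geometric genomic span) and the rest uniform
inter-chromosomal pairs, and 30% of beads lamina-flagged (the rough
genomic LAD coverage in fibroblasts). Homolog copies receive
independent edges. The generator reproduces the *format and scale* of
solver input, not real Hi-C structure: there are no genuine TAD
boundaries, no distance-decay contact law beyond the geometric span,
and no correlated LAD blocks. Passing tests therefore demonstrate the
machinery — constraint optimisation, damage conversion, statistics —
on realistic sizes, not biological fidelity of any particular cell
type.

# Numerical choices and limitations

* Degenerate inputs: one-bead chains support only translation and
  rotation; two-bead chains additionally support arm moves with an end
  pivot; crankshaft requires three beads.
* The solver cap (`max_attempts = 50x` the target) makes greedy runs
  terminate even when strict improvements become rare; the trace and
  best-so-far state are returned with a warning only if nothing was
  accepted at all.
* Ties at the significance-class boundaries go to the less significant
  class; the published thresholds are strict inequalities so ties have
  measure zero in practice.
* Ripley-K edge correction requires points inside the nucleus (V_s >
  0); points outside raise an error in `edge_correction_vs()` and a
  warning when constructing the point set.
* Ellipsoid Ripley-K uses per-point Monte-Carlo corrections and is
  noticeably slower than the analytic sphere path at large n.
* All randomness flows through R's RNG via explicit seed arguments;
  ensemble stage i uses `base_seed + i` so any geometry can be
  regenerated alone.

# Problem sizes used in the tests

The packaged tests run on scaled instances chosen for quick laptop
runs: a ~200-bead diploid fixture (10 chromosomes) for solver
behaviour, 3000-5000 CSR points for Ripley-K, 1e5 deposits for the
sensitive-fraction recovery, 200 photon exposures for the 25 DSB/Gy
check, and 10 LET points x 10 exposures of 20 Gy for the trend suite.
The
production-scale configuration (46 chromosomes, ~6000 beads, 2e6
accepted moves, 200 geometries x 50 exposures) runs through exactly
the same code paths via `run_pipeline()`.
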