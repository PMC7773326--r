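# chromodamage

Radiation damage to DNA is shaped by where the genome sits in the
nucleus: double-strand breaks (DSBs) on intermingling chromosomes can
misrepair into interchromosomal aberrations, one of the most lethal
outcomes of irradiation. `chromodamage` is an R package for
radiobiological modellers and genome-organisation researchers that
couples the two sides of that problem:

1. **Conformation inference.** Hi-C-derived TAD contact constraints
   (Chrom3D-style gtrack files, or a built-in synthetic generator) are
   optimised by a Markov-chain Monte Carlo polymer model — TADs are
   spherical beads chained per chromosome inside a spherical or
   ellipsoidal nucleus, moved by crankshaft / arm-rotation /
   arm-wiggle / translation / rotation proposals under greedy,
   metropolis, or simulated-annealing acceptance. The objective is a
   weighted sum of hinge terms: contact gaps, nuclear-boundary
   excursions, lamina (LAD) shell attraction, and bead overlap.
2. **Damage simulation.** Energy depositions inside beads become
   strand breaks via a 14.1% sensitive fraction and a linear energy
   ramp (0 at 5 eV to 1 at 37.5 eV); breaks within 10 bp on opposite
   strands cluster into DSBs (others are SSBs); photon exposures draw
   Poisson(25 DSB/Gy) sites weighted by chromosome and bead bp; an
   LET-scaled straight-track surrogate generates ion-like deposition
   patterns. Damage is written in a compact SDD dialect.
3. **Spatial statistics.** Inter/intra-chromosomal clustering with a
   homolog-exclusion rule, an edge-corrected 3D Ripley-K

   K(CR) = V_nuc / n² · Σᵢ Σ_{j≠i} I[D(i,j) ≤ CR] / V_s(i),

   normalised so complete spatial randomness sits at 0, radial
   (central/peripheral) positioning, 500 nm chord adjacency across
   ensembles, proximity scores, and Kolmogorov–Smirnov /
   Benjamini–Hochberg significance grids over LET × cluster radius.

## Worked example

```r
library(chromodamage)

nuc   <- nucleus_shape(5)                       # 5 um radius sphere
cfg   <- synth_config(n_chrom = 5, genome_bp = 6e8, tad_mean_bp = 3e6)
specs <- synthesize_genome(cfg, seed = 2)       # ~200 diploid TAD beads
specs$radius <- assign_radii(specs, nuc, occupancy = 0.15)

conf <- build_initial_conformation(specs, nuc, seed = 3)
cons <- contact_constraints(specs)
res  <- solve_conformation(conf, cons, solver_config(
  n_successful_moves = 50000, scheme = "metropolis", temperature = 0.3,
  cost_weights = c(boundary = 10), seed = 4))

res$initial_cost$total; res$final_cost$total
#> [1] 229.9994
#> [1] 61.27225

proximity_score(res$conformation, cons)$score   # mean constrained distance, um
#> [1] 1.329951

sites <- photon_exposure(res$conformation, dose_gy = 1, seed = 9)
damage_yields(sites, 1)$dsb_per_gy              # DSB per Gy, this exposure
#> [1] 21

ps <- suppressWarnings(as_point_set(res$conformation))
ripley_k(ps, cr = c(0.5, 1.0))
#>    cr          K     K_norm
#> 1 0.5  0.3396317 -0.3513512
#> 2 1.0 10.7471409  1.5656909
```

The solve drags the total cost down (here 230 → 61) and the mean
centre-to-centre distance of contact-constrained TAD pairs to ~1.3 um.
The normalised Ripley-K of the solved geometry is negative at 0.5 um
(finite beads exclude each other at short range) and strongly positive
at 1 um (the chromosome territories the optimiser creates), where a
pseudo-random geometry (`generate_pseudo_random()`) sits at 0 at every
radius; the `suppressWarnings()` silences a note about the handful of
boundary beads whose centres end marginally outside the nucleus. A
single 1 Gy photon exposure draws a Poisson count around the
25 DSB/Gy model mean.

A command-line front end with subcommands `synth`, `solve`, `analyze`,
`irradiate`, `cluster`, `compare`, and `run` is installed at
`inst/cli/chromodamage.R` (the nuclear-boundary term is toggled with
the `--ConstrainNucleus` flag); `run_pipeline()` drives the full
synthesize → solve → irradiate → analyse ensemble with per-geometry
seeds and a hashed manifest.

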