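---
title: "Coarse-grained peptide/lipid self-assembly: model, dynamics, and aggregate analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained peptide/lipid self-assembly: model, dynamics, and aggregate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cookesim)
```

## The model

`cookesim` simulates implicit-solvent self-assembly of lipids and
amphipathic peptides with the Cooke force field. There are no water
particles: hydrophobicity is encoded entirely in a broadened pairwise
attraction between hydrophobic (T) beads, while every bead pair repels
through a Weeks–Chandler–Andersen (WCA) core. All interactions are built
from four terms:

* **Repulsion** (every pair):
  $V_{rep}(r; b) = 4\epsilon\,[(b/r)^{12} - (b/r)^6 + 1/4]$ for
  $r \le r_c = 2^{1/6} b$, zero beyond. Bead diameters are assigned by
  class only: $b_{HH} = b_{HT} = 0.95\,\sigma$, $b_{TT} = \sigma$. The
  smaller hydrophilic bead maintains the cylindrical lipid shape.
* **Attraction** (hydrophobic pairs involving at least one lipid bead):
  $-\epsilon$ for $r < r_c$, then
  $-\epsilon\cos^2[\pi(r - r_c)/(2 w_c)]$ over the interval
  $[r_c,\, r_c + w_c]$, and zero beyond, with width $w_c = \sigma$. The
  sign of the middle branch is fixed by continuity: it is the unique
  choice that joins $-\epsilon$ on the inside to $0$ on the outside.
  Peptide–peptide attraction is identically zero — the peptide modeled
  here does not self-aggregate in solution, so all peptide aggregation is
  lipid-mediated.
* **FENE bonds** (lipid chain):
  $V(r) = -\tfrac12 k_{bond} r_\infty^2 \log[1 - (r/r_\infty)^2]$ with
  $k_{bond} = 30\,\epsilon/\sigma^2$ and $r_\infty = 1.5\,\sigma$. We use
  the standard finitely-extensible form, whose energy diverges at
  $r_\infty$; printed variants that place the square outside the
  logarithm do not diverge and are not finitely extensible, so they are
  not used.
* **Harmonic terms**: the lipid is straightened by a head–second-tail
  spring $\tfrac12 k_{bend}(r - 4\sigma)^2$, $k_{bend} =
  10\,\epsilon/\sigma^2$ (its long rest length acts as a permanent
  straightening tension — the 3-bead chain can never physically reach
  $4\sigma$); the peptide is held nearly rigid by an elastic network of
  springs with $k = 30\,\epsilon/\sigma^2$ and rest lengths taken from
  the build geometry.

Units: $\sigma = 0.6$ nm and $\epsilon = 1$ kcal/mol, giving
$kT/\epsilon \approx 0.616$ at 310 K. Internally everything is computed
in a single coherent physical unit system (nm, kcal/mol, amu, K) whose
derived time unit is $\sqrt{\mathrm{amu}\,\mathrm{nm}^2/(\mathrm{kcal/mol})}
= 488.88$ fs; this stores the published parameter values verbatim and
needs no reduced-unit conversion layer.

```{r}
ff <- ff_params()
ff
```

## Molecular topologies

The **lipid** is three beads, H–T–T, chained by two FENE bonds with the
harmonic straightening spring between beads 1 and 3. The **peptide** is a
stack of six filled hexagons — 42 beads, each layer one center plus six
vertices on a ring of radius $0.95\,\sigma$, layers $0.95\,\sigma$ apart
so neighboring beads sit near their repulsion minimum and the network is
born essentially strain-free. Rigidity comes from a fully connected
elastic network: all 21 intra-layer pairs per layer plus all 49 pairs
between adjacent layers, 371 bonds total; a cap bead has 13 bonds, a
middle-layer bead 20.

Eight beads are hydrophobic, mimicking the hydrophobic face of a
membrane-bound amphipathic helix: two adjacent vertices per layer on the
four middle layers, aligned on one face (a contiguous 2×4 stripe), with
fully hydrophilic end caps. The stripe placement is configurable
(`build_peptide(stripe_layers =, stripe_vertices =)`) because the exact
pattern is a modeling choice; the default is the minimal contiguous
arrangement consistent with a single hydrophobic face.

```{r}
pep <- build_peptide()
table(pep$beads$bead_class)
range(elastic_degree(pep))
```

**Nonbonded exclusions.** Elastic-network partners do not additionally
interact through the pair potential: the stiff network already pins those
distances at the reference geometry, and the convention keeps the peptide
interior unfrustrated. Lipid FENE and harmonic partners *do* keep their
WCA repulsion (the usual WCA+FENE construction).

## Dynamics

`run_langevin()` integrates underdamped Langevin dynamics with a BAOAB
splitting — velocity Verlet with an exact Ornstein–Uhlenbeck velocity
refresh mid-step. Production settings follow the model's standard
protocol: 10 fs time step, friction 1 ps$^{-1}$, 310 K, NVT, cubic
periodic box with minimum-image convention. With the friction set to zero
the scheme reduces exactly to velocity Verlet, which is how the test
suite checks integrator correctness (total-energy drift below
$10^{-4}\,\epsilon$ over $10^4$ steps at 0.1 fs).

Bead masses are uniform, 100 amu by default. Masses affect only kinetics,
not any NVT equilibrium observable, so the choice is free; the value
keeps the intramolecular vibration periods two orders of magnitude above
the production time step.

Preparation follows pack → minimize → ramp:

1. **Packing** (`random_pack()`): rigid molecules at uniformly random
   positions and orientations, accepted only if every bead keeps a floor
   distance (default $0.8\,\sigma$) from previously placed molecules.
2. **Minimization** (`minimize()`): steepest descent with backtracking
   and a per-bead displacement cap; during minimization the FENE
   divergence is replaced by a linear continuation so arbitrarily bad
   input relaxes instead of overflowing.
3. **Ramped equilibration** (`equilibrate()`): staged Langevin dynamics
   with the time step raised tenfold per stage, 0.01 → 0.1 → 1 → 10 fs,
   $10^4$ steps per stage by default. The tiny first step lets residual
   overlaps unwind without FENE overextension.

Numerical guards: pair distances are floored at $0.3\,b$ inside the WCA
core (relevant only to pathological overlaps), and FENE overextension or
non-finite coordinates abort the run with a diagnostic rather than
produce silent garbage. Trajectories are bit-reproducible for a given
seed: the integrator draws from a dedicated counter-seeded Mersenne
Twister feeding a ziggurat Gaussian sampler, independent of R's RNG
state; replica $k$ derives its seed as `base_seed + k - 1`.

## Aggregate analysis

The analysis chain mirrors standard practice for micelle/disc
self-assembly trajectories:

* **Clustering** (`cluster_frame()`): single-linkage connected components
  over *hydrophobic beads only*, cutoff 0.9 nm ($1.5\,\sigma$), minimum
  image. Restricting to hydrophobic beads suppresses spurious merge
  events when aggregates merely brush against each other; a molecule
  joins a cluster if any of its hydrophobic beads does.
* **Aggregates** (`analyze_frame()`): clusters below 5 molecules are
  discarded; each surviving cluster is unwrapped across the periodic
  boundary (breadth-first over the molecule contact graph, each molecule
  placed by minimum image against an already-placed neighbor — geometry
  on wrapped coordinates would be meaningless), then measured: all-bead
  radius of gyration and composition.
* **Classification**: label `disc` when $R_g \ge 2.5$ nm, `micelle`
  below. $R_g$ separates the two shapes cleanly but underestimates
  physical extent, so **size** is reported separately as the mean of the
  coordinate ranges along the top two principal components
  (`aggregate_size()`), which tends to the diameter for both spheres and
  flat discs.
* **Free lipids**: lipids in no reported aggregate; sub-threshold
  clusters count as free. This is the only closure consistent with
  reporting aggregates at ≥ 5 molecules, and makes lipid accounting
  exact: free + aggregated = total in every frame.
* **CMC estimation**: from a system-size scan at fixed total
  concentration (`cmc_from_size_scan()`; the free-lipid plateau of the
  largest systems, with small systems flagged artificially low), or from
  a concentration scan at fixed size (`cmc_from_concentration_scan()`;
  the mean free concentration over the region where stable aggregates
  form, ≥ 2 mM for this model).
* **Ergodicity** (`ergodic_measure()`): mean square deviation of the
  aggregate count between replicas vs time, pairwise form
  $\mathrm{mean}_{i<j}[n_i(t)-n_j(t)]^2$; the equivalent
  replica-variance form $2\,\mathrm{var}(n_i)$ is returned alongside.
* **Distribution shape** (`size_distribution_qq()`): histogram of lipids
  per aggregate, maximum-likelihood Gaussian fit (no truncation
  correction — with small aggregates such a fit knowingly puts mass on
  negative counts), QQ pairs, and an upper-tail deviation statistic:
  micelle populations are near-Gaussian, discs contribute a long upper
  tail.
* **Phase diagram** (`build_phase_diagram()`): each (lipid count, P/L)
  point becomes `micelle`, `disc`, or `mixture` from its aggregate
  labels; the finite-size boundary applies the three-times heuristic,
  flagging points whose lipid count is below 3× the preferred aggregate
  size, taken from the largest simulated system at the same P/L.

The equilibrated window defaults to the final third of a trajectory,
overridable everywhere it appears.

## The fixture generator

`generate_fixture()` builds idealized configurations — spherical micelle
(heads out, tails in), flat bilayer disc with rim peptides standing
normal to the disc plane with their hydrophobic stripe facing the lipid
tails ("picket fence"), planar bilayer, fully dispersed monomers, and a
planted micelle+disc mixture with known composition. These exist so every
analysis operation has a ground-truth oracle without hours of
self-assembly: clustering connectivity, label thresholds, unwrapping, and
conservation laws are all tested against planted structure.

What the fixtures do *not* emulate: thermal roughness, exchange dynamics,
compositional fluctuations, or metastable intermediates. A passing
analysis suite therefore demonstrates correctness of the measurement
machinery, not realism of any particular assembly pathway; the end-to-end
self-assembly checks below cover the dynamical side.

## Problem sizes in the tests and the demonstration study

The package's own verification study (`assembly_study()`, also what
`scripts/acceptance.R` runs) uses 20 lipids + 10 peptides at P/L = 1/2
and 10 mM — the composition regime that assembles fastest and forms
exclusively mixed micelles — with 3 replicas of $2\times10^6$ production
steps (20 ns). At this composition the first stable mixed micelles appear
within 2 ns, so the run length is an order of magnitude past assembly;
the analysis window is the final third. Expected behavior: several mixed
micelles whose per-aggregate P/L tracks the bulk ratio, and no disc
labels.

Statistical tests compare simulation averages with closed forms at three
standard errors: the free-bead velocity variance against $kT/m$, and the
mean potential energy of a single elastic bond against direct quadrature
of its radial Boltzmann weight (the $r^2$ Jacobian makes the exact value
differ slightly from the naive $kT/2$; the quadrature oracle is exact).

## Limitations

* No electrostatics, no explicit solvent, no pressure coupling: NVT only.
* The peptide is one fixed 42-bead shape; sequence-specific
  parametrization is out of scope.
* Hydrodynamics are absent (Langevin friction is local), so kinetic
  pathways are qualitative; equilibrium phases and populations are the
  meaningful outputs.
* Single-threaded by design, trading speed for bit-reproducibility.
* CMC estimates at very small system sizes are artificially low —
  that finite-size artifact is itself one of the phenomena the analysis
  quantifies, via the size-scan curve and the three-times heuristic.
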