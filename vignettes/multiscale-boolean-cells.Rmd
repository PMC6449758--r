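---
title: "Multi-scale simulation of cell populations with stochastic Boolean signalling"
author: "boolcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale simulation of cell populations with stochastic Boolean signalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolcell)
```

## The model

`boolcell` couples three descriptions of a growing cell population that live
on different scales and clocks:

1. **Intracellular signalling.** Every cell carries a Boolean network: a set
   of 0/1 variables (receptors, kinases, caspases, transcripts) connected by
   AND/OR/NOT rules.  The network is simulated as a continuous-time Markov
   chain with the asynchronous Gillespie algorithm: in a state $s$, every
   non-input node whose logic disagrees with its current value carries a
   transition rate (`rate_up` when the logic says 1 and the node is 0,
   `rate_down` in the opposite case); the waiting time to the next event is
   exponential in the summed rate and exactly one node flips per event.
   Input nodes carry no transitions — they are written by the coupling
   layer.  Rates at or above $10^5\,\mathrm{min}^{-1}$ act unconditionally
   (not gated by the logic); this is how over-expression and knock-out
   mutations pin a node by sheer mass action while leaving the network
   structure untouched.

2. **Cell mechanics and phenotype.**  Cells are off-lattice soft spheres
   with overdamped dynamics (velocity = net force, unit drag).  A pair at
   centre distance $d$ with radii sum $R$ feels repulsion
   $c_\mathrm{rep}(1-d/R)^2$ inside $R$ and adhesion
   $c_\mathrm{adh}(1-d/(fR))^2$ inside $f R$ ($f = 1.25$ by default).
   Adhesion combines the strain pair's strength (homotypic on the diagonal,
   geometric mean of heterotypic strengths off it) with the geometric mean
   of the two cells' dynamic adhesion coefficients, mirroring the fact that
   junction strength is a property of both partners' cadherin/integrin
   densities.  Volumes (fluid, cytoplasmic solid, nuclear solid) relax
   exponentially toward phase-dependent targets; the cycle is a single-phase
   timer with Erlang(4) duration gated on reaching 95% of the doubled
   volume; apoptotic cells shrink and are removed below 5% of their
   commitment volume, necrotic cells swell toward 1.5x and lyse after 6 h.
   Polarity follows a run-and-tumble process (Poisson tumbling at rate
   $1/\tau$) whose mean-squared displacement obeys the persistent-random-
   walk (Fürth) formula, which the tests verify.

3. **Microenvironment.**  Substrates (TNF, oxygen, a non-diffusing ECM
   density) live on a cubic voxel mesh (default edge 20 µm) and evolve by
   operator-split implicit finite volumes: one backward-Euler tridiagonal
   sweep per axis (unconditionally stable, positivity preserving, mass
   conserving under zero-flux boundaries) followed by exact exponential
   decay.  Injection is a Dirichlet rim: while a schedule is "on", every
   boundary-adjacent voxel is held at the injected concentration, modelling
   a stirred medium; while "off" the rim is held at zero and the substrate
   washes out, as in the microfluidic experiments the validation mimics.
   Cells act as saturating sources and first-order sinks in their containing
   voxel, solved implicitly per voxel.  Sampling is nearest-voxel — a
   deliberate match to the voxel-density semantics, avoiding interpolation
   artefacts in tests.

The three parts run on nested clocks (defaults: diffusion 0.01 min,
mechanics 0.1 min, signalling 10 min; each larger step an integer multiple
of the smaller).  Every signalling step the coupling layer writes the
network inputs (e.g. TNF node = 1 iff the cell's internalised TNF exceeds a
threshold $\theta$), advances the network by one Gillespie window, and
applies the read-outs: `Apoptosis`/`NonACD` latch the irreversible death
fates, `Survival` gates the cycle clock (0 arrests, without killing), and
`NFkB` toggles autocrine TNF secretion and latches the cell's "ever
activated" marker.  Per-cell update phases are staggered by a random
fraction of the signalling step fixed at birth, so the population does not
update in artificial lock-step (a synchronised mode exists behind
`stagger = FALSE`).

## Randomness and reproducibility

Every agent owns a counter-seeded xoroshiro128+ stream derived from the
master seed and its id.  Division order therefore cannot perturb unrelated
cells, ensembles are order-independent, and identical configuration + seed
reproduce output CSVs bitwise — a property the test suite asserts.  The
activated-marker latch is evaluated *inside* the Gillespie window, so an
NFkB transient shorter than the signalling step still counts as activation.

## The bundled cell-fate network

`build_cell_fate_network()` loads a **synthetic reconstruction** of the
published TNF cell-fate topology (no original model files are redistributed
here): TNF receptor engagement branches into (i) the
RIP1–IKK–NFkB survival arm with its transcriptional targets cFLIP, BCL2 and
XIAP, (ii) the DISC–CASP8–BAX–MOMP–CASP3 apoptotic cascade, and (iii) the
RIP1-kinase–ROS–MPT non-apoptotic death (NonACD) arm in which ATP collapse
both commits the cell to necrosis and starves the apoptosome.  mRNA
intermediates (`mXIAP`, `mROS`) carry rates scaled by
`transcription_rate_scale` (default 0.2, i.e. five-fold slower than protein
events), introducing the transcription/translation delay that shapes the
fate decision: raising the scale accelerates XIAP-mediated apoptosis
inhibition and ROS production, shifting fates toward NonACD — a behaviour
the tests check at 3σ over 10⁴ trajectories.

Two reconstruction choices deserve mention.  First, the `Survival` read-out
is wired as `NFkB | !TNF` with an initially active state: unstimulated cells
are proliferative, and under TNF the read-out tracks NFkB.  This resolves a
tension between "Survival gates the cycle" and the requirement that naive
populations grow.  Second, the mitochondrial permeability transition (`MPT`)
is irreversible (`rate_down = 0`), which is biologically defensible and
makes NonACD commitment reliably slower than apoptosis (the tests compare
median first-activation times), because ATP collapse then proceeds on its
own slow clock ($0.02\,\mathrm{min}^{-1}$) once the pore opens.

The rate constants (protein events $0.1\,\mathrm{min}^{-1}$; NFkB-arm
activation $0.2\,\mathrm{min}^{-1}$; DISC $0.05$; CASP8 $0.09$; ROS/MPT
$0.06$; mRNA $0.02$) were calibrated **once** against the published
population-level outcomes — heterogeneous fate commitment with all three
fates populated under sustained TNF, roughly half of a treated spheroid
committing to death under continuous 0.5 ng/mL, about one fifth of cells
dying by apoptosis without ever activating NFkB, and apoptosis committing
faster than NonACD — the same kind of calibration such models undergo
against microfluidic dose-response data.  They are exposed as `$symbols` in
`inst/extdata/cellfate_synthetic.cfg` and can be refit without touching
code.

## TNF handling and receptor model

Extracellular TNF (diffusion 1200 µm²/min, decay 0.0275/min — reconstructed
defaults, config-exposed) binds at rate $k_\mathrm{on} c$, internalises at
$k_\mathrm{int}$, clears at $k_\mathrm{clear}$ (defaults 0.1, 0.5,
0.05/min).  The bound/internalised pools are kept in voxel-concentration
units so that grid + pools conserve ligand mass exactly when decay and
clearance are off (a tested invariant).  The input threshold
$\theta = 0.15$ was chosen so that (i) a 1 ng/mL × 5 min rim pulse activates
an intermediate fraction of a monolayer disk, (ii) stimulus areas below
10² ng·s/mL elicit essentially no response while areas above 10³ saturate,
and (iii) the internalised pool genuinely decays below threshold between
pulses 150 min apart, so pulsed regimes re-sensitise survivors — the
mechanism behind "pulsed kills more than continuous".  NFkB-active cells
secrete TNF into their voxel at the strain's rate (default 0.05
density/min), closing the autocrine/paracrine loop.

## Study conditions and problem sizes

The scripted scenarios default to desk scale so the whole suite runs in
minutes on one core; the published geometries are one argument away
(`radius = 400` for the monolayer disk, 100/200 µm for the spheroids).
Defaults used throughout the tests and the acceptance script:

* **Growth calibration**: mean cycle duration 970 min (Erlang shape 4,
  volume gate at 95% of doubling with growth rate 0.005/min) reproduces a
  ~16 h population doubling time for unconstrained 2D growth — the quantity
  the acceptance script recomputes from a 48 h, 50-cell run over 3 seeds.
* **Spheroid line**: cycle 600 min with growth rate 0.008/min, giving the
  ~4.5-fold untreated 24 h expansion of the faster-growing spheroid
  experiments.  The monolayer and spheroid lines differ deliberately: their
  published growth figures are inconsistent with a single cycle length, so
  each experiment uses its own calibrated strain.
* **Spheroid radius 50 µm** (~135 cells) instead of 100–200 µm; disk
  radius 100 µm (~120 cells) instead of 400 µm.  The treated-arm fold
  change at this scale runs somewhat above the published paper-scale value
  (~2.2–2.5 versus 1.8) because resistant survivors dominate sooner in a
  small spheroid; the untreated/treated ordering and the death fraction are
  preserved and asserted.
* **Oxygen**: D 6000 µm²/min, stirred boundary 38 mmHg, per-cell uptake
  10/min, necrosis threshold 5 mmHg (strict inequality).  At desk scale
  these produce the necrotic-core/proliferative-rim pattern inside 50 µm
  spheroids.
* **Sorting**: homotypic adhesion 8 (strong line) versus 1 (weak line and
  all heterotypic contacts), repulsion 10, motility 1 µm/min with 5 min
  persistence, 24 h horizon, ECM ring of passive spheres.  Weaker adhesion
  contrasts or faster motility wash the sorting signal out.

## What the generator does and does not emulate

The synthetic populations capture stochastic per-cell signalling, mechanical
crowding, substrate transport and clonal competition.  They do not model
cell morphology beyond spheres, deformable or filamentous ECM, advection,
substrate–substrate reactions, contact-inhibition rules beyond mechanics, or
receptor trafficking beyond the three-pool linear scheme.  Passing tests
therefore validate the algorithmic machinery and the reconstructed model's
population phenomenology, not quantitative agreement with any particular
cell line.

## Numerical choices

* Implicit finite volumes are first-order in time; the heat-kernel test
  quantifies the error (<2% of peak for a point source on a fine grid).
* The spatial-hash force evaluation visits pairs in the same order as the
  all-pairs loop, so both give bitwise-identical forces (tested on 200
  agents).
* Coincident cell centres repel along a fixed +x axis rather than a random
  one, keeping mechanics deterministic.
* The master-equation oracle (`master_equation_dist()`, dense
  `Matrix::expm`) is an independent cross-check of the Gillespie kernel on
  networks of up to ~12 nodes; the suite compares empirical state
  distributions at 3 binomial standard errors per state.
* Read-out ties are broken Apoptosis > NonACD > Survival; death read-outs
  are irreversible, so this makes classification deterministic.
* Degenerate inputs are rejected up front: the config loader resolves all
  cross-references (strains ↔ overrides ↔ nodes, substrates ↔ schedules ↔
  rules) and names the offending key before the simulation starts.

## Known limitations

Signalling of death-committed cells is frozen (their network no longer
updates), the `interaction_distance_multiplier` is global rather than
per-strain, and the 2D mode uses spherical-volume radii (a disk of the same
radius) rather than area-equivalent ones.  The Hill validation sweep over
the full 400 µm disk is a long-running job; the bundled tests gate the
fitting routine by noiseless parameter recovery (coefficients 1.5 and 4.8
within 5%) and the sweep end-members at reduced scale instead.
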