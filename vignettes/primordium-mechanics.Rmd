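---
title: "Mechanics of rosette formation in the migrating lateral line primordium"
author: "pllpsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of rosette formation in the migrating lateral line primordium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(pllpsim)
```

## The biological question

The zebrafish posterior lateral line primordium (PLLp) is a cluster of
roughly 140 cells that migrates from behind the ear to the tip of the tail,
periodically assembling groups of cells into epithelial rosettes
(protoneuromasts) and depositing them as sensory organs. Rosette formation is
driven locally by cell-cell adhesion and apical constriction, which pull
cells together; it is opposed globally by the tension that builds along the
tissue when leading and trailing cells migrate with different efficacy.
Slowing the leading cells compresses the column and lets neighbouring
rosettes fuse; slowing the trailing cells stretches it and can split a
rosette in two. This package implements two complementary mechanics models of
that balance — a local activation / long-range inhibition system realized
purely mechanically — together with the cluster readouts used to quantify
them.

## Model 1: spring-linked agent column (ABM)

`run_abm()` simulates a column of point agents ("turtles") on a continuous
2-D plane, 5 wide and 30 long (150 agents), the long axis being the
migration axis. The leading 60% of the column are WNTERs (Wnt-active leading
domain, speed `w = 0.018` grid units per step), the trailing 40% FGFERs
(`f = 0.016`). Each step:

1. WNTERs and FGFERs advance by their speed along +x; DEPOSITERs do not move.
2. Links are removed stochastically at the turnover rate and whenever longer
   than their break threshold.
3. New links form between unlinked pairs within link radius.
4. One spring-relaxation sweep: every linked pair at distance $l$ receives an
   attractive displacement $s\,(l - L)$ along the link (spring constant
   $s = 0.18$, rest length $L$), and every pair within link radius an
   inverse-square repulsion $r/l^2$. Displacements are applied symmetrically
   and capped per sweep.
5. Optional proliferation (off by default), Wnt-domain shrinkage/deposition,
   and density classification.

The force law is a spring-embedder in the Fruchterman–Reingold spirit:
linear attraction along links, short-range inverse-square repulsion. The
published model constants are the spring constant 0.18, the speeds
0.018/0.016, the 60% leading Wnt fraction, and the permitted primordium
length of 1.6 Wnt-domain lengths. Everything else (link radii, rest length,
repulsion, break thresholds, turnover, the density radius and threshold) is
a calibrated default of this package, chosen once so that the three
differential-speed regimes reproduce their published cluster counts, and
recorded in `abm_params()`.

Two calibrated choices deserve comment:

* **Breed-specific link radius.** WNTERs use a slightly larger link radius
  (2.4) than FGFERs (2.0). The leading domain moves as one block with no
  internal speed differential, and its aggregation into a single dense
  cluster under compression is what converts three clusters into two in the
  slow-leader regime; the larger radius encodes the stronger effective
  coupling of the leading domain.
* **Break threshold above link radius** (2.8 vs 2.0–2.4), so that existing
  links survive moderate stretching and transmit tension/compression along
  the column instead of detaching instantly. DEPOSITERs get a low threshold
  (1.0), so the moving column sheds them — the deposition mechanism.

### Density flag and cluster counting

Aggregation is read out exactly as the model displays it: an agent's
neighbour count within the density radius sets its shade, and the agent is
flagged ("cyan") when the count *strictly exceeds* the density threshold.
`abm_cluster_count()` then takes connected components of flagged agents
(adjacency = within the density radius) and discards components smaller than
`min_cluster_size = 3`. The counting rule itself is an operationalization of
a visual count; its two knobs are exposed and reported alongside every
count.

### Wnt shrinkage and deposition

With shrinkage enabled, the Wnt domain shortens by `wnt_shrink_rate` per
step and the permitted primordium length is maintained at
`length_factor = 1.6` times the current Wnt length, measured back from the
leading edge. FGFERs strictly beyond that limit are re-specified as
DEPOSITERs: zero speed, no proliferation, weak links. The initial Wnt-domain
length is set to the initial column extent divided by 1.6, so the rule holds
exactly from step 0 — the published account states the ratio, not the
initial length.

```{r abm-demo}
sim <- run_abm(abm_preset("abm_fast_leader"), n_steps = 300, seed = 1,
               sample_every = 100)
tail(sim$series, 3)
plot(sim$state, mode = "density")
```

## Model 2: compartmentalized Cellular Potts model (CPM)

`run_cpm()` implements a side-view Glazier–Graner–Hogeweg model on a lattice
that is periodic in x and closed in y. A configuration assigns every pixel
to a cell (0 = Medium); its energy is

$$J=\sum \lambda (v-V)^2+\sum \beta (a-A)^2+\sum_{\text{pairs}} H_{ij} +
\sum_{\text{links}} \lambda_{ij}\,(l_{ij}-L_{ij})^2$$

volume and surface penalties, contact energies summed over unlike-owner
neighbour pixel pairs up to neighbour order 3, and focal-point-plasticity
(FPP) spring links between cell centres of mass. Dynamics are Metropolis
pixel copies: one Monte Carlo step (MCS) is width x height attempts; a copy
with energy change $\Delta J \le h$ is accepted, otherwise with probability
$e^{-(\Delta J-h)/T}$. Migration is an external potential: force-bearing
types add `migration_force_x` times the centre-of-mass x-shift to
$\Delta J$, so negative coefficients favour +x motion. The force term is
kept out of the Hamiltonian itself, which makes the incremental
$\Delta J$ identical to the full-recompute difference — the central
correctness oracle of the test suite.

### Numerical conventions

* Copy candidates are drawn from the order-1 (axial) shell; the configured
  neighbour order 3 governs contact and "region of influence" accounting.
* The surface $a$ of a cell is its count of order-1 unlike-owner neighbour
  pixel pairs; this convention is fixed so the $\beta$ term is reproducible.
* Link lengths use centre-of-mass distances with minimal-image unwrapping in
  x; external links break strictly beyond their maximum length, internal
  (within-composite) links never break, and reformable classes re-form only
  when the two cells touch again.
* Attempts that would annihilate a cell's last pixel are rejected; the model
  has no cell death, and a vanished cell would orphan its links.
* Attempts across the closed y-boundary are skipped; x wraps.
* The energy threshold is `h = 0` (the published account names `h` but no
  value).

### The scene

`build_primordium_scene()` tiles the lattice with frozen muscle (5 cell rows
— thick enough to buffer the bottom boundary), a thin ECM row, a skin row
spanning the lattice, and the primordium between skin and ECM: 10 leading
Wnt cells, 20 trailing FGF cells, 6 superficial sheath cells. Each FGF cell
is a composite of three compartments — apical (small target volume, strong
short apical-apical links: the apical-constriction machinery), lateral, and
basal (force-bearing "feet" on the ECM) — stacked apical-up and joined by
unbreakable internal links. A single bridge link ties the trailing-most Wnt
cell to the leading lateral compartment so the primordium migrates as one
unit. The default lattice is 400 x 150; `scene_spec(800, 300)` builds the
same layout at full scale. Simulation analyses in this package use the
400 x 150 scene with the full cell complement — the rosette count scales
with the number of FGF cells, and the shipped composition is calibrated to
settle at four rosettes.

The contact table follows the stated adhesion logic, checked by
`validate_adhesion_hierarchy()`: each type adheres most to itself;
primordium cells adhere to each other more than to skin or ECM; sheath-skin
and basal-ECM adhesion is strong enough to attach but weaker than
primordium-internal adhesion, so the tissue slides rather than sticks. Two
further calibrated contacts encode apicobasal polarity: apical compartments
prefer the sheath surface and avoid basal ends and foreign lateral
compartments, which segregates apical ends along the top of the tissue where
constriction foci can form.

All type, contact and link values are calibrated defaults of this package —
no published numeric values exist for them; they live in one place each
(`scene_spec()`, `scene_contacts()`, `scene_contacts_internal()`).

The fluctuation temperature deserves a note: the published engine setting is
T = 20, and `cpm_engine_params()` defaults to that value for the bare
engine. The shipped *scene* uses T = 33. With this package's calibrated
contact energies the T = 20 dynamics are glassy — acceptance is below 1% and
rosette rearrangement effectively freezes — whereas T = 33 gives fluid
tissue dynamics with the same energy ordering. Since the contact scale
itself is calibrated rather than published, temperature and energy scale are
only meaningful jointly; we chose to keep the energy table simple and raise
T.

### Scenarios

* `wildtype` — all forces on; the initial single apical chain breaks up
  within a few hundred MCS and settles into four rosettes.
* `stall_leading` — the Wnt migration force is set to zero at the stall
  time (chemokine-guidance loss). Trailing basal/sheath forces stay on
  (the flag `stall_all` zeroes them too for sensitivity runs), the column
  compresses against the stalled front, and rosettes fuse 4 to 3 to 2.
* `stall_then_recover` — force restored later; a fused rosette can split
  again.
* `boost_lat_contractility` — lateral-lateral link strength multiplied
  (default x8) and lateral-lateral contact energy reduced (default -80%) at
  the boost time: rosettes fuse although migration is never impaired.

A run samples rosette counts every `sample_every` MCS;
`detect_rosettes_cpm()` counts connected components of apical compartments
(adjacency = shared order-1 boundary or an active apical-apical link) of at
least `min_apical_members = 3`. A configuration counts as stable when the
rosette count is unchanged over at least 200 MCS; `terminal_count()` reports
the most recent stable stretch of a run, so a flicker in the final samples
does not override a long-established configuration. The first 200 MCS are
excluded as relaxation from the rectangular initial tiling.

```{r cpm-demo, eval = FALSE}
sim <- run_cpm(scene_spec(), "wildtype", n_mcs = 2500, seed = 1)
summary(sim)
plot(sim$state)
```

## What the generators emulate — and what they do not

The scene builders are the package's synthetic-data layer: they produce the
initial conditions the models were defined on (the 5 x 30 agent column with
its 60% Wnt domain; the layered side-view lattice). They emulate tissue
topology, relative domain sizes, and the mechanical couplings described
above. They do not emulate: chemokine or FGF ligand fields (guidance enters
only as a constant force), cell-size heterogeneity, proliferation pressure
in the CPM, three-dimensional packing, or imaging noise. Passing tests
therefore demonstrate that the stated mechanical rules reproduce the stated
cluster phenomenology under these idealized conditions — not that the
parameter values are those of the embryo.

Ensemble sizes in the test suite and acceptance analyses are five seeds per
condition, the desk-scale ensemble: modal cluster counts over five seeds
are stable for the strongly separated regimes, and marginal configurations
are reported as such rather than averaged away. The wild-type settled
rosette count is the most seed-sensitive readout (its settled counts spread
over 3-5), so the acceptance analysis uses an eleven-seed ensemble for that
quantity alone.

## Known limitations

* The agent model does not reproduce NetLogo trajectories; only the rule
  structure and published constants carry over, with the remaining
  parameters calibrated (the slow-leader regime's modal count of 2 at step
  2000 is the most parameter-sensitive readout, sitting near a 2/3 regime
  boundary).
* CPM composite cells can fragment under strong rearrangement: apical ends
  pull out of their stacks to join rosette foci while the basal feet stay on
  the ECM. Real cells stretch instead of fragmenting. This is reported as a
  model-health warning (`composite_health()`), not an error, and does not
  disturb the apical-cluster readout, but renders of late states show
  dispersed compartments rather than neat columnar cells.
* The stalling experiment's fusion is slower than its biological
  counterpart in relative terms: full fusion to two rosettes takes several
  thousand MCS of sustained compression.
* Rosette counting has no notion of a shared apical focus; it is adjacency
  clustering with a size threshold, one defensible operationalization of a
  visual count.
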