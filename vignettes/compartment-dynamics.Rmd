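---
title: "Ordered driver mutations across tissue compartments: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordered driver mutations across tissue compartments: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compclone)
```

## The model

`compclone` simulates the clonal evolution of a cancer cell population
migrating through a chain of tissue compartments — in the packaged case
study, breast duct, circulatory system and bone.  Each cell carries a state
$\sigma = \{\mathbf{d}, m_n, m_m, k\}$:

* $\mathbf{d} \in \{0,1\}^{\bar m_d}$ — which driver genes are mutated
  (here EPCAM, CD47, CD44, MET); loci never revert;
* $m_n$ — the number of non-driver (passenger) mutations, which
  destabilize the cell and lower its stemness;
* $m_m$ — the number of metabolic mutations; every division adds one to
  each daughter, and the cell's internal clock fires at rate
  $\alpha (r + m_m)$, so lineages accelerate as they age;
* $k$ — the compartment the cell occupies.

When a cell's exponential timer expires it performs one of four actions:
asymmetric division (one mutated daughter plus one unchanged-mutation
sibling), symmetric division (two identical mutated daughters), apoptosis,
or migration to compartment $k + 1$.  The mutation carried by a division is
a driver with probability $(\bar m_d - m_d)\,/\,[(\bar m_d - m_d) +
\beta(\bar m_n - m_n)]$ (the $\beta$-weighted share of the remaining loci;
the driver locus is uniform over the unacquired ones), otherwise a
passenger.

Action probabilities are normalized products
$P_\text{act} \propto A_\text{act}\,\chi_\text{act}(s)\,
k_\text{act}(m_e, k)$, where:

* $s = \bar s\, m_d / \sqrt{1 + m_n}$ (clipped into $[0, \bar s]$) is the
  cancer stemness — rising with drivers, falling with passengers,
  independent of the metabolic count;
* $\chi_\text{act}$ is a closed window of width $w$ centred on
  $c_\text{act}$, with the ordering constraint
  $c_\text{asym} < c_\text{sym} < c_\text{apop} < \bar s$ enforced at
  validation (windows may overlap);
* the migration filter $k_\text{pass}$ is 1 only when the cell's
  *effective* driver count $m_e$ reaches the compartment's exit threshold;
  $\chi_\text{pass} = 1$ and $k_\text{asym} = k_\text{sym} =
  k_\text{apop} = 1$.

### Mutation order

The compartment chain defines the "right" order of drivers.  Each
compartment $c_k$ requires a gene set $S_k$; the cumulative unions
$S'_k = \bigcup_{j \le k} S_j$ and increments $S''_k = S'_k \setminus
S'_{k-1}$ partition the loci into ordered blocks, and the exit threshold of
compartment $k$ is $|S'_k|$.  A driver acquired out of order stays
*ineffective* until every driver of all earlier blocks is present: blocks
are scanned in order, complete blocks count fully, the first incomplete
block counts its acquired loci, later blocks count nothing.  Within a block
the acquisition order is irrelevant (CD47 and CD44 are exchangeable).  In
*unordered* dynamics $m_e = m_d$ and only the number of drivers matters.
`ordered_sets()` performs this construction from a compartment graph and
`most_probable_paths()` ranks first-passage paths to the absorbing
secondary sites by the product of their transition probabilities.

We implement effective-driver counting as block-prefix counting rather
than an operator calculus; the observable $m_e$ is the same and the
implementation is directly testable by enumeration.

### Drug perturbation

A drug is a partial state signature
$\sigma_\text{drug} = \{\mathbf{d}_\text{drug}, m_{n,\text{drug}},
m_{m,\text{drug}}, k_\text{drug}\}$ plus a driver-count component
$m_{d,\text{drug}}$.  At $t_\text{drug}$ every cell matching all *nonzero*
components is removed instantaneously; zero components impose no
constraint, so the all-zero signature clears the entire population.
`fraction_targeted()` complements the simulation with exact rational
combinatorics: among all driver vectors with a given $m_d$ that are viable
in a compartment (ordered mode: containing every block required to have
entered it), the fraction matching the signature.  For the CD47-specific
case-3 signature in the circulation this yields 1/4, 1/2, 3/4 (unordered)
and 0, 1/3, 2/3 (ordered) for $m_d = 1, 2, 3$.

## Simulation scheme

The engine is an asynchronous, self-clocked event loop: every cell owns an
independent timer drawn from the exponential law of its own $m_m$, and its
action is drawn at birth (reactions do not compete, so the draw can happen
at the start of the period).  Events execute in time order; an event whose
daughters would leave the truncated state space, overfill a
(compartment, $m_d$) capacity class, or exceed a compartment energy budget
$E = \sum_j e(j) N(j) \le E_\text{max}$ is *put back*: the parent survives
unchanged and redraws both timer and action.

Three consequences of this design are worth recording:

* **Rejection is a thinned exponential race.**  Redrawing timer and action
  from the unchanged distribution is probabilistically identical to
  deleting the invalid transition from a continuous-time generator, which
  is exactly how the master-equation module treats the boundaries.  This
  makes the stochastic and deterministic routes comparable without any
  correction terms.
* **Frozen cells.**  A cell whose every remaining action is *permanently*
  impossible (proliferation blocked by the $m_m$ ceiling or mutation
  exhaustion, zero apoptosis and migration rates) would redraw forever; the
  engine freezes its timer instead.  The observable behaviour — the cell
  persists unchanged — is identical.
* **Ties.**  The drug event is processed before any cell event scheduled at
  the same timestamp, and a recording-grid point coinciding with
  $t_\text{drug}$ reports the post-drug state; cell events otherwise follow
  insertion order.  Rejected events are side-effect-free.

Ensembles derive per-replicate sub-seeds from one master seed, so every
run is bit-reproducible; means and standard deviations are reported per
(compartment, driver count) on a regular recording grid.

## The master-equation oracle

`build_generator()` assembles the sparse linear operator $L$ of the
physical-time equation $\mathrm{d}p/\mathrm{d}t = L\,p$ on the truncated
state space, in two modes:

* `reaction_consistent` (default) derives $L$ from the reaction set
  itself: each division removes the parent and adds both daughters at
  $m_m + 1$ (driver branch uniform over unacquired loci with the
  $\beta$-split weights), apoptosis removes the cell, migration carries
  the filtered rate; outgoing flux at the $m_m$/$m_n$/$m_d$ bounds is
  suppressed, mirroring event rejection.
* `as_printed` transcribes the published equation term for term, including
  its asymmetries: gains carry the $1/\bar m_d$ locus weighting and there
  is no loss term for asymmetric division.  Two transcription choices were
  forced: the symmetric-division driver sum (indexed by the metabolic
  count in the printed equation) is taken over the driver loci, consistent
  with the event-count recursion it derives from; and a stray argument $s$
  in one loss term is read as $t$.  This mode exists for fidelity, not for
  oracle duty.

Integration uses `deSolve::lsoda` (relative tolerance $10^{-8}$); the
equation is linear, so the initial mass at $\sigma_0 = \{\mathbf{0},0,0,1\}$
scales the solution.  The test suite checks both routes against each other
(ensemble means within three Monte-Carlo standard errors at five
checkpoints on a $\bar m_d = 2$, $\bar m_n = 2$, $\bar m_m = 6$, $\bar k =
2$ model with 500 replicates) and against the closed form
$N_0 e^{-\alpha r t}$ in the pure-apoptosis limit.

## The packaged scenarios and their calibration

The three `case*.yaml` fixtures share the breast → circulation → bone
chain, the required sets {EPCAM}, {CD47, CD44}, {MET} (exit thresholds
1, 3, 4) and differ only in the drug: case 1 kills circulating
cells with exactly one driver, case 2 with exactly two, case 3 those
carrying CD47.  The driver genes, their order and the drug signatures
follow the published case study; **every kinetic number does not** — the
source prints no values for the amplitudes, supports, $\alpha$, $r$,
$\beta$, capacities, population sizes or times, so the fixtures use
desk-scale defaults calibrated once to place the qualitative regimes of
the published figures, and are flagged `calibrated, not paper-derived` in
their `provenance` field.  The choices, and why:

* `alpha = 0.25`, `r = 4` — unit base cycle time ($1/\alpha r = 1$) with a
  gentle per-mutation acceleration, and `m_m: 20` so the metabolic ceiling
  is not reached inside the horizon (a lineage needs ~20 divisions);
* `beta = 14`, `m_n: 12` — driver hits are rare relative to passenger
  hits, keeping driver acquisition the rate-limiting step;
* `pass: 10` versus division amplitudes ~1 — migration is fast once
  permitted, so unordered-mode cells leave the breast promptly at one
  driver and two-driver cells form *in the circulation*, where the case-2
  drug can reach them;
* circulation capacity 1 cell per driver class (breast and bone 40) — the
  circulation is a thin conduit rather than a growth niche;
* `t_drug = 2.5`, `t_end = 3.5`, 10 founder cells, 100 replicates,
  seed 20190725.

Under these conditions the ordered dynamics keeps a reservoir of
wrong-order cells in the breast (CD47/CD44/MET carriers without EPCAM)
that the circulation-targeted drug cannot touch; after treatment a single
EPCAM hit releases them through the circulation at three or four drivers.
The unordered dynamics has no such protected reservoir — its progress
lives in the circulating one- and two-driver classes, which the case-2
drug erases — so over the horizon no unordered replicate seeds the bone
while a fifth of the ordered ones do, and in case 1 the EPCAM-gated breast
exit leaves systematically fewer circulating tumour cells under ordered
dynamics.  Because the published figures carry no numeric axes, these are
*ordinal* claims, and the tests state them as paired sign tests over the
100-replicate ensembles rather than as magnitude comparisons.

### What the generator does and does not emulate

The synthetic scenarios reproduce the *structure* of the modelled system:
ordered versus unordered filters, stemness-gated actions, metabolic
acceleration, volume exclusion, instantaneous targeted killing.  They do
not emulate measured rate constants, absolute time scales, realistic
population sizes (tens of cells rather than millions), immune
interactions, or spatial structure within a compartment — the model has no
lattice geometry; cells interact only through compartment-level
constraints.  A green test suite therefore certifies the mechanism and its
internal consistency, not quantitative agreement with any clinical
trajectory.

## Numerical choices and degenerate inputs

* Support windows are closed intervals; a boundary stemness value counts
  as inside.  The stemness surface is clipped into $[0, \bar s]$, since
  the raw $\bar s\,m_d/\sqrt{1+m_n}$ exceeds $\bar s$ for many drivers and
  few passengers.
* A state in which *no* action has a positive rate ("stuck") is reported
  as a configuration error naming the state — it indicates a mis-specified
  scenario, not a valid absorbing state.  In the generator such states
  simply carry no flux.
* Extinction is a valid simulation result (zero curves); queue exhaustion
  before the horizon is treated as extinction.
* Capacity checks apply per event: a symmetric division admits both
  daughters or is put back as a whole.
* `fraction_targeted()` uses exact integer enumeration, guarded to 16
  loci; `most_probable_paths()` enumerates simple paths, guarded to 10
  compartments; `build_generator()` refuses state spaces above a
  configurable limit (default 50 000 states).
* Problem sizes in the tests — 500 replicates for the oracle comparison,
  200 for the closed-form limit, 100 for the case studies, $10^4$ draws
  for the waiting-time law — were chosen as the smallest ensembles whose
  Monte-Carlo resolution cleanly separates the tested effects.

## Known limitations

* Driver, passenger and metabolic mutations are disjoint classes; a
  mutation cannot belong to two classes, and driver blocks cannot share
  genes across compartments.
* The dynamics follows one compartment path at a time; branching migration
  is ranked by the path model but not simulated jointly.
* `as_printed` mode is a transcription, not a self-consistent generator;
  population totals under it drift from the reaction picture by design.
* Whether rejected events should age the cell or carry a penalty is
  unspecified in the source; rejection here is side-effect-free.
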