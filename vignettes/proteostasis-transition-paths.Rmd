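---
title: "Transition-path analysis of a chaperone-mediated proteostasis network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition-path analysis of a chaperone-mediated proteostasis network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoPath)
```

## The question the package answers

Bulk kinetic models of proteostasis evolve the concentrations of every
species in a chaperone network — free client conformers, chaperone
complexes, aggregates — but they cannot say what a *single molecule* does.
When a misfolded protein (M) is eventually corrected back to the unfolded
state (U), did it travel through the DnaK/DnaJ/GrpE (KJE) cycle, through the
GroEL/GroES (GroELS) chaperonin, through aggregation followed by
ClpB-mediated extraction (B+KJE), directly, or was it degraded and
re-synthesised?  `proteoPath` answers this by converting the nonlinear bulk
model into a linear master equation for one tagged molecule and then doing
transition-path analysis on that chain: committor probabilities, conditional
committors, mediation probabilities, and an exact entry-channel
decomposition of reactive paths.

## The bulk model

The network is a reduced mass-action model of the *E. coli* proteostasis
machinery acting on one client protein:

* **Core conformers.** U &harr; N (folding, `k_fold`/`k_unfold`) and
  U &harr; M (misfolding, `k_mis`/`k_unmis`).  Reverse rates are fixed by
  the equilibrium constants: `k_unfold = k_fold/K_fold`,
  `k_unmis = k_mis/K_mis`.
* **Synthesis and degradation.** Synthesis is zeroth order in client with
  bulk flux `r_syn = ribosome_activation_rate * [Rib]` (uM/s), drawn from a
  bookkeeping `Null` reservoir; the Lon protease binds U and M and commits
  them to degradation, returning client to `Null`.  The Null state closes
  degradation to re-synthesis so a tagged molecule has continuous dynamics.
* **Aggregation.** Misfolded monomers nucleate and grow,
  M + M &rarr; A2, A\_n + M &rarr; A\_{n+1} up to `n_max` (default 20, a
  reflecting boundary); every monomer-shedding step runs at
  `k_dis = k_ag * c_crit`.
* **KJE.** ATP-DnaK binds U or M, DnaK-bound misfolded client is unfolded
  (`k_kje_unfold`), DnaJ triggers hydrolysis, and GrpE-catalysed nucleotide
  exchange releases the client unfolded.  The cycle always returns U.
* **GroELS.** ATP-GroEL binds U or M; GroES caps the cavity, inside which
  the client folds and misfolds at the bulk rates; a timed cycle
  (`k_cycle = 0.1`/s, the ~10 s GroES residence) releases the cavity client
  in whatever conformation it reached.  With `double_occupancy` a second
  client can bind the open trans ring and becomes the cis client of the next
  cycle.
* **B+KJE.** DnaK + DnaJ prepare an aggregate (sequestering one of each,
  the coupling that depletes free DnaJ), and ClpB extracts one monomer as U;
  the prepared dimer dissolves into one U and one M.

Chaperone totals default to the standard cellular concentrations (uM):
Ribosomes 20, trigger factor 20, DnaK 30, DnaJ 1 (dimer), GrpE 15, GroEL 42,
GroES 35, Lon 0.3, ClpB 1.8.  Each total is an exactly conserved group,
which the integrator is required to preserve to 1e-6 relative (in practice
machine precision, because conservation is structural in the stoichiometry).

### The four client profiles

```{r}
for (p in profilePresets()) print(proteinProfile(p))
```

The six profile parameters are the biophysics of the client.  The presets
span the characteristic behaviours: *Default* is intermediate; *Slow
Folder* folds five times more slowly into a much more stable native state
and its misfolded state is transient (`K_mis = 0.1`), which is exactly what
makes the chaperonin its best route — in the cavity its M converts to U
quickly and is released unfolded, while free M would rebind faster than it
folds; *Bad Folder* has the most stable misfolded state (`K_mis = 200`);
*Aggregator* misfolds ten times faster, aggregates a hundred times faster
and has the lowest critical concentration, so its fate depends on holder
capacity.

### Rate constants that are not part of the profile

Only the six profile parameters and the chaperone totals are taken as
given.  Every other constant (binding on/off rates, hydrolysis, cycle
timer, preparation/extraction, Lon kinetics) is a package default chosen
once to put the presets in their characteristic regimes — KJE-dominant
correction of misfolded Default protein at low synthesis, GroELS-dominant
correction for the Slow Folder, B+KJE usage growing with aggregate load —
and every one is overridable through `buildModel(overrides = ...)`.  The
full resolved table is written next to every CLI run, and
`constants(model)` returns it programmatically.  Orders of magnitude follow
the chaperone literature: client-chaperone association at 0.5/uM/s,
dissociation at 1–2/s, catalytic steps at ~1/s, the GroES timer at 0.1/s.

## Integration

`propagateModel()` integrates the stiff mass-action system (rate constants
span more than seven orders of magnitude) with `deSolve::lsoda` and an
analytic Jacobian assembled from the stoichiometry.  The simulation starts
with no client protein and fixed chaperone totals, and runs to the analysis
time `t_eval` (default 1e4 s), by which the native concentration has
equilibrated in all non-runaway regimes; the output grid is logarithmic
with `t_eval` appended exactly.  The synthesis flux uses a smooth switch
`c_Null/(c_Null + eps)` with `eps = 1e-6` uM rather than a hard cutoff:
this keeps the derivative continuous for the stiff solver *and* makes the
tagged-molecule synthesis rate `r_syn/(c_Null + eps)` exactly
flux-consistent with the bulk model, which is what lets the steady-state
cross-check below succeed at machine precision.  The `Null` reservoir
defaults to 1000 uM, sized so it never empties on any shipped sweep.

## The tagged rate matrix

`extractRateMatrix()` builds the generator `K(t)` of one tagged molecule by
freezing all non-client concentrations at `t_eval`:

* unimolecular client steps keep their rate constants;
* bimolecular steps with a partner S become pseudo-first-order with rate
  `k * [S](t)`; for the tagged M dimerising, the partner concentration is
  the bulk `[M](t)` itself (the nonlinear term linearised at the bulk
  composition);
* multi-client complexes are split into one state per tagged position:
  `GrLd:{U,m}:GrS` is a tagged cavity client with a misfolded trans
  partner, `GrLd:{u,M}:GrS` the tagged trans client.  The untagged partner
  is tracked exactly — trans-bound clients are conformationally inert (they
  are held against the ring wall, not in the folding cavity), and the cis
  partner of a trans-tagged client converts at the bulk unimolecular rates.
  This exact tracking makes the tagged fluxes identical to the bulk fluxes,
  with no composition-weighting approximation;
* aggregates keep one state per size (monomers indistinguishable); any
  monomer-removing event carries the tagged molecule out with probability
  1/n, so extraction from a prepared trimer routes `r/3` to U and `2r/3` to
  the shrunken aggregate;
* columns sum to zero by construction (the diagonal is the negative column
  sum).

Because the generator is frozen at one time, the analysis assumes its
elements are constant on the timescale of transition paths.
`frozenMatrixCheck()` quantifies this by recomputing all channel
probabilities from a matrix frozen at `2 * t_eval`; on the default network
the largest channel-probability change is ~5e-6, and at a true steady state
it vanishes.

## Committors by iterative squaring

`buildTransitionMatrix()` discretises with `T = I + tau * K` and
`tau = 1/(2 k_max)`, where `k_max` is the fastest total exit rate.  The
factor one half guarantees diagonals of at least 1/2 (aperiodicity); the
choice is verified irrelevant by the discretisation-invariance tests, which
require committors and channel probabilities to move by less than 1e-6 when
`tau` is halved.  Sinks are installed by zeroing a column and setting its
diagonal to one, and the absorbed distribution is obtained by squaring the
matrix repeatedly until the non-sink mass is below 1e-12 (configurable; at
most 200 squarings, ~30-40 on the shipped network).  One numerical detail
matters: the roundoff in the column sums doubles with every squaring, so
the engine renormalises columns after each squaring; without this the
committor identity q_A + q_B = 1 degrades to ~1e-8 after 36 squarings.
A direct linear solve of the first-step equations is provided as an
independent route and the two are cross-checked to 1e-8 in the tests,
together with an external jump-chain oracle.

Conditional committors run the same absorption on a doubled state space
carrying a visited-C flag, set on first entry into the mediator set (a
start inside C counts as visited); conservation of probability gives
h + hbar = q_B elementwise, which the constructor verifies to 1e-8.

`stationaryWeights()` solves `K w = 0` directly.  At a bulk steady state of
a non-aggregating configuration the tagged construction is exactly
flux-consistent, so `w` reproduces the client-stoichiometry-weighted bulk
concentrations to machine precision — far inside the 1e-3 tolerance the
acceptance suite demands.  (Aggregation is excluded from this check because
one growth event consumes two bulk monomers while the tagged chain tracks
only one, so exact flux correspondence cannot hold there.)

## Pathway decomposition and mediation

Reactive paths — those reaching the target before returning to the source —
are classified by the edge through which they *first enter* the target.
For M &rarr; U the entry edges partition into five channels: direct
conversion (from free conformers), release from KJE complexes, release from
GroEL complexes, extraction from aggregates (B+KJE), and re-synthesis from
Null (degradation).  The partition is exhaustive and mutually exclusive, so
no tie-breaking is needed for paths touching several systems.

The entry-edge convention and the paper-style mediation probability
(fraction of reactive paths visiting a system's states, from conditional
committors) agree exactly for KJE, whose complexes release only U.  For
GroELS they differ by a real mechanism: a client that folds inside the
cavity is released *native* and re-enters U through the N &rarr; U edge,
which the entry-edge convention books as direct.  Mediation therefore
bounds the channel probability from above, and the difference measures the
native-release detour.  Both numbers are reported; the tests assert the
exact KJE identity and the GroELS inequality rather than a spurious
equality.

Channel fluxes (uM/s) weight the same absorption probabilities by the
source concentration and first-hop rates; for the folding decomposition
(U &rarr; N) the direct-channel flux reduces exactly to `k_fold * [U](t)`,
because any other route to the U &rarr; N edge would have to revisit the
absorbing source first.

## Stochastic validation

`sampleFirstPassagePaths()` draws exact continuous-time jump-chain paths on
the frozen generator (next state proportional to off-diagonal rates,
exponential holding times), each path independently seeded from the global
seed and its index.  Channel fractions, mediation frequencies and
committors estimated from 1e5 paths agree with the matrix computations
within three binomial standard errors on the full default network; the mean
number of visits to transient states matches the fundamental-matrix
prediction on small chains.

## Study conditions and problem sizes

The shipped analyses use: the four preset profiles; synthesis sweep over
ribosome activation rates 1e-6 to 1e-3 /s (four decades, log-uniform, the
default condition being 1e-4 /s); binding-factor grid 1–8 for the
crossover scan (GroEL on-rates multiplied, DnaK on-rates divided by
lambda); capacity factors 1/8 to 1 at a high synthesis rate (3e-3 /s),
where holder capacity limits the Aggregator and the class-III distinction
appears.  The tagged state space has 67 states at `n_max = 20` with double
occupancy, so all matrix work is dense and a full pipeline run takes well
under a second; the complete acceptance computation is ~30 integrations
plus 5e4 sampled paths.

## Design choices at genuinely open points

* **Lon substrate range.** Lon binds U *and* M (same constants).  If Lon
  bound only U, every route from M to Null would pass through U and the
  degradation+re-synthesis channel of the M &rarr; U decomposition would be
  structurally zero; the five-pathway structure requires direct degradation
  of misfolded client, consistent with Lon's known preference for damaged
  and misfolded substrates.
* **Prepared-dimer dissolution.** A2* + ClpB yields one extracted U and one
  residual M (extraction is an active unfolding, passive release is not).
* **Trans-ring occupancy.** Only U and M bind the trans ring, and
  trans-bound clients do not convert until they become cis; native protein
  never binds GroEL.
* **Tagged dimerisation rate.** The tagged M &rarr; A2 rate is
  `k_ag * [M](t)` (the self-reaction linearised with the bulk partner
  concentration).
* **Aggregate boundary.** Growth beyond `n_max` is simply omitted; the cap
  only matters in runaway-aggregation regimes where no steady analysis is
  meaningful anyway.
* **Native yield** reported by experiments counts free N only; cavity-bound
  native protein is transient and tracked separately in `native_total`.

## What the synthetic conditions do and do not show

The model is a self-contained reduction: rate constants outside the client
profile are order-of-magnitude defaults, not a fit to any organism's
measured kinetome; there is one client species, so chaperone competition by
the background proteome is absent (the capacity factor emulates it
indirectly); bacterial growth and dilution, ATP pool depletion and
co-translational folding are not modelled.  Passing tests therefore
demonstrate the correctness and internal consistency of the *analysis
machinery* — generator extraction, committors, decompositions, fluxes — and
the qualitative regime structure of the network, not quantitative rates for
any particular protein.  Applying the machinery to a measured
parameterisation only requires overriding constants.

```{r}
model <- buildModel(proteinProfile("Default"), chaperoneLevels(),
                    modelOptions())
traj <- propagateModel(model)
st <- stateAt(traj, 1e4)
K <- extractRateMatrix(model, st)
decomposeTransition(K, "M", "U", state = st)
```
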