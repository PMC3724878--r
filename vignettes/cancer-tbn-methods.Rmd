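---
title: "Methods: threshold Boolean dynamics of the integrated cancer network"
author: "cancerTBN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold Boolean dynamics of the integrated cancer network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cancerTBN)
```

## The model and its assumptions

A threshold Boolean network assigns every protein a binary activity
`s_i ∈ {0, 1}` and updates all nodes simultaneously:

$$ s_i(t+1) = \sigma\Big(\sum_j a_{ij}\, s_j(t) - \theta_i\Big),
   \qquad \sigma(x) = \begin{cases} 1 & x > 0 \\ 0 & x \le 0.\end{cases} $$

Three modeling commitments are baked in:

* **Strict threshold, ties deactivate.** `σ(0) = 0`. This single convention
  makes the two standard rule archetypes work without extra machinery: a
  node with only inhibitory inputs and threshold −1 is active exactly when
  its inhibitors are silent, and a binary protein complex with threshold +1
  and two +1 inputs forms only when both components are active (one active
  component gives a tie, which deactivates).
* **One shared time scale.** All interactions — phosphorylation,
  transcription, degradation — take one step. Periods and transients are
  therefore qualitative orderings, not durations.
* **Exact integer arithmetic.** Strengths and thresholds are integers and
  the update accumulates integers; no floating point enters the dynamics, so
  trajectories are bit-reproducible across platforms.

Input nodes (the microenvironment) and clamped nodes (mutations, drugs) are
held fixed; everything else is free. Because the state space is finite and
the map deterministic, every trajectory enters a fixed point or limit cycle;
`findAttractor()` detects the first revisit with a hash map of visited
states (transients on the built-in network are a few dozen steps, far below
the default `maxSteps = 1000`). Limit cycles are canonicalized by rotating
the cycle to start at its lexicographically smallest state, so the same
cycle reached through different transients gets one identity key.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `strength` | ±1 | interaction sign/weight; a handful of ±2 exceptions in the built-in model |
| `threshold` | 0 | activation threshold; special values mark constitutive, complex-forming or strongly gated nodes |
| `pLevels` | 0, 0.1, …, 1 | stratified initial-state activation probabilities |
| `samplesPerLevel` | 10,000 | initial states per p-level per environment |
| `maxSteps` | 1,000 | revisit-detection cap |
| overexpression `scale` | 2 | factor on the mutated node's outgoing strengths |

All quantities are dimensionless. The stratified protocol draws each free
node independently Bernoulli(p) at eleven equally spaced levels; it
deliberately over-weights sparse and dense corners of state space relative
to uniform sampling, so basin fractions are defined with respect to this
mixture. Where a ground-truth comparison is wanted (tests), sampling at the
single level p = 0.5 recovers the uniform distribution and converges to the
exhaustive enumeration (`enumerateAttractors()`, exact up to 24 free nodes).
The default of 10,000 states per level keeps the binomial standard error of
a basin fraction below 0.003 at percent scale; the packaged tests and the
acceptance script use 150–10,000 per level depending on how small the
fractions they assert are.

## The built-in cancer network

`cancerNetwork()` loads a 96-node, 249-edge integrated model of the
PI3K/AKT, MAPK/ERK, WNT/β-catenin, TGF-β/SMAD, HIF-1, NF-κB/TNF, p53/ATM-ATR,
apoptosis and cell-cycle pathways with five microenvironment inputs
(carcinogens, growth factors, nutrients, TNF-α, hypoxia — that order defines
the 5-bit environment code, most significant bit first). The node and edge
tables ship as TSV under `inst/extdata/cancer_network/` together with
`PROVENANCE.md`, which separates printed sources (node/edge counts, the five
exceptional ±2 strengths, the special-threshold comments) from curation: the
full edge list is a **reconstruction** assembled from the published pathway
composition, canonical pathway biology, and the published behaviors, not a
verbatim copy of an available rule list. Where the printed threshold
groupings conflicted with the printed behavioral comments, the comments won;
the deviations (Ras −1, Rb −1 with p21/p27 support, p53 0 with positive
autoregulation, CyclinE +1 requiring Myc/Max) are listed there with their
rationale.

The cell-cycle core is a threshold rendering of the standard logical
mammalian cell-cycle model: CyclinD integrates mitogenic, WNT and MYC input
against GSK-3; Rb and p27/p21 gate E2F and CyclinE; the E2f/CyclinE complex
licenses CyclinA; and the CyclinB–Cdc20–Cdh1–UbcH10 module closes the
oscillation. The p53 hub uses positive autoregulation with Mdm2 opposition:
under hypoxia or DNA damage p53 latches stably on, in unstressed cells it
decays, and under simultaneous damage and growth signaling the latch races
the PI3K/MAPK-driven Mdm2 shield — the source of the small, basin-limited
driver-mutation efficacies and of the rare proliferative escape under
genotoxic, mitogenic conditions.

## Phenotype calls

* **Apoptotic**: caspases active in at least one cycle state (default
  `caspaseMode = "any"`; apoptosis is treated as irreversible once the
  effectors fire). An `"all"` mode exists; the two agree on every built-in
  attractor, which a regression test asserts.
* **Proliferative**: limit cycles in which every cyclin is active at least
  once and the switch-on events (0→1 transitions within the canonical
  rotation) follow the cyclic order D, E, A, B. Cyclins constantly active
  along the cycle have no switch-on event and are excluded from the
  ordering; fixed points are never proliferative.
* **Quiescent**: everything else — cyclins silent or mis-ordered.
* Traits are read off marker nodes constant along the attractor:
  glycolytic (Hif1 active under normoxia; not evaluated under hypoxia),
  immortalized (hTert active), migratory (E-cadherin inactive — inactive in
  *every* cycle state, the conservative reading), mutator (Atm/Atr silent
  while the DNA-damage node is on). A trait whose marker oscillates is
  reported under an `oscillating` qualifier rather than guessed.

## Mutations, therapies and DNA-damage bookkeeping

Mutations clamp constitutively (activation → 1, deletion → 0) and
overexpression additionally doubles the node's outgoing strengths — outgoing
only, matching the interpretation of increased interaction strength with the
node's targets. Interventions are the same clamps applied as drugs, plus
input forcing (anti-VEGF = hypoxia on, nutrients off). Conflicting clamps
raise errors unless explicitly overridden (wild-type reintroduction on a
deleted node is an override).

Two DNA-damage bookkeeping modes mirror the biology of integrity sensing:
`auto_on` clamps the DNA-damage node to 1 as soon as any mutation is present
(intact sensors; the default for `driverScreen()`), and `forced_off` clamps
it to 0 (defective sensors; the driver repertoire grows, which a test
asserts). `carcinogenesisRun()` instead defaults to `free`, leaving the
damage node under control of the carcinogens input: the mutation-accumulation
protocol sweeps all 32 microenvironments, and its published stage behaviors
contrast plain normoxia/nutrients against explicitly genotoxic environments
— a contrast that only exists if damage follows the environment rather than
being clamped.

The colorectal default sequence is Apc deletion with Tcf interactions
strengthened ×2 (the strengthening factor is a configurable stand-in for the
published but not numerically recoverable value), then Ras activation, Smad4
deletion, Pten deletion with Akt strengths doubled, and p53 deletion.

## Topology conventions

`topologyReport()` computes degree distributions on the directed graph and
offers two clustering conventions. The default counts directed links among a
node's (undirected) neighbours over k(k−1) ordered pairs, whose null
expectation is the directed density m/(n(n−1)) ≈ 0.027 for the matched
96/249 random ensemble — the convention consistent with the published null
value; the classic undirected projection is available by flag. Path length
averages over connected pairs of the undirected projection (disconnected
pairs are counted and reported); betweenness defaults to the directed graph,
since driver ranking concerns signal flow. The null ensemble (default 1,000
replicates) supports fixed-edge-count and per-edge-probability sampling; the
latter exists because the published ensemble reports a fluctuating edge
count.

## What the tests do and do not show

The property-based suite (oracle equivalence of sampled versus exhaustive
basins, attractor closure, canonical identity, clamp invariance, census
conservation, determinism, serialization round-trips) validates the
*simulator* on randomly generated threshold networks and holds regardless of
any curation. The reproduction suite validates the *reconstruction* against
the published behaviors: the wild-type responses in the canonical
microenvironments, the bistable stress responses, the colorectal stage
progression, the hypoxia evasion screen and the sub-percent normoxia driver
regime all reproduce; the characteristic path length (3.34 vs 3.14),
clustering coefficient (0.15 vs 0.178), the 99.8% apoptotic share of
environment 11000 (measured 100%), and the exact percentages of several
screen entries do not, and the corresponding acceptance assertions are left
failing rather than loosened — they depend on the unpublished edge-level
details that the reconstruction cannot recover. Passing tests therefore
certify the dynamics engine exactly, and the built-in model qualitatively.

Because initial states are synthetic Bernoulli draws, none of this says
anything about how often real cells visit particular expression states; the
basin fractions are a measure on state space under the stated protocol, not
frequencies in a tissue.

## Known limitations

* Synchronous updating can manufacture rotating-wave limit cycles that no
  asynchronous scheme would sustain; the curation deliberately breaks such
  loops in the wild-type network, but perturbed variants may still create
  them. No asynchronous or probabilistic semantics are provided.
* Strength scaling rounds to integers; fractional scales that would zero an
  edge raise an error instead of silently deleting it.
* Exhaustive enumeration is capped at 24 free nodes; beyond that only the
  Monte Carlo protocol applies.
* The built-in network is a reconstruction; edge-level statistics (path
  length, clustering) and fine-grained screen percentages differ from the
  original model even though counts, special values and the behavioral
  repertoire match.
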