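---
title: "Threshold Boolean networks of the fission yeast cell cycle: models and methods"
author: "PombeCycleBN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold Boolean networks of the fission yeast cell cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PombeCycleBN)
```

## The model class

A network consists of binary nodes connected by signed edges of unit weight.
All nodes update synchronously by the threshold rule: node $i$ switches on at
$t+1$ when its signed input sum $\sigma_i(t) = \sum_j w_{ij} S_j(t)$ exceeds
its threshold $\theta_i$, switches off when the sum falls below, and at exact
equality either decays to 0 (*self-degrading* nodes) or holds its previous
value. This equality behaviour is not a technicality — it is what makes the
biology work: Ste9, Rum1 and Wee1/Mik1 hold themselves on through the long G1
arrest (their inputs cancel to zero there), while the Start signal and the
start kinases, which self-degrade, flash on for a single step. Unit weights
keep all tuning in the thresholds and flags, which in turn makes exhaustive
parameter recovery tractable (below).

Three mechanisms extend the plain threshold rule:

* **Clamps.** A clamped node ignores its dynamics and keeps a constant value.
  Cdc10 is clamped on: its activity is regulated by phosphorylation, not by
  expression level, and it shows no level changes across the cycle. Its
  documented regulation of Cig2 and Mik1 is carried by the core rules already
  and adds no separate dynamics in the bundled models.
* **Gated edges.** An edge may be tied to a state pattern and contributes to
  $\sigma$ only while the pattern matches. The Atf1 → Cdc2/Cdc13 activation
  at the G2/M transition is such an edge.
* **Event rules.** After the threshold stage (and clamps), every rule whose
  trigger pattern matches the state at $t$ forces its assignments at $t+1$,
  higher priority last. Two fired rules of equal priority that can assign the
  same node are rejected at validation time, so stepping is a pure function.

### Why exact-pattern gating rather than phase bookkeeping

The extension's biology is phrased in phase language ("phosphorylated during
G2/M", "dephosphorylated at mitotic exit"), which is ambiguous as an update
rule: does the phase of $t$ or of $t+1$ gate the effect? The package instead
anchors every phase-specific effect to the *exact core state* of the relevant
table row (the ten oscillator states double as the phase table). This makes
the dynamics deterministic and checkable cell-for-cell against the printed
tables; phase labels remain pure annotation. Alternative timings that also
reproduce the tables exist, and this encoding deliberately does not try to
distinguish between them.

### Why events override rather than add

The extra Rum1 activation by Sep1/Fkh2 during M phase cannot be expressed as
additive ±1 edges: at the M-phase state Rum1 faces simultaneous repression,
and a unit activation cannot outweigh it on any admissible threshold. The
extension is described as *rules*, and the engine treats it as such: forced
assignments that override the threshold result for the assigned nodes only.
For the same reason the substrates Sep1, Fkh2 and Atf1 have no in-edges at
all — they latch (hold) between events, which reproduces their printed
on/off plateaus.

## The bundled variants

| variant | nodes | events | golden table |
|---|---|---|---|
| `core` | 12 | none | table5.tsv |
| `final` | 16 | phosphorylation + Rum1 activation | table6.tsv (12 columns) |
| `phospho` | 16 | same network as `final` | table7.tsv |
| `phospho_dephos` | 16 | + Fkh2 S-phase and mitotic-exit dephosphorylation | table8.tsv |
| `phospho_dephos_restart` | 16 | + Cdc10-driven cycle restart | table9.tsv |

Decisions that were genuinely open, and how they were settled:

* **Atf1 → Cdc2/Cdc13 gate.** Gated on the *first* G2/M state only; gating on
  both G2/M states would hold Cdc2/Cdc13 on one step too long and break the
  12-column golden run. As shipped the edge is trajectory-neutral: it
  documents the reported wiring without changing the printed dynamics.
* **Fkh2 dephosphorylation "during S phase".** The phase table has no S row;
  the event is anchored to the first G2 state, the only anchoring that
  re-activates Fkh2 by step 5 as printed.
* **Mitotic exit in the restart variant.** The restart event (late-M trigger)
  carries the Sep1/Atf1 reset itself. The pure-G1 mitotic-exit trigger is
  still present but can never fire there, because the restart switches Start
  on before the G1 state is reached — which is exactly why the two printed
  dephosphorylation timings (reset visible at $t=11$ without restart, at
  $t=10$ with it) differ; both are reproduced as printed, per variant.
* **Phosphorylation effect signs.** Defaults are Sep1: activation, Atf1:
  activation, Fkh2: inhibition (dephosphorylation events restore the
  opposite value). `buildModel(..., effects =)` toggles each substrate
  between activation and inhibition; toggled models are validated but have
  no golden table — their behaviour is defined, not asserted.
* **Fkh2's reported negative effect on Sep1-dependent genes is not
  modelled**, matching the source model's own choice.
* **Cdc2_Tyr15** is treated as an opaque node (fitted inputs +Cdc25,
  −Wee1/Mik1); whether it denotes the Tyr15-phosphorylated or the
  high-activity species is left open.

## Recovering the unprinted rule table

The core model's thresholds and flags are not printed anywhere; only the
topology (edge signs, self-degradation loops) and the trajectory are. They
are recovered by `fitNodeRules()`: the 19-row core table yields
$(19-1)\times 12 = 216$ transition constraints, each node is independent, so
an exhaustive per-node search over grid × {self-degrading, not} suffices.

* **Grid {−1/2, 0, +1/2}.** The smallest grid on which the topology admits a
  fully consistent solution (Cdc2/Cdc13 needs the default-on threshold
  −1/2). Half-integer thresholds never equal an integer input sum, removing
  equality cases for those nodes. The grid is an argument, not a constant.
* **Tie-break for the shipped fixture.** Several nodes admit more than one
  consistent parameterisation (e.g. a node whose input sum never hits 0 is
  indifferent between thresholds). The shipped model picks $\theta = 0$
  where possible, then minimal $|\theta|$; self-degradation is searched only
  for nodes drawn with degradation loops. The test suite re-runs the fit and
  asserts the shipped values are in every node's consistent set.
* Edge signs are fixed by the topology and never searched; learning topology
  from data is out of scope.

`expandToLogic()` unfolds a fitted rule into an explicit truth table (adding
the node's own previous value as an input exactly when the hold case is
reachable) and a canonical full-DNF string; it is checked against the
threshold rule input-combination by input-combination.

## Attractors and basins

`detectAttractor()` iterates with a hash of visited states; the first repeat
closes the cycle. `enumerateStateSpace()` computes the successor of all
$2^N$ states in one vectorised pass, then applies pointer doubling
($f \mapsto f \circ f$, $N$ times) so every state maps to a state on its
attractor cycle; cycles are walked once and basins tallied. Basin sizes
therefore sum to $2^N$ by construction of the assignment — the tests assert
it as an output invariant on seeded random networks, and cross-check the
per-state assignment against an independent brute-force walk. Enumeration
refuses networks above 20 nodes (memory grows as $2^N$); the bundled models
need at most $2^{16}$.

## Enrichment

`foldEnrichment(k, n, K, M)` is the ratio of fractions $(k/n)/(K/M)$; with
the published counts (28 of 40 target genes oscillating, ~2000 of ~5000
genome genes) it gives 1.75. The source analysis reports no significance
test, so the exact hypergeometric upper tail (summed point probabilities,
verified against complete subset enumeration for $M \le 12$) is off by
default and clearly an addition of this package. The background counts are
approximate in the literature; the function treats them as exact inputs.

## Random networks and what the tests show

`randomNetwork()` draws Erdős–Rényi-style signed threshold networks
(independent directed edges, fair ± signs, thresholds uniform on the default
grid, no self-loops, no gates or events) purely as property-test material:
determinism, binary closure, basin conservation and
detection/enumeration agreement are checked on them under fixed seeds.
These generated networks emulate the *model class*, not fission-yeast
biology — passing says the engine's algebra is right, not that any random
network means anything. Conversely, everything biological in the package is
asserted against the printed golden tables, which are bundled as
transcribed TSV fixtures (the one header inconsistency in the originals,
"Puc1/Cdc" for "Puc1/Cdc2", is normalised).

Problem sizes used by the shipped tests: exhaustive state spaces up to
$2^{10}$ states, per-state agreement checks up to $2^7$, truth-table
oracles up to $2^8$ rows per node, trajectories up to ~100 steps — the
whole suite runs in seconds on one CPU.

## Known limitations

* Synchronous, deterministic semantics only: no asynchronous or stochastic
  updating, no multi-valued logic, no ODE semantics.
* Event triggers are exact patterns; a model whose "phases" are not
  identifiable from the core state cannot be expressed this way.
* `expandToLogic()` refuses nodes with gated in-edges (their rule is not a
  function of their inputs alone).
* Knockout/overexpression screens are not shipped as an analysis, though
  clamps make them easy to compose.
* The GO-term statistics of the original study depend on an external
  annotation-database snapshot and are deliberately not reproduced; only
  the generic enrichment arithmetic is.
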