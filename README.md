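# PombeCycleBN

Threshold Boolean network models of the fission yeast
(*Schizosaccharomyces pombe*) cell cycle oscillator, and a general engine
for simulating and analysing such networks.

The cell cycle of fission yeast is driven by a small autonomous oscillator
centred on the cyclin-dependent kinase complex Cdc2/Cdc13 together with its
activators (Cdc25, the start kinases Cig1/Cdc2, Cig2/Cdc2, Puc1/Cdc2) and
repressors (Ste9, Rum1, Slp1, Wee1/Mik1, PP). The package implements this
core oscillator as a 12-node synchronous threshold Boolean network, and
extends it with the Cdc2/Cdc13 phosphorylation substrates that are
themselves transcription factors — Sep1, Fkh2, Atf1 and the constitutively
active MBF subunit Cdc10 — whose target genes feed back onto the oscillator.
Phase-specific regulation (phosphorylation during G1/S or G2/M,
dephosphorylation at mitotic exit, cycle restart by Cdc10) is encoded as
event rules gated on exact cell-cycle-phase states, and the bundled model
variants reproduce the published temporal-evolution tables of the core and
extended models cell-for-cell.

## The model

Each node *i* carries a binary state *S<sub>i</sub>(t)*. Every edge *j → i*
has weight *w<sub>ij</sub>* = +1 (activation) or −1 (repression), and may be
*gated*: it contributes only while the network state matches an associated
pattern. All nodes update simultaneously:

- *S<sub>i</sub>(t+1)* = 1 if Σ<sub>j</sub> *w<sub>ij</sub> S<sub>j</sub>(t)* > θ<sub>i</sub>
- *S<sub>i</sub>(t+1)* = 0 if the sum is below θ<sub>i</sub>
- at exact equality, a *self-degrading* node decays to 0, any other node
  holds its previous value.

Clamped nodes (Cdc10) keep a fixed value. After the threshold update, every
event rule whose trigger pattern matches the state at time *t* forces its
assignments at *t+1*, higher priority last. Thresholds of the bundled core
model live on the grid {−1/2, 0, +1/2} and were recovered from the printed
core trajectory by exhaustive per-node constraint search (`fitNodeRules()`),
which the test suite re-runs.

Beyond simulation the package provides attractor detection with cycle
closure, exhaustive state-space enumeration with basin-of-attraction sizes
(basins always sum to 2^N), trajectory-versus-table validation, expansion of
threshold rules to explicit truth tables/DNF, fold-enrichment arithmetic
with an exact hypergeometric tail, a plain-text network format, GraphML
export and a command-line interface.

## Worked example

```r
library(PombeCycleBN)

net <- buildModel("core")
net
#> BooleanNetwork with 12 nodes, 25 edges, 0 event rules
#>   core: 12  substrate: 0  clamped: 0
#>   nodes: Start, Cig1/Cdc2, Cig2/Cdc2, Puc1/Cdc2, Cdc2/Cdc13, Ste9, Rum1, ...
#>   phase table: 10 patterns

traj <- simulateNetwork(net, steps = 18)
df <- as.data.frame(traj, phases = TRUE)
df[1:10, c("Time","Phase","Cdc2/Cdc13","Ste9","Rum1","Slp1","Cdc25","PP")]
#>  Time Phase Cdc2/Cdc13 Ste9 Rum1 Slp1 Cdc25 PP
#>     1 Start          0    1    1    0     0  0
#>     2    G1          0    1    1    0     0  0
#>     3  G1/S          0    0    0    0     0  0
#>     4    G2          1    0    0    0     0  0
#>     5    G2          1    0    0    0     1  0
#>     6  G2/M          1    0    0    0     1  0
#>     7  G2/M          1    0    0    1     1  0
#>     8     M          0    0    0    1     1  1
#>     9     M          0    1    1    0     0  1
#>    10    G1          0    1    1    0     0  0
```

The run walks the cycle Start → G1 → G1/S → G2 → G2/M → M and settles in the
G1 state, where Ste9, Rum1 and Wee1/Mik1 stay latched on — the oscillator's
fixed point. Rows 1–10 are the ten distinct oscillator states; simulating
further repeats row 10. The variant with phosphorylation effects,
mitotic-exit dephosphorylation and Cdc10-driven restart instead settles into
a period-9 limit cycle:

```r
detectAttractor(buildModel("phospho_dephos_restart"))
#> Attractor: cycle of length 9
```

Enrichment of oscillating expression among the 40 transcription-factor
target genes (28 oscillate, against ~2000 of ~5000 genome genes):

```r
foldEnrichment(28, 40, 2000, 5000, pValue = TRUE)
#> Enrichment: 28/40 in subset vs 2000/5000 background; fold = 1.75
#>   exact hypergeometric P(X >= 28) = 0.000112421
```

(The fold value is the headline statistic; the exact tail probability is an
optional extra of this package.)

From the shell, via the wrapper in `inst/scripts/`:

```sh
pombecycle run --model phospho_dephos --steps 18 --out traj.tsv --phases
pombecycle validate --model core --table inst/extdata/table5.tsv
pombecycle enrich --k 28 --n 40 --K 2000 --M 5000
```

## Bundled data

`inst/extdata/` ships the five model definitions in the package's plain-text
network format (`core.net`, `final.net`, `phospho.net`, `phospho_dephos.net`,
`phospho_dephos_restart.net`) and the golden temporal-evolution tables
(`table1.tsv`, `table5.tsv`–`table9.tsv`) the models are validated against.
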