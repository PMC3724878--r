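# cancerTBN

Threshold Boolean network simulation of integrated cancer signaling.

Cell-fate decisions — proliferate, arrest, or die — emerge from the joint
dynamics of interlocking signaling pathways (PI3K/AKT, MAPK/ERK,
WNT/β-catenin, TGF-β/SMAD, HIF-1, NF-κB/TNF, p53/ATM-ATR, the apoptosis
machinery and the cyclin cell-cycle engine), not from any single gene. This
package is for systems biologists who want to interrogate that logic *in
silico*: which constitutive mutations turn a quiescent cell into a
proliferating one, which let a hypoxic cell evade apoptosis, how driver
mutations accumulate along a carcinogenic route, and what single or combined
targeted drugs do to a fully transformed cell.

## The model

Every protein `i` is a binary variable `s_i ∈ {0, 1}`. All nodes update in
parallel in discrete time by a threshold rule

    s_i(t+1) = σ( Σ_j a_ij s_j(t) − θ_i ),   σ(x) = 1 if x > 0, else 0

where `a_ij` is the signed integer strength of the interaction from `j` to
`i` (positive activating, negative inhibiting; almost all `±1`) and `θ_i` is
the activation threshold of node `i` (almost all `0`). Ties deactivate.
Designated input nodes — carcinogens, growth factors, nutrients, TNF-α,
hypoxia — are fixed by the microenvironment, written as a 5-bit code such as
`"00100"` (normoxia, adequate nutrients, no growth or death signals).

Because the dynamics is deterministic on a finite state space, every
trajectory ends in an attractor: a fixed point or a limit cycle. Attractors
are classified into cell phenotypes from marker nodes: **apoptotic** (active
caspases), **proliferative** (all four cyclins fire, switch-on events in the
cyclic order D → E → A → B), **quiescent** otherwise, plus trait flags
(glycolytic, immortalized, migratory, mutator). Basins of attraction are
measured either exhaustively (small networks) or by a stratified Monte Carlo
protocol: eleven equally spaced activation probabilities `p ∈ {0, 0.1, …, 1}`
and a fixed number of random initial states per level.

Mutations are constitutive: activation clamps a node to 1, deletion to 0,
overexpression clamps to 1 and multiplies the node's outgoing strengths
(default factor 2). Therapies clamp nodes (inhibitors / wild-type
reintroduction) or force input bits (an anti-VEGF agent forces hypoxia and
nutrient depletion).

The built-in 96-node, 249-edge pan-pathway cancer network ships as plain TSV
tables (`inst/extdata/cancer_network/`, with provenance notes; the edge list
is a documented reconstruction — see `PROVENANCE.md` there).

## Worked example

```r
library(cancerTBN)

net <- cancerNetwork()
net
#> ThresholdNetwork: 96 nodes, 249 edges (5 input nodes)
#>   inputs: Carcinogens, GFs, Nutrients, TNFalpha, Hypoxia
#>   model: integrated cancer signaling network

# normoxia + nutrients + growth factors
cen <- sampleBasins(net, "01100", samplesPerLevel = 5000, seed = 42)
cen
#> AttractorCensus: environment 01100, 1 attractor(s), 55000 initial states
#>            key        kind period fraction count
#>  60fffed9b8... limit_cycle      4        1 55000

phenotypeCensus(cen)$primary
#>     apoptotic proliferative     quiescent
#>             0             1             0
```

Every one of the 55,000 sampled initial states flows into a single period-4
limit cycle in which the cyclins fire in order — a growth-factor-stimulated
cell commits to the cell cycle. Dropping the growth-factor bit (`"00100"`)
yields a single quiescent fixed point instead, and hypoxia (`"00101"`) a
single apoptotic fixed point: the wild-type network only proliferates on
mitogenic demand and kills itself under oxygen stress.

In-silico screens build on the same machinery:

```r
# which single mutations let a hypoxic cell evade apoptosis?
s <- driverScreen(net, "00101", target = "non_apoptotic",
                  samplesPerLevel = 1000, seed = 1)
head(s$report[order(-s$report$efficacy), c("node", "kind", "efficacy")])

# the classical colorectal mutation sequence, all 32 microenvironments
reports <- carcinogenesisRun(net, colorectalStages(), samplesPerLevel = 500)
```

`efficacy` is the fraction of sampled initial states driven to the new
phenotype; the colorectal run returns a per-stage, per-environment phenotype
census (the mutation-accumulation trajectory of a transforming cell).

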