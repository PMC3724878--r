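# Provenance of the built-in cancer network tables

`nodes_reconstructed.tsv` and `edges_reconstructed.tsv` encode a 96-node,
249-edge threshold Boolean model of the integrated cancer signaling network
(PI3K/AKT, MAPK/ERK, WNT/beta-catenin, TGF-beta/SMAD, HIF-1, NF-kB/TNF,
p53/ATM-ATR, apoptosis and cell-cycle modules, five microenvironment inputs).
The `_reconstructed` suffix is deliberate: the published model's complete
rule list is not redistributed here, so the edge list is a synthetic
curation — assembled from the published special-value tables, the stated
pathway composition, canonical pathway biology, and the published wild-type /
mutant behaviors — rather than a verbatim transcription. Users comparing
against the original model should expect the same counts, special values and
qualitative dynamics but not an edge-for-edge identity.

## What is carried over from printed sources

- Node count 96, edge count 249, five input nodes, mean connectivity 2.59.
- Input order (defines the 5-bit environment code, MSB first): carcinogens,
  growth factors, nutrients, TNF-alpha, hypoxia.
- Exceptional interaction strengths, all five printed rows (the source
  table's own header says "three" but prints five; all five are encoded):
  Nf-kB -> Bcl-2 +2, Ikk -> Nf-kB +2, Gsk-3 -> CyclinD -2, Rb -> E2f -2,
  Vhl -> Hif1 -2. All other strengths are +1/-1.
- Special activation thresholds follow the printed comments: Gsk-3 -3
  (active in the absence of growth factors), E-cadherin -3, hTert +4,
  p14ARF +3, Hif1 -2 (active under hypoxia), Foxo -2 (active unless Akt is
  over-expressed), Max -2 with in-degree 0 (constitutively active), binary
  complexes (p53/Pten, Myc/Max, Gsk-3/Apc, E2f/CyclinE, Cdh1/UbcH10,
  Smad/Miz-1, p53/Mdm2) +1 requiring both components, only-inhibitory nodes
  (CyclinB, Rheb, beta-catenin, Cdh1, eEf2, Miz-1, Pten, Bad, Bcl-Xl,
  AMP/ATP, ...) -1 so they activate when their inhibitors are silent,
  Apc/Nf1/Smad4/Vhl/Phd -1 constitutive, Akt +1 demanding both of its
  inputs, mTor/Glut1/Ldha/Nf-kB/Myc/Snail +1.

## Curation deviations (threshold group boundaries are ambiguous in the
## printed table; behavior comments were treated as authoritative)

- Ras: -1 (not -2); with constitutive Nf1 -1 this realizes "activated by
  growth factors or by Nf1 inactivation" exactly.
- Rb: -1 with p21/p27 as activators and cyclins/Akt/Erk/Mdm2 as inhibitors
  (a threshold rendering of the standard logical cell-cycle rule); a -3
  threshold with four cyclin inhibitors leaves growth-factor-stimulated
  cells trapped in a quiescent fixed point.
- p53: 0 with positive autoregulation, activated by Atm/Atr, hypoxia, Ampk
  and Jnk, inhibited by Mdm2 and Snail. Mdm2: 0 (activated by p53, Akt,
  Erk; inhibited by Atm/Atr and p14ARF). This pair gives a stable p53
  latch under hypoxia/genotoxic stress, a p53-silent unstressed state, and
  initial-state races that produce the small driver-mutation efficacies.
- CyclinE: +1 (requires E2f together with Myc/Max), which enforces
  hypoxia-induced cell-cycle arrest through Hif1 -| Myc.
- eEf2k, p15, Slug, DNA_damage, Chk1/2 and similar adaptor nodes carry
  threshold 0 defaults.

## Sanity anchors used during curation (all reproduced by the packaged
## model; see the package tests)

- Normoxia+nutrients: one quiescent fixed point (100% of initial states).
- +growth factors: one proliferative limit cycle (100%).
- Hypoxia+nutrients: one apoptotic fixed point (100%).
- Hypoxia+nutrients+growth factors: bistable quiescent/apoptotic.
- Carcinogenic+mitogenic without nutrients (11000): ~100% apoptotic.
- Colorectal mutation sequence stage behaviors and the quintuple-mutant
  apoptotic/proliferative-only repertoire.
- Hypoxia evasion drivers (Akt, Bcl-2, Bcl-Xl, Ikk, Nf-kB, p53, Snail) and
  normoxia proliferation drivers (Egfr, Ras, Nf1, Pi3k, Pten, Nf-kB, Wnt
  partially) with percent-scale efficacies.
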