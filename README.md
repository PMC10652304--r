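# oxsens — oxidation sensitivity scoring of joint proteomes

Oxidative post-translational modifications (PTMs) — carbonylation, advanced
glycation/lipoxidation adducts such as 4-ONE, HNE or carboxymethyl —
accumulate on cartilage proteins with age and osteoarthritis, and senolytic
treatment can shift them in age-dependent directions. Which proteins matter
most when that happens? `oxsens` implements a complete analysis chain that
ranks proteins by the predicted proteome-level impact of adding or removing
one oxidative modification, for proteomics researchers working from
site-level PTM evidence, a STRING-style interaction network, and protein
sequences.

The chain has four quantitative ingredients:

1. **%Δ PTM/site** — for each modified site, the percent change of the
   condition-mean quantity, treated vs vehicle; averaged over a protein's
   modified sites (`ptm_change_table()`), totalled (`grand_sum()`), and
   classified by direction (`sign_census()`).

2. **Calibrated eigenvector centrality** — the dominant adjacency
   eigenvector *E* of the whole interaction network (unit Euclidean norm,
   power iteration), carried unchanged onto the detected-protein subnetwork
   so subnetwork values stay on the whole-proteome scale
   (`eigenvector_centrality()`, `calibrated_subnetwork()`). The subnetwork's
   largest connected component is partitioned with Louvain modularity
   optimization (`louvain_partition()`).

3. **Electrostatic destabilization susceptibility** — a screened-Coulomb
   model of the folding free-energy change from a single charge change.
   With net charges Q_n = C⁺ + 0.4·C_His − C⁻ and
   Q_d = C⁺ + 0.1·C_His − C⁻, Flory radii R_n = 2.24·N^0.392 Å and
   R_d = 1.927·N^0.598 Å, Bjerrum length I_b = 7.13 Å and inverse Debye
   length κ = 0.03 Å⁻¹:

   ΔΔG/kT = I_b(±2Q_d + 1) / [2R_d(1 + κR_d)] − I_b(±2Q_n + 1) / [2R_n(1 + κR_n)]

   The per-protein susceptibility aggregates |ΔΔG| over charge gain and loss
   (`susceptibility()`, `proteome_map()`).

4. **Composite sensitivity score (CSS)** — over the scored set P,
   RSS = minmax(ΔΔG) × minmax(E) and CSS = minmax(RSS), so the top-ranked
   protein scores exactly 1 and the bottom exactly 0 (`compute_scores()`,
   `top_percentile()`, `community_summary()`).

A synthetic-data module (`synthetic_config()`, `simulate_dataset()`)
generates proteomes with controlled charge composition, scale-free networks
with planted hubs, and PTM/LFQ evidence with planted effects, so the whole
chain is testable against known truth without any external download.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data; each stage writes its tables under `results/`. Running them in order:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_ptm_changes.R
Rscript analysis/03_network.R
Rscript analysis/05_scores.R
```

prints, among other things:

```
old arm: grand sum -8116.1 (per protein), -124.8 (per modification); 350 down / 150 up
young arm: grand sum +5113.4 (per protein), +81.7 (per modification); 108 down / 392 up
top 5 centrality: SYN00001, SYN00004, SYN00002, SYN00005, SYN00003
mean centrality: full 0.01521 vs detected subnetwork 0.01815
planted hub CSS ranks: 1, 3, 5, 2, 4
top CSS = 1.00 (SYN00001); scored set 500 proteins
```

Reading this: the generator planted loss-dominated effects in the old
treated arm and gain-dominated effects in the young arm, and the per-arm
grand sums and censuses recover exactly those directions. The five proteins
planted as network hubs *and* charge/length extremes take the five top
composite ranks, with the maximum CSS pinned to 1.00 by the normalization
chain — the end-to-end truth check for the ranking.

Equivalent one-call form:

```r
library(oxsens)
cfg <- synthetic_config(network_model = "planted_hub", n_planted_hubs = 5,
                        extreme_hubs = TRUE, seed = 20)
ds  <- simulate_dataset(cfg, out_dir = "results/synthetic")
res <- run_pipeline(ds$paths$fasta, ds$paths$edges, ds$paths$evidence,
                    lfq = ds$paths$lfq, out_dir = "results/scores", seed = 20)
head(res$summary)
```

The package also bundles a published top-20 CSS ranking from a mouse
osteoarthritis joint study (`css_reference_table()`), used by the census and
membership operations: 12 of its 20 proteins belong to the metabolic stress
response community, and 8 show net oxidative PTM loss in the old treated
condition.

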