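# ecoassembly

Community-assembly inference and co-occurrence network analysis for
microbiome count data.

Microbial communities along environmental gradients — the motivating
case is bacteria in coastal groundwater and reservoir water along a
salinity gradient — are shaped by a mix of deterministic selection,
dispersal and drift.  ecoassembly implements the standard inference
stack that separates these processes from an ASV/OTU count table, a
rooted phylogeny and sample metadata:

* **Diversity and dissimilarity** — rarefaction, Shannon (nats),
  Faith's PD, Bray–Curtis, abundance-weighted β-MNTD, PCoA, one-factor
  PERMANOVA (exhaustive on tiny designs), (partial) Mantel tests,
  haversine distance–decay, SIMPER, presence-overlap counts, and
  taxon–environment Spearman screens with BH correction.
* **Assembly processes** — the Sloan neutral community model
  (`F_i = 1 − I_{1/N}(Nmp_i, Nm(1−p_i))`, one free migration parameter
  `m`, R² allowed negative), and null-model partitioning by
  βNTI = (βMNTD_obs − mean βMNTD_null)/sd βMNTD_null and the
  Bray–Curtis Raup–Crick index, classified per sample pair into
  heterogeneous selection (βNTI > 2), homogeneous selection
  (βNTI < −2), dispersal limitation (RC > 0.95), homogenizing dispersal
  (RC < −0.95) and undominated (|RC| ≤ 0.95).
* **Networks** — Spearman co-occurrence graphs (top-N taxa, |ρ| > 0.6,
  FDR < 0.05), topology reports with relative modularity against
  density-matched random graphs, Zi–Pi keystone classification
  (thresholds 2.5 / 0.62), robustness under random vs targeted
  module-hub removal, and natural connectivity
  `ln((1/N) Σ exp(λ_i))` under node removal.
* **Synthetic data** — a seeded generator producing Yule phylogenies
  with Brownian salinity niches, lognormal metacommunities and
  multi-group count tables under controlled regimes (niche selection,
  Hubbell/Moran neutral dynamics with immigration, drifted per-group
  pools), so every estimator can be validated against planted truth.

## Worked example

Simulate the default three-habitat design (two salinity-filtered
groundwater zones, a neutrally assembled reservoir) and run the
assembly analysis:

```r
library(ecoassembly)

ds <- simulate_dataset(simulation_config(seed = 7))
ds
#> synthetic dataset: 1000 taxa x 27 samples, groups: groundwater_in, groundwater_out, reservoir
#> regimes: groundwater_in=niche, groundwater_out=niche, reservoir=neutral

fit_ncm(ds$counts[, ds$metadata$group == "reservoir"])
#> Sloan neutral community model (sse fit)
#>   N = 3000.0, m = 0.6662, R2 = 0.836, 838 taxa, 9 samples
#>   taxa above/within/below prediction: 136/691/11

bnti <- compute_bnti(ds$counts, ds$tree, n_null = 199, seed = 8)
rc   <- compute_rcbray(ds$counts, n_null = 199, seed = 9)
partition_processes(bnti, rc, ds$metadata$group)
#> assembly partition (within pairs, 0 excluded)
#>            group                 process n_pairs    fraction
#>   groundwater_in   homogeneous_selection      19 0.527777778
#>   ...
#>        reservoir             undominated      32 0.888888889
```

The neutrally assembled reservoir fits the neutral model well
(R² = 0.84) and its sample pairs are overwhelmingly "undominated"
(89%), while the niche-filtered groundwater zones are dominated by
selection — the qualitative contrast this kind of survey reports
between surface water and salinity-stressed groundwater.

Networks come from the same table:

```r
gw <- ds$counts[, ds$metadata$group == "groundwater_out"]
net <- build_network(gw[rowSums(gw) > 0, ], top_n = 200)
top <- topology_report(net, seed = 1)
roles <- zi_pi_roles(net, top$membership)
robustness_curve(net, "targeted", seq(0, 1, 0.1), roles = roles, seed = 2)
```

A full run (simulate → diversity → assembly → network, with a
reproducibility manifest) is one call:

```r
run_pipeline(list(stages = c("simulate", "diversity", "assembly", "network"),
                  out = "run1", seed = 1, n_null = 199))
```

or, from a shell, `Rscript inst/cli/ecoassembly.R all --config cfg.yaml
--out run1 --seed 1`.

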