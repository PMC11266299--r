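# soznet

Channel-level localization of the seizure-onset zone (SOZ) from
multichannel intracranial-EEG-style recordings, for researchers working on
epilepsy surgery planning and functional brain-network analysis.

The method classifies each electrode channel as SOZ / non-SOZ by fusing
two per-channel features:

* **ENCS** (epileptic network connectivity strength). Per 30 s epoch and
  frequency band, pairwise connectivity is the weighted phase lag index

      WPLI = |Σᵢ Im(Cᵢ)| / Σᵢ |Im(Cᵢ)|,   Cᵢ = Xᵢ · Ȳᵢ

  over per-sample cross-spectra of the channels' analytic (Hilbert)
  signals — insensitive to zero-lag volume conduction. The weighted matrix
  is binarized by proportional thresholding (strongest 50% of edges kept)
  and ENCS is the node degree kᵢ = Σⱼ aᵢⱼ, averaged across epochs. SOZ
  channels show elevated ENCS.
* **PE** (persistence entropy). Each channel's first 30 s is delay-embedded
  (Takens; delay by first AMI minimum, dimension by false nearest
  neighbours), the Vietoris–Rips persistence diagram is computed for
  homology dimensions 0–2, and PE is the base-2 Shannon entropy of the
  normalized interval lifetimes. SOZ channels, with their more regular
  discharge-like dynamics, show lower PE.

A stratified 5-fold cross-validated RBF-SVM (C = 0.5) classifies the fused
features; accuracy, precision, recall, F1 and AUC are reported from pooled
out-of-fold predictions. A seeded simulator generates recordings with both
planted contrasts so the entire pipeline is testable without clinical
data.

## Worked example

```r
library(soznet)

rec <- simulate_recording(sim_config(n_channels = 20, n_soz = 4, fs = 200,
                                     duration = 35, seed = 1))
res <- run_pipeline(rec, soz_pipeline_config(tda_max_points = 60))
res
#> <soz_result>
#>   channels: 20 (SOZ 4)   epochs: 1
#>   embedding: tau = 18, m = 6
#>   AC 1.0000  P 1.0000  R 1.0000  F1 1.0000  AUC 1.0000

round(tapply(res$features$encs, res$features$label, mean), 2)
#> FALSE  TRUE
#> -0.42  1.70
round(tapply(res$features$pe, res$features$label, mean), 2)
#> FALSE  TRUE
#>  0.44 -1.77
```

The 20-channel recording plants four SOZ channels sharing a phase-lagged
gamma component plus bursting discharge-like rhythms. The pipeline
recovers both expected contrast directions on the z-scored features —
mean ENCS higher (+1.70 vs −0.42 SD) and mean persistence entropy lower
(−1.77 vs +0.44 SD) on SOZ channels — and the cross-validated classifier
separates the channels perfectly (AUC = 1). At `coupling = 0` the same
pipeline degrades to chance-level AUC.

Individual stages are exported (`preprocess_recording()`,
`band_decompose()`, `slice_windows()`, `balance_soz()`, `wpli_matrix()`,
`proportional_threshold()`, `threshold_sweep()`, `encs()`, `ami_delay()`,
`fnn_dimension()`, `delay_embed()`, `rips_persistence()`,
`persistence_entropy()`, `fit_predict_cv()`, `compute_metrics()`,
`group_compare()`); see the vignette in `vignettes/soz-localization.Rmd`
for the model, parameter defaults and design rationale. A thin CLI over
the same functions lives at `inst/cli/soznet.R`.

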