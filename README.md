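# epicascade

Multi-omic time-course analysis of an acute conditional gene knockout:
from negative-binomial count matrices to persistently dysregulated gene
clusters, and from those clusters to their methylation context, protein
occupancy kinetics and histone-mark trajectories.

The package was built around the adult-*Mecp2*-knockout design — tamoxifen
vs vehicle in FloxCre animals, with WT/Flox/Cre tamoxifen treatment
controls, profiled at 1, 2, 3, 4, 6 and 8 weeks — but every stage is a
plain function over standard formats (counts TSV, BED6 gene models,
bedGraph tracks, BED peaks/repeats) and works for any design of the same
shape.

## What it computes

* **Per-time-point differential expression** — median-of-ratios size
  factors and a transparent NB Wald contrast; DEGs at padj < 0.05,
  |log2 FC| > 0.15, SE < 0.5; treatment-control DEGs subtracted.
* **Persistence** — per gene, Fisher's combined probability over the
  adjusted p series, `X² = −2 Σ ln pᵢ ~ χ²₂ₖ`; a gene is persistently
  dysregulated when the knockout score is < 1e−5, the change reaches 20%
  at ≥ 1 time point, and the treatment-control score is ≥ 0.1. Clusters
  (up/down) by sign of the mean log2 FC.
* **Concordance** — overlap with reference DEG sets: shared counts,
  one-sided hypergeometric overlap p, Spearman rho of shared fold-changes.
* **Methylation** — per-context (mCA/mCT/mCC/mCG) gene-body and 2 kb
  promoter signal, length-normalized, in percent.
* **Occupancy kinetics** — spike-in-normalized metagene counts
  (promoter−2 kb through TES), aKO/control log2 ratios per time point,
  per-gene exponential depletion fits `y = e^{τt}` with
  `τ̂ = Σ tᵢ ln yᵢ / Σ tᵢ²` and half-life ln 2/|τ|, Z-scored histone
  trajectories, and repeat-family RPK tests by chromatin compartment.
* **Bootstrap robustness** — 1000 size-matched disjoint background
  subsamples with Kruskal–Wallis + Dunn per replicate, reporting the
  fraction of replicates significant per comparison, with an internally
  calibrated S1-vs-S2 negative control.
* **Synthetic data** — `simulate_experiment()` generates the full study
  (counts, tracks, occupancy, spike-ins, peaks, repeats) with planted
  ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(epicascade)

ds <- simulate_experiment(cascade_sim_config(), seed = 1)
de <- de_timecourse(ds$rna)
pa <- persistence_analysis(de)
table(pa$records$label)
#>  down  none    up
#>   120  1792    88

ratios <- depletion_ratios(ds$occupancy$counts, ds$occupancy$samples,
                           ds$occupancy$spikein, "MeCP2")
fits <- decay_constants(ratios)
median(fits$half_life[pa$records$label == "none"], na.rm = TRUE)
#> [1] 8.965683
```

The study planted 93 up- and 142 down-regulated genes; the persistence
stage recovers 88 and 120 of them (sensitivity 0.84, precision 0.95 at
this seed) with zero tamoxifen/Cre nuisance genes labeled, and the
background occupancy half-life comes back at ≈ 9.0 days against the
planted ≈ 9-day decay. A file-based run of the same analysis:

```r
dir <- tempfile()
write_fixture(ds, dir)                               # TSVs, BEDs, bedGraphs
run_pipeline(file.path(dir, "config.yaml"), "out")   # one TSV per stage
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/epicascade.R simulate --outdir fixture --seed 1
Rscript inst/cli/epicascade.R run --config fixture/config.yaml --outdir out
```

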