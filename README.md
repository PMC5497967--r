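# afcommnet

Communication-network analysis of multi-electrode atrial fibrillation (AF)
electrograms.

During persistent AF there is no stable activation sequence, so methods
that track wavefront direction or geometry struggle. What remains
measurable is *information sharing*: how strongly the activation pattern
at one recording site constrains the pattern at another. `afcommnet`
implements that analysis for 64-electrode basket-catheter recordings (8
splines x 8 electrodes, 60 s at 977 Hz) and for synthetic recordings its
own generator produces:

1. **Far-field removal** — R peaks are detected on a reference surface
   ECG; the mean QRS-T complex is averaged over all beats and subtracted
   from every basket channel with a per-channel least-squares scale.
2. **Windowed mutual information** — each recording is cut into 5
   consecutive 10-s windows; in each window the mutual information
   `I(X;Y)` (in nats) is estimated for all `(64 x 64 - 64)/2 = 2016`
   electrode pairs with the Kraskov-Stoegbauer-Grassberger k-nearest
   neighbour estimator (`k = 4`),

   `I = psi(k) - 1/k - <psi(n_x) + psi(n_y)> + psi(N)`,

   and the five matrices are averaged.
3. **Network construction** — the averaged matrix is binarized by
   *connection density*: the strongest 10–30% of pairs become undirected
   edges (self-edges excluded), giving one network per density on a
   0.10–0.30 grid.
4. **Network parameters** — number of edges, average degree, giant
   component, average clustering coefficient `C`, characteristic path
   length `L`, and the small-world index `sigma = (C/C_rand)/(L/L_rand)`,
   where `C_rand`, `L_rand` come from an ensemble of 100 Erdos-Renyi
   G(n, m) random graphs matched on nodes and edges; `sigma` is also
   expressed as a z-score against the ensemble.
5. **Group statistics** — paired Wilcoxon signed-rank tests (exact,
   tie-aware, by dynamic programming up to n = 25) compare parameter
   curves between conditions, per density and pooled across the grid.

Because no patient recordings are available, the `synthetic_data` module
is a first-class, tested component: it plants a known coupling network
(each edge is a shared latent activation driver), renders AF-like
quasi-periodic electrograms with realistic cycle lengths (120–240 ms),
adds ventricular far-field contamination locked to a slower RR rhythm, and
lets every downstream stage be validated against ground truth.

## Worked example

Simulate a paired ablation cohort of 12 subjects — at baseline each
subject's field is split into two non-communicating bipartite domains
(fragmented, triangle-free information sharing), after "ablation" the
field couples as a connected ring lattice with 50% stronger coupling —
then run the full pipeline on all 24 recordings and compare the six
network parameters:

```r
library(afcommnet)

cfg <- default_config(seed = 61)
cfg$simulation$n_splines  <- 4      # scaled-down 16-electrode array
cfg$simulation$per_spline <- 4
cfg$simulation$duration_s <- 50
cfg$simulation$ventricular_amplitude <- 0
cfg$densities <- seq(0.1, 0.3, 0.05)
cfg$null_ensemble$size <- 50
cfg$cohort <- list(n_subjects = 12, coupling_factor = 1.5)

run_ablation_experiment(cfg)
```

```
Synthetic ablation experiment (12 paired subjects)
            metric     pooled_p mean_baseline mean_post direction significant
           n_edges           NA   24.00000000 24.000000         0       FALSE
        avg_degree           NA    3.00000000  3.000000         0       FALSE
   giant_component 0.0004882812    9.35000000 14.200000         1        TRUE
            C_norm 0.0004882812    0.07805306  1.839450         1        TRUE
            L_norm 0.0004882812    2.26854199  1.009589        -1        TRUE
 small_world_sigma 0.0004882812    0.07203889  1.804883         1        TRUE
```

Reading the table: edge count and average degree are pinned by the density
threshold, so they cannot differ (degenerate test, `NA`). After ablation
the giant component grows (9.4 → 14.2 of 16 nodes: the network integrates),
normalized clustering rises (0.08 → 1.84: local connectivity appears),
normalized path length falls (2.27 → 1.01: global connectivity improves),
and the small-world index rises (0.07 → 1.80) — each direction significant
at the smallest two-sided p attainable with 12 pairs. This mirrors the
clinical finding the pipeline was built to quantify: successful ablation
rewires AF communication networks toward small-world organization.

Single recordings follow the same configuration interface:

```r
res <- run_pipeline(default_config(seed = 1, output_dir = "out"))
head(res$sweep)   # one row per density: edges, giant component, C, L, sigma, z ...
```

A thin command-line front end with `simulate`, `run` and
`ablation-experiment` verbs lives at `inst/cli/afcommnet.R` (exit codes:
0 success, 2 validation failure, 3 stage failure).

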