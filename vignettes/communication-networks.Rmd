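---
title: "Communication networks from multi-electrode AF electrograms: methods and design notes"
author: "afcommnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Communication networks from multi-electrode AF electrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During persistent atrial fibrillation there is no stable activation
sequence: over a 10-second window the wavefront geometry at any electrode
changes continuously. What *can* be measured robustly is how much
information the activation pattern at one site shares with the pattern at
another site. `afcommnet` treats a 64-electrode basket recording as a
communication network: nodes are the tissue patches under each electrode,
and an edge between two nodes means their electrograms share more mutual
information (MI) than the bulk of electrode pairs. The package implements
the full chain from raw multichannel voltages to paired statistical
comparison of network parameters:

1. ventricular far-field removal by mean QRS-T template subtraction,
2. segmentation into 5 consecutive 10-second windows,
3. all-to-all pairwise MI per window with the Kraskov-Stoegbauer-Grassberger
   (KSG) k-nearest-neighbour estimator, averaged across windows,
4. density thresholding into binary undirected networks (10-30% of the
   strongest edges),
5. six network parameters - edge count, average degree, giant component,
   average clustering coefficient, characteristic path length, small-world
   index - normalized against Erdos-Renyi G(n, m) null ensembles,
6. paired Wilcoxon signed-rank comparison of density-resolved parameter
   curves between conditions.

Because no patient recordings are distributed with the package, a
first-class synthetic-data module generates coupled AF-like electrograms
with a planted ground-truth network, so every stage is testable end to end
and the direction of the clinical ablation effect can be reproduced in
silico.

## The synthetic electrogram generator

Each channel is a quasi-periodic train of biphasic
(derivative-of-Gaussian) deflections, width 10-20 ms, with a per-channel
cycle length drawn from 120-240 ms - the cycle-length range of human AF -
Gaussian activation-time jitter (SD 5 ms) and white amplitude noise.
Defaults mirror the clinical acquisition: 64 channels (8 splines x 8
electrodes, labelled `a1`-`h8`), 60 s at 977 Hz.

Coupling uses a latent-driver model: every edge of the planted network has
its own shared activation train `S_e`, and channel `i` is built as

```
x_i = (1 - max_e c_e) * private_i + sum_{e : i in e} c_e * S_e
```

followed by standardization to unit variance and additive noise. A pair
joined with coupling 1 (and no other edges) is identical up to independent
noise; pairs not joined by an edge share no driver, so two-hop neighbours
stay near-independent. Expected pairwise MI is monotone in coupling
strength, and all channels share the same marginal amplitude family, so MI
differences reflect coupling rather than variance differences.

Ventricular contamination adds a stylized QRS-T complex (dominant R wave,
Q/S troughs, broad T wave, 50 ms before to 400 ms after the R peak) at each
R time of a simulated ventricular rhythm (RR 600-900 ms), scaled per
channel by a uniform factor in [0.5, 1.5] - basket electrodes pick up the
far field with position-dependent amplitude. A synthetic surface-ECG
reference carries the same complexes at unit amplitude.

The paper-scale recordings the generator emulates leave two quantities
unconstrained by the source material: electrogram SNR and far-field
amplitude. Both are surfaced in `sim_config()`; the defaults (noise SD 0.1
of the unit-variance signal, i.e. 20 dB; far-field amplitude comparable to
the atrial signal) were fixed once as plausible for clinical unipolar
recordings and are not tuned per analysis.

What the generator does *not* emulate: biophysical tissue dynamics (no
monodomain model, no rotors), 3-D basket geometry, electrode contact
artifacts, baseline wander, or non-stationarity across the 60-s recording.
Passing tests therefore demonstrate that the *pipeline* recovers planted
information structure under realistic signal statistics - not that the
clinical conclusions of any particular dataset are correct.

## Far-field removal

R peaks are detected on the reference ECG by a 5-25 Hz zero-phase
Butterworth band-pass, an adaptive threshold at 0.5 x the rolling maximum
(2-s blocks), a 250 ms refractory period (the larger of two competing
detections survives), and refinement to the raw-signal apex. The mean
QRS-T template is the pointwise average of all beats fully inside the
record. Subtraction is strictly local: samples outside beat windows are
bit-identical to the input.

The template scale applied to each basket channel is fitted by least
squares. The default fits **one scale per channel pooled over all beats**
(`scale = "global"`). A per-beat fit is available but not default: with a
unit-variance atrial background, the single-beat projection onto the
template has enough variance that subtraction injects more atrial
distortion than it removes ventricular residue (measured ~7% end-to-end RMS
error versus ~3% for the pooled fit at default SNR). Physically, the
far-field amplitude of a given electrode is set by its position relative to
the ventricles and is stable on the time scale of one recording, so a
single scale per channel is also the better model.

## The KSG mutual-information estimator

MI is estimated in nats with the second KSG algorithm: in the joint space
`z_i = (x_i, y_i)` the k nearest neighbours of each sample are found under
the max norm (k = 4 by default, following Kraskov's bias/variance
analysis); `eps_x(i)/2` and `eps_y(i)/2` are the marginal projections of
that neighbourhood; `n_x(i)` and `n_y(i)` count samples within and on the
boundary of the marginal neighbourhoods; and

```
I_hat = psi(k) - 1/k - mean_i[ psi(n_x(i)) + psi(n_y(i)) ] + psi(N)
```

with `psi` the digamma function, evaluated only at positive integers via
`psi(1) = -gamma`, `psi(n+1) = psi(n) + 1/n`.

Numerical choices:

* **Tie breaking.** The estimator assumes continuous marginals; repeated
  values corrupt the counts. A seeded Gaussian jitter of 1e-10 x the
  series SD is added before the neighbour search. In `all_to_all_mi()` the
  jitter is drawn once per channel, which makes the matrix exactly
  symmetric and the whole computation bit-reproducible under a fixed seed.
* **Negative estimates** near independence are reported as-is. Clipping at
  zero would bias the ranking of weak edges, and the density threshold
  downstream only uses ranks.
* **Neighbour search.** A static 2-D KD-tree with max-norm box pruning,
  built per pair; marginal counts are binary searches on the sorted
  marginals with a linear boundary extension so the defining neighbour is
  never lost to floating-point rounding of `x_i + eps`. A full 64-channel
  recording (2,016 pairs x 5 windows at 9,770 samples) completes in about
  two minutes on one CPU.
* **Inputs are raw preprocessed voltages.** KSG is invariant under monotone
  marginal transforms in the large-N limit, so no additional normalization
  is applied by default.

One subtlety worth recording: applied to *purely discrete* data (e.g. 4-bin
labels) with infinitesimal jitter, the KSG estimate does **not** converge
to the discrete MI - within-atom neighbourhoods create spurious structure
and the estimate can exceed the discrete MI by large margins. The estimator
agrees with the plug-in histogram MI when the pair is genuinely
piecewise-continuous (bin label plus within-bin uniform offset), which is
the construction used in the test suite.

## Network construction and parameters

The window-averaged MI matrix (diagonal forced to zero; self-edges
excluded) is binarized by **connection density**: all n(n-1)/2 pairs are
ranked by MI descending and the top `round(d x total)` (half-up rounding;
ties broken by ascending row, column index for platform-stable output) are
kept as edges, for d on a grid from 0.10 to 0.30 in steps of 0.01.
Thresholding by density rather than by an absolute MI value makes topology
comparable across recordings with different overall MI levels.

The six parameters, and the conventions adopted where the standard
definitions leave room:

* **Edge count** and **average degree** are fixed by the density, and serve
  as internal consistency checks.
* **Giant component**: node count of the largest connected subgraph; an
  isolated node is a component of size 1.
* **Average clustering coefficient**: mean local clustering over all
  nodes; nodes with degree < 2 contribute 0.
* **Characteristic path length**: mean geodesic distance. Disconnection at
  low density forces a convention for unreachable pairs, and the choice
  changes the *sign* of what fragmentation does to the metric.
  `"reachable"` (excluding unreachable pairs) makes two disjoint edges have
  L = 1 - fragmentation shortens L, which contradicts its use as a global
  connectivity measure and makes "larger giant component with shorter path
  length" structurally impossible at fixed edge count. The pipeline
  therefore defaults to `"penalized"`: an unreachable pair is counted at
  distance n (one more than any possible geodesic), so that L behaves
  monotonically as global connectivity degrades. `"reachable"` and
  `"giant"` (giant-component-only averaging) remain available, and the
  per-function default is `"reachable"` so the bare metric matches the
  textbook definition.
* **Normalization**: clustering and path length are divided by the mean of
  the same quantity over a null ensemble of 100 uniform G(n, m) random
  graphs with the same node and edge counts (hence the same average
  degree), computed with identical conventions. Degree-sequence-preserving
  rewiring is deliberately *not* used: matching only n and m follows the
  Erdos-Renyi reference model.
* **Small-world index** `sigma = C_norm / L_norm`. Its **z-score** is
  computed against the distribution of the same ratio across the null
  ensemble draws (each draw normalized by the ensemble means). The null
  population defining the z-score is a declared convention of this
  package; a graph drawn from the null itself scores |z| <= 3 in >= 95% of
  draws, and Watts-Strogatz small-world graphs (n = 64, k = 6, p = 0.05)
  score sigma > 1 and z > 2 essentially always.

Null ensembles are seeded deterministically from the analysis seed and the
edge count, so two recordings compared at the same density share the same
ensemble.

## Group statistics

Network parameters are compared between paired conditions with a Wilcoxon
signed-rank test. Zero and missing differences are dropped; absolute
differences are midranked; for n <= 25 the exact null distribution of the
rank sum is computed by dynamic programming over doubled midranks (ties
handled exactly, verified against full 2^n enumeration), above that a
tie-corrected normal approximation with continuity correction is used.
Tests are run at each density point, and the headline p-value is a pooled
test on the per-subject density-averaged parameter - a single test per
panel rather than 21, matching the way single p-values are reported per
comparison in the source analyses. No multiple-testing correction is
applied by default (a Benjamini-Hochberg option exists). Group curves are
summarized as mean with t-based 95% confidence bands.

## The synthetic ablation experiment

`run_ablation_experiment()` builds a paired cohort and asks whether the
pipeline reproduces, in silico, the directional effect of ablation on AF
communication networks: after ablation the giant component and the
normalized clustering coefficient increase, the normalized path length
decreases, and the small-world index increases, while edge count and
average degree are pinned by the density and cannot change.

The default cohort mechanism ("reorganization") encodes the two regimes:

* **Baseline - dissociated domains.** The field splits into two
  non-communicating regions; within a region, sites share information
  densely but without transitive closure (complete bipartite coupling over
  an alternating split). The thresholded networks are fragmented,
  triangle-poor, and have long penalized path lengths.
* **Post-ablation - organized propagation.** The whole field couples as a
  ring lattice with nearest and next-nearest neighbour tiers (the second
  tier carries the triangles), with coupling strengths increased by 50%.
  The thresholded networks are connected and clustered.

Both mechanisms the cohort block supports - reorganizing the planted
topology and uniformly scaling coupling strength - raise the coupling
density/strength of the ground truth from baseline to post, and the
comparison is paired within subject. A design constraint worth recording:
a *uniform* strength increase alone cannot reorder edges within the
planted set (order statistics are invariant), so its only observable
effect is at the planted-vs-noise boundary; reproducing all four
directional effects requires the baseline and post topologies to differ,
which is also the more faithful reading of "ablation rewires the network".

## Problem sizes used by the test suite

The packaged tests and the acceptance script scale the study conditions
down so the full suite runs in minutes while preserving the per-window
sample count where it matters: KSG accuracy is checked at N = 10,000
against the bivariate-Gaussian closed form; planted-network recovery uses
16 channels x 5 ten-second windows at 977 Hz; the ablation experiment uses
12-16 channels, a density grid of 0.10-0.30 in steps of 0.05, 50-graph
null ensembles and 12-20 subjects. The 16-channel grid places the planted
structures at connection densities compatible with the 0.1-0.3 grid, which
was calibrated for 64 channels; this is the main distortion introduced by
scaling down and the reason the synthetic effect sizes are larger than
anything expected clinically.

## Known limitations

* The generator's event-train coupling produces amplitude-mixture MI; it
  does not emulate conduction delays, so the directed structure of
  propagation is invisible by construction (the pipeline is undirected
  throughout; transfer entropy is out of scope).
* G(n, m) nulls preserve only node and edge counts. Degree heterogeneity
  of the empirical networks inflates C_norm slightly relative to a
  degree-preserving null; this matches the declared normalization
  convention, but absolute sigma values should not be compared across
  normalization conventions.
* The small-world z-score convention (ensemble sigma distribution) is a
  package decision where the source analysis left the construction
  unstated.
* At 16 channels and density 0.1 a connected network is impossible
  (m = 12 < n - 1), so low-density rows of scaled-down sweeps necessarily
  show fragmented networks; this is a property of the scale, not a defect
  of the method.
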