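# laminacount

Region-wise neuron counting and survival analysis in histological
cross-sections of the injured mouse spinal cord.

After a contusive spinal cord injury, secondary neuronal death spreads
from the epicenter and abates with rostro-caudal distance, hitting some
Rexed laminae far harder than others. Quantifying that pattern from
two-channel fluorescence sections (a neuronal marker such as NeuN plus a
nuclear counterstain such as DAPI) requires a chain of steps, each with
its own failure modes:

* **detection** — threshold-based segmentation of the neuronal channel
  (with grey-matter masking, nuclear colocalization and a strict
  > 25 µm² particle filter), or post-processing of a pixel-classifier
  probability map (components of p > 0.5, area > 25 µm²);
* **consensus** — matching point identifications from K observers and/or
  automated methods into objects, each with an agreement class
  k ∈ {0..K}, and a Reference Number of Neurons
  RNN = Σ<sub>objects</sub> k/K (equal to the mean per-analyst count);
* **concordance** — Bland–Altman repeatability/reproducibility
  (bias ± 1.96 · sd of paired count differences), Pearson accuracy
  against the RNN, and linear-model screening of repeatability drivers;
* **registration** — thin-plate-spline warps
  f(p) = a₀ + A·p + Σᵢ wᵢ U(‖p − cᵢ‖), U(r) = r² log r², fitted to
  landmark pairs so atlas region polygons can be transferred onto each
  section without deforming the detections;
* **quantification** — sections × regions count matrices, survival as
  percent of the per-region *median* control count, distance profiles of
  the injury gradient, and Kruskal–Wallis group comparisons (chi-square
  or permutation p).

A synthetic-section generator (`build_toy_atlas()`,
`simulate_section()`, `simulate_observer()`,
`simulate_probability_map()`) reproduces the statistical structure this
analysis assumes — per-region Poisson counts, a survival gradient
(≈ 2.3% of control at 0.6 mm from the epicenter recovering by ≈ 20
percentage points per 200 µm to a 40% plateau), staining-gain
variability, nuclear-free artifacts, and imperfect observers — so every
stage is testable against known ground truth. See the methods vignette
(`vignettes/laminacount-methods.Rmd`) for the model, parameter
rationale, and limitations.

## Worked example

```r
library(laminacount)

atlas <- build_toy_atlas(frame_um = c(2000, 1500), n_laminae = 10)
atlas
#> toy_atlas: 15 regions (10 laminae + 5 nuclei), frame 2000 x 1500 um

# one injured section, 0.8 mm caudal to the epicenter
cfg <- simulation_config(pixel_size_um = 2, seed = 42)
sec <- simulate_section(atlas, cfg, distance_mm = 0.8)
sec$truth
#> ground_truth 'S1': 57 neurons, 3 artifacts

# pixel-classifier route: probability map -> particle rule
pm  <- simulate_probability_map(sec$truth, sec$image, miscalibration = 0.1)
det <- probmap_to_detections(pm, pixel_size_um = 2)
det
#> detection_set 'probmap' on 'S1': 56 points

# five simulated manual analyses, overlapped into consensus objects
obs <- lapply(1:5, function(i)
  simulate_observer(sec$truth, atlas,
                    observer_profile(sensitivity = 0.8, fp_rate = 1,
                                     jitter_sd_um = 2, seed = 100 + i),
                    source_id = paste0("obs", i)))
tab <- match_detection_sets(obs, radius_um = 10)
tab
#> agreement_table 'S1': 65 objects from 5 sources (K=5 manual), radius 10 um
#>   agreement classes: 0:0 1:9 2:2 3:10 4:27 5:17
reference_number_of_neurons(tab)
#> [1] 47.2
```

57 true neurons yield 56 detections by the particle rule (two touching
somas merge into one component). The five observers at sensitivity 0.8
with 1 false positive/mm² produce 65 matched objects; the 17 objects
found by all five analyses are certain neurons, the 9 found once are
doubtful, and the RNN (47.2) equals the mean of the five per-analyst
counts.

The full synthetic pipeline — simulate a cohort, detect, assign to
regions, quantify — in one call:

```r
res <- run_pipeline(pipeline_config(out_dir = "demo", seed = 42,
                                    sim = simulation_config(pixel_size_um = 4)))
res$distance_profile
#>        condition distance_mm n_sections median_total_percent increment
#> 1        control          NA          4           100.000000        NA
#> 2 injury_vehicle         0.6          2             1.714286        NA
#> 3 injury_vehicle         0.8          2            20.190476 18.476190
#> 4 injury_vehicle         1.0          2            42.095238 21.904762
#> 5 injury_vehicle         1.2          2            39.047619 -3.047619
```

One cohort of 12 sections recovers the configured injury gradient:
near-total loss at 0.6 mm, ≈ 20-percentage-point recovery per 0.2 mm,
and a plateau at ≈ 40% from 1.0 mm. `demo/` receives the atlas
(GeoJSON), detections and counts (CSV), the survival summary (JSON), the
Kruskal–Wallis table, and a provenance record (seed, configuration,
package version).

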