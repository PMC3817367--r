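# switchnet

Multimodal graph analysis of the 22-node **switching motor network**: the
set of medial-frontal, cingulate, basal-ganglia, insular, prefrontal,
premotor, parietal and cerebellar regions engaged when people switch between
competing motor task sets. The package is aimed at researchers comparing
**task-functional** and **diffusion-structural** brain connectivity in the
same subjects — in particular in traumatic brain injury (TBI), where diffuse
axonal injury motivates a "disconnection" account of switching deficits —
and at anyone who needs a fully testable reference implementation of that
pipeline.

Both views of the network are built over one fixed, ordered atlas of 22
spherical ROIs and scored identically:

* **Functional edges** are partial correlations between regional time
  series: with Ω the inverse covariance of the 22 mean ROI signals,
  `r_ij = −Ω_ij / √(Ω_ii Ω_jj)` — the correlation of nodes *i* and *j*
  conditional on the remaining 20 nodes.
* **Structural edges** come from deterministic tensor tractography (1 mm
  Euler steps along the trilinearly interpolated principal eigenvector;
  termination at FA < 0.2 or turns > 45°): edge weight = number of
  streamlines passing through both ROI spheres, or mean FA of the
  connecting streamlines.
* **Graph metrics** per node: degree, strength (Σ weights), local
  efficiency (global efficiency of the neighbour subgraph), betweenness
  centrality (Brandes, 1/w lengths, unnormalized); hubs are nodes whose
  group-mean betweenness exceeds the across-node mean by > 2 SD.
* **Statistics**: pooled two-sample t-tests on per-subject network
  summaries, 2×2 mixed-design ANOVA on task-switching reaction times,
  Pearson structure–function correlations per metric and group.
* **Classification**: median split of switch-block accuracy into good/poor
  performers, then linear discriminant models on structural degree,
  functional degree, and both combined, reported with sensitivity,
  specificity, overall accuracy and Wilks' Λ = det(W)/det(T).

Because the underlying patient data are not public, the package ships a
first-class synthetic cohort generator (default: 17 patients, 16 controls)
with known ground truth — planted precision matrices for the functional
panels, planted fiber bundles in tensor phantoms, and a planted
reaction-time switch cost — so the whole pipeline is verifiable end to end.
See `vignettes/switchnet-methods.Rmd` for the full model description.

## Worked example

```r
library(switchnet)
config <- pipeline_config(
  cohort = cohort_config(n_patients = 6, n_controls = 6,
                         n_timepoints = 150, voxel_mm = 3, seed = 42),
  verbose = FALSE)
res <- run_pipeline(config, out_dir = file.path(tempdir(), "demo"))

dplyr::select(res$metric_tests, modality, metric,
              mean_patient, mean_control, t, p)
#>   modality   metric           mean_patient mean_control      t          p
#> 1 functional degree                11.7         11.8    -0.538 0.602
#> 2 functional strength               1.36         1.13    8.81  0.00000500
#> 3 functional local_efficiency       0.0905       0.0784  5.60  0.000227
#> 4 functional betweenness           11.6          9.43    5.32  0.000335
#> 5 structural degree                 0.788        0.758   0.341 0.740
#> 6 structural strength             214.         202.      0.233 0.821
#> 7 structural local_efficiency      64.8         50.2     0.631 0.542
#> 8 structural betweenness            0.386        0.318   0.946 0.367
```

The pattern is the one the generator plants: the patient group's functional
coupling gain (×1.5 on off-diagonal precision) shows up as significantly
higher functional strength, local efficiency and betweenness, while the
structural networks — which carry no group effect — differ on nothing
(all p > 0.3). Degree is insensitive because zeroing negative partial
correlations leaves a similar number of non-zero edges in both groups.

```r
res$classification[, c("model", "sensitivity", "specificity",
                       "overall", "wilks_lambda")]
#>   model      sensitivity specificity overall wilks_lambda
#> 1 structural          50        50      50          0.989
#> 2 functional          50        50      50          0.930
#> 3 combined            50        66.7    58.3        0.903
```

With 12 subjects the discriminant models are weak, but combining both
modalities gives the best overall accuracy — the qualitative claim the
pipeline is designed to probe. Structural hubs land on the planted
high-degree nodes:

```r
dplyr::filter(res$hubs, is_hub, network == "struct_weighted")
#>   network         group   node    mean_betweenness threshold
#> 1 struct_weighted control DLPFC_R             4.17      2.31
#> 2 struct_weighted control PMd_L               2.33      2.31
#> 3 struct_weighted patient DLPFC_R             5         2.85
#> 4 struct_weighted patient PMd_L               3.17      2.85
```

`run_pipeline()` also writes everything to the output directory: the four
network TSVs per subject (`networks/`), nodal metric tables, group tests,
ANOVA and correlation tables, the hub report, classification reports, and a
JSON run manifest with the serialized configuration.

A thin command-line wrapper is installed at
`inst/scripts/switchnet-pipeline.R`
(`run-all`, `simulate`, `validate` subcommands, YAML/JSON config overrides).

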