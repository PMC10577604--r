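# folliscape

Compartment-aware spatial immunophenotyping for follicular lymphoma
multiplexed-immunofluorescence (M-IF) tiles.

Follicular lymphoma organizes its microenvironment around neoplastic
follicles, and the prognostic signal of rare immune subsets — CD8+FOXP3+
cells, CD4+CD8+ cells — lives in *where* they sit: inside follicles
(intra-follicular) or between them (inter-follicular), and how strongly
they co-localize. `folliscape` is a tool for pathology-image analysts and
computational biologists that implements the full chain from per-marker
"deconvoluted" images to survival-association statistics:

* **synthetic data** — tile scenes with programmable per-compartment
  densities, Thomas-style parent/offspring spatial coupling (strength
  κ ∈ [0, 1]), follicle geometry, rendered two-channel marker images, and
  whole cohorts whose time to progression (TTP) follows an exponential
  proportional-hazards model on the true latent features;
* **detection** — a count-regularized convolutional detector: a small
  fully-convolutional network predicts a centroid heatmap, and a global
  count head (heatmap mass / single-blob mass) adds a relative-count
  penalty `λ·((ĉ − c)/c)²` to the loss; peaks above τ with non-maximum
  suppression become cell centroids, evaluated by one-to-one greedy
  matching (precision/recall/F1, count correlation);
* **phenotyping** — a VGG-style patch classifier giving `p₊ve`/`p₋ve`
  per marker plane (ties to positive, `p₊ve ≥ p₋ve`), and co-expression
  merging of per-plane positives within 5 µm into multi-marker cells;
* **compartments** — DAPI tissue segmentation (Otsu + morphology),
  GeoJSON follicle annotations, intra/inter assignment (boundaries count
  as intra), densities in cells per 1000 µm² pooled per patient;
* **spatial statistics** — honeycomb Voronoi quadrats clipped to a
  compartment, the Morisita-Horn co-localization index

  `MH(x, y) = 2 Σ xᵢyᵢ / ((Σxᵢ²/X² + Σyᵢ²/Y²) · X · Y)`,

  and nearest-neighbor phenotype profiles;
* **prognosis** — two-sided rank-sum tests (exact enumeration for small
  groups), Benjamini-Hochberg correction within feature families,
  median-split Kaplan-Meier with log-rank (asymptotic or permutation p),
  Spearman correlation, and multivariate Cox regression against the
  ordinal FLIPI score.

The methods vignette (`vignettes/folliscape-methods.Rmd`) explains the
models, defaults and design choices in detail.

## Worked example

Generate a small synthetic cohort in which inter-follicular co-localization
of CD8+FOXP3+ with CD4+CD8+ cells is linked to relapse hazard
(log-HR −1.5 per latent SD), extract per-patient spatial features, and run
the association suite:

```r
library(folliscape)

cc <- cohort_config(n_patients = 40, tiles_per_patient = 1,
                    hazard_spec = c(coupling = -1.5), seed = 11)
cohort <- generate_cohort(cc)
cohort
#> Synthetic cohort: 40 patients, 36 events (90%)
#>   median follow-up 2.32 years; FLIPI low/int/high = 5/16/19
#>   1 tiles per patient (1000 x 1000 um)

features <- cohort_features(cohort)          # densities + Morisita-Horn
res <- run_association_suite(
  features, c("density_cd8foxp3", "mh_cd8foxp3_cd4cd8"),
  compartments = "inter")
res[, c("feature", "p_raw", "p_bh", "logrank_p", "cox_hr", "cox_p")]
#>              feature      p_raw       p_bh    logrank_p       cox_hr        cox_p
#> 1   density_cd8foxp3 0.10949578 0.10949578 0.1299314086 3.454322e-01 0.6252734845
#> 2 mh_cd8foxp3_cd4cd8 0.01234475 0.01234475 0.0001214168 7.127732e-06 0.0003744103
```

The linked co-localization feature is flagged (BH-corrected rank-sum
p ≈ 0.012, median-split log-rank p ≈ 1.2·10⁻⁴, Cox HR ≪ 1 per unit of the
Morisita-Horn index, i.e. higher co-localization → longer TTP), while the
density feature — not linked in this cohort — stays null. A per-feature
Kaplan-Meier plot is available via
`plot(median_split_km(features$mh_cd8foxp3_cd4cd8_inter,
features$ttp_years, features$event))`.

The same machinery runs on real inputs: per-marker TIFF tiles
(`detect_cells`, `classify_cells`, `merge_across_planes`), expert follicle
GeoJSON (`load_follicles`, `assign_compartments`), and a clinical CSV. A
thin command-line front end ships in `inst/scripts/folliscape`
(`folliscape synth|run --config cfg.yaml --out dir/ --seed N`).

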