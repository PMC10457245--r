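# camap — calcium–carbon association mapping from X-ray spectromicroscopy

Soil organic carbon in acidic soils is usually assumed to be stabilized by
iron and aluminium phases, yet exchangeable calcium often tracks organic
carbon even at low pH. Testing whether Ca is *spatially and spectrally*
associated with organic carbon requires a chain of spectro-microscopic
analyses: XANES spectrum processing, STXM image-stack analysis with
pixel-level co-localization logic, linear-combination fitting (LCF) against
screened standards, and per-pixel species mapping of multi-energy μ-XRF
maps. `camap` implements that chain as a tested R package for soil
biogeochemists and spectro-microscopists, together with a synthetic-data
generator that produces spectra, particle scenes and bulk tables with known
ground truth, so every stage can be validated end to end without beamline
data.

## What the package computes

* **XANES processing** (`calibrate_energy`, `first_derivative`,
  `merge_replicates`, `normalize_xanes`): energy calibration against a
  reference edge position (derivative maximum, with parabolic sub-grid
  refinement), replicate averaging, and edge-step normalization — a linear
  pre-edge fit subtracted everywhere and a post-edge polynomial whose value
  at E0 scales the edge jump to 1.0:
  `μ_norm(E) = (μ(E) − pre(E)) / post(E0)`.
  Shipped presets: Ca K-edge (pre 4013.39–4033.39 eV, post
  4063.39–4243.39 eV, E0 4043.39 eV) and C K-edge (pre 279.8–283.3 eV,
  post 291.8–302.0 eV, edge jump at 284.8 eV).
* **STXM stack analysis** (`to_optical_density`, `element_map`,
  `saturation_mask`, `classify_pixels`, `subset_spectrum`,
  `pixel_correlation`, `tricolour_export`): optical density
  `OD = −ln(I/I0)`, above/below-edge element contrast maps, masking of
  pixels with OD > 1, and the Boolean co-localization classes
  *total C*, *Ca–C (no Fe)*, *Fe–C (no Ca)* and *Fe–Ca–C*, whose mean
  spectra are the subset spectra used downstream.
* **LCF** (`lcf_fit`, `search_standard_sets`, `total_c_partition`): active-set
  non-negative least squares with an unconstrained weight sum, the raw sum
  recorded and flagged, then weights normalized to 100%; R-factor
  `Σ(y−ŷ)²/Σy²` and reduced χ². `total_c_partition` fits the total-C subset
  spectrum with only the Fe–C and Ca–C subset spectra to estimate how much
  organic carbon is associated with each metal.
* **Standard screening** (`fit_factor_model`, `target_transform`,
  `screen_pool`): uncentred PCA of a sample-spectrum set and
  target-transform testing with Malinowski-style SPOIL values
  (`SPOIL = RET/REP`, bands <1.5 excellent … >6 unacceptable).
* **μ-XRF species mapping** (`sample_standards_at`, `fit_species_maps`,
  `interelement_correlation`): per-pixel non-negative least squares of
  reference spectra sampled at the map energies, dominant-species maps and
  area fractions, and adjusted-R² associations between element channels.
* **Bulk statistics** (`cec_sum`, `base_saturation`, `table_associations`,
  `table_pca`): cation exchange capacity as the valence-weighted charge sum
  over Al³⁺, Ca²⁺, Mg²⁺, Na⁺, K⁺ (H⁺ excluded), base saturation, simple OLS
  associations and correlation-matrix PCA.
* **Synthetic data** (`endmember_library`, `make_scene`, `render_stack`,
  `make_bulk_table`, …): arctangent-edge + Gaussian-peak endmember spectra,
  elliptical particle scenes with Ca–C / Fe–C / Fe–Ca–C / C-only classes
  and log-normal thickness, Beer–Lambert stack rendering with Poisson
  noise, and bulk tables with a prescribed SOC–exchangeable-Ca correlation.

## Worked example

```r
library(camap)

scene <- make_scene(c(128, 128), 300, c(FeC = 0.77, CaC = 0.23),
                    axis_range = c(2, 6), seed = 11)
stack <- render_stack(scene, i0_level = 2000, noise = "poisson", seed = 1009)
an <- analyze_stack(stack)
an$partition
#> <camap_lcf> 2 standards, R-factor 7.21e-07, reduced chi^2 1.14e-06
#>   raw weight sum 98.82%
#>   FeC                    81.0 +/- 0.0 %
#>   CaC                    19.0 +/- 0.0 %
an$truth_partition
#>      FeC      CaC
#> 81.50753 18.49247
```

The scene drew 77% of the organic particles in the Fe-bearing class and
23% in the Ca-bearing class (this seed realized 81.5:18.5 of the measured
carbon mass). After rendering with Poisson counting noise, the pipeline
recomputes optical density, classifies pixels, extracts and normalizes the
subset spectra, and the two-component LCF of the total-C spectrum recovers
the carbon split of the measured region to half a percentage point (19.0%
vs 18.5% Ca-associated C); the raw weight sum before normalization to 100%
is reported alongside (98.8%).

The numbered drivers under `analysis/` run the full study on synthetic
data and write tables under `results/`:

* `01_simulate.R` — endmember library, demo stack, bulk table.
* `02_stack_coloc.R` — 18 stacks in the Ca-coupled regime; prints
  `Ca-C adjusted R2 exceeded Fe-C in 18 of 18 stacks` (means 0.298 vs
  0.076).
* `03_lcf_spoil.R` — the 77:23 partition (`recovered 23.5% (truth 23.0%),
  MAE 0.53 points`) and the SPOIL screen (generating endmembers
  "excellent", decoy "unacceptable").
* `04_xrf_maps.R` — species maps of a painted phantom (area fractions
  0.6/0.4) and inter-element correlations (Mg~Ca adjusted R² ≈ 0.32).
* `05_bulk_stats.R` — SOC~Ca_exch R² = 0.702 (target 0.69), CEC and base
  saturation (mean 91%), correlation-matrix PCA.

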