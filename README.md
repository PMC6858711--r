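# immunomargin

Margin-referenced immune contexture analysis for digital pathology.

Tumors treated with MAPK inhibitors (BRAFi with or without MEKi) respond
very differently depending on their immune contexture: the density and
position of cytotoxic CD8⁺ T cells and protumor CD163⁺ macrophages
relative to the invasive tumor margin. `immunomargin` is an R package
implementing that analysis end to end:

* **Cell detection** on fast-red/hematoxylin RGB stains by channel
  dominance (`R − max(G,B)` for chromogen, `B − max(R,G)` for nuclei),
  connected-component extraction with a 20–400 µm² area filter, and the
  five-field hotspot densitometry read-out (five 10⁻³ mm² fields, density
  = mean count / field area in cells/mm²).
* **Spatial profiling** from the exact signed Euclidean distance d(p) to
  the margin polygon (negative inside the tumor): per-cell compartment
  assignment (intratumoral d ≤ 0; peritumoral 0 < d ≤ 500 µm), 20 µm
  distance-class density histograms within ±100 µm, and band areas by
  adaptive quadtree integration of the distance field (validated against
  closed-form annulus areas to < 10⁻⁴ mm²).
* **Scoring**: positive-cell fraction → ordinal score 0 / 1+ (< 10%) /
  2+ (10–50%) / 3+ (50–100%) → high (2+, 3+) vs low; PD-L1/PD-L2
  positivity at ≥ 5%; β-catenin overexpression above the cohort median;
  and the three-group combinations (e.g. group 1 = high CD8 / low CD163,
  group 3 = low CD8 / high CD163).
* **Association**: multivariable logistic models for overall response
  (odds ratios with Wald 95% CI) and Cox models (Efron ties) for PFS/OS
  (hazard ratios), adjusted for AJCC stage, ECOG PS, LDH and treatment
  (plus subsequent immunotherapy for OS); Kaplan–Meier curves with
  S(t) ≤ q quantiles; chi-square and Kruskal–Wallis auxiliary tests.
* **Simulators with known ground truth**: inhomogeneous Poisson tissue
  scenes whose intensity λ(p) = max(0, λ_base + β·d(p)) varies with
  distance to a circular or blob-shaped margin; pseudo-IHC renders; and
  patient cohorts with logistic response and proportional-hazards
  survival structure at configurable effect sizes.

## Worked example

Simulate an immune-excluded scene (CD8 sparse inside the tumor, abundant
outside), profile it against the margin and score it:

```r
library(immunomargin)

cfg <- scene_config(field_width_um = 2000, field_height_um = 2000,
                    margin_shape = "blob", margin_radius_um = 500,
                    lambda_in  = c(CD8 = 250, CD163 = 700, NEG = 1200),
                    lambda_out = c(CD8 = 900, CD163 = 500, NEG = 1200),
                    gradient_slope = c(CD8 = 3, CD163 = 0, NEG = 0),
                    seed = 42)
sc <- generate_tissue_scene(cfg)
sc
#> <scene> 2000 x 2000 um field, blob margin (r = 500 um)
#>   cells: CD8 = 6474, CD163 = 2172, NEG = 4782

cd <- compartment_densities(sc$cells, sc$geometry)
cd[, c("marker", "compartment", "density_per_mm2", "positive_fraction_pct")]
#>   marker  compartment density_per_mm2 positive_fraction_pct
#> 1    CD8 intratumoral        39.25013              1.991008
#> 2  CD163 intratumoral       659.65543             33.461785
#> 3    CD8  peritumoral      1702.36173             49.950495
#> 4  CD163 peritumoral        531.88259             15.606436

cd$dichot <- dichotomize_score(score_density(cd$positive_fraction_pct))
it <- cd[cd$compartment == "intratumoral", ]
combine_cd8_cd163(it$dichot[it$marker == "CD8"],
                  it$dichot[it$marker == "CD163"])
#> [1] 3
```

The intratumoral CD8 fraction (2.0%, score 1+, low) against a moderate
CD163 infiltrate (33.5%, score 2+, high) lands the scene in combination
group 3 — the low-CD8/high-CD163 immune-excluded phenotype. The CD8
distance histogram (`band_histogram(sc$cells, sc$geometry)`) shows the
gradient directly: 0–120 cells/mm² in the inner bands rising to
~1100 cells/mm² 80–100 µm outside the margin.

Simulate a cohort at the default effect sizes and refit the multivariable
models:

```r
ch <- generate_cohort(cohort_config(n_patients = 158, seed = 1))
fit_response_model(ch, term = "group")
#>                  term    model   n estimate  ci_lo   ci_hi      p
#> 1              group1 logistic 158   7.6647 2.4976 23.5213 0.0004
#> 2              group2 logistic 158   5.2617 2.1992 12.5886 0.0002
#> ...
fit_survival_model(ch, "os", term = "group")
#>                  term model   n estimate  ci_lo  ci_hi      p
#> 1              group1   cox 158   0.2872 0.1355 0.6089 0.0011
#> ...
```

At n = 158 the group-1-vs-group-3 estimates (OR 7.7, HR 0.29) scatter
around the generating values (OR 9.91, HR 0.34); averaged over hundreds
of simulated cohorts they recover them closely (see below). A full
scene-to-model run with a written manifest is one call:
`run_pipeline(pipeline_config(seed = 1))`.

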