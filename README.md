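# anchorscreen

Analysis of **anchored drug-combination screens** in cancer cell lines:
plate quality control, anchor-capped dose–response fitting, Bliss-based
synergy scoring, biomarker discovery by ANOVA with Glass-delta effect
sizes, and protein-interaction network distance analysis — with a
synthetic screen generator carrying planted ground truth so the whole
pipeline is testable without any external data.

## Who this is for

Groups running (or re-analysing) high-throughput 2 × 7 "anchored"
combination screens: an anchor drug at two fixed concentrations crossed
with a 7-point dose response of a library drug, measured by a viability
readout on plates with dedicated control wells. The package takes raw
well-intensity tables and produces per-combination synergy calls,
per-feature biomarker associations and network-distance summaries.

## The model and scoring in brief

Viability is a two-parameter logistic in standardized log2 dose
(top concentration = 9):

    V(x) = u / (1 + exp((x − x_mid)/s))

with the upper asymptote `u` fixed — 1 for monotherapy, the measured
anchor viability `A` for combinations (the *anchor cap*). With a lower
asymptote of 0, IC50 ≡ `x_mid`. Bliss independence predicts the expected
combination curve `A·V_lib(x)`, hence Bliss IC50 = library `x_mid` and
Bliss Emax = `A ×` library Emax. Observed combinations are scored by

    ΔIC50 = Bliss IC50 − combination IC50   (log2 units)
    ΔEmax = Bliss Emax − combination Emax   (viability units)

and a measurement is synergistic when the combination IC50 is in range
(< 10 on the standardized scale, i.e. < 2× the top screened dose) and
ΔIC50 ≥ 3 (8-fold potency shift) **or** ΔEmax ≥ 0.2 (20% viability
shift). Replicates are majority-voted; a combination–cell line pair is
synergistic at either anchor concentration. Plate QC enforces CV ≤ 0.18
on DMSO negatives and Z-factors ≥ 0.3 against effective positive
controls. Biomarkers are flagged at p ≤ 0.001, BH-FDR ≤ 5% and both
Glass deltas ≥ 1. See `vignettes/anchored-synergy.Rmd` for the full
account, including every tunable and its default.

## Worked example

```r
library(anchorscreen)

design <- screen_design(
  cell_lines = sprintf("CL%02d", 1:8),
  anchors    = data.frame(drug = "navitoclax",
                          conc_low_log2 = 5, conc_high_log2 = 7),
  libraries  = data.frame(drug = c("AZD7762", "gemcitabine")),
  tissues    = rep(c("breast", "colon"), each = 4))

truth <- random_ground_truth(design, seed = 1, synergy_fraction = 0.25)
sim   <- simulate_screen(design, truth, seed = 1)
sim
#> Simulated screen: 16 plates, 4032 wells (seed 1 )

qc <- qc_screen(sim$wells)
sprintf("%d/%d plates pass QC (mean Z-factor %.2f)",
        sum(qc$pass), nrow(qc), attr(qc, "mean_z"))
#> "16/16 plates pass QC (mean Z-factor 0.82)"

scored <- score_screen(sim$wells, qc = qc)
scored
#> Scored screen: 32 tuples (0 excluded), 16 pairs, 4 synergistic

dplyr::filter(scored$pairs, synergy)
#> # A tibble: 4 × 8
#>   cell_line anchor_drug library_drug synergy_low synergy_high dual_anchor ...
#> 1 CL03      navitoclax  gemcitabine  TRUE        TRUE         TRUE
#> 2 CL04      navitoclax  AZD7762      TRUE        TRUE         TRUE
#> 3 CL05      navitoclax  AZD7762      TRUE        TRUE         TRUE
#> 4 CL08      navitoclax  gemcitabine  TRUE        TRUE         TRUE

synergy_rate(scored$pairs, by = "tissue")
#> # A tibble: 2 × 4
#>   tissue     n n_synergistic  rate
#> 1 breast     8             2  0.25
#> 2 colon      8             2  0.25
```

The four synergistic pairs are exactly the tuples the generator planted
(25% of 16 pairs). Per-tuple detail lives in `scored$tuples`: e.g. the
CL04 + AZD7762 pair is an *efficacy* synergy (ΔEmax ≈ 0.44 at both anchor
concentrations) while CL05 + AZD7762 is a *potency* synergy
(ΔIC50 ≈ 4 log2 units, a 16-fold shift beyond Bliss).

Downstream, `build_response_matrix()` reduces tuples to one response per
cell line and combination, `run_biomarker_scan()` tests binary features
against them (with `binarize_expression()` for expression features and
`define_context()` for molecular baskets), and `build_interactome()` /
`min_set_distance()` / `shuffle_null()` support target–target and
target–biomarker network distance analyses. `run_pipeline(default_config(),
out_dir)` runs everything end to end into a directory of tables plus a
JSON manifest; `inst/scripts/anchorscreen-cli.R` wraps it for the shell.

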