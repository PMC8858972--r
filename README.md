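# glycospot

Antibody-spot MALDI glycan quantification and fibrosis biomarker panel
selection in R.

## What problem this solves

The N-glycans on serum IgG — and on its subclasses IgG1–IgG4 — shift with
the progression of liver fibrosis: core-fucosylated agalactosylated and
bisected species (e.g. A2BG0F) rise, galactosylated species (A2G1F,
A2BG1F) fall. An antibody-capture spot array measures these shifts without
purification: anti-IgG / anti-IgG1..4 spots capture the glycoproteins from
a few microliters of serum, PNGase F releases the N-glycans on-slide, and
MALDI imaging mass spectrometry records a spectrum per pixel per spot.

`glycospot` is the computational half of that assay, for analysts who have
pixel spectra (or already-quantified glycan tables) and want a staged,
cross-validated glycan biomarker panel:

* **Glycan model** — Oxford-nomenclature parser (`A2BG0F` = bi-antennary,
  bisecting GlcNAc, zero galactoses, core fucose), monoisotopic masses and
  positive-mode adduct m/z for panel construction
  (`parse_oxford()`, `glycan_panel()`).
* **Spot quantification** — TIC normalization per pixel, windowed (±ppm)
  monoisotopic peak areas, pixel averaging, and closure to per-channel
  relative percentiles (`quantify_spot()`, `build_cohort_table()`).
* **Cohort simulator** — seeded logistic-normal compositional cohorts
  (three fibrosis groups, five capture channels) with planted group
  effects and correlated decoy twins (`generate_cohort()`,
  `generate_spot_spectra()`).
* **Screen** — one-way ANOVA filter (discard p > 0.05) with Tukey post-hoc
  timing classification: *early* (shifts at no-fibrosis → early fibrosis),
  *late* (early → advanced), or *both* (`filter_features()`).
* **Panel pruning** — pairwise **Hoeffding's D** similarity, random-forest
  out-of-bag permutation importance, and iterative elimination of the
  lower-importance member of the most-dependent pair, with a CV-accuracy
  stopping rule (`hoeffding_d()`, `iterative_elimination()`).
* **Evaluation** — apparent / leave-one-out / 3-fold random-subsampling /
  repeated 3-fold CV with random forests; Mann–Whitney AUC with DeLong
  95% CI; sensitivity at fixed (90%) specificity; PPV/NPV at the
  operating point (`evaluate_groupings()`, `auc_ci()`, `sens_at_spec()`).

The core selection statistic, Hoeffding's scaled D

    D = 30 [ (n-2)(n-3) D1 + D2 - 2(n-2) D3 ] / [ n(n-1)(n-2)(n-3)(n-4) ]

(with D1 = Σ Qi(Qi−1), D2 = Σ (Ri−1)(Ri−2)(Si−1)(Si−2),
D3 = Σ (Ri−2)(Si−2)Qi over midranks R, S and bivariate ranks Q) detects
*any* bivariate dependence, so redundant glycoforms are caught even when
their relationship is nonlinear.

## Worked example

```r
library(glycospot)

# Theoretical panel: sodiated adducts, disodiated for sialylated glycans
panel <- glycan_panel(c("G.A2G0F", "G.A2BG0F", "G1.A2G2S1"))
panel[, c("label", "adduct", "theoretical_mz")]
#>       label  adduct theoretical_mz
#> 1   G.A2G0F    M+Na       1485.534
#> 2  G.A2BG0F    M+Na       1688.613
#> 3 G1.A2G2S1 M+2Na-H       1976.659

# Simulate the default 3-group cohort (41/28/43 samples, 55 features)
sim <- generate_cohort(synthetic_config(), seed = 1)

# Univariate screen across the three fibrosis groups
screen <- filter_features(sim$cohort, alpha = 0.05)
length(screen$retained)
#> 13 of 55 features pass the ANOVA screen

# Hoeffding-D / importance elimination with CV stopping
sel <- iterative_elimination(cohort_matrix(sim$cohort, screen$retained),
                             sim$cohort$group, seed = 1)
sel
#> <selection_trace> 3 eliminations; best CV accuracy 88.2% with 13 features

# Cross-validated discrimination of the selected panel
reports <- evaluate_groupings(sim$cohort, sel$panel, schemes = "loocv",
                              regroup = FALSE, seed = 1)
reports$group1_vs_group3
#> <eval_report> group1_vs_group3 (n=41 vs 43)
#>   loocv           AUC 0.9932 (95%CI 0.9804-1.0000)  sens 98% @ 90% spec
```

The screen keeps the seven planted marker features plus their decoy twins
and a few closure-coupled neighbours; the elimination trace shows both
decoys falling first (each against its planted partner), and the held-out
AUC separates the no-fibrosis and advanced-fibrosis groups nearly
perfectly, with weaker (as designed) separation of adjacent groups.

`run_pipeline(run_config(mode = "synthetic", seed = 1))` runs all stages
and writes every artifact (cohort TSV, ANOVA TSV, selection-trace JSON,
evaluation JSON/TSV, run metadata) to an output directory;
`inst/scripts/glycospot-cli.R` exposes the same stages as shell
subcommands (`simulate`, `quantify`, `select`, `evaluate`, `run-all`).

## Scope notes

Structures/linkages, isotope envelopes, vendor project formats and imzML
parsing are out of scope; spectra enter via a documented plain-TSV spot
dialect or as quantified cohort tables. The simulator is a study-design
stand-in, not a serum emulator — see the methods vignette
(`vignettes/glycan-panel-workflow.Rmd`) for the generative model, every
tunable default and its rationale, and known limitations.
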