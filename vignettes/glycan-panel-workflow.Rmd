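---
title: "From antibody-spot MALDI spectra to a fibrosis glycan panel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From antibody-spot MALDI spectra to a fibrosis glycan panel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycospot)
```

## The analysis problem

Immunoglobulin G carries a single conserved N-glycosylation site per heavy
chain, and the composition of the glycans at that site shifts with chronic
liver injury: agalactosylated and bisected species rise with fibrosis while
galactosylated species fall. An antibody-capture spot array makes these
shifts measurable per IgG subclass: serum is incubated over printed
anti-IgG / anti-IgG1..4 spots, PNGase F releases the N-glycans in place,
and MALDI imaging mass spectrometry records a spectrum at every pixel of
every spot. Each capture channel therefore yields a compositional profile —
the relative share of each glycan within that channel's panel — and the
question is which channel-specific glycan features, in which combination,
stage fibrosis.

`glycospot` implements the full computational chain: glycan nomenclature
and theoretical masses, pixel-spectrum quantification, univariate
screening, multivariate panel pruning, and cross-validated evaluation,
plus a cohort simulator that stands in for patient sera.

## Glycan model

Oxford names are parsed over the constant trimannosyl-chitobiose core
(2 core GlcNAcs + 3 mannoses): `A<x>` antennary GlcNAcs, optional `B`
bisecting GlcNAc, `G<x>` galactoses, optional `S<x>` sialic acids,
optional `F` core fucose. Validity requires
galactoses &le; antennae and sialic acids &le; galactoses. Masses are sums
of monoisotopic glycosidic residue masses (HexNAc 203.079373, Hex
162.052824, dHex 146.057909, NeuAc 291.095417 Da) plus one water
(18.010565 Da) for the reducing end; there is deliberately no average-mass
mode. Singly charged positive-mode adducts add the cation mass; the
`M+2Na-H` adduct is bookkept as two sodium cations minus one proton
(44.971160 Da). Panels default to `[M+Na]+` for neutral and `[M+2Na-H]+`
for sialylated glycans, the usual positive-mode MALDI behaviour for acidic
species; the adduct is configurable per panel entry because instruments
and matrices differ.

```{r}
glycan_panel(c("G.A2G0F", "G1.A2G2S1"))
```

## Spot quantification

The order of operations is fixed and matters:

1. **TIC-normalize each pixel** (intensities scaled to unit sum), removing
   per-pixel laser and matrix variation;
2. **extract the monoisotopic peak area** per panel glycan as the summed
   centroid intensity within a ±`tol_ppm` window around the theoretical
   m/z (default 10 ppm, matching FT-ICR-grade mass accuracy; the data are
   assumed centroided, so no profile integration is attempted);
3. **average over the spot's pixels** ("mean peak intensity");
4. **close each channel to relative percentiles** summing to 100.

Percentile denominators are per capture channel, never across channels:
each spot is an independent capture with its own total signal. If two
panel windows overlap at the chosen tolerance both receive the shared
points and a warning names the collision — silently splitting ambiguous
signal would hide a panel-design problem. An empty window yields area 0;
an all-zero spot yields a zero percentile row with a warning rather than
an error, since missing spots are a fact of array life.

No imzML reader is bundled: input spectra arrive either through the simple
tabular dialect (`read_spot_tsv()`; one TSV per spot with
`pixel, mz, intensity` columns and a `# spot_id= channel=` header) plus a
manifest mapping samples to files, or as a ready cohort TSV.

## The cohort simulator

No patient-level data are distributed with this package, so every
downstream stage is exercised against simulated cohorts whose structure
mirrors the study design the pipeline targets: three fibrosis groups of
41 / 28 / 43 samples (no fibrosis; early-to-moderate, METAVIR 1–2;
advanced/cirrhosis, METAVIR 3–4), five capture channels, and eleven
glycans per channel (55 features).

Profiles are **logistic-normal**: per sample and channel,
log-abundance = baseline + group shift + N(0, σ), closed to percentiles.
Logistic-normal rather than Dirichlet because the elimination stage needs
independently controllable per-feature shifts *and* correlated feature
pairs, which Dirichlet draws cannot provide. Baselines are set so the
closed profile resembles a serum IgG Fc profile (agalactosylated and
monogalactosylated core-fucosylated species dominant).

Planted effects default to the seven-feature panel the pipeline is meant
to recover — `G.A2G2F`, `G.A2BG0F`, `G1.A2G1F`, `G1.A2G2S1`, `G2.A2G1F`,
`G2.A2G0F`, `G3.A2BG1F` — each with a timing class: *early* features shift
at the group1→group2 transition and then stay, *late* features shift only
at group2→group3, *both* features shift at each transition. The
per-transition shift is 0.8 on the log scale against intra-sample noise
σ = 0.5, i.e. roughly 1.6 SD per affected transition: a strong but not
separable effect, consistent with glycan boxplots that overlap between
adjacent groups yet separate clearly between extremes. Directions follow
the biology above (bisected/agalactosylated up, galactosylated down).

Two **decoy twins** are planted by default: `G.A2BG2F` tracks `G.A2BG0F`
and `G1.A2G1` tracks `G1.A2G1F`, each constructed as
baseline + 0.7 × (partner's log deviation) + N(0, 0.25). They are strongly
dependent on their partner but carry attenuated, noisier signal, so the
pair-elimination path has genuine work to do. One caveat discovered while
characterizing the mechanism: because features are closed per channel, a
decoy's *percentile* can occasionally (order 5–10% of cohort draws) carry
slightly more forest importance than its partner's even though its
log-abundance signal is strictly weaker — the importance contest between
strongly dependent features is decided by realized noise, not only by
construction. The recovery tests therefore bound the per-run success rate
rather than demanding decoy-first elimination in every draw.

Timing-class identities hold exactly on the log-abundance scale; after
closure they hold exactly for a feature's percentile only when the other
planted features in its channel share the timing (otherwise the
denominator moves at the other transition too). Tests of timing fidelity
use channels where the identity survives closure.

What the simulator does *not* emulate: isotope envelopes, instrument
drift, demographic covariates, batch structure, and any real-serum
correlation beyond the planted pairs. Passing tests show the pipeline
recovers what the generative model plants — they do not certify
performance on real sera.

Synthetic spot spectra (for the quantification round trip) place one
centroid per panel glycan at the theoretical m/z with 1 ppm mass jitter,
heights proportional to the profile times a lognormal pixel brightness
(σ = 0.2), multiplicative height noise of relative scale 1/SNR, and 200
uniform low-intensity baseline centroids per pixel. At `snr = Inf` the
single-pixel round trip is exact by construction.

## ANOVA screen and timing classification

Each feature is tested by classical one-way fixed-effects ANOVA across the
three groups; features with F-test p > α (default 0.05, raw) are
discarded. No multiplicity correction is applied by default — the screen
is a permissive pre-filter ahead of multivariate selection, not an
inferential endpoint — but `adjust` accepts any `p.adjust` method.
Percentiles are analysed untransformed by default (they are bounded but
far from the boundary for the features of interest); a logit transform is
a documented alternative the caller can apply upstream. The post-hoc test
on the two adjacent-group contrasts is Tukey HSD at α = 0.05; which
post-hoc procedure the original analysis used is not documented anywhere
we could rely on, so this is an explicit configuration choice, and the
timing label (early / late / both / indeterminate) is derived from those
two contrasts only.

## Panel pruning: Hoeffding's D + random-forest importance

Redundancy among retained features is measured by **Hoeffding's D**, a
rank statistic sensitive to any form of bivariate dependence, not just
linear or monotone association. With midranks R, S and the bivariate rank
Q (half weight for ties in one coordinate, quarter for ties in both):

D = 30 · [ (n−2)(n−3) D₁ + D₂ − 2(n−2) D₃ ] / [ n(n−1)(n−2)(n−3)(n−4) ],

D₁ = Σ Qᵢ(Qᵢ−1), D₂ = Σ (Rᵢ−1)(Rᵢ−2)(Sᵢ−1)(Sᵢ−2),
D₃ = Σ (Rᵢ−2)(Sᵢ−2)Qᵢ.

The scaled statistic lies in [−0.5, 1] and equals 1 for any strictly
monotone relation. The implementation is vectorized over comparison
matrices; the test suite pins it to a naive O(n²) loop evaluation to
1e-12 across tied and untied data.

The elimination loop then repeats: (1) find the most-dependent remaining
pair (ties broken lexicographically, so runs are deterministic); (2) rank
remaining features by out-of-bag permutation importance from a
500-tree random forest with √p features per split; (3) discard the pair
member with lower importance; (4) score the reduced panel by repeated
stratified 3-fold CV accuracy. One feature falls per iteration — the
natural reading of "identify the top pair, discard the weaker member" —
and the full similarity matrix is computed once and subset as features
drop, which is mathematically identical to recomputation because a pair's
D does not depend on the other features.

**Stopping rule.** "Performance consistently and dramatically
deteriorates" is operationalized as: stop when the CV accuracy falls more
than δ = 2 percentage points below the best mean accuracy seen, for 2
consecutive iterations (both configurable), or when `min_features` = 5
remain. The *best*-scoring panel is returned, not the last; exact
accuracy ties favour the smaller panel, implementing "best predictive
ability with the fewest features". The stopping metric uses 5 repetitions
of 3-fold CV with 200-tree forests — small enough to keep a full
elimination run around a second at this cohort size, large enough that
the 2-point tolerance exceeds the metric's rep-to-rep noise.

## Evaluation

Pairwise group comparisons (group1 vs 2, 2 vs 3, 1 vs 3, plus the
METAVIR regrouping 0&1 vs 2&3 and 2&3 vs 4 when stages are recorded) are
evaluated by binary random-forest refits — pairwise refits rather than a
sliced multiclass model, since discrimination is reported pairwise — under
four schemes: apparent (train = test, optimistic by construction),
leave-one-out, 3-fold random subsampling (200 random stratified 2:1
splits, scored on each held-out third) and repeated 3-fold (200 full
stratified partitions). The two "3-fold" schemes are deliberately distinct
named schemes.

AUC is the Mann–Whitney statistic (ties count half); its 95% CI uses
DeLong's placement-value variance, clipped to [0, 1] — a bootstrap CI is
the obvious alternative and can be layered on the retained score vectors.
The operating point takes, among thresholds whose observed specificity is
at least the target (default 90%), the one with maximum sensitivity — no
ROC interpolation, so reported sensitivities are achievable on the finite
sample. PPV/NPV at that threshold use observed prevalence unless
overridden. Repeated schemes report per-repetition metrics averaged, with
the AUC's SD retained.

## Numerical and degenerate-input choices

* Constant features are *errors* in `anova_f()` and `hoeffding_d()` but
  are dropped with a warning by the batch wrappers (`filter_features()`,
  `similarity_matrix()`) — a single dead column should not kill a run.
* `relative_percentile()` of an all-zero vector warns and returns zeros
  (a silent spot), while negative input is an error (a logic bug).
* All stochastic steps take explicit seeds and restore the caller's RNG
  state; reruns with the same config are bit-identical for every
  deterministic stage.
* Fold assignment is always class-stratified; a fold that would lose a
  class entirely cannot arise unless a class has fewer samples than folds,
  which is rejected up front.

## Problem sizes used in the test suite

Property tests run at the default cohort size (112 samples, 55 features)
with 20 seeds for screen calibration and panel recovery, 20 seeds for
discrimination ordering (10 for the null), 100 datasets of n = 5–30 for
the Hoeffding oracle, and 50-pixel spectra for the quantification round
trip — sizes chosen so the full suite completes in a few minutes while
keeping Monte-Carlo error well inside the asserted bounds.

## Known limitations

* Compositions only: linkage isomers, structures and derivatization
  chemistry are out of scope, as is isotope-envelope deconvolution.
* The percentile closure couples features within a channel; effect sizes
  planted on the log scale are not exactly the observed percentile
  differences (the simulator records expected percentiles per group for
  reference).
* Permutation importance between strongly dependent features is
  intrinsically noisy; the elimination order of a near-duplicate pair is
  stable in expectation but not guaranteed per draw.
* Reported operating points are finite-sample: with small comparison
  groups, "sensitivity at 90% specificity" moves in visible steps.
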