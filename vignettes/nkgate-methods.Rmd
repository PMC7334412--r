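---
title: "Methods: the synthetic cohort model and automated gating in nkgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the synthetic cohort model and automated gating in nkgate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nkgate` compares gating strategies for the rare CD56^neg^ NK-cell
subset — above all the NKp80-based gate against the classical CD16-based
gate — on synthetic cytometry cohorts in which every event carries a
ground-truth population label. This vignette documents the generative
model, the automated threshold and gating rules, the statistical
choices, and the places where the design was genuinely open.

## 1. The intensity model

Each population assigns every marker one of three expression states;
intensities are Gaussian **on the arcsinh-transformed scale**
(`asinh(raw / 150)`, the common cofactor for conventional flow data)
and mapped to the raw scale with `sinh(x) * 150`:

| state | location | scale | used for |
|-------|----------|-------|----------|
| neg   | 0        | 0.25  | unexpressed markers |
| pos   | 3.0      | 0.4   | expressed markers |
| high  | 6.0      | 0.4   | CD56 on CD56^bright^ NK cells |

Two-state separation is strong: a positive event clears the neg/pos
midpoint with probability ≈ 1 − 2 × 10⁻⁴, which is what makes truth
labels recoverable by gating and lets the tests demand recovery within
3 binomial SD. The `high` state sits at 6.0 rather than closer to the
positive state so that the derived CD56 dim/bright boundary (Section 3)
cleanly separates dim from bright; with the two states nearer each
other the boundary misassigns a visible share of bright events.
Forward scatter is Gaussian on the raw scale, with larger locations for
monocytes, pDCs, basophils and the CD16+ myeloid-like contaminant —
the size difference behind the FSC comparison of Eomes− versus Eomes+
events in the CD16 gate. No spillover/compensation, doublets or
acquisition-time drift are modelled.

## 2. The population mixture and its calibration

A healthy-donor sample is a 17-population mixture (fractions of all
acquired events): T cells 45%, B cells 8%, monocytes 12%, pDCs 0.7%
(of which 0.055% CD16+), basophils 0.8% (0.055% CD16+), CD56^bright^
NK 0.8%, CD56^dim^ NK 7.8% (7.2% CD16+, 0.6% CD16−), CD56^neg^ NK
0.35% (split evenly CD16+/CD16−, Eomes+ with probability 0.98), an
NKp80+Eomes− ILC-like population 0.09% (split evenly CD16+/CD16−), a
CD16+CD123− monocyte-like population escaping the CD14 dump 0.11%,
lineage-negative "other" lymphocytes 19.35% (CD7+), and dead cells 5%
(viability-dye positive).

The literature this package operationalises prints almost no
frequencies, so the composition is calibrated to the few quantitative
anchors it does state, plus internal consistency:

* **≈ 20% Eomes− inside the CD56^neg^NKp80+ gate**: the gate contains
  0.35% Eomes+ NK (at probability 0.98) plus 0.09% NKp80+Eomes− cells,
  giving an expected Eomes− share of 22%.
* **≈ 50% CD123+ inside the CD56^neg^CD16+NKp80− quadrant**: the
  quadrant holds 0.11% CD123+ (CD16+ pDC + basophil fractions) and
  0.11% CD123− (monocyte-like) contaminants.
* **≈ half of CD56^neg^NKp80+ cells co-express CD16**, and the three
  informative quadrants are of comparable size (0.22% each).
* **NK cells are 5–15% of lymphocytes**: the truth-level NK share of
  viable lymphoid events is ≈ 11%.

One structural choice deserves emphasis: the NKp80+Eomes− population is
split into CD16+ and CD16− halves **in the same ratio as the Eomes+
CD56^neg^ NK cells**. With CD16 status independent of Eomes status
inside the NKp80+/CD7+ lymphoid pool, every gate drawn on that pool
(NKp80-based, CD7+CD16-based) has the same expected Eomes− fraction —
which is the only composition that simultaneously satisfies the ~20%
anchor, the co-expression anchor, and the observation that the
CD7+CD56^neg^CD16+ and CD56^neg^NKp80+ gates are equally pure (their
paired comparison should be non-significant).

**Donor variability** is a Dirichlet-style resampling at the level of
biological compartments: each compartment abundance $a_g$ is replaced by
a Gamma(shape $= c \cdot a_g$) draw (concentration $c = 2000$ by
default) and renormalised; populations within a compartment — the CD16+
fraction of pDCs, the constituents of the CD56^neg^NKp80+ pool, the
CD16+ monocyte-like cells riding the monocyte pool — scale together.
This gives rare compartments a realistic coefficient of variation of
30–70% (the spread of donor dots in typical cohort figures) while
within-compartment proportions, which the anchors above are ratios of,
stay fixed. Modelling within-compartment composition as donor-invariant
is a deliberate idealisation; real donors vary in those ratios too.

**Disease presets** multiply the Eomes+ CD56^neg^ NK abundance by 12
(untreated HIV) or 4 (HIV under cART; multiple myeloma) and
renormalise — exact expansion factors are not published, so these
encode only the ordering (untreated HIV ≫ cART ≈ myeloma > healthy).

**Perturbations.** Cryopreservation scales CD16 raw intensity by 0.55
and redraws CD16 from the negative state for 25% of shed-susceptible
(NK-lineage) events; stimulation (K562 targets or IL-12+IL-18) scales
CD16 by 0.4, sheds 50%, doubles the shedding probability for events
drawn CD107a+ (degranulating cells shed preferentially — the mechanism
by which the CD16 gate loses functional cells), and induces functional
markers per population response probabilities (CD56^dim^ > CD56^neg^ ≫
the ILC-like population for every readout; cytokine responses dominate
under IL-12+IL-18, degranulation under K562). NKp80 is scaled by 1.0
everywhere: its stability is the property under study. The stimulus
names follow the figure labels of the source literature; an IL-15
priming step mentioned elsewhere in that literature is deliberately not
modelled. Perturbations never change event counts or truth labels.

## 3. Automated thresholds

Manual gate placement is replaced by a per-channel rule on the
transformed scale:

1. Fit a two-component unequal-variance Gaussian mixture (mclust,
   `G = 2`, model `"V"`) to at most 8,000 evenly spaced order statistics
   of the channel (a deterministic, distribution-preserving subsample
   that keeps per-donor fitting fast).
2. The cutoff is the **equal-posterior boundary** between the
   components, solved between the component means.
3. If the fit does not support a bimodal reading — separation
   $|\mu_2-\mu_1|/\sigma_{pooled} < 2$, a component weight `< 0.02`, or
   no posterior crossing — fall back to a quantile rule: the 99.5th
   percentile of declared negative-control values when provided, else
   the global 95th percentile, tagged `quantile_fallback`.

The weight floor matters in practice: CD123+ events are ~1.5% of a
healthy sample, so CD123 intentionally takes the fallback path, as do
the functional channels on unstimulated samples (where everything is
negative). The fallback's 5% false-positive tail is the background
visible in functional percentages.

CD56 is split three ways: the mixture cutoff is the neg/dim boundary
and the positive-component mean + 2 SD is the dim/bright boundary (the
published gates distinguish bright/dim/neg without stating boundaries).
Ties at a cutoff classify as negative — deterministic and conservative.
Thresholds are estimated once per donor on the fresh/unstimulated
sample and **frozen** for that donor's perturbed conditions, mirroring
how identical gates are compared before and after stimulation and
preventing CD16 shedding from silently moving the CD16 gate.

Degenerate inputs: a constant channel is an error (no gate is
meaningful), as are fewer than 20 values; non-finite values are
rejected with their indices.

## 4. Gating strategies

A strategy is an exclusion stage — events positive for any dump marker
(viability, CD3, CD14, CD19, optionally CD123) are removed — followed by
predicate trees over per-marker cutoffs. Because subset predicates are
written from the root, containment (child ⊆ parent) holds by
construction, and the CD16×NKp80 quadrants partition the CD56^neg^
gate exactly. An optional FSC pre-gate exists but no parameters are
asserted for it: the published lymphocyte/singlet pre-gating lives in
unavailable supplementary material. Strategies are also expressible in
a YAML text format so new ones need no code changes.

## 5. Statistics and reporting

Within-donor strategy comparisons use the two-sided Wilcoxon
signed-rank test (exact null for ≤ 25 non-zero pairs, ties permitting;
normal approximation with continuity correction otherwise; zero
differences dropped and reported). Cross-condition comparisons use the
two-sided Mann–Whitney U test. α = 0.05, no multiple-testing
correction — matching per-panel star annotations. The exact test
identities behind the published stars are not recoverable from the main
text, so every reported number states the test used. Summaries follow
the corresponding figure legends: mean ± SEM for purity/frequency
panels, median for the FSC and functional panels. Whether published
functional percentages are background-subtracted is also unstated, so
`reproduce()` reports both raw and unstimulated-control-subtracted
values, labelled; comparisons use the raw values.

Undefined statistics (empty gates — routine for CD56^neg^ subsets in
small healthy-donor samples) propagate as missing values, never zeros,
and pairs with missing values are dropped before testing.

## 6. Problem sizes and numerical choices

The default study is 20 donors × 50,000 events per condition, master
seed 42 — the scale of the desk analysis the package targets (cohort
figures show 10–20 donor dots). Per-donor seeds derive affinely from
the master seed (kept below 2³¹); perturbed conditions derive their own
seeds, so every table in a study is reproducible in isolation. The test
suite exercises the full default scale for the acceptance-style checks
and much smaller cohorts (2–5 donors, 2,000–20,000 events) for
structural tests.

## 7. What passing tests do and do not show

The generator emulates: mixture composition, bimodal marker expression,
compartment-level donor variability, disease-dependent expansion,
CD16 shedding, and stimulus-dependent functional responses. It does
**not** emulate spillover, doublets, acquisition drift, within-donor
correlation of marker levels beyond population identity, or
within-compartment compositional variability. Consequently, green tests
show that the gating/statistics machinery recovers the planted
structure under realistic separation and noise — not that NKp80 is
superior in any particular real dataset.

Known limitations:

* In the untreated-HIV preset the CD16 gate's purity deficit, while
  small (≈ 96% vs ≈ 98%), remains statistically significant across 20
  donors, whereas the corresponding published comparison is reported as
  non-significant; the synthetic contaminant load does not shrink in
  disease. `reproduce("4B")` therefore reports, but does not assert,
  the untreated-HIV comparison.
* The Eomes truth channel is bimodal with the same two-state model as
  surface markers; real intracellular stains are messier.
* The quantile fallback ties functional background to the 95th
  percentile by construction (≈ 5% background), which is higher than a
  well-set-up real assay.
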