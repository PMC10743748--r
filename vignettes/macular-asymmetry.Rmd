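---
title: "Methods: hemispheric macular asymmetry statistics and their normative ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemispheric macular asymmetry statistics and their normative ranges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppasym)
```

## The measurement model

The posterior pole protocol samples macular thickness on an 8×8 grid of
3°×3° cells aligned to the fovea–disk axis, for ten layer segmentations
(RNFL, GCL, IPL, INL, OPL, ONL, RPE, INNER, OUTER, RETINA). Rows are
numbered 1 (most inferior) to 8 (most superior), columns 1 (most temporal)
to 8 (most nasal). Because the numbering is *specular* between eyes —
cell 1.1 is inferior-temporal in right and left eyes alike — identically
addressed cells are anatomically homologous across laterality. Two
consequences drive the design:

* **Correspondence is pure arithmetic.** The cell mirrored across the
  horizontal midline is `(9 − r, c)`; `corresponding_cell()` is an
  involution pairing the 64 cells into 32 inferior–superior pairs, and no
  laterality-dependent remapping of data is ever needed.
* **"Right-eye format" is display-only.** Showing left eyes in right-eye
  format is implemented as a column mirror applied at rendering
  (`display_orientation()`); stored addresses and every statistic are
  unaffected. This avoids the classic failure mode of mutating data for
  display and then double-mirroring.

Grids must be complete (64 finite, non-negative cell values). There is no
imputation: clinical practice excludes artefactual scans rather than
repairing them, and a silently imputed cell would contaminate 1 of only 32
pairs.

## Asymmetry statistics

All asymmetries are signed **inferior − superior** differences in microns.
The convention is fixed rather than configurable: a single documented sign
avoids an entire class of interpretation errors, and it makes the RNFL —
physiologically thicker inferiorly — carry positive asymmetry.

For a cohort of $n$ eyes (one per subject; eyes are the independent
sampling units) and one layer:

* per pair, the per-eye differences $d_i$ give $\bar d$, $s_d$ (sample SD,
  $n-1$), $t = \bar d / (s_d/\sqrt n)$, and a two-sided p-value on $n-1$
  degrees of freedom (`paired_t_test()`, hand-implemented and cross-checked
  against `stats::t.test` in the tests);
* per hemisphere, the pooled mean and SD over all eyes × 32 cells, plus the
  paired test on per-eye hemisphere means (`hemisphere_summary()`). The
  pooled mean is identical whether computed over all cell values or over
  per-eye means (equal weights); the pooled SD deliberately pools spatial
  with between-subject variation, matching how hemisphere-level reference
  tables report dispersion (their SDs are far larger than any plausible SD
  of 32-cell averages);
* per pair, the 2.5th and 97.5th percentiles via linear interpolation
  between closest order statistics at rank $1 + q(n-1)$
  (`stats::quantile` type 7 — the documented, bit-exact choice);
* significance at two-sided α = 0.05 per pair, with *no* multiplicity
  correction by default, mirroring standard practice for these cell maps;
  Holm and Benjamini–Hochberg are available (`adjust=`) and affect only the
  `significant` flag, never the reported raw p-values.

Degenerate inputs are resolved explicitly: all-zero differences give
$t = 0, p = 1$ (no evidence of asymmetry); constant non-zero differences
($s_d = 0$, $\bar d \ne 0$) are rejected as degenerate rather than reported
as infinite $t$.

Normality screening uses the one-sample Kolmogorov–Smirnov test with
plug-in mean and SD. With estimated parameters and without a Lilliefors
correction this screen is anticonservative; it is advisory only and never
switches the pipeline to nonparametric tests, because the reference
methodology relies exclusively on paired $t$ tests.

## Normative database and classification

`build_normative_database()` stores, per (layer, pair), the percentile
range plus mean, SD and reference $n$ for audit; 10 × 32 = 320 entries.
Ranges are computed on **signed** differences (two distinct percentiles are
only meaningful for a signed quantity). Classification
(`classify_eye()`) is inclusive at both bounds — only values strictly
*below* P2.5 or *above* P97.5 are flagged — and is monotone in the observed
difference. By construction, classifying the reference cohort against its
own database flags ≈5% of observations per entry (with type-7 interpolated
bounds at $n$ = 300, exactly 16/300 ≈ 5.3% fall strictly outside).
Persistence is versioned JSON (`ppasym-normdb-1`) with round-trip identity
and rejection of duplicate keys or foreign schema versions.

## Maps

The significance-masked heatmap plots **half** the pair's mean difference,
attributed symmetrically: $+\bar d/2$ at the inferior cell and $-\bar d/2$
at the superior cell. The halving makes the two cells' colours sum to the
pair difference while each hemisphere displays its own excess (red =
thicker, blue = thinner); whether the source display plots both hemispheres
or one is not fully determinable, and the symmetric convention is the one
consistent with per-cell red/blue semantics. Non-significant pairs are
masked black as a unit; the midline is drawn green; the colour scale is
symmetric about zero so equal magnitudes get equal saturation. The
device-style per-eye map shows $|d|$ per pair on a linear grayscale ramp
clamped at 30 µm — the instrument's documented display ceiling — so a 45 µm
difference renders like 30 µm.

## The synthetic cohort generator

The generator exists so the whole pipeline — statistics, database,
classification, rendering — is exercised end-to-end on data with known
ground truth. Defaults emulate the reference study population: 300 eyes,
51% right eyes, and per-layer hemisphere means fixed to the published
healthy-adult values (`default_calibration()`).

For eye $e$, layer $l$, cell $a$:

$$y_{ela} = \mu_{l,h(a)} + g_l(a) + b_{el} + \varepsilon_{ela}, \qquad
b_{el} \sim N(0, \sigma^2_{subj,l}),\;
\varepsilon_{ela} \sim N(0, \sigma^2_{cell,l}),$$

floored at 0 µm (under the default calibration the floor is hit with
negligible probability, so expected pooled hemisphere means equal the
calibration means).

**Variance decomposition.** The published hemisphere SDs pool
between-subject and spatial variation without decomposing them. Writing
$\bar\sigma_l$ for the mean of the two printed hemisphere SDs, the defaults
are $\sigma_{subj} = 0.20\,\bar\sigma$, $\sigma_{cell} = 0.35\,\bar\sigma$,
and a deterministic spatial gradient $g_l$ carrying the remainder
($\approx 0.915\,\bar\sigma$, capped at 35% of the smaller hemisphere mean
so base thicknesses stay positive). The noise fraction is the component
that matters scientifically: pair differences have SD $\sqrt2\,
\sigma_{cell}$ because the subject effect and the midline-symmetric
gradient cancel within a pair, and 0.35 makes the implied normative ranges
reproduce the qualitative reference findings — GCL ranges stay within
±30 µm (≈ ±10 µm), while some peripheral RNFL ranges exceed the 30 µm
device ceiling.

**The spatial gradient** (default `spatial_profile = "smooth-gradient"`) is
a pericentral Gaussian mound standardized within each hemisphere to mean 0
and SD exactly `spatial_sd`, so hemisphere-level calibration is untouched
while per-cell maps get realistic spatial structure. It is
midline-symmetric, hence invisible to all pair statistics; `"flat"`
disables it.

**What the generator does not emulate:** the skewed, arcuate RNFL
topography (a Gaussian model with the full printed RNFL SD would produce
negative thicknesses, hence the cap — simulated RNFL pooled SDs understate
the printed ones); per-cell mean structure beyond the smooth mound (no
public per-cell means exist to calibrate it); segmentation error, fixation
artefacts, and age/sex/axial-length effects. Passing tests therefore
demonstrate correctness of the *pipeline arithmetic and its operating
characteristics under the stated model*, not per-cell realism of any
specific population.

**Randomness.** One seeded generator drives each run; the caller's RNG
state is preserved. Lesion assignment (`inject_lesions()`) draws from a
separate seed sub-stream so toggling lesions never perturbs base
thicknesses. `round(affected_fraction × n)` eyes are lesioned, with
per-eye, per-cell ground-truth labels returned; lesioned thicknesses are
floored at 0 µm (a 40 µm thinning of a 33 µm GCL removes the layer).

A small documented inconsistency in the reference demographics (152 right
+ 147 left = 299, reported as 300 with 51%/49%) is resolved by taking
`right_fraction = 0.51` and rounding.

## Problem sizes and numerical checks

The test suite validates on cohorts of 2–300 eyes: structural and oracle
checks on tiny fixtures; parameter recovery at $n$ = 300 against 3
model-based standard errors of the pooled mean,
$\mathrm{SE} = \sqrt{\sigma^2_{subj}/n + \sigma^2_{cell}/(32n)}$ (the
gradient is deterministic and contributes none); type-I error over 1000
null replicates of $n$ = 300 against 99% binomial bounds; per-pair null
rejection rates over 40 generated cohorts; and end-to-end detection of
−40 µm superior GCL lesions in 10% of 300 eyes against a clean-cohort
database. Everything runs in well under a minute on one CPU.

## Limitations

* Normative ranges are empirical percentiles: at $n$ = 300 the 2.5th/97.5th
  percentile estimates carry sampling error of roughly $0.8\sigma_d/\sqrt{n/100}$
  microns; databases built from small cohorts will have unstable tails.
* No covariate adjustment (age, sex, axial length) — reference ranges are
  marginal.
* The KS screen is anticonservative with estimated parameters.
* Classification is binary (inside/outside the central 95% range); no
  continuous percentile score is produced.
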