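---
title: "Measuring asymmetric reporter partitioning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring asymmetric reporter partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asympart)
```

# The measurement model

A dividing budding-yeast cell in telophase carries two nascent nuclei —
one destined for the mother, one for the daughter. A daughter-specific
transcription factor such as Ace2 should appear in exactly one of them.
The package quantifies this from two-channel widefield images:

* a **nuclear marker** channel (histone fusion, e.g. Hta1-CFP) present
  in every nucleus, used for segmentation;
* a **reporter** channel (e.g. Ace2-YFP) whose partitioning is the
  phenotype;
* optionally a **bud-neck** channel (e.g. Myo1-RFP) whose spot between
  the two nuclei marks a cell that has not yet completed cytokinesis.

For each segmented nucleus $k$ and channel $c$ the package computes

$$ I^{\mathrm{corr}}_{k,c} \;=\;
   \underbrace{\overline{I_{k,c}}}_{\text{mean over object}}
   \;-\;
   \underbrace{\overline{I^{\mathrm{ring}}_{k,c}}}_{\text{mean over ring}} $$

where the ring is the pixel set between the 4-step and 2-step
morphological dilations of the object (one step = one application of a
3×3 square structuring element), minus the 2-step dilation of *any*
object, clipped to the image. Excluding every object's inner dilation
prevents the partner nucleus of a pair from inflating the background
estimate; because background is diffuse, pixels shared by the rings of
two nearby nuclei are counted for both.

A telophase pair with corrected reporter intensities $(I_m, I_d)$ is
summarised by the **asymmetry index**

$$ \mathrm{AI} = \frac{|I_d - I_m|}{I_d + I_m} \in [0, 1], $$

undefined when $I_m + I_d = 0$, and by the **cumulative intensity**
$I_m + I_d$. The absolute value makes the index orientation-free, which
the stated 0–1 range for both orientations forces; it is
scale-invariant, so it compares strains imaged at different exposures.
Negative corrected intensities (background over-subtraction under
noise) are clamped to zero before either statistic, and the clamped
count is logged.

## Presence calls and the S-phase reference

Whether a nucleus "contains" reporter is decided against a threshold
calibrated from a reference population that genuinely lacks nuclear
reporter: budded single-nucleus (S-phase) cells. Presence is
`corrected > threshold` with a *strict* inequality — the threshold
defines nuclei *without* reporter, so equality stays negative. The four
categories follow from the two presence calls: daughter-only
(`asymmetric_daughter`), mother-only (`asymmetric_mother`), both
(`symmetric`), neither (`none`). Screen-style tallies merge the two
asymmetric orientations.

**Choice of calibration statistic.** The default is the **maximum** of
the reference values. The alternative — a quantile at level $p$ — pins
the false-presence rate of truly reporter-free nuclei at exactly
$1-p$, because reference and test nuclei sample the same null
distribution; with $p = 0.95$ that builds a 5% error floor into every
reporter-free nucleus, which is enough to push overall pair-category
accuracy below 95% under realistic category mixtures. The maximum of
$n$ reference values instead gives a false-presence rate of about
$1/(n+1)$, which shrinks as the reference population grows, and
matches the operational reading of the protocol ("brighter than every
S-phase nucleus"). `calibrate_threshold()` exposes `percentile` and
`fixed` alternatives; the model records the statistic, the reference
size and the reference median/quartiles for provenance.

## Pairing and staging

The original protocol selects telophase cells manually; the honest
in-silico analog is an annotation table (`pair_id`,
`mother_object_id`, `daughter_object_id`) taken verbatim. For
synthetic data a heuristic mode pairs nuclei that are mutual nearest
neighbours within 20 px (the generator's mother–daughter separation is
14 px and distinct cells are kept farther apart). Mother/daughter
identity is *never* inferred from size — delayed daughters can outgrow
their mothers — so heuristic pairs carry `role_known = FALSE` and only
annotation-backed pairs support the orientation-resolved categories.

A pair is `before` cytokinesis when a bud-neck spot lies within 15 px
of the midpoint between its nuclei, `after` otherwise, and `unknown`
when no bud-neck channel was analysed.

# The synthetic-scene generator

Because the raw screen images are not publicly deposited, validation
runs on generated scenes with exact ground truth. Each scene is driven
by a single integer seed; generation and rendering are fully
deterministic given the seed.

Nuclei are **hard discs** (radius 4 px by default), not Gaussian blobs,
so area- and flux-based oracles are exact; optical blur is applied
afterwards as convolution with a Gaussian PSF (σ = 1.5 px) under
circular boundary conditions, which conserves flux exactly. The
background is a constant (100 a.u.) plus a weak linear gradient
(0.02 a.u./px per axis), mimicking residual illumination slope. Noise
is Poisson shot noise on the expected count followed by Gaussian read
noise (σ = 3 a.u.). With the default reporter amplitude (200 a.u. above
background) the contrast-to-noise ratio is ≈ 10.

Default study conditions, chosen once: 512×512 px scenes;
mother–daughter separation 14 px; cell-to-cell amplitude jitter ±20%;
category mixture 72% daughter-asymmetric / 13% symmetric / 15%
reporter-free, the tally typical of unperturbed cells; stage mixture
70% telophase / 20% S-phase / 10% G1; half of telophase cells retain a
bud-neck spot. Placement is rejection-sampled so the 4×-dilated discs
of distinct cells never touch (clearance 18 px), which guarantees that
background rings of different cells never merge; a scene too dense to
place fails with an explicit density error.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: 3-D defocus, photobleaching, non-linear
illumination fields, camera binning, autofluorescent cytoplasm, cell
bodies and debris, and touching or overlapping nuclei (no watershed
splitting is implemented). Results on real images depend on
segmentation quality in ways the disc-world cannot probe.

# Numerical and algorithmic choices

* **Dilation unit.** "2× / 4× dilation" is read as 2 and 4 iterations
  of a 3×3 square structuring element (the iterate-N semantics of the
  original analysis software); both step counts are configuration. An
  isolated single-pixel object therefore has a ring of exactly
  $9^2 - 5^2 = 56$ pixels, which the tests assert analytically and
  against a brute-force neighbourhood-max oracle.
* **Thresholding.** Otsu's method on the (normalised) histogram for
  nuclear channels, where foreground occupies a few percent of pixels.
  Bud-neck spots cover ~0.1% of pixels, where Otsu provably splits the
  background instead; their default is the robust
  `median + 6 × MAD` rule, falling back to the standard deviation when
  the MAD degenerates to zero on a noise-free flat background. A fixed
  threshold is available for both.
* **Connectivity.** 4-connected components; objects touching the image
  border are measured but flagged, and heuristic pairing excludes them.
* **Area band.** Nuclei: 6–400 px (a radius-4 disc covers 49 px, blur
  widens it); bud-neck spots: 2–40 px.
* **Degenerate inputs.** A constant image segments to zero objects
  (not an error); an empty S-phase reference is an error instructing
  the user to annotate S-phase cells or fix the threshold; a fully
  clipped ring yields `NA` corrected values and an exclusion flag;
  pairs with undefined corrected values classify as `unknown` and are
  excluded from tallies.
* **Quantiles.** All percentiles (threshold calibration, summaries) use
  linear interpolation (type 7), asserted against an independent
  sort-and-interpolate oracle.
* **The noise-free limit.** Classification is exactly 100% accurate in
  the idealized limit: no shot/read noise *and* a flat background.
  With a gradient but no noise, the exclusion of the partner nucleus's
  inner dilation desymmetrises the ring, giving reporter-free telophase
  nuclei a small deterministic corrected offset (±0.05 a.u. at default
  gradient) that isolated S-phase references do not share; only noise
  or a flat field makes the two nulls identical. At default noise this
  offset is ~30× below the noise scale and immaterial.

## Statistical conventions

The tests themselves are standard and delegated to R's stats package;
the package fixes the conventions and validates them against
independent oracles (full hypergeometric enumeration, 10⁵-draw
permutation):

* **Fisher's exact test**: two-sided by the probability-mass
  convention (sum of all tables with the observed margins no more
  likely than observed, with a 10⁻⁷ relative tie tolerance); the
  reported odds ratio is the sample cross-product. Enrichment tests
  are one-sided (greater) — only enrichment is reported.
* **Kruskal–Wallis**: midranks, tie correction, χ² reference with
  k−1 df; H = 0 and p = 1 when all pooled values are identical.
* **Wilcoxon rank-sum**: exact enumeration whenever there are no ties
  and the smaller sample has under 50 observations (R's convention;
  at n = 30 the continuity-corrected normal approximation can differ
  from the exact tail by more than 0.005, so exactness is preferred
  wherever affordable); otherwise the tie-corrected normal
  approximation with continuity correction. The method used is
  recorded in the result.
* **Proportion intervals**: Wilson score by default — it behaves
  sensibly at 0% and 100%, both of which occur in small telophase
  tallies — with Clopper–Pearson as an option.
* **No multiple-testing correction** is applied anywhere; the screen's
  reporting convention is raw p-values.
* **Percent rounding** in screen tabulations is half-up to integers,
  matching the printed style (90% class I, 38% chromosome
  segregation, 56% and 58% coverage).

# The screen layer

Scores from two independent investigators are reconciled per strain:
agreement stands; disagreement is overridden by a third scorer when
present and is otherwise `unresolved`. Reconciliation is idempotent
and order-independent, and the agreement/override/unresolved counts
are recorded.

The packaged hit table (`inst/extdata/table1_genes.tsv`) transcribes
the published 81-gene list with each gene's alleles, phenotype class
(I: partial loss of asymmetry; II: reporter in all nuclei at all
stages; III: symmetric reporter restricted to late mitosis), cellular
function, and membership of the mitotic cell-cycle annotation.
Printed allele spellings are preserved verbatim. Functional enrichment
runs against any user-supplied gene-to-category table — deliberately
not a live ontology: fold enrichment $(k/n)/(K/N)$ with a one-sided
hypergeometric p, sorted by p. Strain-level totals are *not* derivable
from the gene table (several alleles have multiple isolates in the
screened collection) and are never asserted.

# Problem sizes used in validation

The test suite validates on scenes of 10–100 cells at 256²–512²
pixels: ground-truth recovery uses a 100-pair telophase scene plus a
100-cell S-phase calibration scene at default noise (recall,
precision, pairing and category accuracy all ≥ 0.95 there, and exactly
1.0 in the idealized noise-free limit); morphology is checked on 200
random 32×32 masks; Fisher on 200 random tables with totals ≤ 40 at
10⁻¹² tolerance; rank tests against 10⁵-draw permutation oracles on 20
seeded datasets (absolute tolerances 0.02 for the Kruskal–Wallis χ²
approximation at group sizes 8–12, 0.005 for the exact Wilcoxon).
Pipeline determinism is asserted byte-for-byte on repeated runs.

# Known limitations

* No watershed splitting: touching nuclei merge into one object and
  are typically rejected by the area band, costing recall in dense
  fields.
* The heuristic pairing mode cannot assign mother/daughter roles, so
  orientation-resolved categories require annotation.
* Reporter-based segmentation (for experiments without a nuclear
  marker) cannot see reporter-free nuclei; `none` and half of each
  asymmetric pair are invisible in that mode, which the mask metadata
  records.
* The enrichment layer does no ontology propagation; categories are
  taken exactly as supplied.
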