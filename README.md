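# asympart

Quantification of asymmetric transcription-factor partitioning between
the nascent mother and daughter nuclei of dividing budding yeast, and
the bookkeeping of a genome-scale loss-of-asymmetry screen.

## The problem

At the end of mitosis the transcription factor Ace2 accumulates only in
the daughter-cell nucleus; mutations in many essential genes partially
or completely break this asymmetry. Quantifying the phenotype from
two-channel fluorescence microscopy (a histone marker such as Hta1-CFP
to find nuclei, and Ace2-YFP as the reporter) requires a small but
exacting chain of measurements:

1. **Segmentation** — nuclei are found in the marker channel as
   4-connected components above an automatic (Otsu) global threshold,
   filtered by area.
2. **Ring background** — for each nucleus, local background is the mean
   over the pixels between a 4x and a 2x morphological dilation of the
   object (3x3 square structuring element per step), excluding pixels
   near any other nucleus. The *corrected nuclear intensity* of a
   channel is the object mean minus its ring mean.
3. **Presence threshold** — S-phase cells exclude Ace2 from their
   nucleus, so the corrected reporter intensities of annotated S-phase
   nuclei calibrate the "reporter absent" null; a nucleus is
   reporter-positive when its corrected intensity strictly exceeds the
   calibrated threshold (default statistic: the reference maximum).
4. **Pair classification** — each telophase mother/daughter pair is
   `asymmetric` (reporter in one nucleus), `symmetric` (both) or `none`
   (neither), and carries two continuous statistics:

   * the **asymmetry index**,
     `AI = |I_daughter − I_mother| / (I_daughter + I_mother)`,
     ranging from 1 (total asymmetry) to 0 (total symmetry);
   * the **cumulative intensity**, `I_mother + I_daughter`.

   Pairs are staged relative to cytokinesis by the presence of a
   bud-neck (Myo1-RFP) spot near the inter-nuclear midpoint.
5. **Statistics** — Fisher's exact test for category proportions,
   Kruskal–Wallis and Wilcoxon rank-sum for intensity comparisons,
   Wilson 95% confidence intervals for proportions, median/quartile
   summaries.
6. **Screen layer** — reconciliation of two independent scorers with a
   third tie-breaker, tabulation of the published 81-gene hit table by
   phenotype class (I/II/III) and cellular function, and hypergeometric
   functional enrichment against a user-supplied annotation table.

Because the original raw images are not deposited, the package includes
a seeded synthetic-scene generator (`generate_scene()`,
`render_channels()`) that draws dividing cells as hard discs with known
amplitudes, optical blur, a linear background gradient and shot + read
noise — so every stage of the pipeline is validated against exact
ground truth.

## Worked example

```r
library(asympart)

scene <- generate_scene(scene_params(n_cells = 80), seed = 42)
imgs  <- render_channels(scene)

mask  <- segment_nuclei(imgs$marker)
rings <- background_ring(mask)            # 2x / 4x dilation ring
me    <- measure_objects(mask, rings, list(marker = imgs$marker,
                                           reporter = imgs$reporter))

# calibrate the presence threshold from the S-phase reference nuclei
truth <- match_objects(me, truth_table(scene))
ref   <- me$corrected_reporter[match(
           truth$object_id[truth$stage == "s_phase"], me$object_id)]
model <- calibrate_threshold(ref[!is.na(ref)])
model
#> threshold_model: 3.683 (max, n_reference = 15)

pairs <- pair_telophase(me)               # mutual-nearest-neighbour pairs
pairs <- classify_pairs(pairs, me, model)
tally_categories(pairs$category)
#>     category  n  fraction
#> 1 asymmetric 34 0.6538462
#> 2  symmetric  9 0.1730769
#> 3       none  9 0.1730769
```

The tally recovers the generator's mixture (72% asymmetric, 13%
symmetric, 15% none) within binomial sampling error of the 52 usable
pairs. The continuous statistics separate the categories sharply: the
median AI of asymmetric pairs is 0.992 versus 0.059 for symmetric
pairs, and the median cumulative pair intensity is 120.3 a.u.
(IQR 107.7–143.4).

`run_pipeline(run_config(...))` ties the stages into one deterministic
run that writes `measurements.csv`, `pairs.csv`, `summary.json` and an
attrition log; the `exec/asympart` script exposes the same stages as
shell subcommands (`simulate`, `quantify`, `classify`, `compare`,
`screen`, `run`).

The screen layer works from the packaged hit table:

```r
tab <- load_gene_table(system.file("extdata", "table1_genes.tsv",
                                   package = "asympart"))
tabulate_classes(tab)
#> class_summary: 81 genes, 100 alleles
#>   class n_genes pct_genes n_alleles
#> 1     I      73        90        86
#> 2    II       2         2         3
#> 3   III       6         7        11
#>                  category n_genes pct_genes
#> 1  Chromosome segregation      31        38
#> ...
```

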