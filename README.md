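# metalrisk

Assessment pipeline for heavy-metal pollution in surface soils sampled
across land-use functional areas — a commercial (A), an industrial (B)
and an agricultural (C) zone of a semi-arid region in NW China. The
package is aimed at environmental geochemists who need the standard
index battery, spatial surfaces and source-apportionment statistics for
Zn, Cu, Cr, Pb, As and Hg point-sample tables, plus a calibrated
synthetic-sample generator so the whole pipeline runs and is testable
without raw field data.

## What it computes

For a sample with concentration $C_i$ (mg/kg) and regional background
$B_n$:

* **Geo-accumulation index** $I_{geo} = \log_2\big(C_n/(1.5\,B_n)\big)$
  with the Muller class scheme (clean ≤ 0 … very high > 3);
* **Single-factor pollution index** $P_i = C_i/B_n$ (clean ≤ 1 … heavy
  > 5);
* **Potential ecological risk** $E_r^i = T_n^i\,C_i/C_n^i$ per element
  (Hakanson toxic-response coefficients Zn 1, Cr 2, Cu/Pb 5, As 10,
  Hg 40) and the per-sample sum $PRI = \sum_i E_r^i$ with risk classes
  low (< 90) … very high (> 720);
* **Area statistics**: mean ± SD, CV with the 36% strong-variation
  screen, SPSS-style skewness/kurtosis, exceedance ratios against
  Xinjiang background values and GB 15618-2018 screening levels,
  cross-area and composite means;
* **IDW surfaces**: inverse-distance-weighted concentration and PRI
  rasters with cellwise risk classification, exported as ESRI ASCII
  grids;
* **Source apportionment**: per-area Pearson matrices, KMO and
  Bartlett adequacy tests, correlation PCA with Kaiser retention and
  varimax rotation, hierarchical clustering of elements on the 1 − r
  distance.

The synthetic generator (`generate_area()`,
`default_study_fixture()`) draws Gaussian-copula samples with
moment-calibrated truncated-normal marginals and NORTA-inverted latent
correlations, reproducing the reference survey's per-area means,
ranges and correlation matrices at large n. See
`vignettes/pollution-assessment.Rmd` for the methods and their
assumptions.

## Worked example

```r
library(metalrisk)

# synthetic three-area survey, reproducible from one seed
samples <- default_study_fixture(seed = 20190104)
table(samples$area)
#>  A  B  C
#> 26 35 62

# indices per sample; PRI class distribution by area
tbl <- build_index_table(samples)
table(tbl$samples$area, tbl$samples$pri_class)
#>     Low risk Moderate risk Considerable risk High risk Very high risk
#>   A        0             9                17         0              0
#>   B        0            29                 6         0              0
#>   C        0            59                 3         0              0

# desk-level exceedance ratios from the reference area statistics
m <- area_marginals()
ex <- exceedance_ratios(m[m$area == "A", ])
round(ex$ratio_background[ex$element %in% c("Pb", "As", "Hg")], 2)
#> [1] 5.56 9.55 1.50
round(cross_area_mean_ratio(m, "As"), 2)
#> [1] 8.03

# a worked risk index: area-A mean concentration vector
worked <- compute_pri(setNames(m$mean[m$area == "A"],
                               m$element[m$area == "A"]))
round(worked$pri, 2); as.character(worked$class)
#> [1] 189.79
#> [1] "Considerable risk"
```

The Pb/As/Hg ratios say area-A topsoil carries 5.6, 9.5 and 1.5 times
the regional background of those elements; the summed Hakanson index of
the area's mean profile (189.79) falls in the "considerable risk" band
(180–360), driven mostly by As (95.5) and Hg (60).

The `analysis/` directory holds the same workflow as numbered driver
scripts (`01_simulate.R` … `05_sources.R`); each prints what it found
and writes its tables under `results/`.

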