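# karyodens

Quantitative image cytometry of chromatin condensation by Feulgen
densitometry, for cell biologists studying chromatin remodeling — for
example under histone deacetylase (HDAC) inhibitors such as valproic
acid or trichostatin A, which loosen chromatin packing in cultured
cells.

The Feulgen reaction stains DNA stoichiometrically, so the optical
density (OD) summed over a nucleus measures its DNA content, and the
spatial distribution of OD measures chromatin texture. Given a
per-pixel absorbance image, the package removes background (OD ≤
0.020), segments nuclei as 8-connected components, and computes for
each nucleus:

* **A_T** — total integrated absorbance (the Feulgen-DNA value / IOD);
* **A_C** — integrated absorbance over pixels above the condensed
  cutoff (OD > 0.100), and **Ac% = 100·A_C/A_T**;
* **S_T**, **S_C** — nuclear and condensed-chromatin areas (µm², at a
  0.5 µm pixel pitch), and **Sc% = 100·S_C/S_T**;
* **AAR = (A_C/S_C)/(A_T/S_T)** — the average absorption ratio, the
  factor by which condensed-chromatin mean absorbance exceeds the
  whole-nucleus mean (≥ 1 wherever defined).

Chromatin decondensation lowers Sc% and raises AAR; the package plots
each nucleus on the Sc%–AAR phenotype plane, bins Feulgen-DNA values
into C-value ploidy classes (<2C, ~2C, ~4C, …) against a 2C
calibration anchor, compares groups with two-sided Student t or
Mann-Whitney tests (α = 0.05), scores TUNEL DNA-fragmentation images
by relative dark-spot area (gray window 60–100; ranks weak < 5%,
moderate 5–49%, strong ≥ 50%), and tallies mitotic/cell-death index
ratios from visually scored counts. A seeded synthetic-nucleus
generator with exact ground truth makes the whole pipeline testable
without microscope data.

## Worked example

Measure one synthetic nucleus through the full segmentation path:

```r
library(karyodens)

nuc   <- generate_nucleus(nucleus_sim_params(condensed_fraction = 0.6,
                                             seed = 42))
masks <- segment_nuclei(nuc$image)           # background rule + labeling
measure_nucleus(nuc$image, masks[[1]])
#> nucleus_measurement (3063 px): A_T=465.4 S_T=765.8 um2 Sc%=60.82 AAR=1.307
nuc$truth$true_condensed_fraction            # 0.6000653
```

The nucleus was generated with 60% of its area condensed; the pipeline
measures Sc% = 60.8 (the 0.100 cutoff misclassifies ~1% of noisy
diffuse pixels) and a textural contrast AAR of 1.31.

A two-condition comparison, 100 nuclei per preset:

```r
cfg <- run_config(out_dir = "demo", seed = 7, nuclei_per_condition = 100,
                  make_plots = FALSE)
res <- run_karyometry(cfg)
subset(res$summaries, variable %in% c("Sc_pct", "AAR"))
#>         group variable   n      X       S     Md
#> 1     control   Sc_pct 100 62.310 11.1444 62.678
#> 2     control      AAR 100  1.301  0.1137  1.290
#> 5 decondensed   Sc_pct 100 42.589 10.9523 42.704
#> 6 decondensed      AAR 100  1.533  0.1480  1.521
subset(res$comparisons, variable %in% c("Sc_pct", "AAR"))
#>   group_a     group_b variable         test statistic        p significant
#> 1 control decondensed   Sc_pct  t-two-sided      12.6 3.52e-27        TRUE
#> 2 control decondensed      AAR mann-whitney    1094.0 1.39e-21        TRUE
```

The decondensed preset drops the median Sc% from ~63 to ~43 while AAR
rises from 1.29 to 1.52, both highly significant — the signature of
chromatin decondensation. `run_karyometry()` also writes per-nucleus
`measurements.csv`, C-class histograms, an Sc%–AAR scatter plot and a
JSON run manifest; `run_tunel()` does the analogous job for TUNEL
positivity tables. A thin command-line front end lives in
`inst/cli/karyodens`.

See the vignette `vignettes/chromatin-cytometry.Rmd` for the model,
parameter choices and limitations.

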