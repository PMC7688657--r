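# stedsynapse

Quantitative analysis of secretory-pathway marker abundance and
distribution at synapses in multichannel STED images.

Post-synaptic compartments keep local outposts of the secretory pathway —
endoplasmic reticulum (calreticulin), ERGIC (ERGIC53), trans-Golgi network
(TGN38) and spine apparatus (synaptopodin). Whether the amount and the
spatial spread of these markers scale with synaptic *strength* (homer or
vGLUT1 intensity) or *activity* (live SYT1 labelling of recycling
vesicles) is a question one answers with punctum-centred average-image
analysis. This package implements that analysis as a tested, reproducible
pipeline for neuroscientists working with 2-D STED data (~30 nm pixels),
plus a synthetic-image generator with full ground truth so the whole chain
is verifiable without microscopy data.

## The statistic at the core

For each synaptic punctum a 3 × 3 µm crop is excised; crops are sorted
into five equal-occupancy bins by marker intensity (after per-experiment
median normalization and mean ± 3 SD outlier exclusion) and averaged
pixelwise per bin. From each bin's average POI image the radial profile
m(r) — mean intensity at integer radius r from the centre — yields the
**periphery/centre ratio**

    ratio = mean{ m(r) : r = 35..45 px } / mean{ m(r) : r = 0..9 px }

Low values mean the protein is concentrated at the synapse; values near 1
mean it is dispersed (a uniform image gives exactly 1). The bin-5 minus
bin-1 **delta** summarizes how marker intensity modulates the spread.
Abundance is quantified separately by Spearman correlation of POI and
marker intensities, with per-bin means ± SEM and a linear fit over bin
means. POI structures are segmented with an à-trous B3-spline wavelet
(scale 2, MAD threshold), and manually landmarked mushroom/stubby spines
are rigidly aligned (head at centre, shaft down) and averaged.

## Worked example

Simulate a 60-synapse population (4 experiments with batch effects) and
run the post-synaptic-marker analysis end to end:

```r
library(stedsynapse)
synth <- synth_config(n_synapses = 60, seed = 42)
res <- run_pipeline(pipeline_config(), synth = synth, marker_mode = "post")
res$per_bin
#>   bin_index  n marker_mean marker_sem poi_mean poi_sem ratio
#> 1         1 14       0.828    0.00740    0.959 0.00356 0.993
#> 2         2 14       0.914    0.00788    0.997 0.00560 0.700
#> 3         3 13       1.001    0.00401    1.010 0.01110 0.696
#> 4         4 13       1.073    0.01206    1.036 0.01088 0.605
#> 5         5 13       1.243    0.01789    1.031 0.01290 0.577
res$correlations
#>        marker  n spearman_rho  p_value stars fit_slope fit_intercept
#> 1 post_marker 67        0.707 2.24e-11  ****     0.169         0.835
```

Reading the output: 67 valid crops were found, binned by normalized
post-marker mean (`marker_mean` rises by construction). `poi_mean` rises
with the bins and Spearman's rho = 0.71 (****) — the generator couples
POI spot *count* to the strength latent, and the pipeline recovers that
abundance correlation. The per-bin `ratio` here *falls* with bin index:
spot spread is coupled to the independent activity latent, so stronger
synapses gain POI signal over a fixed background and the average image
becomes more centre-weighted. Redistribution proper is demonstrated under
controlled conditions by the recovery benchmark, which builds a fixture
whose spread is known per bin and compares the measured ratios with the
generator's analytic expectation:

```r
run_recovery_benchmark()
#>                                  check    value target tolerance pass
#> 1 gradient: ratios strictly increasing  1.00000  1.000      0.00 TRUE
#> 2          gradient: delta vs analytic  0.46156  0.507      0.05 TRUE
#> 3                 null: |spearman rho|  0.01230  0.000      0.10 TRUE
#> 4                    null: ratio delta -0.00714  0.000      0.03 TRUE
```

A thin command-line wrapper is provided in `inst/scripts/stedsynapse`
(`simulate`, `analyze`, `benchmark` subcommands) for shell-driven runs on
directories of multichannel TIFFs written with `write_multichannel_tiff()`
(multi-page float TIFF + JSON sidecar).

See the vignette `vignettes/quantifying-secretory-markers.Rmd` for the
full model description, parameter rationale, the generator's analytic
expectation (noise chain included) and known limitations.

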