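---
title: "Quantifying secretory-pathway markers at synapses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying secretory-pathway markers at synapses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stedsynapse)
```

## The scientific question and the measurement

Neurons distribute elements of the secretory pathway — endoplasmic
reticulum (calreticulin), ER–Golgi intermediate compartment (ERGIC53),
trans-Golgi network (TGN38) and spine apparatus (synaptopodin) — along
their dendrites, close to post-synaptic sites. Whether the *amount* and
the *spatial spread* of these organelle markers track synaptic strength
(size of the post-synaptic density, read out by homer; size of the
pre-synaptic vesicle pool, read out by vGLUT1) or synaptic activity
(recycling vesicles, read out by live SYT1 labelling) is a quantitative
image-analysis question. `stedsynapse` implements the analysis as a
reusable pipeline for multichannel STED images at ~30 nm pixel pitch:

1. **Localize** synaptic puncta in a chosen marker channel (explicit
   absolute/quantile threshold, 8-connected components, intensity-weighted
   centroids).
2. **Excise** a 3 × 3 µm square crop centred on each punctum.
3. **Clean and normalize**: exclude crops whose marker mean lies outside
   mean ± 3 SD, divide intensities by the median of their experiment.
4. **Bin** crops into five ordinal groups of near-equal size by marker
   intensity, and average the protein-of-interest (POI) channel pixelwise
   per bin.
5. **Radial statistic**: from each bin's average image, compute the mean
   ring intensity at integer radii and form the periphery/centre ratio —
   mean of ring means at radii 35–45 px over mean at radii 0–9 px. A value
   far below 1 means the POI is concentrated at the synapse; near 1 means
   it is dispersed. The bin-5 minus bin-1 delta summarizes how strongly
   marker intensity modulates POI spread.
6. **Spots**: segment the POI into discrete structures with an à-trous
   B3-spline wavelet (scale-2 detail plane, MAD-based threshold) and
   summarize counts and sizes.
7. **Spines**: rigidly align manually landmarked mushroom/stubby spine
   crops (head centre to the image centre, shaft pointing down) and
   average them with missing-pixel awareness.
8. **Statistics**: Spearman rank correlation (exact permutation p for
   n ≤ 9, t-approximation otherwise), per-bin mean ± SEM, OLS line over
   bin means, conventional significance stars with strict thresholds.

Because no microscopy data are redistributed with the package, a
synthetic-image generator with complete ground truth stands in for the
study data; every stage of the pipeline is validated against it.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `crop_side_um` | 3.0 | µm | covers a whole post-synaptic site (~1.5 µm spine length) while limiting neighbours |
| pixel size | 30 | nm | acquisition pitch the windows below are calibrated to |
| `n_bins` | 5 | — | ordinal strength/activity groups of near-equal occupancy |
| `centre_radius_px` | 10 | px (radii 0–9) | "centre" window of the ratio, 0–0.3 µm |
| `ring_range_px` | (35, 45) | px inclusive | peripheral ring, 1.05–1.35 µm |
| `outlier_k` | 3 | SD | single-pass mean ± 3 SD exclusion |
| `wavelet_scale` | 2 | dyadic scale | spot sizes ~4 px at 30 nm pitch |
| `wavelet_threshold_pct` | 80 | % | maps to k = 3 in `t = k·MAD/0.6745` |
| `min_spot_area_px` | `2^scale + 1` (= 5) | px | see "Spot detection" below |
| `min_punctum_area_px` | 4 | px | rejects single-pixel threshold noise when localizing synapses |

Geometry notes. The crop side in pixels is rounded **up to odd** (101 px
for 3 µm at 30 nm), so "centred on the punctum" names an exact central
pixel — a nominal 100 px crop has none, and radial binning needs an
unambiguous origin. The ring window is read inclusively (radii 35–45,
eleven integer radii); the centre window is radii 0–9 (ten radii).
Pixels are indexed 1-based as `(row, col)` with pixel-centre semantics,
the native R convention; all distances are computed between pixel
centres, so the geometry is identical to a 0-based description.

The marker threshold is an explicit, logged rule (absolute value or
intensity quantile, default the 0.98 quantile) replacing an inherently
manual step, so runs are reproducible from their manifest alone.

## The radial ratio and its analytic behaviour

`radial_profile()` assigns every pixel to the integer radius
`round(d)` and records per-radius means and counts up to the largest
complete ring; the profile conserves total intensity by construction.
The ratio is an *unweighted* mean of ring means in each window (the
convention of the ImageJ radial-profile plug-in this replaces). Two
anchors make the statistic interpretable and testable:

* a spatially uniform image gives ratio exactly 1 (fully dispersed);
* for centred isotropic Gaussians the ratio is strictly increasing in the
  width and approaches 1 from below — verified in the test suite on a
  grid of widths against an independently coded lattice oracle.

## The synthetic generator

Each synapse carries two log-normal latent variables: strength `S`
(homer-like amplitude `homer_gain · S`, with log-normal amplitude noise)
and activity `A` (SYT1/vGLUT1-like amplitude), independent by default —
matching the experimental observation that pre- and post-synaptic
strength are uncorrelated — with an optional Gaussian-copula coupling.
The POI is a Poisson number of discrete spots (rate
`lambda0 + lambda_slope · S`, defaults giving ≈3.5 spots per synapse, in
line with the three-to-four spots per spine head seen for these markers)
scattered isotropically around the synapse centre with standard deviation
`sigma0_nm + sigma_slope_nm · A`. Channels are rendered as
Gaussian-blurred point/punctum sources (STED-like 60 nm FWHM for protein
channels, confocal-like 250 nm for actin; marker puncta additionally
carry a 100 nm object size in quadrature), on a flat background
(2 counts), then passed through Poisson noise (gain 1) plus Gaussian
read noise (SD 2 counts) and clipped at zero, as detector counts are.
Each experiment receives a log-normal multiplicative intensity factor
(sdlog 0.15) so the median-normalization stage has real work to do.

Photometry was chosen to be realistic for antibody-labelled STED at this
pixel pitch: an integrated marker punctum of 5000 counts and POI spots of
400 counts give punctum peak SNRs of order 10–100 over the read noise,
and — importantly for the pipeline's own contract — make the marker crop
mean (signal ≈ 0.5–1.5 counts above a 2-count background, against a crop-
mean SEM of ≈0.03) informative enough that quantile binning recovers
intended groupings. With substantially dimmer, sub-realistic puncta the
binning stage degrades into noise ordering, which is a property of the
measurement, not of the code.

What the generator does **not** emulate: dendrite/shaft morphology as
extended structures (markers are puncta only), 3-D optics and axial
blur, photobleaching or temporal dynamics, spatially varying background,
chromatic misalignment, and membrane-shaped ER networks. Passing the
recovery tests therefore demonstrates that the pipeline measures what
the model puts in — not that real tissue satisfies the model.

### The generator-side analytic expectation

For the spread-gradient fixture (five bins of fixed scatter widths with
bin-wise increasing marker brightness), the expected bin-average POI
image is `background + C · G(d; σ_eff)` with
`σ_eff² = σ_scatter² + σ_PSF²` and `C` the expected total spot intensity
per crop. `analytic_spread_ratio()` evaluates this expectation on the
pixel lattice with the same integer-radius binning as the pipeline, and
additionally models two second-order features of the measurement chain,
both of which were found necessary when validating the prediction against
large simulations (600–1500 crops per width):

* **zero-clip of the recorded signal.** `E[max(0, Pois(gµ)/g + N(0, r))]`
  exceeds µ near zero. Crucially the excess must be averaged over the
  *per-crop* pixel distribution — background almost everywhere, sparse
  bright deposits — not evaluated at the ensemble-mean image: the clip
  bonus is essentially `b(background)` wherever no spot lies, and ≈0 on
  the rare deposit pixels. The prediction uses the sparse-deposit form
  `v(d) + b(bg)·(1 − p_spot(d))` with `p_spot` the probability that a
  spot deposit covers the pixel.
* **scatter truncation.** Spot offsets are redrawn to stay inside the
  crop, renormalizing the scatter density; the factor is carried
  explicitly (it cancels in the ratio only in the linear regime).

Both terms were found necessary, and the resulting prediction validated,
against large dedicated simulations during design; in the test suite the
gradient fixture's measured bin-5 − bin-1 delta is compared to the
prediction within ±0.05. At the default conditions (100 crops per bin,
≈3.5 spots per synapse) the delta carries sampling variability from
spot counts and spot positions in the centre window that is inherent to
the statistic at this sample size.

## Spot detection

`atrous_decompose()` implements the undecimated B3-spline ("à trous")
scheme — iterated separable smoothing with (1,4,6,4,1)/16 and dyadic hole
spacing, mirror boundaries — which reconstructs exactly
(`image = ΣW_j + residual`). Detection hard-thresholds the scale-2 detail
plane at `t = k·MAD/0.6745`, with the sensitivity percentage mapped
monotonically to `k = (100 − s)/10 + 1` (s = 80 ⇒ k = 3; larger s is more
permissive). This mapping is this package's explicit convention; it is
*not* guaranteed to equal the thresholding of the original Icy
Spot-Detector plug-in, whose percentage semantics are undocumented.

The minimum spot area defaults to `2^scale + 1` pixels (5 at scale 2)
rather than a fixed single-pixel guard. The reason is empirical and
structural: supra-threshold *noise* in a scale-j detail plane is spatially
correlated and arrives as blobs of up to ~2^j pixels, so a 1–2 px rule
passes roughly one spurious component per 64 × 64 crop at k = 3, whereas
genuine PSF-sized spots at detection-worthy SNR occupy ≥7 px in the
scale-2 plane. The scale-adaptive floor restores the intended behaviour
(false positives ≪ 0.05 per crop at recall ≈ 1 for SNR ≥ 8, measured on
the generator's detection fixture in the test suite) while remaining a
single configurable integer.

Spot size is reported as the equivalent-disk diameter in nm from the
supra-threshold area; centroids are intensity-weighted on the original
(not wavelet) image.

## Spine alignment

Alignment is **rigid** (rotation + translation, bilinear resampling): no
scaling or warping, since overlaying spines of different sizes is a
statement about the data, not a registration choice. The head centre
(centroid of the four manual head border points) goes to the central
pixel and the head-centre→shaft-junction direction to "straight down".
Output pixels whose pre-image lies outside the source are `NA` — never
zero — and `average_aligned()` divides by the per-pixel coverage count,
avoiding rim artefacts that zero-filling would create. Aligning an
already-aligned crop is the identity to interpolation tolerance, and a
90°-rotated copy returns to its reference exactly (grid-coincident
resampling).

Crops remain centred on the synaptic punctum at excision time (the
homer-like channel), while alignment centres on the spine head — the two
stages answer different questions and both conventions are kept.

## Order of operations and other numerical choices

* **outlier exclusion → median normalization → pooled binning.** The
  steps are listed without an order in the protocol this follows;
  excluding first prevents extreme values from moving the experiment
  medians. The exclusion uses the sample SD and keeps boundary values
  (`|v − mean| ≤ k·SD`).
* **Ties and remainders in binning** are resolved deterministically:
  stable input order breaks ties, spare crops go to the lowest bins.
* **Average images are built from raw crop arrays**; normalization
  applies to scalar statistics only, keeping image contrast physical.
* **Spearman** uses midranks; the exact permutation null (n ≤ 9) holds
  the observed ranks fixed and permutes one margin; for larger n the
  t-approximation is used. `cor.test` serves as an independent
  cross-check in the tests, never as the implementation.
* **TIFF storage**: 32-bit float pages scaled per channel into [0, 1]
  with the scale recorded in a JSON sidecar, because float TIFF outside
  [0, 1] is not portable across writers; round-trips restore original
  intensities to float-32 precision.
* Border crops are dropped, not padded: padding would bias the
  peripheral ring of exactly the images the ratio is computed from.

## Problem sizes used by the test-suite

The suite simulates at sizes chosen to keep each property identifiable
while running in well under a minute per file: 100 crops per bin for the
spread-gradient and equal-spread fixtures, 500 synapses for the
decoupled null (|rho| < 0.1, |delta| < 0.03), 200 crops for detector
recall/false-positive rates, and 24–32-synapse fields for end-to-end
determinism. Bands of the statistical checks are sized to roughly three
standard deviations of the corresponding estimator at those sample
sizes.

## Known limitations

* The periphery/centre ratio mixes POI dispersion with background level;
  comparisons are meaningful within an experiment series processed
  identically, which is how the pipeline uses it (deltas across bins).
* The ±3 SD outlier rule is weak at small n (a single extreme value can
  inflate the SD enough to keep itself); this is faithful to the
  protocol, not a recommendation.
* The sensitivity→k mapping and the Icy plug-in may differ; absolute
  spot counts should not be compared across the two tools.
* Axial structure is ignored; overlapping synapses along z appear merged,
  as in any 2-D analysis.
* Manual landmarks are consumed from CSV; no interactive picker is
  provided, and the generator's ground-truth landmarks stand in for a
  human annotator in all tests.
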