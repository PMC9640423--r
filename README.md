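# ripaq — riparian vegetation quality from multispectral imagery

Riparian strips — the vegetated bands between a river channel and the
surrounding land — filter runoff, stabilise banks and carry much of a
basin's biodiversity, but monitoring them in the field is slow and
expensive. `ripaq` implements a desk-based alternative for very high
resolution satellite imagery (WorldView-2-like: eight 2-m multispectral
bands plus a 0.5-m panchromatic band): it maps land cover inside the
stream buffer with object-based image analysis and scores the quality of
the riparian strip at regular sampling stations, so that field crews can
be sent where the index says the strip is degraded.

The package is aimed at remote-sensing analysts and river-basin managers.
All tabular results are tibbles, so they compose with dplyr/ggplot2.

## What it computes

**Riparian Strip Quality Index (RSQI).** For each sampling station (a
100-m stretch of one bank, clipped to the 50-m stream buffer), land-cover
percentages %LU<sub>i</sub> are taken over the station's non-water pixels
and combined with class weights W<sub>i</sub> (forest 10.0, crops 1.9,
bare soil 1.7, infrastructure/urban 1.9):

    RSQI = Σ (%LU_i × W_i) / 10

The index runs from 17 (all bare soil) to 100 (all forest) and is
categorised as very low (< 40), low (40–60), moderate (60–80) or high
(≥ 80). When field QBR scores (a four-block 0–100 habitat-quality index)
are available, stations are additionally triaged into conservation
(QBR > 90), recovery (55–90) or restoration (< 50), and RSQI/QBR
agreement is quantified with descriptive statistics, Shapiro–Wilk and
Levene assumption checks and Pearson correlation.

**The imagery chain.** Pansharpening (least-squares component
substitution with an exact spectral-consistency property), the red-edge
NDVI `(NIR − RE)/(NIR + RE)` (bands 7 and 6), PCA reduction of the eight
bands, and a standardised 4-band composite (PC1–PC3 + RE-NDVI). Objects
come from a multiresolution region-merging segmentation (Baatz–Schäpe
criterion: merge allowed while the colour + shape heterogeneity increase
stays below scale²; defaults scale 25, shape 0.1, compactness 0.1) and
are classified water / forest / crops / urban by a transparent threshold
cascade on RE-NDVI and brightness. Accuracy is assessed on a stratified
validation sample via the confusion matrix, overall accuracy and Cohen's
kappa.

**Synthetic scenes.** Because VHR imagery is proprietary, the package
ships a seeded simulator of WorldView-2-like scenes — meandering river,
riparian strips with crop/urban intrusions, patch-mosaic background,
class-specific spectra, Gaussian sensor noise, 4:1 PAN:MS resolution —
with ground-truth labels, so the whole pipeline is testable end to end.

## Worked example

```r
library(ripaq)

scene <- generate_scene(scene_spec(width_px = 96, height_px = 96, seed = 1))
prep  <- preprocess_scene(scene$ms, scene$pan)      # pansharpen + RE-NDVI + PCA
buf   <- buffer_stream(prep$composite, width_m = 50,
                       centerline = scene$truth$centerline)
seg   <- multiresolution_segment(prep$composite, segmentation_params(),
                                 mask = buf$mask)
seg
#> <ripaq_segmap> 12 segments over 384 x 384 px (scale 25)

objects <- classify_objects(object_features(seg, prep$ms, prep$rendvi))
scores  <- score_stations(class_raster(seg, objects),
                          scene$truth$centerline, n_stations = 1)
scores
#> # A tibble: 2 × 6
#>   station_id bank  chainage_m  n_px  rsqi rsqi_category
#>        <int> <chr>      <dbl> <int> <dbl> <chr>
#> 1          1 left        97.3 16402  66.8 moderate
#> 2          1 right       97.3 15632  60.2 moderate
```

The two rows are the two banks of the single station on this short test
reach: both strips hold a mix of forest and crop/urban intrusions, giving
a "moderate" RSQI in the 60s. On the same scene the object classification
recovers the simulated ground truth exactly (overall accuracy 1.0, kappa
1.0 over 12 objects); `autoplot(scores)` and `autoplot()` on a confusion
matrix give ready-made figures. A full run — including validation
sampling, metrics and artifact writing — is one call:

```r
manifest <- run_pipeline(pipeline_config(), "out/")   # or inst/cli/ripaq.R
```

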