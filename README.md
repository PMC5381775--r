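# stainring

Pixel-wise stain classification and radial ring profiling for
micropatterned stem-cell colonies.

## The problem

Human mesenchymal stem cells (hMSCs) grown in circular micro-confinements
differentiate in a spatially patterned way: adipogenic cells (fat lineage,
stained red by Oil Red O) accumulate at the colony center, osteogenic
cells (bone lineage, stained blue by Fast Blue detection of alkaline
phosphatase) at the periphery, and undifferentiated cells — negative for
both chromogens — next to the confining wall. Quantifying this pattern
from brightfield micrographs takes two steps:

1. **Pixel classification.** Each pixel carries a 3-vector of intensities
   *(R, G, B)*. Reference crops dominated by one class are used to train a
   soft-margin support vector machine with a radial-basis kernel
   *K(x, x′) = exp(−γ‖x − x′‖²)* on channel values scaled to [0, 1]³. The
   trained decision surface partitions RGB color space into three regions
   (one-vs-one voting; ties broken by decision-function margin, then by
   the lowest class code), and every pixel of a micrograph is labeled
   independently as adipogenic (1), osteogenic (2) or negative (3).
2. **Radial profiling.** The circular confinement (known center, radius
   *R*, pixel size in µm/px) is partitioned into coaxial rings of fixed
   thickness Δr = 25 µm: pixel *p* belongs to ring *k* iff
   *k·Δr ≤ d(p, center) < (k+1)·Δr*, the outermost ring truncated at *R*.
   Per ring, the area fraction of each class is the pixel count of that
   class divided by the ring's pixel count; replicate colonies are
   combined into per-ring mean ± sample SD curves against both distance
   from the center and distance from the wall.

A seeded synthetic colony simulator — Gaussian RGB color clusters along
the gray diagonal of color space, a radial class layout with an
adipogenic core, osteogenic annulus and undifferentiated rim — provides
exact ground-truth label maps, so classifier and profiler are testable
end to end with no microscopy data.

## Worked example

```r
library(stainring)

# train on simulated reference crops (1000 px per class, channel SD 10)
crops    <- simulate_training_crops(stain_color_model(),
                                    crop_size = c(25, 40), seed = 42)
training <- load_training_crops(crops)
model    <- train_stain_classifier(training)
model
#> <stain_classifier> radial SVM on RGB/255 features
#>   cost = 1, gamma = 3.796645, support vectors = 16
#>   training: n = 3000, accuracy = 1.0000 (0 misclassified)

# classify a simulated 200 µm colony with a step transition at 50 µm and
# an undifferentiated rim beyond 85 µm, then profile it in 25 µm rings
colony  <- simulate_colony(diameter_um = 200, seed = 7,
                           layout = radial_layout(r_adipo_um = 50,
                                                  r_osteo_um = 85))
labels  <- classify_image(model, colony$image)
mean(labels == colony$labels)   # per-pixel agreement with ground truth
#> [1] 1

rings   <- build_ring_index(colony$geometry, dim(labels),
                            ring_thickness_um = 25)
compute_ring_fractions(labels, rings)
#> # A tibble: 4 × 9
#>    ring r_inner_um r_outer_um r_mid_um dist_wall_um n_pixels frac_adipogenic
#>   <int>      <dbl>      <dbl>    <dbl>        <dbl>    <int>           <dbl>
#> 1     0          0         25     12.5         87.5     1976               1
#> 2     1         25         50     37.5         62.5     5884               1
#> 3     2         50         75     62.5         37.5     9832               0
#> 4     3         75        100     87.5         12.5    13736               0
#>   frac_osteogenic frac_negative
#> 1           0             0
#> 2           0             0
#> 3           1             0
#> 4           0.365         0.635
```

The profile reads off the biology: the two inner rings (mid-radii 12.5
and 37.5 µm) are purely adipogenic, the 50–75 µm ring purely osteogenic,
and the wall-adjacent ring is 63.5% undifferentiated — the rim beyond
85 µm occupies (100² − 85²)/(100² − 75²) ≈ 0.634 of that ring's area.
`aggregate_profiles()` combines replicate profiles into mean ± SD,
`autoplot()` draws the three class curves, and `run_pipeline()` /
`inst/cli/stainring.R` run the whole train → classify → profile →
aggregate workflow from a YAML config with a reproducibility manifest.

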