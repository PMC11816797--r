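# siliquant

Silique morphometrics from instance segmentation masks.

High-throughput phenotyping of *Arabidopsis* fruit (siliques) scans whole
mature stems on a flatbed scanner and segments every fruit as its own
binary mask. `siliquant` is the measurement half of such a pipeline: it
takes per-instance masks (COCO instance JSON or a PNG-per-instance
folder), applies structural quality control, and computes four traits per
accepted fruit, in metric units derived from the scan resolution
(`mm/px = 25.4 / dpi`):

| Trait | Definition |
|---|---|
| SA (mm²) | foreground pixel count × (mm/px)² |
| SL (mm)  | step-sum length of the thinned spinal line (1 orthogonal, √2 diagonal) |
| SD (mm)  | 2 × max Euclidean-distance-transform value along the spinal line |
| SV (mm³) | disk stack ∑ π r(s)² Δs with r(s) the EDT radius along the line |

Quality control rejects masks that are not a single 8-connected shape or
whose skeleton, after pruning side branches of ≤ 5 px, is not a single
clean line — the signature of one mask covering two touching fruits.
Downstream, per-sample aggregates (mean, percentiles, RSD), genotype-level
exclusion bookkeeping, a paired treatment t-test, broad-sense
heritability (one-way ANOVA repeatability), and mapping-ready phenotype
export support quantitative-genetic analysis of the traits. A COCO-style
evaluator (AP/AR at IoU 0.5, 0.75 and 0.5:0.05:0.95, boxes and masks)
scores the segmentation model itself, and a synthetic capsule generator
with closed-form ground truth makes every stage testable offline.

## Worked example

A curved synthetic capsule with radius 6 px, measured at 300 dpi:

```r
library(siliquant)

sp  <- capsule_spec(rbind(c(0.3, 14.5), c(60.3, 26.5), c(120.3, 14.5)),
                    radius = 6)
cap <- generate_capsule(sp)
res <- extract_traits(cap$instance, dpi = 300)
str(res$traits)
#> List of 4
#>  $ area_mm2   : num 11.4
#>  $ length_mm  : num 11
#>  $ diameter_mm: num 1.03
#>  $ volume_mm3 : num 8.68
```

The capsule's centerline is 122.8 px ≈ 10.4 mm long and its true diameter
is 12 px ≈ 1.02 mm: SL lands within the expected digital-length band
(chain-code steps over-measure oblique runs slightly) and SD within half a
pixel of truth. Evaluating deliberately dilated "predictions" of a
six-fruit synthetic scene:

```r
sc    <- generate_scene(6, seed = 1, image_size = c(200, 260),
                        length_range = c(40, 80), radius_range = c(4, 6))
preds <- perturb_instances(sc$instances, "dilate", px = 1,
                           scores = seq(0.95, 0.7, length.out = 6))
evaluate_detections(preds, sc$instances)
#>                  AP50   AP75     AP     AR
#> Detection       100.0  100.0   80.5   83.3
#> Segmentation    100.0   72.1   57.2   58.3
```

Every dilated mask still finds its fruit at IoU 0.5 (AP50 = 100), but the
one-pixel halo pushes masks below the stricter thresholds — exactly the
qualitative signature such a perturbation should produce.

A command-line wrapper over the same functions ships at
`inst/cli/siliquant.R` with subcommands `simulate`, `traits`, `evaluate`,
`aggregate` and `export-qtl`.

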