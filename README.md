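# achrosim

Color-appearance simulation under chromatic illuminants of varying
intensity, built on a simple geometric observation: in CIELAB normalized to
D65 (`CIELAB_D65`), the locus of achromatic points — the chromaticities an
observer calls colorless — under a chromatic illuminant runs *parallel to
the lightness axis*, with a constant offset (a₀\*, b₀\*) that crosses the
illuminant-chromaticity locus near L\* = 25.

For whom: vision scientists and color engineers who want a minimal,
testable chromatic-adaptation pipeline that stays accurate in the dark
lightness range, and a fully synthetic harness for evaluating it against
(real or simulated) asymmetric color-matching data — the kind of individual
differences made famous by #theDress.

## The algorithm

Three steps, each exposed as a function:

1. **Locus estimation** (`estimate_locus_from_region`): mean CIE xy
   chromaticity of a reference region, re-rendered at L\*₍base₎ = 25, gives
   the locus offset (a₀\*, b₀\*).
2. **Iso-lightness chromatic shift** (`apply_chromatic_shift`): per pixel,
   von Kries cone gains derived at that pixel's own lightness,
   k(L) = LMS(L, 0, 0) / LMS(L, a₀, b₀), are applied in a D65-normalized
   Hunt–Pointer–Estévez cone space; the pixel's L\* is then restored
   exactly. The achromatic locus lands on the lightness axis at *every*
   lightness level — unlike the classic single-gain von Kries models
   (`flat_von_kries` implements that baseline for comparison).
3. **Lightness shift** (`apply_lightness_shift`): one additive L\* offset
   anchors a region's mean lightness to a target (body appears white, or
   lace appears black), clamped to [0, 100].

Around the core sit the evaluation tools: a 7×7 grid of assumed-illuminant
variants between the white/gold and blue/black extremes
(`make_variant_grid`, `render_grid`), 2.5-step chromaticity histograms and
modal points (`histogram2d`, `modal_points`, `contrast_bl`),
optimal-variant selection against matching records
(`find_optimal_variant`), residual ΔE\*₍LAB₎ statistics with a 10,000-draw
bootstrap reference (`residual_report`), and a synthetic dress-like scene
generator with simulated observers (`render_scene`,
`make_synthetic_matches`) so the whole pipeline runs without any external
imagery.

## Worked example

```r
library(achrosim)

# a dress-like scene under a strongly bluish, dim illuminant
ep <- default_grid_endpoints()
scene <- render_scene(scene_spec(seed = 1), ep$wg)
print(scene)
#> <rendered_scene> 64 x 64, illuminant (a0*, b0*) = (0.00, -60.00), offset -10.0 L*

# 7 x 7 grid of assumed illuminants between the two percept extremes
grid <- make_variant_grid(ep$wg, ep$bb, n = 7)
print(grid)
#> <variant_grid> 7 color columns x 7 intensity rows (49 variants)
#>   A-1: (a0*, b0*) = (0.00, -60.00), anchor L* = 95.0
#>   G-7: (a0*, b0*) = (0.00, 0.00), anchor L* = 17.0
renders <- render_grid(scene$image, grid, appearance_config())

# 15 simulated observers matching at assorted variants, 3 dE of jitter
matches <- do.call(rbind, lapply(1:15, function(i) {
  gen <- names(renders)[((i - 1) * 3) %% 49 + 1]
  m <- make_synthetic_matches(renders, gen, jitter_de = 3, n_subjects = 1, seed = i)
  m$subject_id <- i
  m
}))
report <- residual_report(renders, matches, n_boot = 10000, seed = 42)
print(report)
#> <residual_report>
#>   all        (n=15): chromatic   2.95 +/- 0.27   achromatic   2.93 +/- 0.34
#>   blue/black (n= 3): chromatic   3.94 +/- 0.69   achromatic   3.24 +/- 1.01
#>   white/gold (n=12): chromatic   2.70 +/- 0.26   achromatic   2.85 +/- 0.37
#>   bootstrap reference (n_boot=10000): chromatic mean 54.35, 95% CI [43.19, 65.32]
```

Reading the report: each simulated subject's optimal grid variant is chosen
by the proximity of their *achromatic*-part match (dress body for
white/gold observers, lace for blue/black) to the render's modal point; the
residual of the remaining, chromatic-looking part is the figure of merit.
Here it sits near the injected 3 ΔE match jitter, while picking variants at
random (the bootstrap reference) leaves a mean residual an order of
magnitude larger — the selection is doing real work.

A command-line front end wrapping the same functions ships in
`inst/cli/achrosim` (`synth`, `simulate`, `grid`, `compare`).

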