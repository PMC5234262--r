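# torusseg

Segmentation of chronic-wound (pressure ulcer) photographs without an
initial contour, for clinicians and image-analysis researchers who need the
wound region delineated for area and shape measurement.

## Method

The grayscale amplitude `A = 0.2126 R + 0.7152 G + 0.0722 B` of the
photograph is decomposed into a stack of contrast levels. Each pixel gets a
*synthetic frequency*

    f(m, n; r) = 1 / Ã(m, n)^r ,     Ã = A + 1 ∈ [1, 256],

which modulates the x/y parametric maps of a torus surface, re-read as
per-pixel transforms:

    THD(u; f) = [R + cos(2π f u)] · cos(2π arctan f)
    TVD(v; f) = [R + cos(2π f v)] · sin(2π arctan f)

combined with the amplitude through Hadamard products into the additive and
product operators `T_a = Ã ∘ (TVD + THD)` and `T_p = Ã² ∘ (TVD ∘ THD)`,
each normalized to `[0, 1]`. Sweeping the frequency parameter `r` over
`[0.013, 0.015]` in 30 steps produces the levels; each is split into a
dark/bright partition `Ω₁/Ω₂` by an Otsu threshold optimized on the
histogram of `T̄_p` and applied to `T̄_a`. Level contours are accumulated
and refined morphologically (closing, hole filling, component filtering,
darkest-component selection) into the wound mask. Accuracy against a ground
truth is scored by digital image correlation (Pearson correlation over all
pixels).

Because no public wound-photograph corpus with ground truth exists, the
package ships a seeded phantom generator — dark reddish elliptical lesions
with optionally blurred boundaries on gradient-lit skin, plus distractors
and noise — with exact masks, used by the test suite and the acceptance
script.

## Worked example

```r
library(torusseg)

ph  <- generate_phantom(phantom_spec(seed = 7))   # sharp 256x256 phantom
res <- segment(ph$image, torus_config())
res
#> <torusseg_segmentation> 256 x 256
#>   levels: 30 used, 0 skipped
#>   mask: 3295 px (5.0% of image)
image_correlation(res$mask, ph$truth)
#> [1] 0.9735145
head(res$per_level[, c("level", "r", "t", "t_value", "omega1_area")], 3)
#> # A tibble: 3 × 5
#>   level      r     t t_value omega1_area
#>   <int>  <dbl> <int>   <dbl>       <int>
#> 1     1 0.013    200   0.781        3322
#> 2     2 0.0131   190   0.742        3295
#> 3     3 0.0131   178   0.695        3230
```

The mask covers 3295 of 65536 pixels and correlates at 0.97 with the exact
ellipse truth; the per-level table shows each contrast level placing its own
threshold (`t` of 256 bins) while the dark class `Ω₁` stays pinned on the
lesion (its area barely moves). Batch scoring over a 20-phantom stress suite (blur 0–8 px, noise
0–10 gray levels, 0–2 distractors):

```r
suite <- phantom_suite(20, seed = 1)
evaluate_batch(lapply(suite, function(p) segment(p$image)),
               lapply(suite, `[[`, "truth"))
#> <torusseg_eval> n = 20 (0 failed)
#>   rho: mean 0.929, sd 0.063 (sample), min 0.749, max 0.978
```

A command-line interface is installed as `exec/torusseg`:

```sh
torusseg phantom  --n 20 --seed 7 --out phantoms/
torusseg segment  photo.png --out mask.png --config cfg.yaml --diagnostics diag/
torusseg evaluate --pred masks/ --truth truths/ --report report.json
```

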