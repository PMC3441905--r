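# ecvmap — automated pixel-wise myocardial ECV mapping

`ecvmap` turns pre- and post-contrast MOLLI inversion-recovery series
into a pixel-wise map of the myocardial **extracellular volume fraction
(ECV)** — the percent of tissue occupied by extracellular space, a
quantitative marker of diffuse fibrosis and edema that conventional late
gadolinium enhancement cannot resolve. It is aimed at quantitative
cardiac MRI researchers and method developers who need the full
processing chain, including its failure modes, under test on synthetic
ground truth.

The measurement chain:

1. **Pixel-wise T1 mapping.** Each pixel of a MOLLI series (8 images at
   inversion times `TI` over two inversions in an 11-heartbeat
   breath-hold) is fit to the magnitude inversion-recovery model
   `s(TI) = |A − B·exp(−TI/T1*)|` by multi-start downhill simplex, with
   Look-Locker correction `T1 = T1*(B/A − 1)` and a per-pixel residual
   sum-of-squares (goodness-of-fit) map.
2. **Motion correction (MOCO).** Each frame is registered (non-rigid,
   optical-flow/demons with Gaussian regularization) to a *synthetic*
   motion-free image of matching contrast computed from the current T1
   estimate; seed, register, refit, iterate. The final frames are each
   interpolated exactly once from the original data (5th-order
   B-spline).
3. **Co-registration.** The post-contrast breath-hold is aligned to the
   pre-contrast frame via the two longest-TI images (near-full
   magnetization recovery makes their contrast similar), and each post
   frame is warped once with the composite of its motion field and the
   co-registration field, then the post T1 map is refit.
4. **Blood pool & ECV.** Blood is segmented automatically on the
   pre-contrast T1 map (threshold > 1250 ms, isolated-pixel removal,
   erosion); with `ΔR1 = 1/T1_post − 1/T1_pre` and venous hematocrit
   `hct`,

   ```
   ECV(%) = 100 · (1 − hct) · ΔR1_pixel / ΔR1_blood
   ```

   Blood pixels themselves must read `(1 − hct)·100` — a built-in
   control. Without a hematocrit, a partition-coefficient map
   `λ = ΔR1_pixel/ΔR1_blood` is produced instead.

A digital short-axis phantom (`phantom_spec()`,
`simulate_molli_series()`) simulates the whole acquisition — TI
schedules, inversion-recovery signals, respiratory drift, inter-series
shift, magnitude noise — with exact ground truth for every stage.

## Worked example

Simulate a moving phantom (ECV 25%, hematocrit 0.42, breath-hold drift
up to 4 px, 5 px shift between breath-holds) and run the full pipeline:

```r
library(ecvmap)
ph  <- phantom_spec()                      # 192 x 130, blood 1500/300 ms, myo 1000 ms
sch <- build_ti_schedule("5-3", heart_rate = 60)
sch$ti_values
#> [1]  110 1110 2110 3110 4110  190 1190 2190

pre  <- simulate_molli_series(ph, sch, motion_spec(drift_amplitude = 4, seed = 11),
                              noise_sd = 0.02, seed = 1)
post <- simulate_molli_series(ph, sch, motion_spec(drift_amplitude = 3, seed = 12),
                              noise_sd = 0.02, seed = 2, contrast_phase = "post")
shift <- deformation_field(matrix(5, 192, 130), matrix(0, 192, 130))
for (i in 1:8)
  post$series$images[, , i] <- warp(post$series$images[, , i], shift)

res <- run_pipeline(pre$series, post$series, hematocrit = 0.42,
                    out_dir = "ecv_out", verbose = FALSE)
res$blood
#> blood mask: 546 px (T1 > 1250 ms, erosion r=1); blood T1 pre 1501 ms, post 299 ms
res$ecv
#> ECV map: 4886 valid px; median 39.2% (IQR 23.4-63.0); hct 0.42, blood dR1 0.0026776 /ms

myo <- pre$truth$label_map == 2
median(res$ecv$ecv[myo], na.rm = TRUE)     # simulated truth: 25
#> [1] 25.07265
sd(res$ecv$ecv[myo], na.rm = TRUE)
#> [1] 3.280963
```

(The map-wide median of 39.2% mixes myocardium at ~25% with blood at
~58%; the myocardial statistics are the measurement.) The median
myocardial ECV lands within a tenth of a percentage point of the
simulated 25%. Running the same data with
`pipeline_config(moco = list(enabled = FALSE), coreg = list(enabled = FALSE))`
gives a myocardial median of 26.8% with SD 32.5% — a tenfold larger
spread, the quantitative reason motion correction and co-registration
are on by default. `ecv_out/` contains the T1, residual, blood-mask and
ECV maps as NIfTI plus `report.json`.

The same pipeline is scriptable from the shell:

```sh
inst/cli/ecvmap simulate --out sim --seed 5
inst/cli/ecvmap ecv --pre sim/pre.nii --post sim/post.nii --hct 42% --out ecv_out
inst/cli/ecvmap report --dir ecv_out
```

## Scope notes

Single 2-D slice processing; NIfTI + JSON sidecar interchange (no DICOM
reader); in-plane motion only; no inversion-efficiency or heart-rate
correction of T1. See the methods vignette
(`vignettes/ecv-mapping-methods.Rmd`) for models, parameter defaults,
simulator fidelity limits, and design rationale.
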