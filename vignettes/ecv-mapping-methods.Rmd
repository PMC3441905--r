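---
title: "Automated myocardial ECV mapping: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated myocardial ECV mapping: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecvmap)
```

## The measurement

The extracellular volume fraction (ECV) of the myocardium is the percent
of tissue occupied by extracellular space. It is estimated from the change
in longitudinal relaxation rate $\Delta R_1 = 1/T_{1,\mathrm{post}} -
1/T_{1,\mathrm{pre}}$ caused by an extracellular gadolinium agent, which
is proportional to the local contrast concentration
($\Delta R_1 = \gamma\,[\mathrm{Gd}]$, $\gamma = 4.5\ \mathrm{L\,mmol^{-1}
s^{-1}}$). In a dynamic steady state the tissue-to-blood concentration
ratio equals the ratio of distribution volumes, and because the blood's
own extracellular volume is $(1-\mathrm{hematocrit})$,

$$\mathrm{ECV} = (1-\mathrm{hct})\,
\frac{\Delta R_{1,\mathrm{myo}}}{\Delta R_{1,\mathrm{blood}}}.$$

`compute_ecv()` evaluates this per pixel; `partition_coefficient_map()`
drops the hematocrit factor and maps
$\lambda = \Delta R_{1,\mathrm{myo}}/\Delta R_{1,\mathrm{blood}}$ when no
hematocrit is available. A useful internal control: blood pixels
themselves must map to $\mathrm{ECV} \approx (1-\mathrm{hct}) \times 100$.

## T1 mapping

Pixel T1 comes from a MOLLI acquisition: magnetization inversion followed
by single-shot images at 8 inversion times spread over two inversions in
an 11-heartbeat breath-hold (`build_ti_schedule()`; "3-5" and "5-3"
variants, minimum TI 110 ms, increment 80 ms, one RR interval between TIs
within a block). Because the images are magnitude detected, each pixel is
fit to

$$s(TI) = \left| A - B\, e^{-TI/T_1^*} \right|,$$

by multi-start Nelder-Mead downhill simplex (`fit_pixel()`, `fit_map()`),
and the apparent constant is corrected for the readout perturbation with
the Look-Locker relation $T_1 = T_1^*(B/A - 1)$
(`look_locker_correct()`). The residual sum of squares of every pixel is
kept as a goodness-of-fit map.

Numerical choices (none are prescribed by the model itself):

* **Multi-start**: $T_1^*$ starts at 150, 400, 800, 1500 ms with
  $A = \max s$, $B = 2A$; one degenerate start at $B = 0$ (the optimum
  for constant signal); and three starts from the best distinct basins of
  a coarse 25-ms $T_1^*$ scan with sign-iterated linear least squares for
  $(A, B)$. The magnitude model is multimodal near signal nulls and some
  spurious basins are only tens of ms wide, so plain multi-start simplex
  provably misses them. The winner is polished by a simplex restart. The
  test suite holds the fit to a dense 1-ms $T_1^*$-grid oracle.
* **Acceptance bounds**: a pixel is flagged `fit_ok` only if
  $1 \le T_1 \le 5000$ ms and $1 \le B/A \le 3$ — the physiological and
  protocol range; everything else (air, pure noise) is excluded from all
  downstream maps. Pixels with peak signal below $10^{-6}$ of the series
  maximum are not fit at all.
* **No polarity restoration**: the absolute-value model is fit directly.

The crude two-point initializer (`initial_t1_estimate()`) uses only the
shortest- and longest-TI images with $A = s(TI_{\max})$, $B = 2A$. When
$s(TI_{\min}) < s(TI_{\max})$ the short-TI sample is taken as still
inverted — true for every tissue of interest at $TI_{\min} = 110$ ms.
Degenerate or out-of-range pixels fall back to 1000 ms. On the noiseless
phantom this estimate is within about 30% of truth over myocardium; blood
lands on the fallback (~33% error) because its recovery is incomplete
even at the longest TI. That is sufficient for its only purpose: seeding
motion correction.

## Motion correction and co-registration

Respiratory motion within a breath-hold is corrected by registering each
measured image to a *synthetic* motion-free image of matching
inversion-recovery contrast (`moco_series()`), computed from the current
T1 fit. This sidesteps the central difficulty that raw MOLLI frames have
wildly different contrast and transient signal nulls. The loop is: crude
T1 seed (shortest/longest TI images, which avoid nulling) → synthesize →
register each frame → refit, for `n_iterations` (default 2, stopping
early when the largest field update falls below 0.5 px). The reference
respiratory position is the longest-TI image, which has the highest SNR.

Two choices here were settled empirically on the phantom. First, each
outer iteration *re-registers the original frame* to the current
synthetic, warm-started from the accumulated field, rather than
composing an incremental field onto it: with composition, any deformation
absorbed in iteration 1 (when the synthetic contrast is still crude)
leaks into the refit, reappears in the next synthetic, and becomes
unobservable to later iterations; with warm-started replacement the
later, better-contrast iterations can undo it (on the moving phantom
this halved the residual displacement error and reduced the median
myocardial T1 error by a further third). Second, the field
regularization follows a schedule across outer iterations (default
$2\sigma$ then $\sigma$): iteration 1 faces synthetics whose blood
contrast can be substantially wrong near the blood null, so it only
trusts coarse-scale motion — which is what respiratory drift is.

Registration (`register_nonrigid()`) is a classical variational optical
flow/demons scheme: symmetric-gradient intensity updates, per-update
"fluid" smoothing ($\sigma = 1$ px), per-iteration "diffusion"
regularization of the field ($\sigma = 4$ px), a 3-level
multi-resolution pyramid, at most 50 iterations per level, per-image
intensity normalization. These defaults were chosen at the 192×130
acquisition-matrix scale and are all config-exposed; they make no claim
of numerically matching any particular reference implementation.

Two structural guarantees matter more than the registration parameters:

* **Single interpolation.** Displacement fields are *composed*
  ($c(x) = f_1(x + f_2(x)) + f_2(x)$, `compose_fields()`), and each
  output image is produced by warping the original data exactly once with
  a 5th-order B-spline interpolator (`warp()`), preserving spatial
  resolution. The tests verify composed-vs-sequential warp equivalence
  and that single-warp output beats double-warp output against analytic
  ground truth.
* **Longest-TI co-registration.** The post-contrast breath-hold is
  aligned to the pre-contrast frame by registering the two longest-TI
  images (`coregister_pre_post()`), where magnetization is nearly
  recovered and the pre/post contrast is most similar (phantom
  correlation > 0.95). The co-registration field is composed with each
  post frame's own motion field; the post T1 map is then *refit* from the
  composite-warped images rather than warping the fitted map (the map is
  a non-linear function of the data, so warping it would not commute with
  fitting; a debug mode could warp the map directly, but the refit is the
  principled route).

## Blood-pool segmentation

`segment_blood()` thresholds the pre-contrast T1 map strictly above
1250 ms (native blood T1 is roughly 1300-1800 ms, above most tissues),
removes 8-connected components smaller than 10 pixels (isolated noise),
and erodes one pixel layer (disk radius 1) to drop blood-tissue boundary
pixels with partial-volume T1s. Component size and erosion radius are
config-exposed since the source method states neither. Blood T1s are
medians over the final mask; the post-contrast median is taken on the
*co-registered* post map, which by construction sits at the pre-contrast
position. An empty final mask is a hard error instructing manual blood T1
entry — silently proceeding would corrupt every downstream pixel.

## The phantom simulator

`phantom_spec()` + `simulate_molli_series()` generate a short-axis-like
section — circular blood pool, myocardial ring, low-signal background —
with known T1s, proton densities, per-image motion and noise, and return
exact ground truth for every stage. Defaults state a typical 1.5 T
protocol: 192×130 matrix, 2.1×1.9 mm pixels, blood 1500→300 ms,
myocardium 1000 ms native, ECV 25%, hematocrit 0.42, noise SD 2% of unit
proton density, drift up to 4 px within a breath-hold and a 5 px shift
between breath-holds where motion is exercised. The post-contrast
myocardial T1 is *derived* from the target ECV via `t1_post_from_ecv()`,
so the simulated world is exactly consistent with the ECV relation (the
round trip is checked to $10^{-10}$).

Deliberate simplifications, and hence what a green test does **not**
establish:

* Ideal inversion ($B = 2A$) and $T_1^* = T_1$: no SSFP readout bias is
  simulated (an optional scalar `t1_star_factor` exists as a hook). Real
  MOLLI underestimates T1 through imperfect inversion efficiency; the
  pipeline inherits whatever bias the acquisition has.
* Noise is additive Gaussian on the magnitude (rectified), with a Rician
  option; the fitter sees magnitude data either way.
* Motion is in-plane only (translation drift + smooth non-rigid field);
  through-plane motion and cardiac-phase mismatch between series are not
  modeled — both are acknowledged failure modes of in-plane
  co-registration, not correctable by it.
* A smooth deterministic intensity shading stands in for the coil
  profile so that tissue interiors carry gradients; real coil profiles,
  ghosting and banding artifacts are absent.

The phantom validates the *processing pipeline* — fitting, registration,
composition, segmentation, calibration arithmetic — not sequence physics
or clinical accuracy.

## Degenerate inputs and tie-breaks

* Constant images: registration returns an identity field with a
  warning; pure-noise pairs stay bounded by the regularization.
* Registration failure for one frame keeps that frame's previous field
  and logs it; failure of the pre/post co-registration itself degrades
  to an identity field with a prominent warning rather than aborting.
* Longest-TI ties are broken by the globally maximal TI across both
  inversion blocks.
* ECV display values are clipped to [0, 100]% with raw values retained;
  negative raw ECV marks the pixel invalid.
* The schedule arithmetic follows $TI_0 + j\,RR$ literally; at 60 bpm
  this makes the longest TI ≈ 4.1 s, slightly below the "approximately
  5 s" sometimes quoted for this protocol family (which likely includes
  the trigger delay). Nothing downstream depends on the absolute number.

## Known limitations

**Residual sub-pixel fields on motion-free input.** An SSD-driven demons
registration cannot distinguish a contrast error in its target from
motion. On frames acquired near the blood signal null, the crude-seed
synthetic is most wrong, and a spurious deformation of up to ~0.5 px
(mean over the frame) survives the iteration even when the input has no
motion at all. The regularization schedule bounds it but does not remove
it; the test suite asserts the bound rather than pretending identity.
This is the cost of the simple registration backend, not of the
synthetic-image strategy itself.

Single-slice processing (no multi-slice blood borrowing for apical
slices); no inversion-efficiency or heart-rate correction of T1; no
DICOM reader (NIfTI + JSON sidecar is the interchange format); the
registration defaults are engineering choices validated on phantoms, not
a numerical reproduction of any clinical implementation.
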