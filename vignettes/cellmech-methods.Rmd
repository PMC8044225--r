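---
title: "Methods: thin-sample Hertz fitting and object-based colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thin-sample Hertz fitting and object-based colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmech)
```

## Scope

`cellmech` quantifies two complementary views of a spreading epithelial
cell: its mechanics, from force-volume AFM nanoindentation maps, and the
localization of trafficking/contractility markers, from multi-channel
fluorescence stacks. This vignette explains the models, the parameters
that matter, the synthetic data used to validate them, and the design
choices made where the underlying procedures are genuinely open.

## Force-volume AFM analysis

### Contact model and assumptions

Each pixel of a force-volume scan holds one approach curve: cantilever
force F against piezo displacement z. The indentation is
$\delta = (z - z_0) - F/k$ — the piezo travel past the contact point
$z_0$ minus the cantilever's own deflection $F/k$ — and the contact force
of a paraboloidal tip on a thin elastic layer bonded to a rigid support is

$$F(\delta) = \frac{4}{3}\frac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2} f(\chi),
\qquad \chi = \frac{\sqrt{R\delta}}{h},$$

$$f(\chi) = 1 + 1.133\chi + 1.283\chi^2 + 0.769\chi^3 + 0.0975\chi^4 .$$

The polynomial $f$ is the bonded-sample, paraboloidal-tip bottom-effect
factor; it is isolated in `bottom_effect_factor()` so an alternative
correction can be swapped in one place. Assumptions inherited from this
model: linear elasticity, incompressibility ($\nu = 0.5$ by default),
a rigid flat substrate, and quasi-static indentation. Fast force-volume
scanning violates the last point in a rate-dependent way, so the fitted
quantity is reported as an *apparent* modulus throughout; no viscoelastic
or adhesion (JKR/DMT) model is fitted.

### The two-pass procedure

1. **Virtual-deflection correction.** A least-squares line through the
   first 30% of samples (`baseline_fraction`) is subtracted from the whole
   trace. The baseline is "identifiable" when its residual SD is below
   25 pN and the corrected force in the window shows no sustained
   excursion above 3× that SD (4 consecutive samples — a single noise
   spike should not disqualify a curve). Curves failing either criterion
   are excluded as `no_baseline`. The 25 pN ceiling is a package default:
   it is ~6% of the 400 pN trigger force, well above the few-pN photodiode
   noise of a working instrument and well below any real contact signal.
2. **Pass 1 — linearized Hertz fit.** On the contact branch,
   $y = F^{2/3}$ is linear in the tip–sample separation $s = z - F/k$:
   the slope $a$ and x-intercept give
   $E = \tfrac{3}{4}(1-\nu^2)a^{3/2}/\sqrt{R}$ and $z_0$. The branch is
   found by the first sustained crossing of the 3×-noise threshold,
   refined once from the fitted intercept, restricted to
   $\delta \le 800$ nm, and fitted by iteratively reweighted least
   squares (Tukey bisquare, 3 iterations) so stray points near contact do
   not bias the slope. Fewer than 8 usable points, or a non-positive
   slope, yields `no_contact`.
3. **Substrate and flattening.** Pixels with a converged pass-1 modulus
   above 65 kPa are bare plastic. A least-squares plane through their
   contact points removes stage tilt; local height is the signed distance
   from that plane, clamped at zero from below (the clamp count is
   reported — on a noiseless scan it counts substrate pixels whose fitted
   height is a numerical hair below zero).
4. **Pass 2 — bottom-effect refit.** With $h$ known per pixel, the full
   thin-sample model is refit by Levenberg–Marquardt
   (`minpack.lm::nls.lm`): the modulus is free on a log scale and $z_0$
   may move within ±20 nm of pass 1 (`z0_window_nm`), which prevents the
   degenerate $E$–$z_0$ trade-off on shallow curves; setting the window
   to 0 refits the modulus only. Pixels thinner than 20 nm
   (`min_refit_height_um`) keep the pass-1 value: the correction diverges
   as $h \to 0$ and such pixels are substrate by definition. A
   non-converged refit keeps pass 1 and is flagged `fallback`.
5. **Masking and band statistics.** The cell mask requires height
   ≥ 100 nm, modulus ≤ 65 kPa and a usable fit. Band means use
   lower-inclusive, upper-exclusive height edges ([2, 5) and [0, 2) µm by
   default), so a pixel at exactly 2 µm belongs to the body band.

All fits are deterministic: no random initialization anywhere.

### Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `tip_radius` | 35 | nm | tip apex radius R |
| `spring_constant` | 0.068 | N/m | cantilever stiffness k |
| `poisson_ratio` | 0.5 | – | incompressible sample |
| `trigger_force` | 400 | pN | approach termination |
| `max_indentation_nm` | 800 | nm | fit window cap |
| `stiff_threshold_pa` | 65e3 | Pa | substrate / mask threshold |
| `min_height_nm` | 100 | nm | mask height threshold |
| `baseline_fraction` | 0.3 | – | pre-contact window |
| `z0_window_nm` | 20 | nm | pass-2 contact-point freedom |

## Colocalization

Channels are min–max normalized (Phansalkar's parameters assume unit
range), thresholded locally with
$t = m(1 + p e^{-qm} + k(s/r - 1))$ over a 15 px window
(k = 0.25, r = 0.5, p = 2, q = 10 — the method's published defaults as
shipped by standard auto-local-threshold tools; none are printed by the
analyses this package descends from, so all are configurable), and
despeckled with a binary median filter. Manders split coefficients are
then computed with the "signal present" condition realized through the
segmentation masks: raw confocal intensities are essentially never exactly
zero, so thresholded foreground is the operational reading of
$S_i > 0$. Z-stacks are segmented slice-wise and the coefficients pooled
over all slices (one number per cell); per-slice computation is available
by calling `manders_split()` on individual slices.

**The median filter's "16 neighborhood".** The filter size is given as a
single number, 16, interpreted here as the window *area* in pixels — the
`medfilt2([m n])` convention, side `round(sqrt(16)) = 4`, bumped to 5 for
a well-defined centre. The alternative reading (a window of side 16,
i.e. 17×17 after the same bump) would delete every object smaller than
about 145 px — all the punctate vesicles this pipeline exists to segment —
so it cannot be what a working implementation used. Both readings, and a
radius interpretation, are selectable via `interpretation=`.

**Conjunction intensity.** For triple colocalization the conjunction mask
is the AND of two channel masks; its intensity image is taken from the
first-listed channel (option: pixel-wise minimum of the two). Median
filtering is applied per channel before the AND.

## The synthetic ground truth

Every generator returns a `synthetic_truth` alongside its data and is
bit-reproducible under a fixed seed (each consumes a private RNG stream;
the caller's RNG state is untouched).

* **Force curves** follow the forward model above exactly: the implicit
  deflection equation is solved per sample by bisection (60 halvings,
  i.e. to machine precision against the 1e−9 relative tolerance target),
  plus a linear virtual-deflection baseline and additive Gaussian force
  noise. Defaults of 10 pN noise and a few hundred samples per curve are
  package choices for a plausible instrument, not measured values.
  Scans lay contact points out in a common piezo frame
  ($z_0 = z_{\text{offset}} - h + \text{tilt}$) so topography and stage
  tilt are real features of the data. The virtual cell is a spherical cap
  — the simplest shape giving both height bands — with a stiffer
  peripheral band below 2 µm.
* **Vesicle stacks** place disk vesicles (radius 4 px ≈ 0.8 µm at
  0.1 µm/px, the scale of tubulo-vesicular recycling compartments) in a
  160×160 px field, share a controlled fraction of centres between
  channels, keep all other vesicles ≥ 4 radii from any channel-1 vesicle,
  then blur (Gaussian PSF, σ = 1 px) and add Gaussian noise, rounding to
  non-negative integer counts. Rejection sampling restarts from scratch
  up to 5 times before raising a placement error.
* **Traction fields** are uniform or edge-concentrated magnitudes with
  random directions under a mask; the truth stores the exact noise-free
  mean stress and total force ($\Sigma|T| \cdot a$, Pa·µm² = pN).
* **Movies** prescribe inclusive-frame contact intervals: a vesicle's
  rounded position is inside the compartment exactly during those frames
  and hovers in a 2–5 px ring outside it otherwise, so enter/exit steps
  remain small enough for nearest-neighbour linking.

What passing on these data does **not** show: robustness to uneven
illumination or autofluorescence backgrounds, chromatic misregistration,
anisotropic or tubular object shapes, viscoelastic force response, curved
or soft substrates, or camera gain/shot-noise statistics. The generators
are deliberately idealized so that failures indict the implementation,
not the data model.

## Quantification conventions

* Traction summaries dilate the cell mask by a configurable margin
  (default 2 µm) to capture stresses "near" the cell; `total_force` is
  reported in nN and equals `mean_stress × area` exactly for uniform
  fields.
* Corrected total cell fluorescence uses the standard
  integrated-density − area × mean-background formula with an explicit
  per-cell background mask.
* Aspect ratio comes from second moments of the mask (ratio of principal
  axis lengths of the best-fit ellipse); a Feret-caliper alternative is
  available. Rotation invariance holds to ~2% for masks of ≥ 1000 px.
* Track metrics report path length, net displacement *and* mean speed
  (path length over elapsed time) because "distance traveled" is
  ambiguous between the first two; consumers can pick either.
* Residence times count inclusive frames (enter 3, exit 7 at 1 s/frame is
  5 s) with centroid-in-mask contact and nearest-pixel rounding.

## Problem sizes

The validation suite runs a 32×32 px virtual-cell scan at 256 samples per
curve for the end-to-end modulus-recovery check, 160×160 px stacks over a
5-point overlap sweep × 10 seeds for Manders recovery, and 128×128 px
images for the segmentation oracles — sizes at which every property of
interest is already expressed while the whole suite stays fast enough to
run on every change.

## Known limitations

* The bottom-effect polynomial is accurate for moderate $\chi$; for
  extremely thin samples (here, below the 20 nm refit floor) no
  correction is attempted.
* The pass-1/pass-2 contact-point coupling assumes the pass-1 $z_0$ is
  within ±20 nm of the truth; pathological baselines outside the flagged
  criteria could violate this silently.
* Manders coefficients on noisy data carry a small downward bias at high
  true overlap from independent per-channel segmentation jitter at object
  boundaries (boundary pixels carry real intensity but enter only one
  mask). On default synthetic data this bias is a few percent; it is a
  property of object-based colocalization generally, not of this
  implementation.
* The nearest-neighbour linker is greedy and frame-local; it is not a
  global tracker and will fragment trajectories that cross closely.
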