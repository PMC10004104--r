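---
title: "Quenching-corrected OSL foil dosimetry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quenching-corrected OSL foil dosimetry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

LiMgPO4 (LMP) silicone foils are thin (0.54 mm), flexible OSL detectors read
out as 2D images by a CCD camera under blue-LED stimulation. Their
dose-response is linear over the clinical range, which makes a stack of
foils in a PMMA phantom an attractive 3D verification tool for ocular
proton therapy. The obstacle is ionization quenching: the light output per
unit dose falls as protons slow down, so an uncorrected foil stack
under-reports the dose progressively towards the Bragg peak — by roughly a
third on the entrance plateau of a 58.8 MeV beam and almost entirely in the
distal fall-off, where proton energies drop below ~10 MeV.

The package implements the full correction chain: extract a per-foil OSL
statistic from raw camera frames, know each foil's water-equivalent depth,
know the proton kinetic-energy spectrum at that depth, model the relative
luminescence efficiency as a function of energy, and divide it out.

## Relative efficiency and the composite model

The relative luminescence efficiency of a foil is

\[ \eta = \frac{\mathrm{OSL}_k / D_k}{\mathrm{OSL}_\gamma / D_\gamma}, \]

the per-unit-dose signal under protons relative to the same quantity under
a reference Co-60 gamma irradiation (60 Gy in the reference protocol). It
is dimensionless and invariant under rescaling of either the signal or the
dose units — both invariances are tested.

Its energy dependence is modelled as a composite of a step and a linear
term,

\[ \eta(E) = \frac{A}{1 + e^{-(E - E_0)/w}} + sE + c, \]

with the logistic step capturing the efficiency collapse below a threshold
energy and the linear term the weak residual dependence above ~20 MeV. The
reference parameter set is \(A = 0.56\), \(E_0 = 13.73\) MeV,
\(s = 0.0015\,\mathrm{MeV}^{-1}\), giving \(\eta(58.8\,\mathrm{MeV}) =
0.648\) (the ~0.65 plateau) and \(\eta(5\,\mathrm{MeV}) = 0.0076\) (well
below 0.05). Three choices here were genuinely open and are resolved as
follows:

* **Functional form.** The published description names the three parameters
  and their roles but never writes the formula. The additive
  logistic + linear form above reproduces every printed consequence of the
  model (midpoint \(A/2\) at \(E_0\), plateau \(A + sE\), near-zero floor),
  so it is adopted. Error-function and arctangent steps are retained in
  `compare_step_shapes()` as a comparison harness, mirroring the original
  model selection; the logistic is the default.
* **Width.** No width is printed; it is a free shape parameter initialized
  at 1 MeV. The synthetic generator uses \(w = 1\) MeV.
* **Intercept.** None of the printed numbers resolves whether the linear
  part has an offset; the intercept defaults to 0 and can be freed with
  `fit_intercept = TRUE`.

### Fitting

`fit_efficiency_model()` is a weighted Levenberg-Marquardt least-squares
fit (via `minpack.lm`) of \(\eta(E)\) against per-depth observations
\((E_{\mathrm{median}}, \eta_{\mathrm{obs}})\). The stated prescription —
"IQR as weighting factor" — does not fix a direction; the package reads a
broad spectrum as a less reliable single-energy label and uses
\(w_i = 1/\max(\mathrm{IQR}_i, 0.1\,\mathrm{MeV})\). The opposite reading
(`weighting = "iqr"`) and an unweighted fit are selectable. A floor of
0.1 MeV avoids infinite weight at the entrance, where the spectrum is
nearly monochromatic. The fit refuses data lying entirely on one side of
the starting threshold (the centre would be unidentifiable), and bounds
keep the centre inside the observed energy span.

### Correction

`apply_correction()` divides each measured dose by
\(\max(\eta(E_{\mathrm{median}}), 0.05)\). The 0.05 floor prevents
unbounded amplification where the model tends to zero (distal depths);
floored depths are flagged rather than dropped, since a flagged point still
shows where the measurement stops being correctable.

Efficiency observations are only formed where the reference dose exceeds
1% of its maximum (`ref_floor_frac`). At and beyond the distal fall-off the
reference dose vanishes while the foil still reads residual noise, so the
ratio there is noise divided by zero and carries no information about
efficiency; the reference analysis likewise discarded an unusable deep
point by hand.

## The imaging chain

`process_stack()` applies, in order: sensitivity-drift correction,
per-detector background subtraction, detector localization, flat-field
correction, spatial alignment, ROI extraction. The order matters —
drift-correcting both frames *before* subtracting makes the result
independent of acquisition times, and a test checks that the pipeline's
enforced order reproduces the commutative result.

Numerical choices:

* **Drift** is a fractional sensitivity gain of `rate` per minute (0.1 for
  the reference readout); correction divides by \(1 + rt\) with \(t\)
  measured from the session's first acquisition. Negative times are an
  error (mis-ordered session).
* **Background subtraction** clips at zero; if more than 0.1% of
  central-ROI pixels clip, a warning flags the pair. Clipping rectifies
  noise on near-zero frames, which is why near-zero depths are excluded
  from efficiency observations (see above) rather than "fixed" by
  smoothing. No median or other intensity filter is used anywhere: a
  smoothing filter biases the ROI mean, which is the dosimetric statistic.
* **Localization** thresholds the live view at its 30% intensity quantile
  (robust to hot pixels, unlike a fraction of the maximum), opens the
  binary mask with a 5 px disc brush to remove noise speckle (this touches
  only the mask, never intensities), and takes the largest 4-connected
  component. Centre = centroid, radius = equivalent-disc radius. The
  orientation marker — a dim notch on the detector rim — is the minimum of
  the rim-band intensity profile over 36 angular bins with parabolic
  sub-bin refinement; 10 degree bins plus refinement recover the angle to
  well under the 2 degree tolerance that matters for a radially symmetric
  ROI statistic.
* **Flat-field** gain is the flat's central-ROI mean divided by the flat,
  so multiplying by the gain removes the optical pattern and leaves the
  central scale untouched. The historical processing description words the
  normalization the other way around, which would imprint the pattern
  instead; `literal_gain = TRUE` reproduces that literal reading for
  comparison.
* **Alignment** translates the detector centre to pixel (512, 512)
  (0-based coordinates) and rotates about that pixel by minus the marker
  angle, in one bilinear resampling pass with zero fill. Bilinear
  interpolation preserves the ROI mean of a radially symmetric scene to
  well under 0.5%.
* **Extraction** is the mean and standard deviation over the circle of
  radius 300 px centred at (512, 512).

## The transport surrogate

The analysis consumes only two things from particle transport: the
depth-dose curve and the kinetic-energy spectrum at each foil depth. Both
are produced by a deliberately minimal 1-D model: Bragg-Kleeman
range-energy relation \(R = \alpha E^p\) (\(\alpha = 2.2\times10^{-3}\)
cm MeV\(^{-p}\), \(p = 1.77\)) with Gaussian range straggling
\(\sigma_R = k R^m\) (\(k = 0.012\), \(m = 0.935\)) — standard water values,
all configurable, with `calibrate_range_relation()` available to pin the
relation to a measured range anchor. There are no nuclear interactions, no
lateral scattering and no secondary-particle transport. With these
defaults the relation puts 58.8 MeV protons at 29.8 mm (published anchor:
29 mm), the residual range at 13.4 MeV at 2.17 mm (2.07 mm) and at 20 MeV
at 4.42 mm (~4.2 mm).

Each primary samples an initial energy from the beam's truncated Gaussian
(mean 58.4 MeV, FWHM 1.4 MeV, hard cut-off 58.55 MeV) and a stopping depth
from the straggled range. Dose scoring on 0.05 mm slabs is by exact energy
bookkeeping — a slab receives the energy lost crossing it, and a stopping
proton deposits its residual energy in its final slab — so the deposited
total closes on the injected energy to floating-point accuracy and the
dose beyond the deepest sampled range is exactly zero. One consequence of
the truncation worth noting: the entrance median energy is ~58.1 MeV, not
58.4, because the cut-off at 58.55 MeV removes a quarter of the upper half
of the distribution; the entrance-median test asserts the analytically
derived truncated-normal median.

Spectra are histogrammed in 600 bins over 0-60 MeV. Single-beam medians
and IQRs use unbinned type-7 quantiles (the convention is frozen in a
test: the sample \(\{10,20,30,40\}\) has median 25 and IQR 15); pooled
SOBP spectra use weighted histogram quantiles with linear within-bin
interpolation, which agrees with the unbinned convention to the 0.1 MeV
bin width.

### SOBP composition

The modulator is represented as water-equivalent shifts of the pristine
curve (PMMA WET 1.15), with per-component fluence losses folded into the
weights — exactly the role the weighting factors play in the reference
simulation. `solve_sobp_weights()` finds non-negative weights flattening a
chosen plateau by non-negative least squares and rescales the composite to
plateau mean 1. The default modulator uses 19 steps at 0.9 mm
water-equivalent spacing: the spacing must stay below the surrogate's
Bragg-peak width (~1.5 mm FWHM here) or the composite ripples; 0.9 mm
steps keep the plateau flat to a few tenths of a percent, while the
18 mm-deep plateau (14-28 mm) emulates full modulation.

## Phantom bookkeeping

The reference stack is 5 foils, three PMMA plates (7.2 mm total, so 2.4 mm
each — only the total is published), then 35 foils. Depths are cumulative
water-equivalent thicknesses (foil WET 1.05, PMMA WET 1.15). The published
total available range is 30.6 mm, while the arithmetic from the same
constants gives \(40 \times 0.54 \times 1.05 + 7.2 \times 1.15 =
30.96\) mm; the package uses the computed value and documents the
discrepancy.

Within a foil, the OSL grains sediment into the lower 0.4 mm of the
silicone during curing, so the default scoring convention attributes the
signal to the centre of the grain layer (+0.21 mm water); `front` and
`mid` conventions are selectable for sensitivity checks and shift all foil
depths by a constant, leaving depth differences intact.

## What the synthetic generator emulates — and what it does not

`camera_model()` / `generate_session()` produce frames with: linear OSL
response (`signal_per_gray`), a multiplicative vignette normalized to unit
mean over the central ROI, a uniform additive dark level (the dark level
is electronic and does not pass the optics, so it is deliberately not
vignetted), sensor drift of 0.1 per minute, random detector pose with a
rim-notch marker, per-pixel Poisson shot noise and Gaussian read noise,
16-bit quantization, and a per-acquisition multiplicative readout-gain
jitter of 1.5%.

The jitter deserves a word: per-pixel noise averages to ~0.01% over the
283,000-pixel ROI, so without a frame-level term the extracted means would
be unrealistically clean. Two independent 1.5% gains (proton and gamma
acquisition) give ~2% scatter on the calibrated dose, the scale the
efficiency fit is expected to tolerate.

Not emulated: OSL decay-curve kinetics, grain-scale optics, CCD defect
maps, dose nonlinearity (the material is linear to ~1 kGy), intra-foil
quenching gradients in the default mode (quenching is applied at the
foil's single attributed depth), and the skewed-spectrum effects that make
deep SOBP corrections genuinely hard in real data. Passing closed-loop
tests therefore demonstrate that the pipeline inverts its own generative
model exactly and remains accurate under realistic noise — not that the
efficiency model captures every feature of real deep-SOBP foil response,
which the reference analysis itself leaves open.

## Problem sizes and determinism

The closed-loop studies use \(10^5\) primaries (the reference simulation
used \(10^6\); the surrogate's statistical error at \(10^5\) is already
well below the 2% readout scatter) and the full 40-foil stack. Parameter
recovery uses 40 observations spanning 3-58 MeV, noise sd 0.03, 25
replicates. Every stochastic stage takes an integer seed and is
bit-reproducible under it; identical seeds give identical frames, ranges
and fits.

## Known limitations

* The transport surrogate has no nuclear attenuation, so the entrance
  plateau is slightly flatter than a measured curve; efficiency ratios are
  unaffected because generator and analysis share the curve.
* The efficiency model is energy-parameterized; an LET parameterization is
  out of scope.
* Below the 0.05 efficiency floor (median energies under ~10 MeV) the
  correction is intentionally bounded and the corrected dose there is a
  flagged lower bound, not an estimate.
* The marker-angle estimator assumes a single dominant rim notch; a
  symmetric detector without a marker yields angle 0 and an arbitrary
  rotation, which is harmless for the radially symmetric ROI statistic.
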