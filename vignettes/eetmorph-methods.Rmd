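---
title: "Separating morphology from physiology in mediated EET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating morphology from physiology in mediated EET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eetmorph)
```

## The problem and the model

Cyanobacteria reduce non-membrane-permeant mediators such as
ferricyanide at (or near) the cell's outer membrane. When cells are in
excess relative to the mediator, the reaction is mass-transfer limited
and the per-cell reduction rate equals the diffusive supply rate
through the boundary layer,

$$r = k \, A \, \big([\mathrm{Fe^{3+}}]_b - [\mathrm{Fe^{3+}}]_s\big),$$

with $k$ the liquid-to-cell mass-transfer coefficient (m s$^{-1}$),
$A$ the geometric outer-membrane area (m$^2$) and $\Delta c$ the
bulk-to-surface concentration difference (mol m$^{-3}$). Both $k$ and
$A$ are pure functions of cell geometry, while $\Delta c$ absorbs
whatever physiology or metabolism does to the reduction machinery. A
difference in $r$ between two cultures therefore decomposes
multiplicatively,

$$(1+\Delta r) = (1+\Delta k)(1+\Delta A)(1+\Delta \Delta c),$$

and the morphology effect ratio
$\mathrm{MER} = \sigma(|\Delta(kA)|/|\Delta\Delta c|)$ with
$\sigma(x) = 1/(1+e^{-x})$ condenses the comparison: the sigmoid maps
the unbounded channel ratio into $(0.5, 1)$, with
$\sigma(1) \approx 0.7311$ marking equal contributions. The sigmoid is
a convenience transform only — it is monotone, so the ordering of
comparisons is preserved.

Assumptions worth stating explicitly: the reduction site is the outer
membrane (or transport across the outer membrane is fast relative to
boundary-layer transport); cells are fully suspended; and the mediator
is supplied in a regime where transport, not kinetics, limits the
rate. If internal (periplasmic) diffusion limits, the inversion
$\Delta c = r/(kA)$ is no longer meaningful; the package deliberately
does not model that regime.

## Geometry: the spherocylinder

Rod cells are modelled as cylinders of length $L-D$ capped by
hemispheres of diameter $D$: $A = \pi D L$ and
$V = \tfrac{\pi}{4} D^2 (L - D/3)$, with $A/V = 4L/(D(L - D/3))$
decreasing from the sphere value $6/D$ toward the cylinder limit
$4/D$. The implementation enforces $L \ge D > 0$ and is exact at the
sphere limit. When the reduction site is taken at the plasma membrane,
`periplasm_correct()` subtracts twice the periplasmic-space thickness
(default 10 nm, the peptidoglycan-layer value for *Synechococcus*)
from both dimensions, erroring on underflow.

## Mass transfer

For small particles suspended in an agitated liquid,

$$k = \frac{2 D_{AB}}{d_p} + 0.31 \left[
  \frac{D_{AB}^2\,|\rho_p-\rho_c|\,g}{\mu_c}\right]^{1/3},$$

valid for $1\,\mu\mathrm{m} < d_p < 600\,\mu\mathrm{m}$ (treated as a
strict open interval; out-of-range lengths warn and are flagged rather
than refused). The characteristic length $d_p$ is fixed to the cell
*length*: across the observed 3–7 µm range cell width changes by under
0.2 µm, so elongation is the dimension that matters. Default constants
(ferricyanide in dilute BG11 at 30 °C): $D_{AB} = 7.44\times10^{-10}$
m² s⁻¹, $\rho_p = 1040$, $\rho_c = 995.65$ kg m⁻³, $g = 9.80665$
m s⁻², $\mu_c = 7.9735\times10^{-4}$ kg m⁻¹ s⁻¹. The diffusivity
default is the tabulated working value rather than the arithmetic mean
of the three literature measurements it derives from
($7.375\times10^{-10}$ via `average_diffusivity()`); users supplying
their own temperature-specific constants can override every field of
`physical_params()`. With these defaults the diffusive term is of
order $10^{-4}$ m/s and the gravitational term of order $10^{-5}$
(order = floor of log10), so $k$ is diffusion-dominated and length
errors propagate as $\sigma_k = (2 D_{AB}/L^2)\,\sigma_L$ — the
gravitational term is length-free.

Elongation pulls $r$ in two directions: $A$ grows
($\partial A/\partial L = \pi D$) while the diffusive part of $k$
shrinks ($\partial k/\partial L = -2 D_{AB}/L^2$).
`rate_length_derivative()` reports both channels of
$\partial r/\partial L = [A(-2D_{AB}/L^2) + k \pi D]\,\Delta c$
separately; for observed geometries the area channel wins and the
derivative is positive (tested against a central finite-difference
oracle).

## Measurement pipeline

**Assay rates.** The average reduction rate over the assay window is
the OLS slope of concentration vs time — ordinary least squares over
all sampled time points (default protocol: 1 mM ferricyanide, samples
at 0/10/30/120 min), chosen as the standard estimator for a short
linear decay. Absorbance converts through Beer–Lambert with the
ferricyanide extinction coefficient 1.05204 mM⁻¹ cm⁻¹ A⁻¹. The
per-cell normalisation uses cells l⁻¹ (×1000 from cells ml⁻¹); all
unit conversions live in one place and $\Delta c$ is reported in
mol m⁻³ (numerically mM), the only coherent choice for the inversion.
Replicate-level rates are the unit of error; SEMs combine in
uncorrelated first-order quadrature ($\sigma_{\Delta c}/\Delta c =
\sqrt{(\sigma_r/r)^2 + (\sigma_k/k)^2 + (\sigma_A/A)^2}$) because no
covariance information is available at this level of aggregation.

**Morphometry.** Images are binarised, 8-connected components
labelled, and each region summarised by the ellipse with the same
normalised second central moments: axes $= 4\sqrt{\lambda}$ of the
pixel-coordinate covariance with $1/12$ added to the diagonal (the
unit-pixel-square spread; it makes an $a\times b$ rectangle's axis
ratio exactly $a/b$ and keeps one-pixel-wide regions non-degenerate).
Three thresholding methods are provided. Otsu (default) is
deterministic and parameter-free but assumes reasonably balanced
classes; a contrast-to-noise guard (class-mean separation ≥ 3 pooled
within-class SDs) returns an empty mask on images with no separable
foreground, since Otsu applied to pure noise would otherwise mark
half the image. For dim sparse objects — where Otsu's threshold
collapses into the background distribution — the `robust` method
Gaussian-smooths (matched filter, default σ = 1 px), detects
candidates above median + 3 MAD, and refines the threshold to the
half-way level between background and foreground medians, a
half-maximum criterion that preserves object boundaries under
symmetric blur. A manual threshold bypasses everything.

QC filters mirror standard practice: minimum eccentricity (default
0.6) rejects out-of-focus round blobs, maximum minor axis (default
2 µm) rejects merged/dividing cells, minimum area (20 px) rejects
debris, and border-touching regions are excluded. The numeric defaults
are calibration choices against this package's synthetic generator —
they are not literature values and should be tuned per microscope.
Every rejection is tagged with the first rule it failed, so the log
partitions the removals.

Population statistics weight per-image means by cell count; the
weighted SD of those means summarises the sampling distribution of the
mean and the SEM divides by $\sqrt{n_\mathrm{images}}$. A single image
is degenerate (SD and SEM reported as 0 and flagged). Pairwise length
comparisons default to the pooled-variance Student's t (Welch
optional), two-tailed for lengths and one-tailed (test > control) for
rates; identical groups return $t=0,\,p=1$ rather than erroring so
automated sweeps stay total.

**Known limitation — the moment-axis convention.** For a true
spherocylinder footprint the moment-equivalent ellipse *overestimates*
the pole-to-pole length by roughly 9% and the width by roughly 12%
(closed form: a 40 × 12 px rod has moment axes 43.5 × 13.4 px). This
bias is inherent to the convention, which is also what standard
regionprops-style morphometry reports, so measured and literature
dimensions share it; tests therefore score recovery against the
continuous stadium-moment prediction, not against the generating
$L, D$. Users needing unbiased absolute dimensions would have to
invert the stadium moments — deliberately out of scope here.

**Growth.** The reparameterised Gompertz curve
$y(t) = A\exp(-\exp(\mu_\max e/A\,(\lambda - t) + 1))$ on
$y = \ln(N_t/N_0)$ carries the biologically meaningful parameters
directly. Because $y(0)$ is not exactly zero under this form, fitting
against the first sample as reference would bias every parameter;
when raw concentrations are supplied the package instead fits
$\ln N(t) = \ln N_0 + y(t)$ with $\ln N_0$ a free nuisance parameter
(exact recovery on noiseless data). Starting values are data-driven
(max log ratio; steepest finite-difference slope; 5%-of-plateau
crossing minus half a day, floored at 0) and the `port` algorithm
bounds $A, \mu > 0$, $\lambda \ge 0$. With day-scale sampling and an
hours-scale lag, $\lambda$ is structurally ill-determined; the fit
reports its large standard error rather than hiding it.

Doubling times default to the **decadic** convention
$t_d = 24\log_{10}2/\mu$: of the two conventions only the decadic one
reproduces all three benchmark rate/doubling-time pairs
(0.55 d⁻¹ → 13 h, 0.20 → 36 h, 0.36 → 20 h) to the nearest hour,
although it is unconventional for a "specific growth rate". The
natural-log convention remains available by flag; the discrepancy is
documented, not resolved. OD750 converts to cells ml⁻¹ with an
instrument-specific factor (default 2.95e-9 ml cell⁻¹ cm⁻¹ A) and a
linear-range cap at measured OD 0.8 that warns rather than rejects,
since the standard workflow dilutes into range and back-multiplies.

## Length regressions

Pooled per-condition regressions of width, area and surface-to-volume
ratio on length reduce the per-day error of population-mean estimates.
Cells are binned by length (0.4 µm bins, left-closed, anchored at the
minimum observed length; bin mean length is the mean of member
lengths, not the bin centre, avoiding partial-bin bias); bins with
fewer than 50 cells are dropped; and the per-bin mean property is
fitted against the per-bin mean length by least squares *weighted by
bin count*, since a bin mean of $n$ cells has variance
$\propto 1/n$. The model family is not dictated by the data source, so
the default is the simplest consistent with near-linear trends:
ordinary polynomials of degree 1 (degree 2 optional); the area and
surface-to-volume regressions are fitted independently rather than
derived from the width model. Uncertainty of a predicted mean is the
half-width to the pointwise 95% confidence band on the mean response;
predictions outside the fitted range warn (extrapolation) but
proceed.

## Synthetic data: what it emulates, what it does not

The generator produces every input the pipeline consumes, with ground
truth, as pure functions of (spec, seed):

* **Populations**: truncated-Normal lengths (default mean 3.7 µm, SD
  0.8 µm, bounds 1.8–8 µm — the exponential-phase mean with enough
  spread to populate several 0.4 µm bins; a log-Normal family is
  available), linear width law $D = 1.05 + 0.04L \pm 0.08$ µm (width
  gain under 0.2 µm across 3–7 µm), uniform orientations.
* **Images**: rasterised spherocylinder footprints, isotropic Gaussian
  PSF, background plus Gaussian read noise, optional Poisson shot
  noise; minimum-separation placement with bounded retries, or
  deliberate overlap for QC fixtures. No Airy optics, no bleaching, no
  autofluorescence spectra — enough to stress segmentation and QC, not
  to emulate a microscope.
* **Assays**: linear decay at the slope implied by a per-cell rate and
  cell concentration, additive Gaussian noise (default SD 0.005 mM, a
  spectrophotometer-scale jitter), truncation warning if the mediator
  would be exhausted.
* **Growth curves**: Gompertz-consistent concentrations referenced to
  the true inoculum, multiplicative log-normal noise (default CV 5%).

A green test on synthetic data establishes that the estimators recover
what the generator encoded under the stated noise — not that real
confocal images or real assays satisfy the generator's simplifications
(no cell-to-cell rate variability, no focus drift, no pipetting
error).

## Numerical conventions and degenerate inputs

Internal geometry stays in µm and converts to SI only at the
mass-transfer boundary (avoids float underflow in tables). CSV output
is fixed at 9 significant digits so identical runs are byte-identical.
The pipeline configuration is JSON (no YAML parser is available in the
target environment); unknown keys are rejected. MER edge cases:
$|\Delta\Delta c| = 0$ with a nonzero morphology channel returns the
limit 1 flagged `denominator_zero`; both channels zero returns 0.5.
Dominance calls use a $10^{-6}$ tolerance band around 0.7311.
Constant images, empty masks, single-bin regressions, zero-variance t
tests, non-positive dimensions and infeasible truncations all have
defined, tested behaviour (warning or typed error naming the rule).
Pipeline stages fail loudly with the stage name; provenance records
config and input digests (MD5) plus the package version and seed.

Choosing a mass-transfer-limiting cell/mediator combination is an
experimental-design step, not a computation: the pipeline records the
concentrations used and warns below $10^7$ cells ml⁻¹, the order below
which limitation becomes doubtful.
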