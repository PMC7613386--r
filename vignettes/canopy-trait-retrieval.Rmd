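---
title: "LUT-based retrieval of maize canopy traits: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LUT-based retrieval of maize canopy traits: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopylut)
```

This vignette is the package's own account of the science it implements:
the forward radiative transfer model, the look-up-table (LUT) inversion,
the preprocessing around them, the synthetic study the tests run on, and
the design decisions taken where the problem was genuinely open.

## The retrieval problem

A multispectral camera on a UAV measures, per ~1.5 cm ground pixel, ten
band reflectances between 444 and 842 nm. We want three canopy traits per
field plot: leaf area index (LAI, m² one-sided leaf area per m² ground),
leaf chlorophyll content (LCC, µg chlorophyll a+b per cm² leaf) and canopy
chlorophyll content (CCC = LCC · LAI, the canopy-integrated pigment pool).
Physically based retrieval inverts a radiative transfer model: find canopy
states whose simulated reflectance matches the measurement. The inverse
problem is ill-posed — different states produce near-identical band
spectra — which motivates priors per acquisition date, regularising noise,
and averaging over many acceptable solutions rather than taking the single
best.

## Forward model

### Leaf: generalised plate model

`prospect5()` treats the leaf as `N` compact layers with rough interfaces.
Per wavelength, the absorption coefficient of one elementary layer is

\[ k = \frac{C_{ab}\,k_{ab} + C_{cx}\,k_{cx} + C_{bp}\,k_{bp} +
  C_w\,k_w + C_m\,k_m}{N}, \]

its isotropic transmissivity is \((1-k)e^{-k} + k^2 E_1(k)\) (exponential
integral via `pracma::expint_E1`), and the one-layer and \(N-1\)-layer
reflectance/transmittance follow from the Fresnel-based interface
transmissivities and the closed-form Stokes stack solution, with the
conservative-scattering limit handled separately. The output is a
reflectance and transmittance spectrum on the fixed 1 nm, 400–2500 nm grid
used throughout the package.

**Spectral constants are synthetic.** The published calibration tables
(refractive index and specific absorption coefficients) are distributed
with the original model code and are not reproduced here;
`leaf_optical_constants()` builds smooth stand-ins from Gaussian absorption
bands at the physically correct positions (chlorophyll at 430/662 nm,
carotenoids 426–480 nm, brown pigment decaying across the visible and gone
by 800 nm, water at 970/1200/1450/1790/1940/2270 nm, dry matter rising
into the SWIR with a broad weak term near 1100 nm that gives the leaf a
realistic few-percent NIR absorptance). Consequences: every qualitative
contract holds (energy conservation, red trough deepening with
chlorophyll, NIR saturation with LAI, soil hiding under dense canopies),
and the retrieval machinery is exercised exactly as with the published
constants — but simulated spectra, and therefore retrieved values on
*real* imagery, are not comparable to runs of the original calibration.
The package is a faithful pipeline with a synthetic spectral library, and
says so.

### Canopy: four-stream turbid medium

`foursail()` implements the classic four-flux canopy solution: extinction
and scattering coefficients are integrated over an ellipsoidal leaf
inclination distribution parameterised by the average leaf inclination
angle (ALIA), discretised over the 13 standard angle classes; the linear
system for the diffuse fluxes is solved in closed form; single scattering
toward the observer includes the hot spot correction (bidirectional gap
probability along the sun–view path, 20-point integration); soil interacts
through the standard multiple-bounce terms. `prosail()` is the composition
of the two models. With `LAI = 0` the soil spectrum is returned
bit-identically — a contract the tests rely on.

The R implementation is cross-checked, spectrum by spectrum, against an
independently written scalar NumPy/SciPy transcription of the same
published equations (`inst/oracle/prosail_reference.py`); the two routes
agree to ~1e-14, and the test suite enforces 1e-4 on 100 random parameter
sets. This guards against translation slips, though both routes share the
model equations and the synthetic constants.

### Bands and geometry

`resample_to_bands()` convolves spectra with a normalised Gaussian
spectral response per band (FWHM = the band's stated bandwidth); a boxcar
is available, and the weights are convex so constants are preserved.
`solar_zenith()` computes sun geometry with the NOAA solar-calculator
equations (declination, equation of time, hour angle, optional
refraction), accurate to a few hundredths of a degree. When reproducing
campaign metadata quoted at "13:00 local time", the package interprets
local time as standard time (UTC+1 at the emulated site) rather than
daylight time: sun-angle tables distributed with such campaigns are
commonly produced by tools configured that way, and only this reading
reproduces both quoted angles (27.81° on 23 June, 48.14° on 14 September)
within 0.3°.

## Radiometric preprocessing

`raw_to_radiance()` applies the camera vendor's conversion
\(L = V(x,y)\,\frac{a_1}{g}\,\frac{p - p_{BL}}{t_e + a_2 y - a_3 t_e y}\)
with \(p\) the digital number normalised by \(2^B\); the vignette
polynomial is an input, not fitted. `fit_elm()` fits the empirical line
method — per-band OLS of panel nominal reflectance on observed radiance —
with the saturation rule: panels brighter than 22 % nominal reflectance
are excluded in visible bands (centre < 700 nm; the regions are named in
practice but no cutoff is, so 700 nm is this package's choice) and kept in
red-edge/NIR bands. OLS is unconstrained (no positivity forced on the
slope). `apply_elm()` clips to the physical range [0, 1] and reports clip
counts rather than losing pixels silently. Panel radiance is extracted
from the eroded interior of each panel polygon (default erosion 25 % of
the short side) so mixed edge pixels do not bias the fit.

## Masking

Leaf chlorophyll must be retrieved from sunlit green pixels only.
`hue_mask()` thresholds an RGB colour index; the exact hue formula used by
field-phenotyping toolchains is not published in a recoverable form, so
the default — \(\mathrm{HI} = \arctan\frac{2(B-G-R)}{30.5\,(G-R)}\),
retain when \(\mathrm{HI} < 0\) — was calibrated once against the
generator's labels (≥ 95 % balanced accuracy enforced in tests) and the
index function is a pluggable argument so alternates (excess green, etc.)
drop in. Two auxiliary rules handle degenerate pixels: near-black pixels
(R+G+B below 0.05) are removed as shadow, and pixels with `G == R`
(undefined index) are removed and counted. `chm_mask()` is the fallback
for senescent canopies whose brown leaves resemble soil: threshold the
crop height model (DSM − DTM) at a configurable minimum height (default
0.05 m); the "manual" threshold used operationally is a config value, not
a constant. LAI and CCC retrievals deliberately use *no* mask: the
plot-level leaf area ground truth integrates row gaps, so soil and shadow
belong in the signal.

## LUT inversion

`param_space()` encodes the per-date sampling space: N uniform 1.2–1.8;
C_ab Gaussian (location/scale from the date's field statistics, truncated
to 0–70 µg/cm²); C_cx and C_w fixed (8 µg/cm², 0.015 g/cm² — the
upstream toolbox defaults are not published, so these are exposed
constants, not hard-coded); C_bp fixed at 0 early season or uniform 0–0.5
under senescence (`browning = TRUE`); C_m uniform 0.004–0.0075 g/cm²; LAI
uniform 0–7; ALIA on the integer grid 20–70°; hot spot uniform 0.01–0.5
(a narrower 0–0.2 literature range is selectable — both ranges circulate
and the package defaults to the wider one); geometry fixed per date (SZA
from `solar_zenith()`, nadir view); soil drawn per entry from a dry/wet
pair.

`sample_param_space()` draws a Latin hypercube (`lhs::randomLHS`): each
non-fixed marginal places exactly one sample in each of its n
equal-probability strata; Gaussians are mapped through the truncated
inverse CDF; the leaf-angle grid receives equal mass per integer value.
Building combinatorial grids with hundreds of thousands of entries and
then subsampling 10,000 by LHS is statistically equivalent to drawing the
10,000 stratified samples directly, so the package does the latter.

`build_lut()` runs the forward model per entry (angular coefficients are
cached per distinct leaf angle, making the default 10,000-entry build
about 40 s on one CPU); `add_noise()` perturbs each simulated reflectance
once by \(r(1+\varepsilon)\), \(\varepsilon \sim N(0, 0.02)\) — the 2 %
is read as *relative* noise applied to the LUT side (an additive-absolute
mode exists); a table can only be perturbed once, and negative results
clip to zero.

`invert_spectrum()` ranks entries by band-space RMSE (cost functions are a
registry — RMSE, summed squares, spectral angle — because exploring costs
is a known lever), breaks ties by entry index (stable sort), retains
`ceiling(0.05 · n)` solutions (500 of 10,000; the "best 5 %" is read as a
fraction of entries, not a fixed count) and reports the per-variable mean
and standard deviation over the retained set. CCC is derived per retained
solution as C_ab · LAI and then averaged — not retrieved independently,
and not computed as mean(C_ab) · mean(LAI).

### Aggregation strategies

`invert_plot_mean()` inverts one spectrum per plot — the mean over
(optionally masked) valid pixels; plots without valid pixels are reported
missing, not failed. `invert_pixelwise()` inverts every valid pixel,
optionally after block-averaging to a coarser grid (default 0.09 m for
LAI/CCC maps; native resolution for LCC), and `aggregate_plots()` averages
the resulting maps per plot. On a homogeneous plot the two strategies
coincide exactly — a useful invariant the tests enforce. On mixed plots
they differ: averaging reflectance before inverting a nonlinear model is
not the same as inverting then averaging, and the synthetic experiments
reproduce the operationally observed direction — adding shadow pixels
raises mean-reflectance LAI estimates.

## Trait conversions and validation

`spad_to_lcc()` applies the maize calibration
\( \mathrm{LCC} = 9.1411\,e^{0.0318\,\mathrm{SPAD}} \) (so SPAD = 0 maps
to exactly 9.1411 µg/cm²); `ccc()` multiplies by LAI. CCC is labelled
µg/cm² of ground area — multiplying µg/cm² by a dimensionless LAI cannot
change the unit, even though µg/m² sometimes appears in this context;
the package keeps the dimensionally consistent label. `evaluate()` joins
estimates to truth and reports RMSE (root of the mean squared difference —
the conventional reading of the formula), rRMSE = 100·RMSE/mean(observed)
and r², per variable and grouping (date, maize type, pooled). r² is the
squared Pearson correlation (the scatter-plot convention); regression R²
differs when the fit is biased, and `r_squared()` documents the choice.

## The synthetic study

`scene_config()` / `generate_scene()` emulate the field trial the pipeline
targets: 84 plots (12 × 7) of 3 × 3 m at 0.015 m GSD by default; sweet
and silage maize rows with contrasting leaf-angle truth ranges (30–50°
planophile-ish vs 45–65° erect) and shading (silage rows carry more
shadow); per-plot truth LAI 0.5–5.5 and chlorophyll 30–55 µg/cm², inside
the retrieval prior; crop rows rendered as vegetation/shadow/soil stripes
with a 0.75 m repeat; shadow as a multiplicative darkening (default 0.25)
of the soil spectrum — the minimal model that reproduces the mixture-bias
mechanism; nine flat calibration panels (2–63 %); additive Gaussian sensor
noise (sd 0.005 reflectance). Ground truth emulates field sampling: SPAD
obtained by inverting the calibration at the truth chlorophyll plus meter
noise, LAI plus noise. Everything is deterministic given the config seed,
and regeneration is bit-identical.

What the generator does **not** emulate: 3-D canopy structure and
photogrammetric artefacts (blur, seamlines, view-angle mixtures),
brown-leaf spectra distinct from soil, within-plot trait gradients,
atmospheric variability. Passing tests therefore demonstrate internal
consistency of the chain — forward model, sampling, masking, inversion,
statistics — under controlled conditions, not field accuracy. Headline
field accuracies depend on real campaign data that is not distributable,
and the package makes no claim to reproduce them.

## Numerical choices and problem sizes

* Wavelength grid: 1 nm, 400–2500 nm, fixed (2101 points).
* SRF: Gaussian, FWHM = stated bandwidth, truncated at ±3σ inside the
  grid; trapezoid-normalised convex weights.
* Cost sort: stable, ties by entry index; solution count by ceiling.
* Clipping: reflectance clipped to [0, 1] after the empirical line and
  after noise (at 0), always counted or flagged, never silent.
* Degenerate inputs: zero-width distributions rejected; plots/blocks with
  no valid pixels reported missing; `G == R` hue pixels removed and
  counted; non-finite measurements rejected.
* Test problem sizes (package choices for a laptop-class run): unit tests
  use 400-entry LUTs and 30 × 30-pixel plots; the acceptance checks build
  one full 10,000-entry LUT (~40 s), run a 10-plot noiseless homogeneous
  study end-to-end against a second 10,000-entry LUT, and compare 100
  random parameter sets against the Python transcription. The full
  default 84-plot scene at 0.015 m (3.4 M pixels) renders in a few
  minutes and is not exercised inside the test suite.

## Known limitations

Synthetic spectral constants (above) are the main one. Others: a single
observer zenith angle per scene (no per-pixel view geometry, consistent
with nadir mapping practice); no atmospheric model (the empirical line
absorbs the atmosphere into the panel fit); the LUT prior for chlorophyll
requires field statistics (or defaults) per date; the hue index formula
is a calibrated guess behind a pluggable interface; rasters are plain
pixel tables (tibbles with x, y and band columns) and plot polygons are
rectangles — adequate for the synthetic study and for teaching the
method, but real GeoTIFF/vector workflows would wrap these functions
behind their own I/O layer.
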