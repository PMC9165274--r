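---
title: "Models and methods behind the vmsot pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the vmsot pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmsot)
```

# Scope and data model

`vmsot` implements a desk-scale, fully synthetic analogue of whole-brain
volumetric multispectral optoacoustic tomography (vMSOT) of a far-red
tau-binding probe, from photon absorption to group statistics. The central
objects are S4 classes: a `SpectralLibrary` of chromophore absorption
spectra, a `BrainPhantom` (atlas-labelled voxel grid, vessel mask, HbO map),
a `FrameSeries` of time-resolved probe concentration maps, a `Sinogram` of
detector traces, a `VolumeStack` of reconstructions indexed by wavelength
and frame, `AbundanceMaps` after unmixing, and `VOIReport`/`FitReport`
containers for the quantification and binding outputs. All absorption
values and abundances are in arbitrary consistent units (a.u.); no molar
calibration is attempted.

# Spectral model

The bundled table (`bundledSpectralLibrary()`) tabulates HbO and HbR from an
approximate literature compilation at 5 nm steps over 550--700 nm,
normalized to unit maximum. The probe spectrum is synthetic: no numerical
tabulation of the measured spectrum is available, so PBB5 is modeled as a
skewed Gaussian peaking at 630 nm with a half-maximum span of roughly
590--690 nm, which reproduces the two facts that matter for unmixing — a
far-red absorption peak at 630--640 nm located exactly where hemoglobin
absorption decays monotonically (the shipped HbO values decrease strictly
over 600--640 nm; a test asserts this premise). Interpolation is linear:
spectra are smooth at 5--10 nm resolution and linearity keeps the unmixing
oracle exact. Queries outside the grid are refused rather than
extrapolated.

# The digital phantom and its kinetics

`makePhantom()` is a geometric stand-in for an MRI atlas: a brain ellipsoid
(about 9 x 11 x 8 mm, inside the instrument's 15 mm field of view)
subdivided into eight regions — a dorsal cortical shell, paired hippocampi,
central thalamus, posterior cerebellum, paired striata, olfactory bulb,
brainstem, and a midbrain remainder — plus a superior-sagittal-sinus tube
with two transverse branches as the vessel mask. The seed jitters region
centers and axes mildly (0.1 mm scale) to emulate inter-subject anatomy;
everything is deterministic given the seed. Atlas *registration* is
deliberately out of scope: VOIs live in phantom coordinates.

Probe kinetics use the simplest family that reproduces the qualitative
in vivo curve shapes:

* vascular pool: gamma-variate bolus with shape 3 and scale 30 s, starting
  at the injection time (30 s on a single continuous clock) and peaking
  90 s later;
* parenchyma: two-compartment uptake from the vascular pool at rate
  `uptakeRate` (5e-3 s^-1) times a regional tau-load multiplier, with slow
  washout (2e-4 s^-1), evaluated in closed form through the incomplete
  gamma function.

Tau load defaults encode the tauopathy phenotype: cortex = hippocampus = 1,
thalamus = 0.8, cerebellum = 0 (reference region), remaining regions 0.3.
Wild-type animals retain a 0.35 fraction of the transgenic load, emulating
non-specific binding, so the group contrast is graded rather than binary.
Dose enters exactly once (in the vascular amplitude), making every
concentration linear in dose; the 5/25/50 mg/kg analogues are dose scales
0.2/1/2. The rate constants are stand-ins chosen for curve shape only — no
kinetic parameters are claimed to be fitted values.

The acquisition timeline follows the experimental schedule on one clock:
pre-injection frames before 30 s, bolus/injection frames to 540 s, then
retention frames at 20--120 min. (The real acquisition uses separate
pre/during/post sessions; collapsing them onto one clock with injection at
30 s matches the kinetics configuration and keeps "time < injection implies
zero probe" a hard invariant.)

`planarFluorescenceReadout()` provides the epi-fluorescence channel
analogue: an exponential depth-weighted sum (length constant 1 mm) of the
probe map over the cortical shell. Its time course correlates with the
cortical VOI mean above r = 0.9 by construction, mirroring the cross-modal
validation logic.

# Optical and acoustic forward model

Per wavelength, `absorptionMap()` forms the linear mixture
mu_a = sum_c eps_c(lambda) C_c. The effective attenuation is taken from
diffusion theory, mu_eff = sqrt(3 mu_a (mu_a + mu_s')) with constant
mu_s' = 10 cm^-1 — the source method names the quantity but not the
functional form, so the diffusion expression is adopted and documented as
an interpretation. Fluence decays as exp(-integral of mu_eff) accumulated
along the top-illumination axis, with fluence exactly 1 in the surface
layer; a single top-illumination model is used for both in vivo and ex vivo
configurations (a simplification — the real ex vivo setup illuminates from
four fiber arms).

`projectVolume()` bins each voxel's spherical impulse
p0 V / (4 pi r) at the rounded time-of-flight sample and applies a central
difference in time (the N-shape model, switchable off for oracle tests).
Detection is modeled as a Gaussian band (default center 4 MHz, 100%
fractional bandwidth) applied in the frequency domain, followed by
per-pulse energy scaling (log-normal jitter, sd 0.03) and i.i.d. Gaussian
noise whose sd defaults to 2% of the clean-signal sd. The detector array is
a Fibonacci lattice of 256 (default) detectors on the lower hemisphere of a
15 mm sphere, sampling at 40 MHz. The array specifications of the real
instrument are not published in the source method, so these are package
defaults, and the instrument's ~115 um resolution figure is *not* claimed:
resolution here is whatever the simulated aperture yields, and only the
FWHM *estimator* is validated analytically. Speed of sound is constant at
1.50 mm/us with no skull layer (the skull was reported negligible for
resolution at this scale).

# Reconstruction

`backproject()` is unweighted delay-and-sum with linear interpolation in
delay, solid-angle weights normalized to sum 1, and the ramp-filtered trace
q = -t ds/dt as the default pre-filter. This pairing is chosen for
self-consistency with the derivative forward model: back-projecting the
ramp-filtered N-shaped signal of a point source produces a sharp positive
peak at the source (the point-localization tests verify a zero-voxel error
at 64^3 / 0.2 mm / 256 detectors, and that two sources 3 mm apart resolve).
Out-of-window delays contribute zero and increment a warning counter;
negative values are preserved — clipping is a visualization decision, not a
reconstruction one. Energy normalization divides each (wavelength, frame)
block by its pulse energy and is idempotent; with noise off it cancels
simulated jitter to machine precision.

# Spectral unmixing

`unmixLSQ()` solves per voxel min ||M a - y||^2 with the design M of
component spectra on the chosen wavelengths (default: HbO + PBB5 on
600--640 nm, 10 nm step). The solution is unconstrained by default —
negative abundances are reported, not clipped — with an optional exact
small-K nonnegative variant (active-set enumeration over coefficient
subsets). A condition number above 1e6 is a hard error rather than a silent
pseudo-inverse. No fluence (spectral-coloring) correction is applied before
unmixing; the fluence model exists for simulation realism, and the residual
spectral coloring is part of what the validation correlations measure.

The probe spectrum can be taken from the library or extracted from the data
(`extractProbeSpectrum()`): average the baseline-subtracted images over
bolus-phase frames at dorsal vessel seed voxels, per wavelength, and
normalize to unit maximum. Because the seeds are shallow, spectral coloring
is mild and the extracted spectrum matches the generating one to cosine
similarity above 0.99 in the default study. The configuration is validated
by `crosscheckUnmixing()`: Pearson correlation between the unmixed probe
map and the baseline-subtracted 640 nm image, both averaged over the
3--7 min post-injection window.

Including HbR as a third component is supported but degrades the probe map:
over 600--640 nm the HbR column is nearly collinear with HbO, inflating the
estimator variance, and on the default noisy study the PBB5 root mean
squared error (after optimal scaling to truth) increases for every battery
seed. This reproduces the empirical two-component design choice.

`unmixVCA()` implements vertex component analysis for the ex vivo route
(600--655 nm, 5 nm step): SNR-adaptive subspace projection (uncentered
p-dimensional subspace with projective scaling at high SNR; (p-1)-dim
centered subspace plus a constant coordinate at low SNR) and iterative
orthogonal-projection vertex selection under the pure-pixel assumption,
with the random direction vectors drawn from a caller-supplied seed.
Requesting more endmembers than the data rank is an error.

# Quantification and statistics

`voiTimecourse()` averages maps over integer-labelled VOIs; label 0
(extracranial) never contributes, bit-exactly. `retention()` reports
absolute a.u. at the nearest frame to the requested time (matching how the
regional results are plotted), with an optional cerebellum-ratio output
since the cerebellum serves as reference region. `fitFWHM()` fits a
Gaussian plus offset by Levenberg-Marquardt (moment-based initialization)
and reports FWHM = 2 sqrt(2 ln 2) sigma.

The statistical battery wraps base R: `aov()` for the balanced two-way
ANOVA (group, region, interaction) with per-region pooled t tests and
Bonferroni multiplication by the number of regions; unbalanced designs are
a hard error so the sums-of-squares decomposition stays the textbook one
(the test suite checks it against a hand computation to 1e-8).
"Pearson's rank correlation" in the source description is internally
inconsistent terminology; linear Pearson correlation is implemented as the
default with a Spearman option. Interrater reliability is emulated by
re-running the VOI analysis with labels eroded or dilated by whole voxels
(`jitterLabels()`), and correlating regional values between the two runs.

# Binding analysis

`fitCompetition()` fits one-site and shared-plateau two-site competition
models in log10-concentration space (Hill slope fixed at 1, as only
one-/two-site models are specified) with multi-start initialization over
eight IC50 seeds spanning the data range, via `minpack.lm`. The two-site
parameterization shares the top/bottom plateaus between sites — how the
original "partial replacement" was parameterized is not stated, so the
shared-plateau convention is adopted. `chengPrusoff()` converts IC50 to Ki
given [L] and Kd; Kd must be supplied by the user (it is not published for
this radioligand), and the homologous convention Ki = IC50 - [L] is
provided separately. Model selection uses the extra-sum-of-squares F test
at alpha = 0.05; a two-site fit with larger SSE than the one-site fit is
flagged and the one-site model kept. The published Ki values cannot be
reproduced because the raw assay data are not public; the tests instead
verify noiseless identifiability to 1e-6 relative, median Ki error below
10% at 5% CV with quadruplicates, and binomial type-I control of the F
test.

# Problem sizes, seeds, and what passing means

Default study sizes are desk scale by design: 32^3 voxels at 0.4 mm with
128 detectors for the bolus study, 24^3 at 0.5 mm with 64 detectors per
animal in cohort simulations, 64^3 at 0.2 mm with 256 detectors for the
point-source characterization. The seed battery for every-seed direction
checks is seeds 1--5 at phantom level and 1--3 for full acoustic runs. The
grid-search oracle for the unmixer uses unit-max-normalized component
spectra so both abundance axes are comparably scaled; with the raw bundled
spectra the SSE valley is nearly flat along the (tiny-normed) HbO axis and
a discrete argmin is not well defined at the 0.01 step.

The generator emulates the statistical structure of the experiment —
genotype contrast, dose linearity, bolus timing, band-limited noisy
detection, energy jitter — but not everything about real data: no acoustic
heterogeneity or attenuation, no transducer spatial impulse response beyond
the band model, no realistic vascular trees, no motion, and VOIs are exact
by construction rather than registered. Passing tests therefore validate
the *algorithms* (consistency, identifiability, statistical calibration) on
a faithful synthetic analogue; they do not certify performance on real
instrument data, and no published headline number (spatial resolution,
inhibition constants, in vivo p values) is claimed to be reproduced.

# Known limitations

Single top-illumination fluence model for all configurations; derivative
and ramp filters as the only signal-model pair (no exact-aperture inverse);
unweighted delay-and-sum (no apodization); balanced-ANOVA-only statistics;
Hill slope fixed at 1; the sinogram container is a package-documented flat
binary + JSON layout rather than a standard scientific container format.
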