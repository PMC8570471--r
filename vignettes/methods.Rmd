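---
title: "Oscillating-gradient and microscopic-anisotropy dMRI: models, simulation, and test-retest statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillating-gradient and microscopic-anisotropy dMRI: models, simulation, and test-retest statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogmua)
```

## What this package computes

`ogmua` implements a complete analysis chain for two advanced diffusion-MRI
contrasts in the rodent brain and for assessing their test-retest
reproducibility:

* **OGSE (oscillating gradient spin echo)**: mean diffusivity measured at
  several gradient oscillation frequencies $f$ probes progressively shorter
  diffusion times. Across the 0-200 Hz range, tissue MD follows a power law
  in $\sqrt{f}$,
  $$\mathrm{MD}(f) = \mathrm{MD}_0 + \Lambda \sqrt{f},$$
  and the *diffusion dispersion rate* $\Lambda$
  (units $\mu m^2\,ms^{-1}\,Hz^{-1/2}$, with $f$ in Hz) summarizes the
  frequency dependence. $\Delta\mathrm{MD}$ is the difference between the MD
  maps at the highest frequency (190 Hz) and at 0 Hz (PGSE).
* **Microscopic anisotropy (muA)**: comparing powder-averaged signals under
  linear (LTE) and spherical (STE) tensor-valued encoding separates true
  microscopic anisotropy from fiber orientation dispersion. The
  powder-averaged signal of a multi-Gaussian system follows the cumulant
  (kurtosis) representation
  $$\ln S_X(b) = \ln S_0 - b D + \tfrac{1}{6} b^2 D^2 K_X, \qquad
    X \in \{\mathrm{LTE}, \mathrm{STE}\},$$
  where $K_\mathrm{LTE}$ reflects variance of both directional and isotropic
  diffusivity and $K_\mathrm{STE}$ only the isotropic part. Microscopic
  anisotropy and its normalized form are
  $$\mu A^2 = \frac{D^2 (K_\mathrm{LTE} - K_\mathrm{STE})}{6}
            = \frac{\ln(S_\mathrm{LTE}/S_\mathrm{STE})}{b^2}, \qquad
    \mu FA = \sqrt{\frac{3}{2}\,
      \frac{\mu A^2}{\mu A^2 + 0.2\,D^2}}.$$
  The printed form of the $\mu A$ equation is ambiguous about the root and
  constant; the form above is the unique reading consistent with the stick
  limit, where $\mu A^2 = 0.4\,D^2$ gives exactly $\mu FA = 1$.

The in-vivo test-retest dataset that motivates these tools (12 mice scanned
twice, 5 days apart) is not redistributable here, so the package ships a
first-class synthetic-cohort generator that emulates its design, and every
estimator is validated against analytic oracles on that generator.

## Encoding module

Waveforms are idealized (infinite slew): rectangular PGSE lobes and
integer-period cosine OGSE lobes on either side of the $180^\circ$ pulse,
whose sign reversal is applied implicitly when integrating. The b-tensor is
computed numerically as $B = \int q q^\mathsf{T} dt$ with
$q(t) = \gamma \int g\,dt'$ evaluated at sample midpoints (exact for
piecewise-linear $q$, giving PGSE b-values accurate to $\sim 10^{-8}$
relative at the default $dt = 0.01$ ms). Oracles: the closed forms
$b = \gamma^2 G^2 \delta^2 (\Delta - \delta/3)$ for PGSE and
$b = (\gamma G / 2\pi f)^2\, T_\mathrm{osc}/2$ for cosine OGSE.

Design choices made here:

* **STE construction.** The contract is isotropy of the b-tensor, not a
  specific waveform. Each lobe is time-multiplexed into three consecutive
  single-axis cosine segments with equal per-axis weighting; since $q$ on
  each axis returns to zero before the next axis plays, off-diagonal terms
  vanish identically and each eigenvalue is exactly $b/3$.
* **FTB at 50 Hz.** The acquisition's frequency-tuned bipolar waveform is
  represented as a cosine lobe at 50 Hz with an optional bipolar pre/post
  segment. Downstream analysis consumes only the (frequency, b) pair, so
  this choice is isolated in the encoding module.
* **Direction sets** are deterministic Fibonacci-sphere points, antipodally
  reduced, rotated by a seeded random rotation (the study does not print
  its direction tables).
* **Units**: b in $ms/\mu m^2$, diffusivity in $\mu m^2/ms$, so $bD$ is
  dimensionless; frequencies in Hz at every interface.
* **Zero-padding** to a common encoding time (equal TE across frequencies)
  prepends/appends zero samples and provably leaves $B$ unchanged; the
  power spectrum $|F(f)|^2$ of $q(t)$ is normalized so its total equals b
  (Parseval), and OGSE spectra peak at the nominal frequency within the
  intrinsic resolution $1/T$.

The two study protocols are reproduced by `build_protocol()`: OGSE with
PGSE + 50/100/145/190 Hz at $b = 0.8\ ms/\mu m^2$, 10 directions each, 10
interspersed b0 volumes (60 volumes); muA with LTE and STE at
$b = 2.0\ ms/\mu m^2$ (30 directions each) and $1.0\ ms/\mu m^2$ (12 each),
8 interspersed b0 volumes (92 volumes).

## Synthetic tissue and cohorts

A substrate is a mixture of axially symmetric Gaussian compartments with an
orientation model (coherent, Watson with concentration $\kappa$, or
uniform). Frequency dependence enters as an isotropic scaling of each
compartment tensor so that its MD follows
$\mathrm{MD}_0 + \Lambda_c \sqrt{f}$ exactly — the study fits this power law
but does not prescribe a microstructural generator, so the generator is
built to satisfy the fitted law by construction. Powder-averaged cumulants
of any such mixture are available in closed form (`analytic_moments()`):
$\bar D = \sum_i f_i\,\mathrm{MD}_i$,
$V_\mathrm{STE} = \sum_i f_i (\mathrm{MD}_i - \bar D)^2$,
$V_\mathrm{LTE} = V_\mathrm{STE} + \sum_i f_i \tfrac{4}{45}
(\mathrm{AD}_i - \mathrm{RD}_i)^2$, $K_X = 3 V_X / \bar D^2$ — independent
of the orientation models, which is precisely the dispersion-invariance
property that separates $\mu FA$ from FA. A brute-force powder average over
$10^5$ directions serves as an independent oracle.

The default phantom is a $16 \times 16 \times 4$ grid: five tissue bands
named after the study's ROIs (corpus callosum, internal capsule,
hippocampus, cortex, thalamus) inside a one-voxel CSF border
($\mathrm{MD} = 3.0\ \mu m^2/ms$ with a negative dispersion rate emulating
flow, exercising the CSF filter). Each tissue region mixes two Gaussian
sub-compartments with MDs split $\pm 20\%$ (cell-size heterogeneity, so
that the isotropic kurtosis $K_\mathrm{STE}$ is positive as in real brain
— with a single compartment it would be identically zero and its
within-subject CV undefined) plus a 0.5-2% CSF partial-volume fraction.
Ground-truth dispersion rates span 0.0051-0.0068
$\mu m^2\,ms^{-1}\,Hz^{-1/2}$, matching the range reported in vivo.

Cohorts: each subject draws, per ROI, a multiplicative diffusivity scale
(applied jointly to AD and RD, preserving compartment shape) and a
dispersion-rate scale from lognormals with median 1 and coefficient of
variation `cv_between` (default 10%); each session re-draws about the
subject value with `cv_within` (default 5%). Scaling AD and RD jointly is
deliberate: it makes every diffusivity-derived ground-truth metric inherit
the nominal CV exactly, so the reproducibility estimators can be validated
against the generator. (Drawing AD and RD independently would shrink the
CV of derived quantities below the nominal value and break that identity.)
Lognormal rather than normal draws keep diffusivities positive at large
CV, with $\sigma_{\log} = \sqrt{\ln(1 + CV^2)}$. Noise is Rician — the
magnitude of complex Gaussian channels with
$\sigma = S_{b0}/\mathrm{SNR}_{b0}$ (single-channel coil; no multi-coil
noncentral-$\chi$ model); SNR defaults to 40. Geometry is shared across
sessions (registration is out of scope). What the generator does *not*
emulate: restriction/exchange (time dependence enters only through the
fitted power law), EPI artifacts, partial-Fourier effects, motion, and
signal drift — so green tests demonstrate estimator correctness on the
model class the fits assume, not robustness to those real-data effects.

## Fitting

**OGSE.** Per frequency, an unweighted log-linear least-squares tensor fit
(single shell, 10 directions + b0) yields MD; FA uses the standard
eigenvalue formula with negative eigenvalues clamped to zero (FA only).
$\Lambda$ and $\mathrm{MD}_0$ come from ordinary least squares of MD
against $\sqrt{f}$ — unweighted, matching the study's plain least-squares
description. ROI analysis averages MD over the ROI first and fits the ROI
means (the study's "first non-signal parameter" convention); voxel-wise
analysis fits per voxel.

**muA.** Signals are powder-averaged per (encoding, b) shell; all b0
volumes form one shared $b = 0$ point (both encodings share interspersed
b0 volumes at a single TE). The joint fit uses parameters
$\theta = (c, D, w_S, \Delta w)$ with $\ln S_X = c - bD + b^2 w_X/6$,
$w_\mathrm{LTE} = w_S + \Delta w$, and constraints $D \ge 0$,
$w_S \ge 0$, $\Delta w \ge 0$; the ordering constraint
$w_\mathrm{LTE} \ge w_\mathrm{STE}$ enforces $\mu A^2 = \Delta w / 6 \ge 0$
(the study states non-negative least squares; the ordering is implied by
the definition of $\mu A$). Because the model is linear and the constraints
are simple bounds, the convex problem is solved *exactly* by enumerating
the $2^3$ active sets and keeping the feasible solution with the smallest
residual — no iterative solver, no convergence tolerance. $K_X = w_X/D^2$
is reported where $D > 0.1\ \mu m^2/ms$; $\mu FA$ is clamped to $[0, 1]$
(cumulant truncation can push $\mu A^2$ slightly past the stick limit
$0.4 D^2$, and the physical range is part of the metric's definition).
No Rician-floor correction or high-b exclusion is applied by default,
mirroring the study (which notes the CSF/$K_\mathrm{STE}$ noise-floor
artifact rather than correcting it); a `max_b` argument allows exclusion.

### Known systematic errors, quantified

Two effects matter when validating against analytic moments, and both are
properties of the method, not of this implementation:

* **Cumulant truncation.** With three distinct b-values and effectively
  three free parameters, the log-domain fit interpolates exactly, so K
  absorbs all higher-order cumulants. For the two-isotropic-compartment
  mixture ($D = 1, 2$, true $K = 1/3$) the closed-form fit value at the
  protocol b-values $\{0, 1, 2\}\ ms/\mu m^2$ is $K = 0.266$, a $-20\%$
  truncation bias ($bD$ reaches 3); at $b = \{0, 0.1, 0.2\}$ the bias is
  $-0.3\%$. For sticks ($K = 2.4$) even $b = \{0, 0.2, 0.4\}$ leaves
  $-6\%$ on K and $-5\%$ on $\mu A^2$, dropping to $-2.6\%$ at
  $b = \{0, 0.1, 0.2\}$. Tests therefore assert tight recovery only in
  the small-b regime and document the protocol-b bias.
* **Direction-set quadrature.** A 30-direction powder average of a
  *coherent* stick deviates from the sphere integral by $\sim 10^{-3}$ in
  $\ln S$, and the $b^2$ lever amplifies this into tens of percent on
  $\mu A^2$ at small b. Orientation-dispersed substrates do not suffer
  from this (each volume's signal already integrates over orientations),
  which is why moment-recovery tests use uniformly dispersed sticks while
  the coherent stick is exercised through the full pipeline where $\mu FA$
  saturates at 1. The coherent-vs-Watson dispersion-invariance comparison
  is likewise made at the protocol b-values ($b = 1, 2\ ms/\mu m^2$),
  where the lever is weak and the invariance of the estimator itself is
  what is measured.

## Reproducibility statistics

The pipeline order is: CSF mask (voxels with $\mathrm{MD}(0\,\mathrm{Hz})
> 0.9\ \mu m^2/ms$ excluded from all scalar maps; strictly greater, so an
exact 0.9 is retained) → metric maps → scaled-MAD outlier removal
(threshold $3 \times 1.4826 \times \mathrm{MAD}$, applied animal-wise for
ROI tables and voxel-wise for maps; a zero MAD removes all deviating
points with a warning) → Bland-Altman ($\mathrm{bias} \pm 1.96\,SD$ of
paired differences, sample SD) → CVs → sample sizes. Masking precedes
outlier removal because the CSF rule is defined on $\mathrm{MD}_0$, not on
the metric under test (the study does not state the order). In the
pipeline's ROI means no erosion is applied — the phantom's rectangular
ROIs are exact label sets with nothing to trim — while `roi_means()`
implements the study's one-voxel 6-connectivity erosion (exempting the
corpus callosum) for real, registered label maps.

CV definitions follow the study exactly: between-subject CV is
$100 \cdot SD/\mathrm{mean}$ across subjects, computed per session and
averaged; within-subject CV uses the two-point sample SD
$|test - retest|/\sqrt{2}$ per subject, averaged over subjects. The
two-point SD has expectation $\sqrt{2/\pi} \approx 0.798$ of the true
session SD, so a cohort generated with a 5% within-subject CV is
*expected* to read back $\approx 4.0\%$ — a bias inherent to the study's
estimator (its limitations section acknowledges it), reproduced rather
than corrected here.

Sample sizes use normal-approximation formulas at $\alpha = 0.05$,
power 0.80: per group
$n = \lceil 2 (z_{1-\alpha/2} + z_{1-\beta})^2 (CV/\delta)^2 \rceil$
(coefficient $15.7$, the van Belle "16" anchor at $CV = \delta$), and for
the paired design
$n = \lceil (z_{1-\alpha/2} + z_{1-\beta})^2 \sigma_d^2 /
(\delta \mu)^2 \rceil$, floored at $n = 2$. SNR maps divide the
powder-averaged magnitude of the combined averages by
$\sigma_{\mathrm{single}} / \sqrt{N_{avg} N_{dir}}$, with
$\sigma_{\mathrm{single}}$ the real/imaginary-averaged background SD of a
single average of a single direction, computed from synthetic complex
acquisitions.

## Numerical and scope notes

* Problem sizes: the shipped analysis uses the $16 \times 16 \times 4$
  phantom with 12 subjects; estimator-validation simulations use an
  $8 \times 8 \times 2$ phantom with 200 replicate cohorts and
  orientation grids of 128-4096 points, sizes at which every quadrature
  and Monte-Carlo error examined is far below the assertion tolerances.
* All randomness flows from explicit integer seeds; cohort generation,
  the pipeline, and its JSON summary are bit-reproducible for a fixed
  seed and configuration.
* Units caveat: the study prints $\Lambda$ in $\mu m^2/ms^{1/2}$, but its
  numeric range is consistent with $f$ in Hz, i.e.
  $\mu m^2\,ms^{-1}\,Hz^{-1/2}$; the latter is used throughout.
* The gradient separation (5.5 ms) is honored, but per-frequency lobe
  durations are configurable since the acquisition does not print them;
  the 0-200 Hz frequency range's length-scale interpretation (1.2-4.2
  $\mu m$) has no printed formula and is not computed.
* Out of scope (performed upstream with third-party tools in the original
  workflow): reconstruction, denoising, Gibbs-ringing and distortion
  correction, skull stripping, registration and atlas alignment. The
  voxel-wise analyses assume a common grid.
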