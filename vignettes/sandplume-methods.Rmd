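---
title: "Modeling chemodetection of buried prey: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling chemodetection of buried prey: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sandplume)
```

## The scientific problem

Some benthic fish locate prey buried in sand using chemosensitive leg-like
appendages. A buried source (a mussel, or a gel capsule of known
concentration used experimentally) releases small chemostimulant molecules
— amino acids, betaine and related osmolytes — that must diffuse up through
the sand and accumulate at the surface above the sensory detection
threshold of the legs before the fish can find it. `sandplume` implements
the physics of that process, the electrophysiological quantification used
to measure leg sensitivity, and seeded synthetic-data generators that let
every stage be tested end to end without any recorded data.

## Diffusion model

In sand, bulk water flow is suppressed, so transport is diffusive. The
scale argument is immediate: a solute of diffusivity $D$ spreads a distance
$\sqrt{Dt}$, so over a 30-minute trial a small molecule with
$D \approx 5\times10^{-10}\,\mathrm{m^2/s}$ travels about 1 mm
(`diffusion_length(5e-10, 1800)` = `r round(sqrt(5e-10*1800)*1e3, 2)` mm).
Only a thin surface layer above the source ever carries signal.

The quantitative model treats the capsule as a prolate ellipsoid (full
axes 16 mm and 6.3 mm) lying flat with its center at depth $\ell$ below
the sand/water interface ($z = 0$; $z$ grows downward into sand). Each
volume element releasing $dM$ moles at $\mathbf{r}_s$ contributes the
free-space heat kernel

$$dc = \frac{dM}{8(\pi D t)^{3/2}}\, e^{-r^2/4Dt},$$

and the two bounding treatments of the water column are:

* **free interface** — perfectly still water, no boundary condition
  (`scenario = "free_interface"`);
* **Dirichlet** — fast flow dilutes everything reaching the interface,
  $c(z{=}0) = 0$, enforced by the method of images
  (`scenario = "dirichlet"`), subtracting a mirror kernel at $-z_s$.

The real hydrodynamics lies between the two; the package computes both and
the surface-layer onset times they predict differ by well under a factor
of two across the concentration range of interest, so conclusions do not
depend on the choice.

### Source normalization

The capsule carries total moles $M = c_0 V$ with $V$ the configured
capsule volume (1 mL in the experiments). The stated axes give a geometric
volume $(\pi/6)\,a_{\mathrm{major}} a_{\mathrm{minor}}^2 \approx 0.33$ mL;
when the configured $V$ differs from the geometric volume, the uniform
source density is taken as $M/V_{\mathrm{geom}}$ so that the capsule
carries exactly $M$ moles (dimensional consistency; conservation is one of
the tested invariants). When $V$ is derived from the axes the density
reduces to $c_0$, and `capsule_concentration(..., t = 0)` returns that
initial condition directly (the kernel itself is singular at $t = 0$, so
kernel operations require $t > 0$).

### Quadrature

`capsule_concentration()` integrates the kernel over the ellipsoid by
first doing the $z$ integral analytically (an erf difference across the
capsule thickness at each horizontal source position — the kernel
factorizes into per-axis Gaussians) and then a 2-D rule over the ellipse
cross-section: Gauss–Legendre radially and a periodic trapezoid rule in
azimuth, in coordinates scaled to the unit disk. The radial order starts
at $\max(12,\ 3A/\sqrt{4Dt} + 8)$ nodes ($A$ the semi-major axis); the
azimuthal count is chosen separately so the arc spacing at the ellipse
rim resolves the kernel width ($\approx 5\pi A/\sqrt{4Dt}$ nodes). Both
refine until two successive rules agree to a relative tolerance of
$10^{-3}$ per probe, with an absolute floor at $10^{-6}$ of the largest
value in the evaluated probe set: every decision quantity in the model
(threshold crossings, mass, field comparisons) lies within four orders of
magnitude of the local maximum, and the *relative* error of a vanishing
far-field integral never settles. Non-convergence at the largest
supported order (96 radial nodes) is an error, not a silent result.

Total mass (`field_mass()`) is evaluated as a tensor-grid trapezoid of the
field over all space at spacing $\sqrt{4Dt}/3$; because every quadrature
node contributes a separable Gaussian–Gaussian–erf term, the 3-D sum
factorizes into three 1-D trapezoids per node, which is exploited for
speed without changing the result.

### Surface statistic and onset

Legs presumably sample the topmost ~0.5 mm of sand, so the observable is
the vertical *average* of concentration over $z \in [0, 0.5\,\mathrm{mm}]$
(4-node Gauss–Legendre), and its horizontal *maximum*, which sits directly
above the capsule center by symmetry — `detect_onset()` therefore tracks
the center column only. Onset is the earliest $t \in (0, t_\max]$ at which
that statistic reaches the threshold $c^*$, found by a 25-point
log-spaced scan plus bisection to 1 s (adequate against
$t_\max = 1800$ s). The default $c^* = 10\,\mu M$ is the permissive end of
the measured 10–100 µM range; both the layer depth and the threshold are
arguments.

The burial depth used in the capsule experiments is not printed anywhere;
the package default of 5 mm (capsule center, i.e. ~1.9 mm of sand above
the capsule top) represents the shallow burials at which capsules are
found reliably, and every sweep function exposes depth as a free
parameter.

## Brownian-walk oracle

`init_particles()` / `simulate_particles()` give an independent route to
the same field: equal-weight particles uniform in the ellipsoid, Gaussian
steps of per-axis variance $2D\,dt$, and — under the Dirichlet scenario —
killing of any particle that ends a step in water. Discrete-step killing
under-absorbs by $O(\sqrt{D\,dt})\approx 0.03$ mm at $dt = 1$ s,
negligible against the 0.5 mm observation layer; $dt$ is configurable.
Binned estimates (`density_estimate()`) carry binomial standard errors,
and the test suite requires quadrature/oracle agreement within 3 SE at 23
probe boxes (inside the capsule and on two rings just outside its
boundary, placed so expected counts are non-negligible at the earliest
snapshot) for both scenarios at $t = 60, 600, 1800$ s with $10^5$
particles. With ~138 such comparisons a stray 3-SE excursion is expected
occasionally; the acceptance check therefore asks for at least 20 of 23
boxes per snapshot, which is the spec'd form of the comparison.

## Nerve-response quantification

The electrophysiological pipeline mirrors standard extracellular practice:
the absolute value of the signal is low-pass filtered with a Gaussian
kernel, the mean over a pre-stimulus window is subtracted, negative
excursions are clipped at zero, and the response is integrated over the
stimulus window plus a tail.

Numerical conventions, stated because the verbal recipe underdetermines
them:

* "lowpass 25 Hz gaussian filter" is parameterized by its −3 dB point:
  $\sigma_t = \sqrt{\ln 2}/(2\pi \cdot 25\,\mathrm{Hz}) \approx 5.30$ ms,
  unit-sum kernel (unity DC gain), zero phase, reflection padding. The
  tests verify the $1/\sqrt2$ gain at 25 Hz directly.
* The response window runs from stimulus onset to offset plus a 20 s tail
  (configurable) so slow sustained responses are not truncated; blanks are
  measured over the same window length.
* The decay fraction is the mean clipped envelope over the last 5% (at
  least 2 s) of the window divided by the peak — a single end sample would
  be noise-dominated.
* The peak *location* (time to peak) is read from a 1 s moving average of
  the clipped envelope: multi-unit envelopes are shot-noise dominated
  (only a couple of spikes fall inside one 25 Hz smoothing width), so the
  raw argmax is an unstable timing estimate. Peak amplitude and area use
  the unsmoothed envelope.
* Kinetics classes: `none` if the peak fails a $3\times$ baseline-SD noise
  floor; `fast_transient` if time-to-peak ≤ 10 s *and* decay fraction
  ≤ 0.3; otherwise `slow_sustained` (a late peak or a sustained tail both
  indicate the slow class, and the ambiguous middle band of decay
  fractions resolves conservatively to slow). All cutoffs are arguments.
* Thresholds: a dose is detected when its mean area exceeds the blank
  mean + 3 blank SD; with n = 4 replicates per dose a deterministic,
  scale-free rule is preferable to a t-test. The same integration serves
  area-under-curve quantification of luminescence series unchanged.

## Synthetic-data generators

The generators define the study conditions the tests run under; they are
not tuned per test.

* **Traces** (`gen_trace()`): Gaussian baseline noise (10 µV SD) plus
  inhomogeneous-Poisson multi-unit spikes — biphasic 2 ms, 50 µV sine
  waveforms with lognormal (20%) amplitude jitter — on a 10 Hz spontaneous
  rate. Spike-based synthesis (rather than drawing envelopes directly)
  means the rectify-and-filter path is genuinely exercised. The
  stimulus-locked rate is a Hill dose gain (coefficient 4, half-activation
  at the species' threshold for the compound) times a kinetics envelope:
  fast = alpha function (1 s rise, 3 s decay), slow = sigmoid rise
  (half-rise 10 s, width 5 s) to a plateau with a 60 s post-offset decay.
  The steep Hill coefficient encodes the near all-or-none species contrast
  the dose grid is designed around. The rate scale is calibrated so the
  peak envelope elevation at full gain is `snr` baseline-envelope SDs,
  using the exact expectation $E|n+w| - E|n|$ per waveform sample
  (rectification is not additive); the stored ground-truth area
  (`meta$truth_area`) uses the same calibration and is accurate up to
  spike-overlap at high rates and clipped-noise bias at low ones, which is
  why exact-area recovery tests use deterministic envelope traces instead.
* **Dose grids**: 7 half-decade doses, 10 µM–10 mM. Seven points on this
  grid contain both species' nominal thresholds (100 µM and 10 mM)
  exactly, which a 7-point grid over 10 µM–100 mM cannot; the grid is the
  generator default and the acceptance script's input.
* **Dose-response series** (`gen_dose_response()`): 4 replicates per dose
  plus 4 blanks, per-replicate sub-seeds drawn once from the series seed;
  default trace SNR 10, representing the clearly supra-noise responses on
  which published thresholds are read.
* **Trials** (`gen_trials()`): Bernoulli success at `encounter_prob`
  (default 0.8; true per-trial encounter statistics are unreported, so
  this is a free parameter, not an estimate) when the model marks the
  condition detectable, else `false_rate` (default 0 — control capsules
  are never found). `summarize_trials()` reports exact Clopper–Pearson
  intervals via `binom.test()`.

What the generators deliberately do **not** emulate: spike-sorting
difficulty and unit identity, electrode drift, movement artifacts,
correlated multi-unit bursting, or the animal's search trajectory.
Passing tests therefore demonstrate that the quantification recovers what
the generator encodes under realistic noise — not that real recordings are
this clean.

## Problem sizes

The shipped tests run the oracle comparison at $10^5$ particles
($dt = 1$ s, snapshots at 60/600/1800 s), classification recovery over 200
seeded traces at SNR 5, threshold recovery over 10 series seeds, and
synthetic traces at 2 kHz sampling for 60 s (5 kHz is the generator
default; both are far above the 50 Hz needed by the 25 Hz envelope).
These sizes give comfortably stable statistics for every assertion while
keeping a full run in the minutes range on one core.

## Known limitations

* No sand tortuosity, porosity or adsorption corrections: free-water
  diffusivity throughout, matching the modeling assumption being tested.
* Biological sources (mussels) have unknown emission rates; only the
  fixed-inventory capsule is modeled.
* The two boundary scenarios bracket, but do not resolve, the actual
  hydrodynamics above the sand.
* The ellipsoid axes are read as full axis lengths; if they were
  semi-axes the geometric volume would change eightfold, but the
  configured $V$ — not the geometry — carries the released mass, so
  surface predictions shift only through the source's spatial extent.
* `estimate_threshold()` is grid-quantized by design: it reports the
  lowest *tested* dose that clears the blank criterion, exactly as a
  stepwise assay protocol does, not an interpolated EC.
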