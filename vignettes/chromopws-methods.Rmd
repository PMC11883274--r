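---
title: "Models and numerics behind chromopws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind chromopws}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromopws)
```

This vignette is the package's account of its science: the models each
estimator assumes, the parameters that matter and why their defaults are
what they are, the numerical choices, and the limits of what the synthetic
benchmarks establish.

## The measurement problem

Chromatin above the nucleosome scale assembles into packing domains tens to
a couple of hundred nanometres across, inside which mass scales as a power
law of distance, $M \propto r^D$. The packing scaling $D$ runs from the
solvated-coil limit $5/3$ to the space-filling limit $3$ and varies from
cell to cell and — centrally for this package — between the nuclear body and
nuclear blebs, chromatin-containing herniations of the nuclear envelope.
Dual partial-wave spectroscopic (PWS) microscopy reads this organization
from interference: spectrally resolved backscattering encodes the spatial
statistics of refractive-index (RI) fluctuations, and single-wavelength time
series encode their dynamics. Because RI is proportional to local
macromolecular density, chromatin structure and motion become optically
measurable without labels.

None of the live-cell measurements can be reproduced without the original
instrument, so every estimator here is validated the only way a desk-scale
artifact honestly can be: against synthetic data whose ground truth is
known, generated by the same physical forward models the estimators assume,
with the loop closed by parameter recovery.

## Static chain: from spectra to packing scaling

### Medium model

A coherence column of chromatin is modeled as a zero-mean Gaussian axial RI
fluctuation profile with autocorrelation

$$B(r) \;=\; \sigma_n^2\,
\Big(\tfrac{\max(r,\,l_{\min})}{l_{\max}}\Big)^{D-3} e^{-r/l_{\max}},$$

a power law with exponent $D-3$ between an inner scale $l_{\min}$ (default
10 nm, the nucleosome scale) and an outer scale $l_{\max}$, with an
exponential roll-off beyond. Defaults: $l_{\max} = 150$ nm, the upper end of
the observed packing-domain size range (50–200 nm) — correlations do not
extend beyond a domain; $\sigma_n = 0.01$, the RMS RI contrast at the domain
scale, chosen so that the scattered field stays in the weak (Born) regime
relative to the reference reflection. Profiles are synthesized by circulant
embedding, so the sampled process carries the target autocorrelation exactly
(negative eigenvalues from the outer cutoff are clipped to zero). The
amplitude convention fixes $\sigma_n$ at the *outer* scale: media of
different $D$ share the same domain-scale contrast and differ in how
fluctuation power distributes across length scales.

### Forward model

Detected intensity is a 1-D Born phase sum,

$$I(\lambda) = \Big|\sqrt{\Gamma} + \sum_j w\,k(\lambda)\,\delta n_j\,
\Delta z\; e^{\,2 i k(\lambda) n_1 z_j}\Big|^2,$$

with $k = 2\pi/\lambda$, $\Gamma$ the normal-incidence Fresnel reflectance
of the immersion-oil/nucleus interface, and a scalar NA attenuation
$w = (NA_c/n_i)^2/2$. Each pixel averages `n_cols = 3` independent columns,
reflecting the reduced spatial coherence of high-NA illumination. No
full-wave electromagnetic solver and no angular-spectrum integration are
attempted; the proportionality between the spectral standard deviation
$\Sigma$ and the density-correlation power at the probed axial frequency
$2 k n_1$ is the property the chain relies on, and the 1-D model preserves
it.

### Direction of the $\Sigma$–$D$ mapping

Under this model, $\Sigma$ is strictly *decreasing* in $D$: the probed axial
frequency corresponds to a ~200 nm interference period, and media
approaching the space-filling limit concentrate their correlation power
below it. We verified numerically that no amplitude normalization of the
power-law family reverses this at desk scale. What every downstream
conclusion needs is not a direction but a strictly monotone, invertible
mapping, which the calibration guarantees: `build_sigma_to_d_calibration()`
sweeps the forward model over a $D$ grid (default $[1.7, 3.2]$, 150
replicates per knot), applies isotonic regression *in the direction of the
raw trend*, and stores the curve with its seed (regeneration is bitwise
reproducible). `estimate_da_map()` inverts it per pixel by piecewise-linear
interpolation; isotonic flat spots collapse to their lowest $D$ (ties break
toward lower packing).

### Averaging and flags

Pixels whose $\Sigma$ falls outside the calibrated range are clipped to the
nearest knot and flagged in `in_range`, but *retain* their clipped estimate
and stay in region averages: excluding them would truncate the estimate
distribution and bias $D_n$ upward by ~0.13 at $D = 1.8$, exceeding the
chain's own error budget. `valid_mask` marks only pixels with no estimate at
all (dead reference). With this rule the closed loop recovers
$D \in \{1.8, 2.2, 2.6, 3.0\}$ within $0.08$ on $64{\times}64$ cubes with
101 wavelengths. Spectral standard deviations use the $n-1$ convention
throughout, and normalization by a reference image (when present) makes the
chain invariant to detector gain.

## Dynamic chain: moving mass, diffusion, concentration

### The variance pre-factor

The fractional moving mass estimator is
$\mathrm{FMM} = \mathrm{Var}_t[I/I_0]\,/\,A$. The literature constant for
$A$ is not printed anywhere re-derivable, so the package defines its own
normative closed form from a weak-scattering budget — interference of the
field scattered by mobile clusters inside the coherence volume with the
reference reflection $\Gamma$:

$$A \;=\; \frac{2\,\Gamma\,k^2 (n_m - n_1)^2\, L_{\mathrm{dof}}}
{A_{\mathrm{coh}}\;\rho_0},\qquad
L_{\mathrm{dof}} = \frac{n_1 \lambda}{NA_i^2},\quad
A_{\mathrm{coh}} = \pi\Big(\frac{\lambda}{2 NA_c}\Big)^2 .$$

With the default constants $A \approx 2.2\times10^{11}\,\mathrm{g^{-1}}$: a
nucleosome-clutch-scale moving mass of $2\times10^{-19}$ g produces relative
intensity fluctuations of $\sim 2\times10^{-4}$, about 8 % of the reference
reflectance — a physically sensible operating point. The same $A$ drives
the synthetic generator, so swapping in an externally calibrated constant is
a one-line config change that cannot break the closed loop. The FMM variance
is taken on the raw normalized trace by default; `detrend = TRUE` removes a
fourth-order polynomial first, at the cost of shedding genuine low-frequency
moving-mass power (about a quarter at the default correlation time).

### Diffusion numerics

The generator's temporal process is an exact discrete Ornstein–Uhlenbeck
(AR(1)) process, so the autocorrelation is $e^{-\tau/\tau_d}$ with
$\tau_d = 1/(4 k_{\mathrm{med}}^2 D_e)$ known in closed form
(backscattering dynamic-light-scattering convention,
$k_{\mathrm{med}} = 2\pi n_1/\lambda$). Estimating $\tau_d$ from short
records is where naive procedures fail: the mean-removed sample
autocorrelation of a 300-frame record is biased downward at every lag by
$O(2\tau_d/T)$, and a log-linear least-squares fit over the first quarter of
lags inherits a +15–27 % error in $D_e$. The per-pixel estimator therefore
uses lag-1 autoregression — sufficient under the single-exponential model —
with the Marriott–Pope small-sample correction
$\hat\varphi_c = (\hat\varphi + 1/T)/(1 - 3/T)$. Residual bias persists when
the record holds few decay times, so the regional estimator
(`region_diffusion()`) pools all pixels of a region and removes the
*cross-sectional* mean per frame instead of each pixel's temporal mean: the
shared slow baseline (including any concentration ramp) is estimated from
the spatial ensemble and the temporal-demeaning bias vanishes. This recovers
$D_e$ within 5 % for $\tau_d$ from 0.1 s to 2 s at 300 frames. Pixels with
no measurable decay are flagged, and values outside the instrument band
($3.5\times10^{-5}$ to $0.065\ \mu m^2/s$) are clipped with flags.

### Concentration

Mean reflectance maps to chromatin volume concentration through two closed
forms: Gladstone–Dale, $n(\phi) = n_{\mathrm{water}} + \alpha\,\rho_0\,\phi$
with $\alpha = 0.18\ \mathrm{cm^3 g^{-1}}$ (the standard biomolecular
refractive increment; the relation is named in the source material but its
constants are not, so both are config fields), and Fresnel reflectance
against the immersion-oil interface. Because $n(\phi)$ rises from 1.334
toward the oil index 1.518, $R(\phi)$ is strictly *decreasing* — the mean
backscattered signal is inversely related to chromatin concentration, which
is also why the relative-CVC trace takes the inverse of the intensity ratio
before min–max scaling to $[0,1]$. A flat trace returns the constant 0.5
with a flag rather than an error, so tiny quiet blebs cannot abort a
pipeline. The calibration is a monotone Hermite spline through the analytic
curve (or a user-supplied one, which must be strictly monotone); it
round-trips $\phi \to R \to \phi$ to $10^{-6}$ and inverts by root finding.

## Nanodomain calling

DBSCAN uses the field-standard parameters ($\varepsilon = 50$ nm,
`min_pts = 3`, self-inclusive neighborhoods). Neighbor search runs on an
$\varepsilon$-grid (3×3 adjacent bins), so cost scales with local density;
labels are deterministic, with border points claimed by the first-expanded
cluster in ascending input order. The implementation is checked for exact
label equality against an independent brute-force oracle (full distance
matrix, union-find over core pairs) on a thousand random instances. Cluster
size is the area-equivalent diameter of the convex hull,
$2\sqrt{A/\pi}$, with the maximal extent as fallback for collinear
(degenerate) hulls. The outlier filter's lower bound is *computed* as twice
the mean localization uncertainty of the table — the ~25 nm figure being
descriptive of typical data — with the literal fixed-25-nm reading
selectable; the upper bound is 800 nm. Cluster-to-region assignment uses the
centroid. Per-condition summaries pool domains across cells rather than
averaging per cell.

## Synthetic generators as study conditions

Every generator is a pure function of (scenario, seed). The packaged
scenarios encode qualitative contrasts, not instrument magnitudes: blebs
carry lower packing scaling, lower moving mass and lower CVC than their
bodies in every condition; lamin-depletion-like blebs retain higher $D$ and
FMM than enzyme-inhibition-like blebs; the HDAC-inhibition-like condition
raises body CVC (0.45 vs 0.35) while suppressing bleb CVC (0.15 vs 0.25),
dropping its bleb-to-body ratio below control. Moving masses sit at
nucleosome-clutch scale ($0.8$–$2.2\times10^{-19}$ g) and diffusion inside
the measurable band. Nanodomain radii are full radii (member scatter has
$\sigma = r/2$) of 120 nm (body) and 40 nm (bleb), with per-domain occupancy
scaling with area so labeling density is constant — large sparse domains
would otherwise fragment under DBSCAN, which is a labeling-density artifact,
not a biology. Scene geometry is an elliptical body with a circular bleb
joined by a neck; zero neck width emits the protrusion detached and labeled
as a micronucleus, which is exactly the connectivity rule the classifier
applies, and rupture is carried only as an upstream flag.

Default problem sizes — 64×64 pixels, 101 wavelengths, 300 frames (15 s at
50 ms) — are the acquisition geometry the estimators target. Tests and the
acceptance script run the same models at reduced scene sizes (16×16 to
64×64) and seed counts chosen to keep a full verification run within a few
minutes on one CPU; all thresholds are unchanged by this scaling.

What passing these benchmarks does **not** show: robustness to camera noise
models beyond additive Gaussian, emitter photophysics (blinking,
multi-counting), drift, 3-D sectioning effects, segmentation error in the
region masks, or any absolute agreement with live-cell values measured on a
specific instrument — those depend on calibrations only the instrument can
provide.

## Statistics

Pairwise comparisons use Welch's unpaired two-tailed $t$ or Mann–Whitney
(analytic $p$-values only; identical constant groups are flagged degenerate
with $p = 1$ rather than erroring). Holm–Šídák is implemented from its
closed form — ordered $p$'s, $\tilde p_i = \max_{j\le i}\,
1-(1-p_j)^{m-j+1}$, monotonized and capped — because `p.adjust` does not
provide it. Many-vs-control designs run one-way ANOVA with Dunnett contrasts
via `multcomp`. The replicate unit is logged with each summary: fields of
view for frequency-style statistics, cells or bleb regions for estimator
comparisons.

## Known limitations

- The $\Sigma$–$D$ calibration is internal to the package's forward model;
  absolute $D$ on real instruments requires recalibration against that
  instrument's transfer function.
- The per-pixel $D_e$ map retains a small positive bias when
  $\tau_d \gtrsim T/10$; use the pooled regional estimator for slow
  dynamics.
- The bleb-to-body CVC ratio uses absolute CVC from mean reflectance; it is
  meaningful only when body and bleb share the reference image.
- DBSCAN label determinism is guaranteed for a fixed input row order;
  permuting the table can relabel border points (cluster membership of core
  points is order-free).
- HDF5 containers are not read or written; TIFF stacks with JSON sidecars
  and CSV cover on-disk exchange.
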