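---
title: "Models and methods behind trackStates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trackStates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackStates)
```

## The problem

Membrane receptors such as the B cell antigen receptor diffuse laterally in
the plasma membrane, and their mobility reflects their biochemical state:
receptors engaged in signaling clusters move slowly, free receptors move
fast, and the cortical actin cytoskeleton modulates both. Single-molecule
TIRF imaging at high frame rates (bursts of 1000 frames at 33 Hz, repeated
every minute) produces thousands of short, noisy trajectories per cell.
`trackStates` implements the analysis chain for such data: localization and
linking, unbiased diffusivity estimation on short tracks, unsupervised
classification of trajectory segments into discrete diffusive states,
spatial statistics of the state-sorted molecules, and image-correlation
velocimetry of the underlying cortical flow. A synthetic-data module
generates all of these inputs with known ground truth, so every stage is
testable without raw movies.

## Displacement statistics under noise and blur

Measured positions differ from true positions in two ways: additive
localization noise with standard deviation $\sigma$ (20–80 nm at
single-molecule photon budgets), and motion blur, because the camera
integrates the moving molecule over the exposure. For uniform exposure over
a fraction of the frame interval $\Delta t$, blur is summarized by the
coefficient $R$, equal to $1/6$ for full-frame exposure. For pure Brownian
motion with diffusivity $D$, one axis of the displacement sequence
$d_n$ is zero-mean Gaussian with

$$\mathrm{E}[d_n^2] = 2D\Delta t - 4RD\Delta t + 2\sigma^2, \qquad
  \mathrm{E}[d_n d_{n+1}] = 2RD\Delta t - \sigma^2,$$

and all longer-range correlations vanish. Two consequences drive the whole
package:

* the ensemble MSD is $4Dn\Delta t + 4\sigma^2 - 8RD\Delta t$, so a naive
  MSD slope-plus-intercept fit confounds $D$ and $\sigma^2$ on short
  tracks;
* the covariance-based estimator (CVE)
  $$\hat D = \frac{\overline{d_n^2}}{2\Delta t} +
             \frac{\overline{d_n d_{n+1}}}{\Delta t}, \qquad
    \hat\sigma^2 = R\,\overline{d_n^2} + (2R-1)\,\overline{d_n d_{n+1}}$$
  is exactly unbiased under noise and blur and needs no regression, which
  is why `cveDiffusivity()` uses it as the primary per-segment estimator.
  Unbiasedness requires keeping negative $\hat D$ values; they are never
  clipped, and distributions and CDFs include them.

## The segment mixture model and pEM

Trajectories are cut into consecutive, non-overlapping 15-frame segments
(`segmentTracks()`); 15 frames at 33 Hz balances diffusivity resolution
against the chance of a state switch inside a segment. Tracks shorter than
15 frames carry too little information and are discarded; tracks longer
than 105 frames are discarded too, because slow molecules are less likely
to be interrupted by path crossings and would otherwise be over-counted.

Each segment contributes 14 displacements per axis. Under state $k$ the
displacement vector is zero-mean multivariate normal with the symmetric
tridiagonal-Toeplitz covariance built from $(D_k, \sigma_k^2)$ above. The
eigenvectors of any such matrix form the discrete sine basis, independent
of the parameter values, with eigenvalues
$\lambda_j = a + 2b\cos\!\big(\tfrac{j\pi}{15}\big)$. `trackStates`
sine-transforms every segment once; after that, any state's log-likelihood
is a 14-term sum, which makes the EM inner loop a single matrix product.

`emFit()` runs expectation-maximization on the $K$-state mixture. The
M-step starts from the inversion of the $\gamma$-weighted moment estimates
of $(a, b)$, projects to the feasible cone ($D \ge 0$, $\sigma^2 \ge 0$,
positive-definite covariance) and polishes with a bounded quasi-Newton
step, accepting a candidate only if it improves the expected complete-data
log-likelihood — so the total log-likelihood is non-decreasing at every
iteration by construction, and the test suite asserts this on every seeded
run. States whose weight falls below $1/N$ are dropped and $K$ reduced.
The x and y axes are treated as independent and identically distributed
(isotropic diffusion, a scalar $D$); their log-likelihoods are summed.

The mixture likelihood is multimodal, so `pemSearch()` wraps `emFit()` in
the perturbation scheme: for each $K$ up to `Kmax` (default 15), EM runs
from `nReinit` (default 20) random starts; the best fit is then perturbed
`nPerturb` times (default 150) — log-normal jitter with scale 0.5 on
$D_k$ and $\sigma_k^2$, Dirichlet jitter with concentration 10 on the
weights — and each perturbation is polished by EM, keeping the best
log-likelihood. These jitter scales are the package's own construction;
only the counts of reinitializations and perturbations are standard. The
number of states is chosen by the Bayesian information criterion
$\mathrm{BIC} = -2\log L + p\ln N$ with $p = 3K - 1$ free parameters
($K$ diffusivities, $K$ noise variances, $K-1$ independent weights),
minimized, ties resolved towards smaller $K$; this convention is the
package's choice, as is registering a run that collapses to fewer states
under its effective $K$. Random initializations draw $\log D$ uniformly
over the range spanned by the per-segment CVE estimates.

Hard labels are maximum-posterior states; states are always reported
sorted by increasing $D$ and renumbered, so state 1 is the slowest.
Population fractions per time point carry Wilson score intervals (the
Wald interval misbehaves at fractions near 0 or 1, which occur routinely
for the fastest state at late time points). State transitions are counted
between consecutive segments within parent tracks longer than 30 frames;
a track of 31–44 frames yields two segments and hence one transition.

## Spatial statistics

For pair-correlation analysis each distinct particle contributes one point
— its first localization — so long tracks do not dominate the pattern; a
multi-segment particle takes the majority label over its segments (ties
towards the slower state — slow states are the clustered, biologically
salient ones, and a deterministic tie-break keeps runs reproducible).
States adjacent in diffusivity are pooled pairwise ({1,2}, {3,4}, ...) for
statistical power; an odd final state stays alone.

`pairCorrelation()` estimates $g(r)$ as the ratio of the observed
pair-count histogram to the histogram of a uniform Monte-Carlo sample in
the same mask (at least 20 times as many reference points), each
normalized by its own pair count. Measuring the reference with the same
estimator inside the same mask cancels edge effects for arbitrary mask
geometry, which an analytic isotropic correction would only do for simple
shapes. Bins with no reference pairs are flagged invalid. Default bins
are 50 nm wide out to 5 um. The pair-distance histogram itself is a small
grid-bucketed C++ kernel; tests verify it against brute-force
$O(N^2)$ counting exactly.

## STICS velocimetry and directional coherence

Cortical flow is measured from cytoskeleton movies by spatio-temporal
image correlation: the stack is tiled into 8 × 8 pixel subregions shifted
by 2 pixels, time into 5-frame windows shifted by 3 frames, and each
(subregion, window) yields one velocity vector. Before correlation, the
static image component is removed by subtracting each pixel's 20-frame
moving average (`immobileFilter()`; Fourier DC removal is available as an
option).

Within a window, the spatial cross-correlation of frame pairs $\tau$
frames apart is averaged for $\tau = 0, \dots,$ `maxLag` (default: window
length − 1). Three numerical choices matter here and were fixed after
ground-truth experiments with the flow generator:

* windows are zero-padded to twice the subregion before the FFT and the
  correlation is overlap-normalized — cyclic correlation of so small a
  window biases peak displacements towards zero by a large factor;
* the discrete peak is *tracked* across lags: for $\tau \ge 2$ the search
  window is centered on the displacement extrapolated from the previous
  lag (radius 2 px), which suppresses the spurious secondary maxima that
  otherwise dominate the sparse large-lag correlations;
* sub-pixel refinement uses Gaussian apex interpolation through the peak
  and its two axis neighbors (the exact least-squares Gaussian through
  3 points per axis); a least-squares Gaussian surface fit on the 5 × 5
  neighborhood is the fallback when a neighbor is non-positive. On
  uniform-flow ground truth the 3-point form clearly outperformed the
  5 × 5 surface fit (93% vs 70% of vectors within 10% of the true speed).

The velocity is the least-squares slope of peak displacement versus lag
time. A vector is discarded (`valid = FALSE`) when any peak displacement
exceeds half the subregion, the peak fit fails, or the lag-1 peak
amplitude is below twice the median-absolute-deviation floor of its
correlation plane — the package's reading of an otherwise unspecified
"subregion threshold" rule, exposed as parameters.

Directional coherence is the cosine of the angle between a flow vector
and the direction from its position to the cell centroid: +1 inward, −1
outward. Inward/outward fractions use the 0.9 cutoff, and two conditions
are compared with a pooled two-proportion z-test (two-sided). Near the
centroid the inward direction is undefined; analyses of radial test
fields exclude nothing by default, but vectors of zero length are always
excluded.

## The synthetic-data module

`simulateTracks()` emulates the acquisition: Markov switching between $K$
diffusive states (optionally only every `transitionEvery`-th frame, which
reproduces segment-level switching exactly), Brownian displacements at 10
sub-frame steps over the exposure window whose average is the reported
position (converging to the continuous-exposure covariance, $R \to 1/6$),
per-state Gaussian localization noise, geometric track lengths of mean 40
frames, bursts of 1000 frames at 33 Hz, and a reflecting disk or
rectangle mask standing in for the cell contour. Designated "cluster
states" spawn their particles inside small disks (default 0.2 um radius)
and confine them there, producing the short-range $g(r) > 1$ signature of
receptor clusters. `renderSpotMovie()` turns tracks into TIFF movies of
integrated-Gaussian spots with Poisson plus read noise;
`simulateFlowStack()` advects a static speckle texture (correlation
length 0.06 um, the Gaussian sigma of a ~145 nm FWHM PSF) along uniform,
radial, or zero velocity fields with periodic sub-pixel interpolation.

What the generator does *not* emulate — and therefore what passing tests
do not certify on real data: photophysics (blinking, bleaching is only
implicit in the geometric track-length law), anomalous or confined
diffusion other than hard reflection, 3-D motion, spatially varying
background, and non-Markovian state dynamics. The generator defines the
conditions under which the estimators are validated, not a claim about
any particular cell.

## Numerical choices and degenerate inputs

* EM stops when the log-likelihood gain falls below `tol` (default
  `1e-6` in `emFit()`, `1e-4` in `pemSearch()`, where BIC differences of
  interest are orders of magnitude larger); `maxIter` defaults to 300.
* Parameter floors $D \ge 10^{-9}$, $\sigma^2 \ge 10^{-12}$ keep the
  covariance positive-definite; a state proposed outside the feasible
  cone is projected back.
* `cveDiffusivity()` refuses segments with fewer than 3 positions; a
  degenerate all-ties Kruskal–Wallis draw reports p = 1 with a warning;
  a zero pooled variance in the two-proportion test reports p = 1 with a
  `degenerate` flag.
* Linking is greedy mutual-nearest-neighbor with no gap closing; *any*
  ambiguity within `maxDisp` terminates all tracks involved (the
  crossing-interruption rule). The ambiguity radius equals `maxDisp`
  because no separate radius is specified anywhere; the recommended
  `maxDisp` is $3\sqrt{4D_{\max}\Delta t}$.
* Detections closer than twice the PSF sigma are merged (brightest
  kept): noise can split one molecule into two maxima, and a spurious
  twin would otherwise trigger the crossing rule and shred tracks.
* All stochastic functions take explicit seeds and restore the caller's
  RNG state; `runPipeline()` writes byte-identical bundles for identical
  configs and seeds.

## Problem sizes used in the validation suite

The test suite and the acceptance script validate on: $10^4$ simulated
segments for CVE unbiasedness (3% on $D$, 10% on $\sigma^2$); three
log-spaced states (0.003/0.03/0.3 um²/s, 1000 segments each, noise
20/40/80 nm) for state-number recovery over 10 seeded runs with a reduced
search (3 reinitializations, 6 perturbations, $K \le 5$) — recovery at
this separation is insensitive to the full-size search, which exists to
polish marginal, closely spaced states; $10^4$ CSR points for $g(r)$
calibration; 1500 45-frame tracks for transition recovery; and
48 × 48 × 16 (uniform) and 64 × 64 × 16 (radial) flow stacks for STICS.

## Known limitations

* The mixture model assumes normal diffusion within a segment; a state
  switch inside a segment is absorbed into intermediate parameter
  estimates rather than detected.
* CVE variance grows quickly for $D\Delta t \ll \sigma^2$; per-segment
  estimates of the slowest states are individually uninformative and only
  meaningful in ensembles — which is exactly why the mixture model, not
  the per-segment histogram, is the primary classification tool.
* STICS assumes locally uniform flow within a subregion and window;
  strongly divergent flow (e.g. at the centroid of a radial field) gives
  low-quality vectors that the amplitude and displacement checks only
  partially remove.
* Masks are disks or rectangles; arbitrary polygon contours would need a
  polygon point-in-region test and reflection rule, which the pair
  correlation's Monte-Carlo normalization would accept unchanged.
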