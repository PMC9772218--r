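---
title: "Models and methods behind simscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind simscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

simscope simulates and reconstructs two-dimensional structured illumination
microscopy (SIM) data for an interferometric pattern generator, in which the
fringe period is proportional to the excitation wavelength.  This vignette
explains the physical model, the estimators, the design decisions that were
genuinely open, and what the simulation-based tests do and do not establish
about real microscope data.

## Image formation model

The detection path is a scalar, two-dimensional diffraction model: a uniform
circular pupil of radius $\mathrm{NA}/\lambda_{em}$, optionally carrying a
primary-spherical phase term $2\pi\,A\,\sqrt5\,(6\rho^4-6\rho^2+1)$ with $A$
the aberration amplitude in waves RMS.  The PSF is the squared modulus of
the pupil's Fourier transform; the OTF is its autocorrelation, normalized to
one at DC and identically zero beyond the incoherent cutoff
$k_c = 2\mathrm{NA}/\lambda_{em}$.  Because primary spherical aberration is
rotationally symmetric, the OTF is radial; `otf_radial()` evaluates the
pupil-overlap integral by Gauss–Legendre quadrature (801 radii, cached), and
`make_psf()` independently computes the PSF by FFT of the pupil on a
two-fold padded grid.  The two routes agree with the closed-form
unaberrated OTF to better than $10^{-4}$ and serve as mutual checks in the
test suite.  The model is deliberately scalar and two-dimensional: no
vectorial high-NA corrections, no defocus, no depth-dependent aberration.
These are adequate for the frequency bookkeeping that 2D-SIM reconstruction
rests on, and are a documented limitation for quantitative comparison with
real high-NA data.

The excitation pattern is a sinusoid
$1 + m\cos(2\pi\,\mathbf k_0\!\cdot\!\mathbf r + \phi)$ applied analytically
on a fine grid with half the camera pixel pitch.  The pattern frequency is a
fixed fraction of each channel's excitation passband
$2\mathrm{NA}/\lambda_{ex}$ — this is the defining property of the
interferometric generator, whose fringe period scales with wavelength, so
one mirror geometry is "optimal" for every color simultaneously.  The
modulation depth $m$ collects coherence and polarization losses into one
scalar; microscopic modelling of the interferometer arms is out of scope.

A simulated frame is: fine-grid product of specimen density and pattern,
multiplication by the radial OTF in the Fourier domain, $2\times2$ area
binning to the camera grid, scaling so the brightest widefield pixel expects
`peak_signal` photons, background addition, then Poisson counts, Gaussian
read noise, and clipping at zero — in that order.  Applying the blur by
spectral multiplication implies periodic boundary conditions; fringes that
do not complete an integer number of cycles across the field therefore have
a wrap seam, exactly as a real field of view has edges.  Reconstruction
offers a Tukey border fade (`fade_border`) for this reason, and the exact
algebraic identities in the tests use grid-commensurate fringes so that the
identity is not confounded by seams.

### Phase stepping and the multicolor phase law

Phase stepping is a lateral fringe displacement: $\delta\phi = 2\pi\,\Delta
x / p(\lambda_{ex})$ with $p = \lambda_{ex}/(f\cdot 2\mathrm{NA})$ the
fringe period at pattern fraction $f$.  In sequential acquisition the
displacement is retuned per color, so every channel sees even steps of
$2\pi/3$.  In simultaneous acquisition one displacement sequence, sized for
a reference wavelength, serves all colors at once; channel $c$ then
receives steps $(2\pi/3)\,\lambda_{ref}/\lambda_c$ — e.g. 2.408 rad at
488 nm when 561 nm is stepped evenly.  This unequal stepping is what breaks
classical reconstructions that assume even steps, and is the reason the
band-separation stage below is formulated for arbitrary phases.

## Synthetic specimens

`generate_sample()` provides three structure classes on the fine grid:
anti-aliased hard disks at random positions with a minimum separation
(calibration beads); smoothed random-walk curvilinear networks
(tubulin/ER-like filaments); and band-limited positive random fields
(texture).  All are deterministic given a seed, normalized to peak one, and
intended as fluorophore density in "expected photons per fine pixel at unit
exposure".  They emulate the spatial-frequency content of typical SIM
specimens, not their photophysics: no bleaching, no blinking, no
out-of-focus background from 3D structure.  Consequently the simulation
study shows that the algorithms are correct and well-calibrated under the
stated model; it cannot certify performance on aberrated, background-rich
real data.

## Classical reconstruction with arbitrary phase steps

Each frame of one orientation mixes three Fourier components of the
specimen — the widefield band $B_0 = \tilde S(\mathbf k)H(\mathbf k)$ and
the shifted bands $B_\pm = \tilde S(\mathbf k \mp \mathbf k_0)H(\mathbf k)$:
$$D_n = B_0 + \tfrac{m}{2}e^{i\phi_n}B_+ + \tfrac{m}{2}e^{-i\phi_n}B_-.$$
`separate_bands()` inverts this $3\times3$ system per Fourier pixel.  The
inversion requires only pairwise-distinct phases, not even steps, and is
exact in the noiseless case for any distinct triple — the property that
makes simultaneous multicolor stacks reconstructable.  A condition-number
threshold turns nearly coincident phases into an explicit error naming the
offending pair.

### Parameter estimation

*Wavevector.*  The bands are provisionally separated under an even-step
assumption, OTF-weighted and high-passed (both bands are dominated by their
own near-DC content, which otherwise swamps the correlation), and
cross-correlated.  The correlation magnitude at each candidate lag is
normalized by the OTF-overlap weight at that lag — without this, lags with
larger band overlap always win regardless of the data.  The discrete peak
is accepted only if its robust z-score against the score distribution over
the search annulus exceeds 8 (an `m = 0` stack fails with "pattern not
found"), then refined to sub-pixel precision by direct optimization of the
overlap-normalized correlation at continuous frequency.

*Phases.*  With a Stokes-shifted emission channel and the pattern near the
excitation passband, the pattern frequency lies at or beyond the detection
cutoff: the fringe itself is barely transmitted, and the spectrum value at
$\mathbf k_0$ carries no usable phase.  simscope therefore reads phases
from the spectral cross-correlations of the OTF-weighted frames at lag
$\mathbf k_0$, $C_{nm} = \langle F_n(\mathbf k),\,F_m(\mathbf k +
\mathbf k_0)\rangle$, which accumulate the band overlap.  Each $C_{nm}$
equals $\alpha a_m + \beta a_n + B$ with $a_n = (m/2)e^{i\phi_n}$ and
sample-dependent speckle terms $\alpha,\beta,B$; differencing over the
second index cancels $B$ and $\beta a_n$ exactly, leaving the chord vectors
$a_2-a_1$ and $a_3-a_1$ up to one positive scale.  The three phasors are
recovered as points on a circle about the origin consistent with those
chords — a linear circumcenter solve.  Residual bias scales with the
inverse spectral richness of the specimen: negligible for filaments and
textures, a tenth of a radian for very sparse bead fields on small grids.
A final global band-phase correction, taken from the complex argument of
the band-overlap regression used for $m$, aligns the shifted bands to the
widefield band.

*Modulation depth.*  $\hat m$ is the magnitude of a weighted least-squares
regression of the separated $+1$ band against the $\mathbf k_0$-shifted
widefield band over their overlap, with OTF-ratio weighting.

### Wiener combination

The $\pm1$ bands are moved to $\pm\mathbf k_0$ on a doubled grid by exact
sub-pixel Fourier shifting (real-space phase ramps), and all bands are
merged as
$$\hat S = \frac{\sum_b H_b^{*} D_b}{\sum_b |H_b|^2 + w^2},$$
where a shifted band's transfer function is $m\,H(|\mathbf k \mp \mathbf
k_0|)$.  The regularization is either a scalar $w$ or, by default
(`wiener_parameter = "auto"`), the radial noise-to-signal power ratio
measured from the data itself: the white-noise floor from the spectral
power beyond the cutoff and the ring-averaged signal PSD above it,
log-linearly extrapolated beyond the band.  That is the textbook Wiener
filter with estimated spectral densities, standing in for the "factor
chosen empirically per image" of common practice.

The combined spectrum is then apodized.  The default shapes the output MTF
like the autocorrelation OTF of an ideal aperture with the enlarged cutoff
$k_c + |\mathbf k_0|$ — the same choice as the widely used open-source SIM
reconstruction software.  This gives the reconstruction a diffraction-like
PSF at the doubled resolution, which is exactly the "expected for the
pattern frequency" behaviour: a 100 nm bead at NA 1.2, 488/515 nm, pattern
at 0.95 of the excitation passband, reads a mean 2D-Gaussian FWHM of about
122 nm.  A cosine-bell apodizer and no apodizer are available; the
unapodized Wiener-flattened passband yields visibly sharper but
ring-prone images (beads near 95 nm) and is not the default.  Optional
Gaussian notches at DC (zero-order suppression) and at $\pm\mathbf k_0$
(stripe suppression) are off by default, matching the processing that the
inverse-matrix route is usually run with.

For the widefield reference, `wiener_deconvolve()` defaults to the scalar
factor $w = 0.2$, which caps the peak spectral amplification at
$1/(2w) = 2.5$.  This conservative restoration is the package's reading of
gentle "deconvolved widefield" processing; the measured-NSR mode is
available but restores far more aggressively on high-signal data (beads
near 140 nm rather than about 186 nm).

## Evaluation metrics

*FWHM.*  Per-emitter 2D Gaussian fits (Levenberg–Marquardt; amplitude,
centre, two sigmas, offset) in a window of about seven expected FWHMs —
wide enough for a stable offset estimate.  Candidates with overlapping
windows, border contact, non-convergent fits, or relative RMS residual
above 0.25 are excluded and counted.  The report gives the mean of the
per-emitter geometric-mean FWHM.

*FRC.*  Ring-wise normalized cross-correlation of two independent-noise
images of one scene, one frequency pixel per ring, fixed 1/7 threshold,
linear interpolation at the first downward crossing.  Pairs are generated
by simulating two full acquisitions of the same specimen with independent
noise (half-frame splitting is not used; with nine frames per image the
two-acquisition protocol is cleaner to define).  A Tukey taper suppresses
spectral leakage from non-periodic borders; tests that construct periodic
scenes disable it.

*Stripe energy.*  Incorrect phase assumptions mix the bands and imprint
the pattern: striping at $\pm\mathbf k_0$, honeycombing at
$\pm2\mathbf k_0$.  The default statistic is a local peak-to-background
ratio: spectral power in a small disk at each artifact frequency over the
power in the surrounding equal-radius annulus, averaged over masks; a value
near 1 means no artifact.  A fraction-of-total-power variant is provided,
but the total is dominated by the specimen's own spectrum and by noise, so
it barely responds to exactly the artifact the statistic is meant to flag —
with the pattern at 0.95 of the passband, the detection OTF transmits the
artifact frequencies at the percent level, and the total-power fraction
changes in the third decimal.  The failure-mode demonstrations therefore
place the pattern at 0.75 of the passband, where the $\pm2\mathbf k_0$
honeycomb falls inside the enlarged support: reconstructing uneven-phase
data under a false even-step assumption then raises the local ratio by an
order of magnitude, while reconstruction with the true phases stays at the
ground-truth baseline.

*PSNR* is $10\log_{10}(\mathrm{peak}^2/\mathrm{MSE})$ with the reference
maximum as peak; `match_scale()` performs the affine intensity alignment
used before comparing reconstructions in arbitrary units against ground
truth.

## The learned reconstructor

`build_network()` assembles a residual-in-residual channel-attention
network: grouped residual blocks of two 3×3 convolutions with
squeeze-and-excitation channel attention, a global residual, and sub-pixel
(pixel-shuffle) upsampling from nine input frames to one output plane on
the doubled grid, plus a fixed bilinear-upsampled mean-frame skip so the
network learns a correction to the widefield image rather than the image
itself.  The convolutions, attention, shuffling, Adam and backpropagation
are implemented in R with an im2col/BLAS formulation; a central-difference
gradient check is part of the test suite.  The desk preset (2 groups × 2
blocks × 16 features; 21 convolutional layers counting the 1×1 attention
convolutions) trains on a CPU in minutes.  The full-scale preset
(7 × 3 × 64; 94 layers) is built and shape-checked but not trained in the
tests; no claim is made that desk-scale training reproduces full-scale
quality — the claim under test is only that the trained desk model beats
the bilinearly upsampled widefield baseline in median PSNR on held-out
uneven-phase stacks.

Training details, each of which measurably mattered: inputs are per-stack
percentile-normalized (1st to 99.9th), and targets are flux-matched to the
normalized input scale (blurring preserves the mean, so the ratio of means
maps truth units to input units) — otherwise the network wastes capacity on
per-stack intensity regression; residuals are standardized per example so
bright specimens do not dominate the gradient; random flips and transposes
augment each batch (a mirrored SIM stack is a valid stack with mirrored
pattern orientations); the learning rate (2e-3) halves after 60% of the
steps.  The training distribution randomizes aberration (0–0.25 waves),
global pattern rotation (±10°), phase mode (even, uneven-by-wavelength with
a 561 nm reference, or jittered by ±0.6 rad), modulation depth (0.3–1),
peak signal (20–400 photons) and structure class; these ranges are design
choices, set once, matching what the package's own simulator treats as
realistic acquisition variability.

## Problem sizes used by the tests

The test suite runs the bead-FWHM and FRC experiments on 256² camera grids
with 30 beads, and the network training on 80 patches of 32² camera pixels
for 1200 optimizer steps (batch 4) — sizes chosen so the whole suite
completes in minutes while leaving every measured quantity scale-free.
The acceptance script uses the full 512² camera grid with 50 beads.  Both
report the same FWHM and FRC values to within a few percent, as expected
for intensive quantities.

## Known limitations

Scalar 2D optics without defocus or vectorial effects; periodic-boundary
simulation (with border fading as mitigation); phase estimation bias on
extremely sparse scenes; a single scalar modulation depth per acquisition;
no photobleaching, 3D background, or camera fixed-pattern noise; the
learned reconstructor is desk-scale and trained purely on the package's own
simulator.
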