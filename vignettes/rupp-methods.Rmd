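---
title: "Projection pipelines for FD-OCT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection pipelines for FD-OCT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rupp)
```

## The problem

A Fourier-domain OCT acquisition records, at every lateral position $(x, y)$,
a spectral interferogram $E(k)$ over $K$ wavenumber samples; repeating the
scan $N$ times at each slow-axis position adds a temporal axis, giving a raw
volume ordered $K \times X \times Y \times N$. The conventional route to an
en-face projection reconstructs every A-line by FFT,
$I(z) = |\mathcal{F}\{E(k)\}|$, and then collapses depth:
$Proj(x,y) = \sum_z I_{x,y}(z)$. For angiography (OCTA) the reconstructed 4D
volume is additionally clutter-filtered along the repeat axis before the
depth collapse. Both steps are the dominant cost of projection generation.

The summation pipeline implemented here skips the FFT. The zero-frequency
DFT coefficient of a real signal is exactly the sum of its samples, so

$$Proj(x,y) = \sum_{k=1}^{K} E_{x,y}(k)$$

costs one addition per sample. On a detector, the DC level of $E(k)$ carries
the depth-integrated sample power (the autocorrelation terms of the
interference), which is why this sum forms a structural image at all: the
oscillatory fringe terms largely cancel over $k$, and what remains tracks
total backscattered power per A-line. The two projections are therefore
*correlated*, not equal — the FFT path sums magnitudes, the summation path
sums the raw signed spectrum — and the package asserts rank/Pearson
agreement rather than equality.

Angiography follows by stacking the $N$ per-repeat projections
($Proj^N$, an $N \times X \times Y$ array, conceptually clutter + flow +
noise) and filtering along the repeat axis in 2D:

* **Speckle variance** (`rupp_sv`): per-pixel population variance
  $\tfrac{1}{N}\sum_n (Proj_n - Proj_{mean})^2$ — reported as a variance,
  the literal form of the statistic.
* **Eigen-decomposition filtering** (`rupp_ed`): the $N \times N$
  correlation matrix $\hat C = \tfrac{1}{N} P P^H$ of the Casorati matrix
  $P$ (frames as rows, $X\,Y$ columns) is eigendecomposed, and the $r$
  dominant eigenvectors — the static-tissue clutter — are projected out:
  $Proj_a = (Id - \sum_{i \le r} e_i e_i^H)\,P$. Automatic $r$ counts the
  eigenvalues strictly above their mean; $r = 0$ (all eigenvalues equal) is
  allowed and leaves the stack untouched, with a warning, rather than
  silently deleting signal from a pure-noise stack.

The same eigen kernel, applied per repeated B-frame of the *reconstructed*
volume, provides the conventional baseline (`frame_ed`), and per-voxel
variance with depth summation provides the volumetric speckle-variance
baseline (`sv3d`).

### Casorati orientation and collapse rule

Two conventions the equations do not fix had to be chosen. The Casorati
matrix is oriented frames-as-rows ($N \times XY$): only that orientation
produces the $N \times N$ correlation matrix the filter diagonalises. The
$N$ residual frames left by the eigen filter are collapsed to a single map
as the mean of absolute values over $N$ — a symmetric choice that treats
every repeat equally. Note its consequence: the eigen-filtered map lives on
an *amplitude* scale while the speckle-variance map is a *variance*; the
two are monotonically related (squaring one approximately yields the other)
but score differently against any fixed reference, which matters when
ranking methods (see "Evaluation protocol").

The filter paths are written with Hermitian transposes even though the
summation pipeline is real-valued (no phase survives the spectral sum), so
the identical kernel serves complex frame-wise baselines.

## The simulator

`simulate_volume()` synthesises the acquisition the pipelines expect, with
known ground truth. Per A-line, discrete reflectors at integer depth bins
$z_j$ produce fringes; per wavenumber index $i = 0..K-1$ and repeat $n$:

$$E(i) = B + g \sum_j a_j(n)^2
       + \sum_j a_j(n) \cos(2\pi z_j i / K + \phi_j(n)) + \epsilon_i,
  \qquad \epsilon_i \sim N(0, \sigma^2).$$

Depth bin $z$ maps to discrete frequency $z$ cycles per $K$ samples, so the
magnitude DFT peaks at bin $z$ — the simplest faithful grid when no
physical $k$-calibration is being modelled. Depths are drawn *without
replacement* within an A-line: each discrete reflector occupies its own
axial resolution cell, so the reflectivity ground truth (the per-pixel
amplitude sum) agrees with what both projection paths measure. Scatterers
are confined to the superficial half of the Nyquist depth
(`depth_range = 0.5`), emulating light attenuation in dermal/oral tissue;
that also makes the default phantom band-limited below $K/4$, the regime in
which half-band spectral down-sampling is information-preserving.

The $g$-weighted term is the depth-integrated sample power riding on the
detector DC (the autocorrelation contribution to the interference
intensity). It is what gives the spectral sum its structural contrast: with
integer-bin fringes every cosine sums to exactly zero over a full number of
periods, so without this physically real term the summation image would
contain no tissue signal at all.

Flow is modelled per vessel pixel (tubes and disks in the lateral plane) by
extra *dynamic* scatterers whose phase is redrawn uniformly per repeat —
full decorrelation, the strongest simple instance of a temporally varying
flow component — and whose amplitude is jittered per repeat
(`dynamic_amplitude_jitter`, default 0.5 fractional). The jitter is the
component magnitude-based statistics detect: with integer depth bins, a
pure phase redraw leaves every fringe's spectral sum (zero) and magnitude
spectrum (flat at $a K/2$) unchanged, so it is invisible to SV, to the
eigen filters on magnitudes, and to the summation path alike. Physically
the jitter stands in for red-blood-cell flux through the voxel. The phase
redraw is kept because it decorrelates the *raw* A-lines, as repeated
in-vivo scans do.

### Defaults and what they mean

| parameter | default | rationale |
|---|---|---|
| `K, X, Y, N` | 768, 400, 400, 4 | a realistic swept-source acquisition size |
| `n_static_scatterers` | 6 per A-line | a few resolvable reflectors per cell column |
| `depth_range` | 0.5 | penetration-limited superficial imaging |
| `dc_offset` $B$ | 10 | reference-arm dominated detector background |
| `sample_dc_gain` $g$ | 0.5 | autocorrelation power at half the cross-term weight |
| amplitudes | $U(0.5, 1.5)$ | order-unity reflectivity spread |
| `noise_sigma` | 0.2 | fringe SNR high enough that spectra are DC-dominant; at this level the summation and FFT projections correlate at $\ge 0.9$, the regime the method targets |
| `dynamic_amplitude_jitter` | 0.5 | strong per-repeat flow decorrelation |

`default_phantom_config()` is the same statistical structure at desk scale —
$64 \times 64$ lateral grid, $K = 256$, $N = 4$ (12 for ground-truth
acquisitions), two crossing vessel tubes plus a disk, ~13% dynamic pixels —
the size used throughout the tests and the acceptance script.

### What the simulator does *not* emulate

No source spectral envelope, dispersion, depth-dependent roll-off, galvo
artifacts, or — deliberately — sample motion and bulk phase drift. The last
omission matters for interpretation: on real tissue, motion spreads clutter
over several eigenvectors and corrupts phase, which is the mechanism the
literature credits for speckle variance outperforming eigen filtering on
phase-free projection stacks. In this motion-free simulation the two
filters agree to within a display-scale change (see below), so passing
tests here demonstrate algorithmic correctness, not in-vivo robustness or
in-vivo quality rankings.

## Down-sampling

`downsample_volume_half()` keeps the odd-numbered spectral samples (1st,
3rd, ... — the keep-first-then-every-second reading of "odd-numbered"),
halving $K$ and the Nyquist depth. It emulates acquisition-time decimation
and is the only entry point for the "with down-sampling" variants, since
the point is that no processing cost is incurred. A fringe at bin
$z < K/4$ appears at bin $z$ of the half-length reconstruction; the package
asserts both that depth-index preservation and $\ge 0.99$ pixelwise
correlation of the summation projections with vs without decimation on the
band-limited default phantom.

## Ground truth and evaluation protocol

In vivo there is no ground truth; the convention adopted here is the
12-repeat average: A-line intensities averaged over 12 repeats and
depth-summed for the structural reference, and the frame-wise eigen filter
run on a 12-repeat reconstructed volume for the angiography reference. The
latter is a documented stand-in: the published reference pipeline for this
role is a *windowed* eigen filter whose window parameters are not specified
in a reproducible form, so the package uses its own frame-wise eigen
baseline, which shares the clutter-suppression principle.

Metrics follow the stated definitions literally: MSE; PSNR with the peak
taken from the *input* image's maximum (asymmetric and data-dependent, by
definition — a `peak` override restores the conventional constant); SSIM as
the mean over sliding windows of
$C_l^\alpha C_c^\beta C_s^\gamma$ with the standard stabilisers
($K_1 = 0.01$, $K_2 = 0.03$, Gaussian $11 \times 11$ window with
$\sigma = 1.5$, dynamic range $= \max(gt) - \min(gt)$), the de-facto
toolbox defaults, all exposed as arguments. Local SSIM statistics are
evaluated at fully interior window positions (valid mode, no padding);
with general exponents the signed structure term is raised as
$\mathrm{sign}(s)\,|s|^\gamma$.

Because the different methods emit images on incommensurable scales (raw
spectral sums, magnitude sums, variances), `compare_projections()` min-max
normalises both images to $[0, 1]$ before computing metrics; the bare
metric functions operate on raw values. One consequence is worth stating
plainly: normalisation is affine, so it cannot reconcile *nonlinear* scale
differences. The eigen-filtered map (amplitude scale) always resembles the
eigen-family ground truth more than the variance-scale SV map does —
$\sqrt{SV}$ scores within a fraction of a dB of the eigen map — so the
SV-vs-ED ranking under this protocol reflects display-scale conventions,
not filter quality, and the package does not claim to reproduce in-vivo
rankings between them.

## Numerical choices

* FFT path: per A-line mean subtraction before the unnormalised DFT (the
  minimal step that stops the DC bin dominating every depth sum), magnitude
  of bins $1..K/2$ kept; no spectral window.
* Eigendecomposition is done on the $N \times N$ correlation matrix
  (`eigen(symmetric = TRUE)`, eigenvalues returned sorted decreasingly);
  spatial filtering is recovered through the Casorati rows. $N$ is
  typically 4, so this is exact and cheap.
* Automatic $r$ uses a strict inequality against the mean eigenvalue, so a
  flat spectrum gives $r = 0$ rather than removing an arbitrary component.
* The speckle variance uses the numerically stable two-pass form
  (subtract the mean frame, then average squares), keeping the
  identical-frames case exactly zero.
* Simulation is vectorised as a cosine/sine basis multiply over the
  distinct depths present; identical seed and configuration give
  bit-identical volumes regardless of platform BLAS because all stochastic
  draws happen in R's RNG in a fixed order.

## Problem sizes

Tests and the acceptance script run on the desk-scale phantom
($64 \times 64 \times 256$, $N = 4$ or 12) and smaller: large enough that
vessel statistics and method orderings are stable across seeds, small
enough that the whole suite completes in well under a minute. The
full-size default ($768 \times 400 \times 400 \times 4$, ~2 GB of doubles)
is supported but is a memory-bound batch job, not a test fixture.

## Known limitations

* The summation projection carries no depth information and cannot be
  layer-segmented after the fact; that is the price of skipping the FFT.
* The simulator's flow model (phase redraw + amplitude jitter) is a
  stand-in for in-vivo decorrelation statistics, not a claim of
  equivalence.
* Absolute PSNR/SSIM values on synthetic phantoms are not comparable to
  values reported on in-vivo data; only within-run orderings and
  properties are meaningful here, and the SV/ED ordering specifically is
  protocol-dependent (see above).
* Wall-clock timings are logged for orientation and never asserted;
  relative speed-ups depend on the BLAS/FFT implementation at hand.
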