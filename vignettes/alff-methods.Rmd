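---
title: "ALFF and fALFF in alffr: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ALFF and fALFF in alffr: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alffr)
```

## The measures

The amplitude of low-frequency fluctuations (ALFF) summarizes, per voxel,
how much a resting-state BOLD time series oscillates inside a low-frequency
band, conventionally 0.01–0.08 Hz. Fractional ALFF (fALFF) expresses the
same in-band amplitude relative to the full analyzed range (0, fc], where
fc is the low-pass cutoff of the preprocessing stage (0.2 Hz by
convention). Both exist in two mathematically distinct variants that the
literature has often conflated, and `alffr` computes all four:

Let $s(m,n)$ be the demeaned series of voxel $m$ ($n = 0,\dots,N-1$
timepoints at repetition time TR), and $S(m,k) = |\mathrm{FFT}(s)(k)|$ the
raw magnitude spectrum. The frequency resolution is $\Delta f = 1/(N\cdot
TR)$; $k_{fl}, k_{fh}, k_{fc}$ are the bins closest to $f_l, f_h, f_c$
(ties round up, bin 0 excluded). The scaled one-sided amplitude
$2S(m,k)/N$ is the amplitude of the underlying oscillation at bin $k$
(the unmirrored Nyquist bin of an even-length series is scaled $1/N$).

* **amALFF** — arithmetic mean of $2S(m,k)/N$ over $k \in [k_{fl},
  k_{fh}]$: the classical definition.
* **qmALFF** — quadratic (root-mean-square) mean of the same quantities:
  the amplitude of the single sinusoid carrying the band's mean power,
  which is the physically natural summary when amplitude is read as the
  square root of power.
* **amfALFF** — $\sum_{band} S \,/\, \sum_{k=1}^{k_{fc}} S$.
* **qmfALFF** — $\sqrt{\sum_{band} S^2 \,/\, \sum_{k=1}^{k_{fc}} S^2}$,
  the fraction of RMS amplitude living in the band.

Because the quadratic variants are energies under the square root,
Parseval's theorem gives them a second, FFT-free route: bandpass-filter
the series, take the per-voxel RMS, and scale by $\sqrt{2/n_{bins}}$
(`qm_alff_time()`); qmfALFF is the RMS ratio of the bandpassed to the
fc-low-passed signal (`qm_falff_time()`). With a brick-wall (FFT-mask)
band selection the two routes agree to machine precision — the package
exposes that path (`filter = "ideal"`) precisely so the equivalence is
testable — while the practical Butterworth path approximates it.

Two algebraic facts shape the recommended pipeline:

* **Mean BOLD intensity (MBI)** — the temporal mean of the raw signal,
  averaged over voxels — multiplies the whole spectrum, so un-normalized
  am/qmALFF track scanner gain and physiology across subjects. Dividing a
  subject's map by its mask mean (`normalize_map()`) makes every subject
  average 1 and cancels any multiplicative factor exactly, including the
  spectral scaling convention itself.
* **z-scoring** a voxel's series scales its spectrum by $1/\sigma(m)$ and
  removes the DC term. Both fALFF variants are therefore invariant under
  z-scoring, while the normalized ALFF maps change whenever $\sigma$
  varies across voxels — z-scored input is the wrong starting point for
  ALFF, and `znorm_map()` exists to quantify how wrong.

## Conventions and numerical choices

**Spectral scaling.** The one-sided amplitude convention $2S/N$ for
interior bins and $1/N$ at Nyquist is fixed by two internal requirements:
amALFF and qmALFF must be means of the *same* per-bin quantities (so the
QM $\ge$ AM power-mean inequality holds voxelwise), and the time-domain
qmALFF must equal the frequency-domain form exactly under brick-wall
selection. Any global constant cancels under subject-level normalization,
so only these internal consistencies matter.

**fALFF denominator.** The denominator runs from bin 1, not bin 0. The
series is demeaned, so the DC magnitude is analytically zero; including it
would only add floating-point dust to a term that contributes nothing.

**Odd series lengths.** For odd $N$ the one-sided spectrum has bins
$0,\dots,(N-1)/2$ with no Nyquist bin and all $k \ge 1$ doubled; every
estimator accepts odd $N$ and is tested against the naive-DFT oracle there.

**Bin mapping.** $k(f)$ minimizes $|k\Delta f - f|$ with ties broken
toward the larger bin, clamped to $k \ge 1$. Degenerate bands (empty bin
range, fc above Nyquist) are hard errors, not silent clamps.

**Filtering.** "Zero-lag fourth-order Butterworth" is implemented as a
design-order-4 filter applied forward and backward, which cancels phase
and squares the magnitude response; users who read "fourth order" as the
effective two-pass response can set `order = 2`. Edge handling deserves a
longer note. The widespread recipe — odd-reflection padding of a few dozen
samples before the forward-backward pass — assumes the filter's impulse
response is short relative to the padding. A 0.01–0.08 Hz band at typical
TRs is an extremely narrow filter whose impulse response extends over
hundreds of seconds: with 27-sample padding, the edge transient of a pure
0.15 Hz (stopband) input retains about 20% of the input RMS over a
240-volume series, completely masking the filter's excellent steady-state
attenuation ($|H|^2 < 10^{-3}$), and longer padding does not help because
the reflection kink itself injects in-band energy. `alffr` therefore
defaults to Gustafsson's method, which chooses the forward and backward
initial filter states so that forward-backward and backward-forward
filtering coincide: the same stopband measurement drops to ~2.5% and the
passband deviation to ~$10^{-4}$. The padding variant remains available
as `filter_spec(edge = "pad")` for comparison with other toolboxes.

**RMS-ratio clipping.** Filter ripple can leave marginally more energy in
the bandpassed than in the low-passed signal when essentially all energy
is in-band; `qm_falff_time()` clips ratios above 1 back to 1 with a
warning rather than reporting an impossible fraction.

**z-score convention.** Population standard deviation (divide by $N$), so
z-scored rows have RMS exactly 1 and the time-domain qmfALFF identity for
unit-RMS signals holds exactly; the sample convention is available as an
option. MBI is always computed from raw, pre-demeaning intensities, which
the `bold_series` object retains through demeaning, filtering and
z-scoring.

**Degenerate voxels.** In-mask voxels with zero temporal variance are
dropped at read time with a logged count. Every downstream formula divides
by a spectral or RMS quantity that would be zero for them, so dropping
with a report was chosen over propagating NaN maps; how the original
pipelines handled such voxels inside their templates is not documented
anywhere we could verify, so this policy is the package's own.

**Voxel ordering.** Masked voxels are stored in sorted flattened-index
order of the volume's native (column-major) layout, making repeated reads
and all downstream maps bit-reproducible.

## The synthetic generator

`synth_spec()`/`make_dataset()` build cohorts of voxel series as

$$x_{s,v}(t) = g_s \left( \mu + \textstyle\sum_i A_i \cos(2\pi f_i t +
\phi_i) + \varepsilon_v(t) \right)$$

with per-subject gain $g_s$, baseline intensity $\mu$ (default 500
scanner units), sinusoidal components of known frequency/amplitude/phase
(snapped to the FFT grid by default so noiseless spectra are exact), and
Gaussian white noise. Defaults — a 6×6×6 grid with a 100-voxel mask, 240
timepoints at TR = 2 s — keep $\Delta f = 1/480$ Hz below the 0.01 Hz
band edge while every test runs in well under a second.

The noise stream is keyed by voxel (derived arithmetically from the master
seed), *not* by subject: a cohort that differs only in $g_s$ is then an
exact multiplicative family, which is what makes MBI exactly collinear
with un-normalized ALFF and the normalized maps identical across subjects.
When gains are powers of two the multiplication is exact through every FFT
butterfly and the normalized maps are *bit*-identical; for arbitrary gains
they agree to rounding (~$10^{-15}$). Set `independent_noise = TRUE` for
per-(subject, voxel) streams — required whenever a quantity (like fALFF)
must actually vary across subjects to correlate with anything.

What the generator does **not** emulate: hemodynamic response shapes, 1/f
spectra, spatial autocorrelation, motion, and cardiac/respiratory
structure. Passing tests therefore demonstrate algebraic and numerical
correctness of the estimators on signals with known spectra, not
robustness to real-data artifacts; the preprocessing that removes those
artifacts is explicitly upstream of this package.

## Group-level analysis

`subject_table()` (one row per subject: MBI and the mask means of the four
maps) and `voxel_table()` (one row per voxel: across-subject MBI,
across-subject means of per-subject *normalized* am/qm ALFF, and of the
fALFF maps) feed `correlation_matrix()`, which reports pairwise Pearson r
with two-sided p-values and no multiplicity correction — Pearson because
the relationships of interest are linear-transformation claims, raw
p-values because that is the reporting convention the tables mirror.
`cluster_mbi()` provides a deterministic 1-D k-means on MBI
(quantile-seeded, labels ordered by cluster mean) for cohorts whose MBI
distribution is multimodal, e.g. after scanner software changes; it is a
convenience, not a modelling claim. On synthetic cohorts built with
between-cluster MBI shifts, pooled and within-cluster correlations
reproduce the Simpson's-paradox-style pattern in which the pooled
r(MBI, ALFF) exceeds every within-cluster r.

One statistical caveat is worth stating explicitly: assertions of the form
"r is near zero" on a 50-subject cohort involve a null correlation whose
sampling standard deviation is $1/\sqrt{50} \approx 0.14$. The test suite
pins such checks to a fixed generator seed and treats them as properties
of that fixture; they are qualitative structure checks, not estimates.

## Validation strategy and problem sizes

Every estimator is checked against an independent route computed at small
scale: a naive $O(n^2)$ DFT oracle for all four frequency-domain metrics
(50 random voxels, $n \le 256$, agreement to $10^{-9}$ relative); the
brick-wall Parseval path for the time-domain forms (100 voxels, $10^{-9}$);
hand-derived closed forms for bin-aligned cosines; the power-mean
inequality (1,000 voxels); exact normalization algebra; and Monte Carlo
flat-spectrum expectations for white-noise fALFF (200 voxel streams,
3-standard-error band). The Butterworth path is compared with the
frequency domain on band-dominated fixtures whose components stay 15%
inside the band edges — at the exact edge a Butterworth passes half power
by definition, so edge components measure the filter's definition rather
than its implementation. `scripts/acceptance.R` re-runs the same
quantities from scratch at the same sizes and writes them as JSON.

## Limitations

The package computes masked voxelwise metrics from already-preprocessed
4D volumes; registration, motion correction, confound regression and
surface analysis are out of scope. No harmonization across sites or
scanners is attempted — normalization removes a subject-level
multiplicative factor, not site effects on spectral shape. The voxel-level
association between MBI and fALFF reported in real cohorts has no
mechanism in our generator and is deliberately not asserted on synthetic
data.
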