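# alffr

Amplitude of low-frequency fluctuations (ALFF) and fractional ALFF (fALFF)
for resting-state fMRI, in R.

## The problem

ALFF summarizes, per voxel, how strongly a BOLD time series oscillates in a
low-frequency band (conventionally 0.01–0.08 Hz); fALFF expresses that
amplitude relative to the full analyzed range (0 to the preprocessing
low-pass cutoff fc, conventionally 0.2 Hz). The literature has conflated two
distinct constructs under the name "ALFF", and popular toolboxes implement
different ones. `alffr` computes both, explicitly:

For a demeaned voxel series $s(m,n)$ with spectrum $S(m,k) =
|\mathrm{FFT}(s)(k)|$ and band bins $k \in [k_{fl}, k_{fh}]$,

- **amALFF** $= \dfrac{1}{k_{fh}-k_{fl}+1}\sum_k \dfrac{2S(m,k)}{N}$ — the
  arithmetic mean of the one-sided amplitudes (the classical definition);
- **qmALFF** $= \sqrt{\dfrac{1}{k_{fh}-k_{fl}+1}\sum_k
  \left(\dfrac{2S(m,k)}{N}\right)^2}$ — their quadratic mean, the amplitude
  of the sinusoid carrying the band's mean power;
- **amfALFF** $= \sum_{band} S \big/ \sum_{k=1}^{k_{fc}} S$ and
  **qmfALFF** $= \sqrt{\sum_{band} S^2 \big/ \sum_{k=1}^{k_{fc}} S^2}$.

By Parseval's theorem the quadratic variants have an equivalent time-domain
form — bandpass filter (zero-phase Butterworth), take the per-voxel RMS,
scale by $\sqrt{2/n_{bins}}$ — which the package implements alongside the
frequency-domain route and verifies against it. Subject-level normalization
(divide a map by its mask mean) removes the mean-BOLD-intensity (MBI)
dependence of ALFF across subjects; z-scoring the input leaves fALFF
untouched but corrupts normalized ALFF whenever the temporal standard
deviation varies across voxels. Both behaviors are implemented, tested, and
demonstrated on synthetic cohorts.

It is intended for neuroimaging researchers who want a transparent,
validated reference implementation of all four metrics over NIfTI volumes
(plus a mask), either as R functions or from the shell.

## Worked example

```r
library(alffr)

# a 3-subject synthetic cohort: 0.04 Hz (in-band) + 0.15 Hz components,
# white noise, subjects differing by a multiplicative gain
spec <- synth_spec(n_subjects = 3, n_voxels = 100, n_timepoints = 240, tr = 2,
                   components = data.frame(freq = c(0.04, 0.15),
                                           amp = c(2, 1), phase = 0),
                   noise_sd = 0.5, mbi_gain = c(0.8, 1.0, 1.25), seed = 1)
out <- write_dataset(spec, "demo")

series <- read_bold(out$bold[2], out$mask)
#> <bold_series> 100 voxels x 240 timepoints, TR = 2 s

band <- band_spec(fl = 0.01, fh = 0.08, fc = 0.2)
qm_t <- qm_alff_time(demean(series), band)   # time domain, no FFT
normalize_map(qm_t)
#> <voxel_map> qmALFF_norm: 100 voxels, mean 1, range [0.959658, 1.05009]

alff_maps(series, band)$qmfALFF              # frequency domain
#> <voxel_map> qmfALFF: 100 voxels, mean 0.875527, range [0.853407, 0.89791]
```

The qmfALFF mean of ≈0.88 is the expected RMS fraction for these signals:
the in-band 0.04 Hz component carries 4/5 of the deterministic power
(√0.8 ≈ 0.894), pulled down slightly by broadband noise. The subject table
shows the MBI structure the normalization exists to remove — ALFF scales
with the gain, fALFF does not:

```r
subs <- lapply(out$bold, read_bold, mask_path = out$mask, verbose = FALSE)
subject_table(subs, band)
#>   subject MBI amALFF qmALFF amfALFF qmfALFF
#> 1       1 400 0.0914  0.280   0.462   0.876
#> 2       2 500 0.1143  0.350   0.462   0.876
#> 3       3 625 0.1428  0.437   0.462   0.876
```

MBI rises 400 → 625 with the gain and amALFF/qmALFF rise in exact
proportion, while both fALFF columns are constant to 4 decimals — the
gain cancels in the ratio. `correlation_matrix(subject_table(...))` reports
the corresponding Pearson r matrix with p-values, and `cluster_mbi()`
splits multimodal cohorts before correlating within clusters.

The same pipeline runs from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","alff.R",package="alffr"))')" \
    compute --bold demo/sub-002_bold.nii.gz --mask demo/mask.nii.gz --out maps_out
```

which writes `qmALFF_norm.nii.gz`, `qmfALFF.nii.gz`, a per-subject summary
CSV, and a `parameters.json` sidecar recording every setting (band, filter
order, bin indices, dropped-voxel count, package version) so any output is
reproducible from its sidecar alone. `--domain frequency --metrics all`
adds the arithmetic-mean variants, raw maps, MBI and sigma maps; `synth`
and `group` subcommands generate fixture datasets and group-level
correlation tables.

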