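---
title: "Detecting fluorescently labeled cells in 3D volumes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fluorescently labeled cells in 3D volumes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cells3d` detects and counts fluorescently labeled cells (typically nuclei)
in 3D fluorescence microscopy volumes — confocal or light-sheet stacks of
whole-mount tissue or thick sections. This vignette explains the model and
the procedure, the parameters that matter, the synthetic-data generator the
package validates itself against, and the design decisions and limitations a
user should know about.

## The detection problem

A 3D stack contains point-like bright objects (labeled nuclei) over a
background that varies between samples and within a sample. The practical
obstacles are well known to anyone who has tried to automate such counts:

* **sample-to-sample variation** — staining efficiency and detector gain
  shift the whole intensity distribution, so absolute thresholds do not
  transfer between samples;
* **autofluorescence** — vessels, lipofuscin and connective tissue can be as
  bright as the marker, in every channel;
* **inhomogeneous staining** — thymidine analogs (EdU, BrdU) incorporate
  into replicating DNA in patches, so one nucleus can look like several
  small blobs, or like none;
* **background gradients** — a cell on a bright slope may not be separated
  from it by any global threshold;
* **overlapping cells** — dividing or densely packed cells touch, and naive
  connected-component counting merges them.

The pipeline addresses each obstacle with a dedicated, classical stage, and
then adds the package's statistical core: a bootstrap test that decides, per
candidate segment, whether it is shaped like a cell.

## Pipeline

`detect_cells()` executes, in order:

1. **Histogram matching** (`match_histogram`). Voxel intensities are
   remapped by the monotone quantile (CDF-inverse) map onto a reference
   histogram — the histogram of the sample on which the parameters were
   tuned. Rank order is preserved exactly (mid-rank handling of ties); the
   output's empirical CDF matches the reference to within one bin width
   (1024 bins by default). After this step one parameter set serves a whole
   batch.
2. **Autofluorescence subtraction** (`subtract_background_channel`). A
   second co-registered channel, acquired at a wavelength where the marker
   does not emit, sees only the autofluorescent structures. It is first
   histogram-matched to the signal channel (the two channels' gains differ),
   then subtracted voxel-wise; negative differences are clipped to zero
   because everything downstream treats intensities as non-negative.
3. **Band-pass filtering** (`bandpass_filter`). The volume is convolved with
   a difference of Gaussians, `G(sigma_low) - G(sigma_high)`, in one FFT
   pass. The low-pass sigma sits between the noise-artifact radius and the
   cell radius (it erases intra-nucleus patchiness); the high-pass sigma
   exceeds the cell radius by a factor of about 1.5–2 (it flattens the
   background so one threshold works everywhere). Both kernels are sampled,
   sum-normalized Gaussians, so a constant volume maps exactly to zero.
4. **Thresholding** (`apply_threshold`). Voxels below a fraction (typically
   5–10%) of the *maximum of the band-passed volume* are zeroed, as are all
   negative band-pass responses. The maximum of the filtered volume, not the
   raw one, is the reference: filtering precedes thresholding in the
   pipeline, and the filtered maximum is the quantity on the same scale as
   the filtered voxels being cut.
5. **Watershed segmentation** (`watershed_segments`). The positive support
   is flooded downhill from its regional intensity maxima (equivalently, a
   watershed of the negated image). Every regional maximum seeds exactly one
   segment; voxels where two basins meet become watershed lines (label 0);
   zeroed background is excluded from flooding entirely, so there is no
   giant background catchment. This is what splits touching cells: two
   overlapping nuclei have two maxima and the boundary falls along the
   intensity valley between them.
6. **Size filtering** (`remove_small_segments`). Segments far smaller than a
   cell (below 10–100 voxels, depending on resolution) are discarded.
7. **Bootstrap significance** (`classify_segments`), described next, on the
   *unfiltered* intensities of step 2's output.

## The bootstrap Gaussian-fit test

A labeled nucleus is modeled as a 3D Gaussian blob,

> I(r) = I0 · exp(−½ · rᵀ Σ⁻¹ r),

with `r` the voxel offset from the segment's intensity peak and `Σ` a full
3×3 variance matrix (the blob may be anisotropic and arbitrarily oriented).
Taking logarithms makes the model linear in the 6 distinct entries of
`A = Σ⁻¹` plus the intercept `ln I0`, so it is fitted by ordinary least
squares — no starting values, no iterations, deterministic. The square roots
of the eigenvalues of `Σ` are the blob's *principal standard deviations*:
rotation-invariant half-axis scales in voxels.

Practical details, each of which matters:

* Only voxels of the segment within `fit_radius` (default 7 voxels) of the
  peak enter the fit — enough to include local background, but not the
  segment's far tails. The raw, unfiltered intensities are used: the filter
  would impose its own smoothness on every segment and make everything look
  like a blob.
* Voxels with non-positive intensity cannot enter `ln I` and are dropped
  from the regression (no arbitrary offset is added). A fit with fewer than
  10 positive voxels is invalid.
* The fit is **valid** only when the regression has full rank and the fitted
  `A` is positive definite. A non-positive-definite `A` is not a blob of any
  size; treating it as anything but a failure would bias the test.

The test itself: the region's voxel list is resampled with replacement
(classical bootstrap, resample size = original size) `bootstrap_iters`
(~1000) times; each resample is refitted; an iteration **passes** when the
fit is valid and every principal standard deviation lies in
`[std_min, std_max]` (optionally the amplitude in `[amp_min, amp_max]`). The
**p-value is the fraction of failing iterations** — the estimated
probability that the segment does not satisfy the user's definition of a
cell. Segments with `p < p_threshold` are reported as detections, with the
mean principal stds over passing resamples.

Two implementation guarantees: resampling uses a deterministic per-segment
stream derived from `(rng_seed, segment_label)`, so results are identical
across runs and independent of processing order; and segments whose failure
count already guarantees `p >= p_threshold` stop resampling early — a pure
optimization, since the emitted set and every reported p-value equal the
full run's.

## Parameters and presets

Six published parameter sets ship as `detection_preset()`s, one per
validated sample type:

| preset | σ_low | σ_high | threshold | min size | stds (voxels) | p |
|---|---|---|---|---|---|---|
| `edu_wm` | 0.4 | 10 | 10% | 10 | > 1.5 | 0.01 |
| `cfp_wm` | 0.4 | 10 | 5% | 10 | > 1.5 | 0.01 |
| `edu_section` | 2 | 6 | 6% | 100 | 4–9 | 0.3 |
| `brdu_section` | 2 | 3 | 8% | 100 | 4–9 | 0.5 |
| `cfos_section` | 2 | 3 | 4% | 100 | 4–9 | 0.1 |
| `dapi_section` | 2 | 6 | 6% | 100 | 4–9 | 0.3 |

All spatial parameters are in voxels and accept per-axis (z, y, x) triples
for anisotropic acquisitions; all presets use `fit_radius = 7` and 1000
bootstrap iterations. Whole-mount (WM) presets describe coarser-resolution
acquisitions (nuclei spanning ~1.5–2.5 voxels per axis); section presets
describe higher-resolution imaging (nuclei ~4–9 voxels). The loose section
p-thresholds (0.3–0.5) compensate for the much lower per-voxel SNR of those
samples: individual resample fits are noisy, so even genuine cells fail a
sizable fraction of iterations.

## Evaluation

`match_detections()` computes a maximum-cardinality one-to-one matching
between detected and reference centroids among pairs within a Euclidean
tolerance (augmenting-path bipartite matching; deterministic, with
candidates tried closest-first). From the resulting TP/FP/FN counts,
`f_score()` returns precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
`F = 2PR/(P+R)`. Optimal rather than greedy matching makes the score an
upper bound that is stable under permutations of the input.

`compute_snr()` implements the decibel signal-to-noise measure used to
characterize sample difficulty: `20·log10` of the mean signal amplitude over
cell peaks divided by the noise amplitude, where the noise amplitude is the
standard deviation of the volume after high-pass filtering and a peak's
signal amplitude is its raw intensity minus the local background. The local
background is the **mean** intensity in a spherical shell between `radius`
and `2·radius` around the peak. The mean — rather than a low quantile — is a
deliberate design decision: under additive noise the shell mean is unbiased,
while a low-quantile estimator drifts downward as noise grows (an order
statistic of the noise), inflating the apparent signal amplitude and giving
the measure an asymptotic floor near −1.5 dB; sample types around or below
that floor could then never be characterized, let alone simulated.

## The synthetic generator

`generate_volume()` produces a signal channel, an autofluorescence channel
and a ground-truth table from a `synthetic_spec()`. It emulates exactly the
challenge taxonomy above:

* **cells** — anisotropic Gaussian blobs with per-axis stds and amplitudes
  drawn uniformly from configurable ranges, placed by rejection sampling
  with a minimal pairwise separation; real-valued (sub-voxel) centers,
  sampled at voxel centers. Cells keep a per-axis margin of
  `min(3·sigma_max, dim/4)` from the volume faces — the 3-sigma rule is
  capped so that thin-section geometries (e.g. 32 slices with 6-voxel
  nuclei) remain usable;
* **overlapping pairs** — a configurable number of cells placed at 1–2 mean
  sigma (default 1.5) from a partner, exempt from the separation rule;
* **patchy nuclei** — a configurable fraction rendered as 2–4 sub-peaks with
  sigma 0.4× nominal, centers within one nominal sigma, and amplitudes that
  sum to the nominal peak amplitude. Patchy nuclei are therefore *dimmer*
  than solidly stained ones — patchiness is a failure mode, not a beacon —
  and their sub-peak scale is what the low-pass filter is meant to fuse;
* **background** — a linear gradient in a random direction, or a smooth
  wide-Gaussian blob field, with configurable amplitude;
* **vessels** — smoothed random-walk tubes (Gaussian cross-section, default
  sigma 2.5 voxels, amplitude 0.8× mean cell amplitude) rendered identically
  into both channels; the autofluorescence channel contains the vessels and
  its own noise realization but no cells;
* **noise** — additive white Gaussian voxel noise whose standard deviation
  is calibrated so that `compute_snr()` of the emitted volume equals
  `target_snr_db` (±0.25 dB in practice; ±0.5 dB guaranteed by the
  calibration loop). The emitted volume is clipped at zero, as a
  fluorescence image's dark background sits at the detector floor.

Calibration solves for the noise scale by bracketing and root-finding on a
central crop (clipping makes the high-pass noise amplitude nonlinear in the
noise scale, so each candidate requires re-filtering), then refines with
full-volume secant steps — the crop alone misjudges spatially non-uniform
clipping under a background gradient. `preset_specs()` ships one spec per
sample type, carrying the published SNR (16.9, 10.7, 6.2, −3.6, −6.3 and
2.81 dB) and the matching structural regime.

What the generator does **not** model: the optical point-spread function,
Poisson (shot) statistics, autofluorescence emission spectra, or spatially
correlated "texture" noise. Noise is white at the voxel scale because the dB
SNR definition above constrains nothing beyond the high-passed standard
deviation, and white noise is the minimal model consistent with it. This
choice has consequences, discussed below.

## What the surrogate checks show — and what they cannot

The test suite closes the loop: generate a preset volume, run the pipeline
with the matching published parameter set, score against ground truth. Two
findings from these surrogates are important for interpreting them
(`tests/testthat/test-acceptance.R` computes the numbers; the analysis here
explains the mechanism).

**White voxel noise at the published whole-mount SNR fragments the
watershed.** The WM presets use `sigma_low = 0.4`, which leaves white voxel
noise essentially unattenuated in the band-passed image (the sampled
0.4-voxel kernel removes only ~22% of white-noise power). At 16.9 dB under
the definition above, the noise standard deviation is forced to about 1/7 of
the mean cell amplitude; after filtering it remains large enough to plant
spurious regional maxima on every cell's support, so the watershed shatters
cells into fragments whose fits then fail the size criteria. The surrogate
F-scores at the WM presets therefore fall far below the published 99%/97% —
not because the pipeline differs from its description, but because a real
sample measured at 16.9 dB cannot have carried that much *voxel-level*
noise: its high-passed standard deviation must have been dominated by
structured tissue content (vasculature, residual background texture) rather
than white noise. The SNR measure does not distinguish the two; the
watershed very much does.

**The section criteria apply to fitted, not true, sizes.** In the section
regime the fit's radius-7 neighborhood spans less than the log-profile of a
5-voxel-sigma nucleus, and the local floor (clipped noise plus background
gradient) flattens the observed log-intensity range. Fitted principal stds
are therefore systematically 1–4 voxels larger than the true ones. With true
stds of 4–6 voxels, a sizable fraction of resamples crosses the published
`std_max = 9`, which caps the surrogate recall at those presets. The
published [4, 9] band and the real samples' fitted sizes were, by
construction, self-consistent; a surrogate that pins *true* sizes at 4–6
inherits the inflation on top.

Within a regime the expected ordering holds (higher SNR, higher F; patchy
EdU sections below patch-free DAPI sections at comparable noise), and that
is what passing the closed-loop tests demonstrates about real data: the
stage-level contracts (filter responses, watershed splitting, fit recovery,
p-value arithmetic, matching) are exact, and end-to-end behavior degrades
with noise in the expected direction. What the surrogates cannot certify is
the absolute published F-scores, which were measured against experts on
tissue whose noise was not white.

## Numerical choices

* **Coordinates**: arrays are indexed `(z, y, x)` matching TIFF page order;
  all user-facing centroids are 0-based voxel coordinates, with physical
  micrometers alongside (from `spacing`).
* **FFT boundaries**: volumes are padded by `3·sigma_high` voxels of
  edge-value replication before the periodic FFT and cropped afterwards;
  padded lengths are rounded up to 5-smooth sizes for speed.
* **Watershed determinism**: 6-connectivity; plateau maxima form a single
  marker; voxels are scanned in lexicographic (z, y, x) order and the
  flooding queue breaks intensity ties first-in-first-out. Segment peaks
  break intensity ties toward the lexicographically smallest coordinate.
* **Degenerate inputs**: an all-zero volume yields zero segments and zero
  detections (not an error); a constant volume has a single-bin histogram;
  an empty fit region gives `p = 1` by convention; a noise-free volume makes
  the SNR undefined and raises a classed error.
* **Matching ties**: candidates are tried in order of ascending distance,
  then index; the matching is maximum-cardinality, so ties affect which
  pairs form, never how many.
* **Problem sizes**: the study conditions are 256×256×64-voxel volumes with
  ~150–210 cells for whole-mount presets and 256×256×32 with ~100 cells for
  section presets (those are the preset defaults). The acceptance script
  (`scripts/acceptance.R`) runs five replicate volumes per sample type on
  192×192 fields with cell counts scaled to preserve density; the test
  suite runs further-reduced replicas (128×128×32, two seeds). Cell sizes,
  separations, background and noise calibration are identical across
  scales by construction.

## Known limitations

* The Gaussian blob is the only cell model: crescent, lobed or hollow
  nuclei are fitted as blobs, and acceptance then depends on where their
  effective half-axes land.
* No multiple-testing correction across segments — the per-segment p-value
  is thresholded directly, as many segments as there are.
* Channels must be co-registered; there is no registration step.
* The generator's noise model is white and Gaussian (see above); surrogate
  scores at the published SNRs are lower bounds on behavior under
  equally-measured but structured real noise.
* `write_volume()` emits 8/16-bit integer TIFFs only; float volumes must be
  quantized (the CLI's `synth` does this automatically).
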