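---
title: "Models and methods behind irestoolbox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind irestoolbox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irestoolbox)
```

This vignette explains the statistical models and procedural choices in the
package: what each analysis assumes, which parameters matter, what the
synthetic generators do and do not emulate, and where the design was
genuinely open.

## The biological setting

IRES (internal ribosome entry site) elements in 5' UTRs recruit ribosomes
cap-independently. Quantifying their activity draws on several assay
families with very different raw data but a shared analysis core: counting
single mRNA molecules and their isoform identity in tissue sections
(smFISH), measuring reporter fluorescence in gated cell subpopulations
(flow cytometry of a circRNA split-EGFP reporter), and converting qPCR
quantification cycles into relative and absolute template abundances. The
package implements that shared core as composable, tibble-in/tibble-out
functions.

## smFISH spot detection and isoform classification

A transcript with two alternative transcription start sites yields a long
5' UTR isoform carrying the IRES-like element and short isoforms without
it. Two probe channels distinguish them: the CDS probe marks every
molecule, the IRES probe only the long isoform. Classification is purely
geometric — a CDS punctum partially overlapping an IRES punctum is a long
molecule.

**Detection model.** Puncta are diffraction-limited, so a local
thresholding rule suffices: pixel is foreground when
`I > median_w(I) + k * MAD_w(I)` over a `w × w` window. Defaults `w = 15`
px and `k = 5` were chosen for robustness in spot-dense neighborhoods — a
median/MAD background tracks slowly varying autofluorescence and is not
dragged up by nearby bright spots the way a mean/SD would be. The unscaled
MAD is used (no 1.4826 normal-consistency factor), so `k = 5` corresponds
to roughly 3.4 Gaussian sigmas. Foreground pixels form 8-connected
components; the area band `[2, 200]` px discards single-pixel noise and
merged blobs (no watershed splitting is attempted). Centroids are weighted
by background-subtracted intensity. The implementation is compiled (Rcpp);
a brute-force per-pixel R reimplementation serves as its oracle in the test
suite and the two agree exactly on random images.

**Overlap definition.** "Partially overlaps" is implemented as at least
`min_overlap_px = 1` shared pixel between masks. With sub-pixel
registration and puncta several pixels wide, one shared pixel is the
weakest criterion that is still deterministic; it is exposed as a parameter
for stricter use. A CDS punctum is counted once however many IRES puncta it
touches; an IRES punctum may support several CDS puncta. IRES-only puncta
are tallied as QC (they should be rare — an IRES signal without a CDS
signal has no biological interpretation here).

**Pooling.** Counts from all images of an embryo are summed before the
long/short ratio is formed; the region summary is the mean ± SD of
per-embryo proportions. Pooling before dividing weights images by their
molecule content and avoids the instability of per-image ratios on sparse
fields. Embryos with zero CDS puncta have an undefined proportion and are
excluded with a flag rather than imputed.

**Coordinates.** Image coordinates are 0-based `(row, col)`; transcript
coordinates in the sequence module are 1-based inclusive, matching the
public-database convention used for probe descriptions. Both are stated in
the function documentation.

## The smFISH generator

`simulate_smfish_image()` plants `n_spots` isotropic Gaussian puncta
(σ = 1.3 px, log-normal amplitudes) on a constant background with additive
Gaussian noise, and gives a `long_fraction` share of them an IRES partner
displaced by at most 1 px — guaranteeing mask overlap under any reasonable
threshold. Spot centers keep a minimum separation of 6σ so puncta stay
resolvable; placement is rejection-sampled and fails loudly when the
requested density cannot be met. The negative-control channel carries a
stated low count of false puncta. Presets encode the two tissue regimes:
`somite` plants 80% long isoform, `neural_tube` 20%.

Default study conditions used throughout the tests and the acceptance
script: 3 embryos × 5 images of 128 × 128 px at 40 puncta per image
(≥ 500 CDS molecules per cohort), background 100, noise SD 5, amplitudes
around 60. These are round values typical of cropped confocal fields; the
generated data are 2-D, noise is Gaussian rather than Poisson (a Poisson
component would matter at much lower signal), and there are no optical
aberrations, no cell boundaries, and no tissue autofluorescence gradients.
Passing recovery tests therefore demonstrates correctness of the counting
and classification logic under the stated point-spread model, not
robustness to every imaging artifact of real sections.

## Flow-cytometry gating

The gating chain mirrors standard practice: QC → viable → singlet →
transfected → MFI.

- **QC.** Clogs corrupt events after them; the flag method trusts the
  instrument's anomaly annotation, while the rate method bins events in
  0.1 s windows and drops bins whose rate deviates from the run median by
  more than 3-fold (the terminal, incomplete bin is exempt from the
  low-rate test).
- **Viable.** A robust ellipse on log10 FSC-A / log10 SSC-A — center at
  the medians, half-axes `k = 4` scaled MADs — excludes the low-scatter
  debris floor without hand-drawn polygons. Data-driven gates were chosen
  over fixed coordinates so the procedure is reproducible across
  instruments and requires no interactive step.
- **Singlet.** Doublets conserve total signal, so FSC-A ≈ 2·FSC-H; events
  with FSC-H/FSC-A within ±15% of the viable-population median ratio are
  singlets.
- **Transfected.** The mRuby threshold is the 99.9th percentile of a
  control population's viable singlets. Whether the control is
  untransfected cells or the empty vector is left to the caller — both are
  defensible and the package supports either.
- **Readout.** The median (not mean) EGFP of the mRuby+ subfraction, which
  is insensitive to the long right tail of strongly expressing cells.

Fold activity divides each replicate MFI by the mean reference MFI of the
same batch (when batch labels exist; globally otherwise), so the reference
construct's mean fold is exactly 1. Statistics use the Welch (unequal
variance) form of the two-tailed unpaired t-test: with n of 3–6 per
construct, assuming equal variances buys little and risks anticonservative
p-values. Tiers follow the conventional cutpoints 0.05 / 0.01 / 0.001 /
0.0001.

The event generator draws log-normal scatter and fluorescence for four
planted categories (debris, doublets, untransfected, transfected) and
scales transfected EGFP by `activity_fold`, whose distributional median is
exactly `baseline × fold` — so fold recovery has a closed-form target. It
does not model spectral spillover, compensation, or instrument drift.
Recovery tests run at 20,000 events and folds 1–13, the scale of the
strongest viral IRES in this reporter class.

## qPCR computations

All Ct mathematics assume the exponential amplification model
`quantity ∝ efficiency^(-Ct)`. The generator anchors its baseline so 1 pg
gives Ct 20 at efficiency 2 — an arbitrary but fixed convention recorded
here and in the generator documentation.

- `rel_quantity()` is `2^-(ΔCt)`. Replicates are aggregated as arithmetic
  means of Cts, i.e. geometric means of linear levels, which respects the
  log-scale error structure of qPCR.
- RNase R enrichment: within each treatment arm, levels are normalized to
  a reference amplicon; each amplicon's enrichment is its digested over
  undigested level; the construct readout is circular over linear
  enrichment. In the noiseless model this ratio equals
  `d_linear / d_circular` exactly, independent of the reference's own decay
  — the identity the tests assert.
- Standard curves: least squares of Ct on log10 quantity; efficiency
  `10^(-1/slope)` with a warning outside `[1.8, 2.1]`; r² computed from
  residuals. The canonical series is five tenfold dilutions from 1 pg to
  0.1 fg. `absolute_quantify()` inverts the line and flags extrapolation
  beyond the fitted range.
- Polysome distributions: per fraction, `2^-(Ct_amplicon − Ct_spike)`
  corrects recovery differences using the constant spike-in, then levels
  are normalized to sum to one. The distribution is invariant to any
  uniform shift of spike Cts (a property test). Five portions — free,
  40S/60S, 80S, light polysome, heavy polysome — partition the fractions;
  the mapping is user configuration because fraction counts vary by run,
  with an even default split.
- Missing Cts ("undetermined") stay missing and propagate, with one
  documented exception: `no_rt_delta()` substitutes a max-cycle ceiling
  (default 40) for undetermined no-RT controls and flags the row, since an
  undetectable no-RT signal is the *good* outcome and dropping it would
  discard the informative case.

The Ct generator supports treatment arms (RNase R with class-specific
decay, no-RT with a residual-template leak of `2^-10` by default, i.e. a
10-cycle offset), gradient designs with per-fraction weights, and dilution
designs with explicit quantities. At zero noise every analysis inverts it
exactly; tests exploit this for round-trip checks at 1e-9 relative
tolerance. It does not simulate primer-sequence effects, melt behavior, or
plateau-phase chemistry.

## Sequence features

Inverse (reverse-complement) inserts preserve length and GC content by
construction — the identity that makes them matched controls for
length- and GC-dependent effects while destroying sequence-specific
activity; the package property-tests it on random sequences against a
hand-rolled oracle independent of the Biostrings implementation used
internally. The uAUG scanner defines the main start codon as beginning
immediately after the last UTR base: `distance = utr_length − offset`,
`frame = distance mod 3` (frame 0 in-frame). A uAUG with an in-frame stop
fully inside the UTR is a uORF; one that runs into the main ORF is classed
"overlapping". RNA-style `U` input is normalized to `T`.

## Numerical and degenerate-input conventions

- All generators draw from one seeded RNG per call and restore the
  caller's RNG state; identical seeds give bit-identical outputs.
- A constant image has zero local MAD everywhere and strictly-greater
  thresholding yields zero spots; at zero noise, masks grow to the full
  truncated PSF footprint, so degenerate-limit tests use wider spot
  separation.
- Median convention everywhere is the mean-of-middle-pair for even counts
  (R's default), asserted explicitly for MFIs.
- Empty gates, empty spot lists, and embryos without CDS puncta return
  flagged missing values rather than errors; genuinely contradictory
  requests (fractions outside [0, 1], unplaceable spot densities,
  non-nested exclusions) abort with messages.

## Known limitations

The generators validate logic, not instruments: no 3-D stacks, optical
aberration, spillover/compensation, or amplification-curve chemistry. Spot
detection deliberately omits watershed splitting, so heavily overlapping
puncta beyond the area ceiling are dropped rather than split; at realistic
planted densities this loss is negligible (recovery error well under 0.03
across planted fractions 0–1) but dense tissue may need stricter imaging
or a segmentation front-end. The mRuby control choice (untransfected vs
empty vector) and the gradient portion boundaries are scientific decisions
left to configuration.
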