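---
title: "Methods: shifted-excitation Raman difference spectroscopy with neural spectrum purification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shifted-excitation Raman difference spectroscopy with neural spectrum purification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Near-infrared Raman spectra of fresh biological tissue are dominated by
autofluorescence: a broad, featureless emission that can exceed the Raman
lines by an order of magnitude or more. Shifted-excitation Raman difference
spectroscopy (SERDS) exploits a physical asymmetry between the two signals.
When the excitation laser is detuned by a small amount (here 784 nm versus
785 nm), the fluorescence emission is essentially unchanged — it depends on
the electronic relaxation of the fluorophores, not on the precise excitation
photon energy — while every Raman line tracks the excitation, because a
Raman shift is an energy *difference* between excitation and scattered
photon. Subtracting the two acquisitions therefore cancels the fluorescence
(and any background fixed on the detector, such as etaloning ripple) and
leaves each Raman line as a derivative-like positive/negative doublet.

`serds` implements the full processing chain for such dual-excitation
acquisitions — block averaging, z-score normalization, difference
formation, recovery of the background-free spectrum with a one-dimensional
convolutional encoder–decoder, PCA-LDA tissue classification under
stratified cross-validation, and peak annotation — together with a
synthetic cohort generator that makes every stage testable against known
ground truth. The motivating application is discrimination of cutaneous
neurofibroma, a benign nerve-sheath tumor of the skin, from surrounding
physiological tissue (skin, nerve, fat, bone, mucosa) on surgical
specimens.

## Geometry of the measurement

The detector records intensity against wavelength $\lambda$ on a fixed grid
(default 1024 uniform pixels over 800–940 nm). Under excitation
$\lambda_{ex}$, the Stokes shift of a pixel is

$$\tilde\nu \;=\; 10^7\left(\frac{1}{\lambda_{ex}} - \frac{1}{\lambda}\right)
\quad [\mathrm{cm}^{-1}],$$

so the 800–940 nm window corresponds to roughly 239–2100 cm$^{-1}$ under
785 nm excitation. Changing the excitation from 784 to 785 nm moves every
line's apparent position by the *excitation-step equivalent*
$10^7(1/784 - 1/785) \approx 16.25$ cm$^{-1}$ — exactly constant across the
axis, a convenient property of the reciprocal relation. On an axis
referenced to the 785 nm excitation, the 784 nm rendering of a line at
shift $s$ appears at $s - 16.25$ cm$^{-1}$.

## Processing chain

For each measurement locus, 50 spectra are acquired at each excitation.
The chain is fixed as: average the 50 repeats per excitation; z-score each
mean spectrum (population convention, divisor $N$ — the convention choice
is immaterial downstream since the two normalizations differ by a common
factor); subtract on the shared pixel grid. No per-repeat normalization and
no pre-interpolation is performed: both acquisitions share one
spectrometer, so the pixel grids are identical by construction. Resampling
onto a uniform Raman-shift axis (1 cm$^{-1}$ steps over the 550–1800
cm$^{-1}$ fingerprint window, referenced to 785 nm, linear interpolation)
happens once, at the purifier boundary.

Two recovery paths map the difference spectrum back to a background-free
Raman spectrum:

* **Classic shift-and-accumulate** (`classic_reconstruct()`): cumulative
  summation along the shift axis turns each doublet into a box-smeared copy
  of the line, centred half an excitation step below the true position; a
  least-squares line is subtracted to remove integration drift and the axis
  is re-centred by $+\Delta/2$. This linear estimator is kept as the
  comparison baseline: it is exactly correct for noise-free doublets but
  accumulates noise into a random walk, which is what the neural purifier
  improves on.
* **Convolutional encoder–decoder** (`purify()`): described next.

## The purifier network

The purifier is a one-dimensional U-Net: an encoder that halves the
resolution and doubles the channel count at each level, a mirrored decoder,
and skip connections that concatenate encoder features into the decoder at
matching resolution so fine positional detail survives the bottleneck. All
activations are ReLU except the final linear single-channel projection.
Defaults: 4 levels, kernel width 9, 8 base channels, 245k–ish learnable
parameters at the default width (the exact count is asserted in the test
suite by a layer-by-layer audit). The 1251-bin working axis is zero-padded
to 1280 so that four halvings stay integral, and cropped after inference.

Width was fixed at 8 base channels as a deliberate accuracy/runtime
trade-off: the mapping from doublet to line is nearly linear and local, so
the task saturates well below image-scale capacity, and the default
training budget (2000 synthetic pairs, 10 epochs, Adam at $10^{-3}$,
minibatch 32, mean-squared-error loss on unit-maximum targets) completes in
a few minutes on one CPU core while reaching held-out Pearson correlation
around 0.99 against clean truth. Training is implemented from scratch in
C++ (im2col + GEMM, single precision) and is a pure function of its
arguments: weight initialization (He-scaled) and batch order derive from
the configuration seed, so identical seeds give bit-identical models on a
given machine.

About 5% of training pairs are rendered background-only with a zero
target. This teaches the network to stay silent on signal-free input
rather than hallucinate library peaks — a failure mode that would
otherwise go unnoticed because ordinary training pairs always contain
lines.

## Synthetic cohort generator

No specimen spectra are distributed with this package; the generator is a
first-class module that emulates the statistical structure the analysis
assumes, with six tissue classes at the study's cohort composition
(9 neurofibroma, 12 skin, 6 nerve, 13 fat, 15 bone, 27 mucosa = 82 loci;
50 repeats per excitation gives 8,200 raw spectra).

* **Raman emission**: each class template is a list of Lorentzian lines
  (centre, FWHM 10–45 cm$^{-1}$, mean amplitude). Lorentzian is the natural
  line shape for Raman bands; the broad amide III (1200–1320 cm$^{-1}$) and
  amide I (1600–1670 cm$^{-1}$) envelopes are modelled as 2–3 overlapping
  wide Lorentzians. Per locus, each line's amplitude is drawn log-normally
  with the template mean and a coefficient of variation of 0.2 — a
  mid-range value for between-locus biochemical variability in soft
  tissue. Neurofibroma emphasizes protein and nucleic-acid signatures
  (1004/1038 phenylalanine, 1095/1338/1378 DNA-related, amide bands); fat
  and nerve are lipid-dominated (1073, 1300, 1440–1470); bone alone has the
  960 cm$^{-1}$ phosphate line; skin and mucosa share the protein pattern
  of neurofibroma with shifted weightings and are deliberately the hardest
  classes to separate.
* **Fluorescence**: a smooth two-Gaussian profile in detector wavelength
  whose peak height defaults to 20× the strongest Raman line (the "extreme
  interference" regime; the ratio is not quantified in the source setting,
  so a value deep in the fluorescence-dominated regime was fixed once),
  with log-normal per-locus height variation (CV 0.3, floored so
  fluorescence always dominates). The profile is a function of detector
  wavelength only, hence *identical at both excitations* — exact Kasha
  insensitivity. Real spectra retain small residuals; a
  `kasha_residual` knob (default 0) perturbs the background with
  excitation if that robustness is to be probed.
* **Detector**: 1024 uniform pixels over 800–940 nm (the physical
  spectrometer's pixel count is not public; 1024 is a standard CCD
  format), constant dark offset, per-pixel per-repeat Poisson counting
  noise, and an optional etaloning ripple fixed in pixel space (default
  amplitude 0).

Training-pair generation uses the exact aggregation identity
$\overline{X}_{1..50} \sim \mathrm{Pois}(50\lambda)/50$ to draw block
means directly, which is distributionally identical to averaging 50
rendered repeats at a fiftieth of the cost; full repeat blocks are still
rendered for cohort-level work.

What passing tests on this generator do *not* show: performance on real
tissue. The generator has no spatial heterogeneity within a locus, no
cosmic-ray spikes, no wavelength-calibration drift between acquisitions,
no detector nonlinearity, and exact Kasha insensitivity. End-to-end
accuracies on synthetic cohorts are a property of this pipeline under the
stated noise model, not a reproduction of any patient-derived number.

## Classification

Purified spectra restricted to 550–1800 cm$^{-1}$ are classified by PCA
followed by multiclass linear discriminant analysis under stratified
5-fold cross-validation (80%/20% splits). Leakage safety is structural:
within each fold, the training-row mean, the PCA basis, the retained
component count (smallest number explaining ≥ 95% of *training* variance,
capped at $n_{train} - n_{classes}$), and the LDA are all computed from
training rows only; test rows are centred with the training mean and
projected on the training basis. The test suite audits this by deleting
test rows (the fold model must not change) and by checking that
predictions are independent of the other rows in a test batch.

Binary panels report the tumor class against all physiological tissue
pooled and against each class separately, each panel restricted to the
rows of the two groups involved. Sensitivity is the true-positive rate of
the tumor class; specificity the true-negative rate of the physiological
side. AUC uses the Mann–Whitney rank formulation with midranks on pooled
out-of-fold posterior scores (per-fold averaging is the alternative; the
pooled form is the common choice when fold test sets are small, here 2–17
rows).

The stratified partition deals shuffled within-class indices round-robin,
so every fold's class mix mirrors the cohort and every locus is tested
exactly once; the partition is a pure function of (labels, k, seed).

## Peak annotation

`detect_peaks()` keeps local maxima whose apex height *and* topographic
prominence both exceed a threshold fraction of the spectrum maximum
(default 0.05). Purified spectra are baseline-free, so height and
prominence agree for isolated lines; the joint criterion keeps prominent
shoulders of strong bands while rejecting both tall-but-unprominent ripple
and low-lying noise maxima. Assignment matches single-line library entries
within 8 cm$^{-1}$ (about half a typical band width) and band entries by
containment, nearest entry winning ties. The 960 cm$^{-1}$ phosphate call
is deliberately absent from the assignment table: its presence as an
unassigned call is itself the bone-specific discriminator in this library.

## Numerical choices and degenerate inputs

* z-scoring a constant spectrum, empty shift windows, single-class
  datasets, confusion panels with an empty positive or negative margin,
  and untrained purifiers all raise typed errors rather than propagating
  NaN.
* Linear interpolation is used for all axis resampling; bins outside
  detector coverage are zero and the clipped range is reported on the
  rendered block.
* The difference operator is exactly antisymmetric; classic reconstruction
  is exactly linear (both are asserted as properties).
* Training determinism holds per machine (single device, fixed BLAS); the
  suite asserts bit-identical parameters for repeated runs in-session.

## Problem sizes used by the test suite

The suite trains the default purifier once (2000 pairs × 10 epochs,
roughly four minutes on one core) and shares it across tests; held-out
evaluation uses 150 pairs; the end-to-end benchmark runs ten full
82-locus cohorts; the permutation null uses 200 label permutations of one
cohort; the contrast-monotonicity property uses 3 contrast levels × 10
seeds of reduced 16-locus two-class cohorts with the classic
reconstruction path. These sizes were chosen to keep the whole suite at
desk scale while leaving the statistical assertions well-powered.

## Known limitations

* The purifier is trained only on the synthetic generator's distribution;
  applying it to spectra from a different instrument or background regime
  requires retraining (`train_purifier()` accepts any pair set).
* The classic baseline's axis re-centring assumes the constant-step
  geometry of a sub-nanometre excitation detuning; large detunings would
  need per-pixel compensation.
* Multiclass metrics beyond overall accuracy (macro-averages, per-class
  one-vs-rest panels for non-tumor classes) are not reported.
* The command-line layer (`serds_run()`, `inst/cli/serds.R`) writes plain
  delimited text only; no HDF5/JCAMP ingestion.
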