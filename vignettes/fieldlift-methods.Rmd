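---
title: "Methods: simulating paired-field NMR mixtures and learning the low-to-high-field conversion"
author: "fieldlift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating paired-field NMR mixtures and learning the low-to-high-field conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Benchtop NMR spectrometers (here modelled at 100 MHz proton frequency) are
affordable and maintenance-free but deliver lower spectral resolution and
signal-to-noise than superconducting high-field instruments (here 400 MHz).
Because scalar J-couplings are field-independent in Hz while chemical shifts
are field-independent in ppm, a multiplet that spans `J/f` ppm collapses
four-fold in ppm when the field is raised from 100 to 400 MHz, and lines of
fixed Hz width sharpen four-fold in ppm.  Overlapping low-field multiplets
therefore separate at high field — which is exactly what makes high-field
spectra easier to quantify, and what a learned low-field-to-high-field
(LF→HF) conversion must emulate.

`fieldlift` builds the whole study around that physics:

1. a parametric simulator that renders the *same* mixture at both fields on
   one shared ppm grid,
2. an augmentation workflow that adds the nuisance structure of real
   acquisitions (noise, shift jitter, baseline offsets, artifact peaks,
   metabolite dropout),
3. six sequence-to-sequence conversion networks and a quantification MLP,
   trained with MSE/Adam/early stopping,
4. an evaluation suite comparing conversion quality (per-spectrum MSE) and
   three quantification pipelines (direct LF-MLP, direct HF-MLP,
   convert-then-quantify) by mean absolute percent error.

## Spectral model

A metabolite is a named set of first-order multiplets; each multiplet has a
center (ppm), a list of couplings (Hz), a proton count, and a Lorentzian
full width at half maximum (Hz).  The weak-coupling splitting rule expands
each coupling into a symmetric doublet at ±J/(2f) ppm; coincident lines
merge, giving the binomial 1:2:1, 1:3:3:1, … patterns.  Rendering sums one
Lorentzian per stick line.

*Amplitude convention.*  Intensity units are fixed by declaring that a
1-proton singlet at 1 mM with a 1.0 Hz linewidth has unit peak height at
400 MHz; everything else follows by linearity.  Consequences worth knowing:

* the ppm-integral of a metabolite's spectrum is
  `conc × protons × π × γ_ref` with `γ_ref = 0.5/400` ppm, independent of
  field and linewidth — integrals are concentration-proportional, as in
  quantitative NMR;
* at equal concentration, low-field peaks are four-fold shorter and
  four-fold broader (in ppm) than their high-field counterparts.

*Limitations by design.*  Only first-order (weak-coupling) patterns are
produced.  Real 100 MHz spectra of strongly coupled spin systems show
second-order distortions (roofing, extra lines) that this simulator does not
reproduce; conclusions drawn from the synthetic corpora therefore concern
resolution and noise, not second-order effects.  There is no FID-domain
simulation, no relaxation, no solvent/pH shift model.

*Synthetic library.*  The package ships no downloaded reference spectra.
`synthetic_library(n)` returns `n` spin models (`SM01`, …) with parameters
frozen by an internal seed: shifts in 0.5–9.5 ppm, couplings 2–12 Hz, one to
four multiplets of plausible patterns per metabolite.  The 87-metabolite
library extends the 21-metabolite one; `unseen_library()` draws a disjoint
held-out set.  These are labelled synthetic stand-ins: they emulate the
*role* of database reference spectra (known multiplet structure per named
compound), not any particular compound.

## Mixtures and augmentation

A mixture draws one concentration per included metabolite uniformly from
1–50 mM; in the dropout half of a corpus each metabolite is independently
left out with probability 0.5.  Every spectrum receives a 2.96 mM 9-proton
reference singlet at 0.0 ppm (the TSP-d4 analogue), whose rendered peak
height normalizes the nuisance amplitudes:

| parameter | default | meaning |
|---|---|---|
| `noise_pp_frac` | 0.001 | uniform noise, peak-to-peak ≤ 0.1% of the reference height |
| `lf_noise_multiplier` | 1 (4 in adjusted-SNR corpora) | extra noise on the low-field member |
| `shift_max_ppb` | 3.4 | per-metabolite chemical-shift jitter bound |
| `baseline_max_frac` | 0.006 | constant baseline offset bound (±) |
| `max_singlets`, `max_triplets` | 3, 3 | artifact peaks at random shifts |
| `dropout_prob` | 0.5 | metabolite dropout (dropout half only) |
| `ref_conc` | 2.96 mM | reference singlet concentration |

Choices the configuration leaves open were resolved once and are fixed:

* *Jitter granularity* — the whole rendered component of one metabolite is
  translated (not individual peaks), matching how a pH or temperature change
  moves one compound's resonances coherently.  The shift is realized as a
  nearest-integer grid translation (3.4 ppb ≈ 15 points on the full 46,000
  point axis), avoiding interpolation artifacts.
* *Artifact shapes* — a 1-proton singlet, and a generic 1:2:1 triplet with
  J = 7.0 Hz that field-scales through the same stick-pattern machinery.
  Artifact amplitudes are concentration-equivalent draws from 1–50.
* *Pairing* — composition, jitters, artifact set and baseline offset are
  drawn once per pair and rendered at both fields; only the noise is drawn
  independently per field.  Anything else would either leak the target into
  the input (shared noise) or make the mapping ill-posed (independent
  compositions).
* *Noise normalizer* — within a pair, both fields' noise amplitudes are
  fractions of the *high-field* reference height (the pair's common
  intensity scale), so `lf_noise_multiplier = 4` means literally four times
  larger low-field noise on the shared scale.
* *Baseline sign* — symmetric ± draw; a one-sided offset would be trivially
  learnable.

A corpus is 10,000 all-present plus 10,000 dropout mixtures split
16,000:4,000 into train/validation by a seeded shuffle, plus a held-out
all-present test set (default 100 pairs; the desk protocol uses 50).
`(library, augmentation, corpus config)` determine every byte of the
persisted corpus directory.

## Architectures

All conversion networks map a length-46,000 intensity vector to a
length-46,000 vector (4,600 at desk scale); hidden activations are ReLU and
output layers are linear (targets contain negative noise excursions, so a
ReLU output would be mis-specified).

* **DAE** — dense 46000–2000–200 encoder, reciprocal decoder
  (≈ 185 M parameters at full scale).
* **CAE** — four 1-D conv layers of 16, 32, 64, 128 kernels (size 3,
  stride 1, padding 1), reciprocal decoder to one channel.  Taken literally,
  stride 1 with no pooling preserves spatial length everywhere; channel
  count is the only "compression".
* **U-Net** — the CAE plus one skip connection concatenating the encoder
  32-kernel activation onto the input of the decoder layer that produces 32
  kernels.
* **UNet-Chunks** — the U-Net applied independently to each of 46
  contiguous 1000-point bins, outputs concatenated.
* **TCN** — three residual temporal blocks (25, 50, 100 channels), each two
  causal dilated convolutions (kernel 2; dilations 1, 2, 4 by block;
  dropout 0.2) with a 1×1 residual projection where channel counts change,
  then a linear projection to one channel.  Receptive field
  `1 + (k−1)·2·(1+2+4) = 15` samples; causal padding is kept although
  spectra are not temporal, matching the standard reference design.
* **Transformer** — chunk into 46 tokens of 1000 points, linear embedding
  to 512, six post-norm encoder layers (8 heads, feed-forward 2048, dropout
  0.1 on attention weights and sublayer outputs), per-token linear head back
  to 1000, concatenate.  No positional encodings anywhere: chunks keep
  their chemical-shift order by construction, so the encoder is exactly
  permutation-equivariant with dropout off — a property the test suite
  asserts to numerical precision.
* **Quantification MLP** — dense 46000–200–K, outputs read as mM per
  library metabolite; small negative estimates are clamped to zero only at
  reporting time.

Weight initialization is Glorot-uniform with zero biases, drawn under the
spec seed, so `(spec, seed)` reproduces a network bit for bit.  Because no
deep-learning framework is available in the target environment, the forward
and backward passes are implemented in the package itself (dense and
attention algebra over BLAS; convolution/ReLU/dropout kernels in C++), and
every backward pass is validated against central finite differences in the
test suite's development history; the training loop's correctness is
guarded by the convex-fit, early-stopping, and restore-best tests.

## Training protocol

MSE loss over all points; Adam at the conventional default step size 0.001
with moments (0.9, 0.999); at most 300 epochs, stopping when 25 epochs pass
without a *strict* improvement of validation loss (ties do not reset
patience); the best-validation parameters are restored on return.  Batch
size is not part of the published protocol; the default is 16 and it is
exposed in `train_config()`.  Per-epoch shuffling and all dropout masks
derive from the training seed, so identical seeds give identical histories.
No input normalization is applied by default — the generator's amplitude
convention already puts all corpora on one bounded scale — but
`normalize = TRUE` enables max-scaling for experimentation.

## Evaluation

* `spectrum_mse_report()` — per-spectrum MSE of `predict(lf)` against the
  paired ground-truth HF spectrum, plus the arithmetic mean (the Table-1
  analogue).
* `quant_mape()` — `100/K · Σ |est−truth|/truth`, defined only for strictly
  positive truth; the fixed-concentration test spectra have all metabolites
  present.  Absent metabolites (zero truth) are never scored by MAPE.
* `convert_then_quantify()` — the two-stage pipeline
  `HF-MLP(converter(LF))`.
* A corpus's uniform target noise with peak-to-peak amplitude `a` puts an
  analytic floor of `a²/12` under any model's achievable test MSE;
  the suite uses it as a leakage guard.

## The desk-scale replication

The full-scale study (20,000 × 46,000-point corpora, a 185 M-parameter DAE,
a six-layer transformer) is a GPU-scale computation.  `desk_protocol()`
freezes a reduced configuration that reproduces the study's *qualitative*
findings on one CPU in minutes:

* 10 synthetic metabolites, 4,600-point axis (same ppm range), linewidth
  2.0 Hz — chosen so the 400 MHz FWHM (5 ppb ≈ 2.2 grid steps) is resolved
  on the coarser grid; with 1 Hz lines the high-field spectrum would be
  under-sampled spikes;
* 1,500/300/50 train/validation/test pairs;
* reduced architectures: DAE 4600–460–46; CAE/U-Net/UNet-Chunks/TCN at
  their standard channel counts; transformer with 2 layers, 128 embeddings,
  4 heads, feed-forward 512 (keeping the 4× d_model ratio), 46 × 100
  chunking;
* per-architecture epoch budgets proportional to per-epoch cost, all within
  a 50-epoch allowance: the dense and transformer networks are cheap per
  epoch and receive the larger budgets, while the stride-1 convolutional
  autoencoders — whose per-epoch cost exceeds the transformer's by an order
  of magnitude — receive single-epoch budgets.  The budgets were fixed
  after one calibration run and are not tuned per seed;
* quantification: a 1,000-pair no-triplet corpus (800/200 split),
  4600–100–10 MLPs, scored at 5/25/50 mM; the acceptance threshold
  (direct MLP MAPE < 15% at 25 mM on noiseless inputs) was frozen after the
  same calibration run.

What passing desk-scale tests shows: the implementation learns, the
transformer's chunked attention solves the resolution-lifting task where
the baseline architectures do not, and quantifying directly at low field is
at least as accurate as converting first — the study's directional
findings.  What it does not show: any particular absolute MSE/MAPE value at
full scale (those depend on data source, scale, and seeds), behaviour on
strongly coupled real spectra, or robustness to acquisition artifacts
outside the augmentation list.

## Numerical notes

* Coincident stick lines are merged with a 10⁻⁹ ppm tolerance
  (weight-averaged positions), which realizes exact binomial patterns for
  repeated equal couplings.
* ReLU backward uses the `output > 0` subgradient; at exactly-zero
  pre-activations (possible at zero-bias initialization when an entire
  channel's input is zeroed) the zero subgradient is taken.
* The chemical-shift jitter is an integer grid translation; vacated edge
  points are zero-filled.  On the desk axis 3.4 ppb is at most ±1 grid
  step.
* Corpus persistence is a directory of serialized matrices plus a JSON
  manifest (seed, config and library hashes, per-file checksums); writing
  is deterministic, and the test suite asserts byte-identical re-builds.
* All randomness flows through `with_seed()`/derived stream seeds; the
  package never perturbs the caller's RNG state.

## Reduced problem sizes used by the shipped checks

The test suite and the acceptance script run the desk protocol exactly as
stated above (1,500/300/50 conversion pairs, 1,000 quantification pairs,
4,600-point axis).  Unit and property tests use further-miniaturized
networks and corpora (tens of points, tens of samples) whose expected
values come from closed forms, brute-force enumeration, or independent
oracles computed in the tests themselves.
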