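---
title: "Estimating brain-to-brain synchrony with the diagonal cross-bispectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating brain-to-brain synchrony with the diagonal cross-bispectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b2bsync)
```

## The problem

Hyperscanning records EEG from two interacting people simultaneously and
asks how coordinated their neural signals are. `b2bsync` implements a
streaming estimator of that coordination for a minimal, wearable montage:
four dry electrodes per subject (ear cups A1/A2, central scalp C3/C4) at
250 Hz. The design constraint throughout is that every quantity must be
computable window-by-window as data arrive — no forward-looking filters,
no cross-window spectral averaging — so that the same code path serves
live acquisition and offline replay identically.

## The estimation pipeline

### Windowing

Both subjects' streams are cut into contiguous, non-overlapping 4 s
windows on a shared clock (1000 samples, 500 one-sided DFT bins, 0.25 Hz
resolution, 125 Hz Nyquist). Window 0 is discarded: process startup can
cost up to a second, so the first window's content is not trusted. A
window is consumed only once both subjects' copies exist; the session
scheduler is a deterministic single-threaded loop that polls both sources,
and `stream_source()` is the seam where a concurrent live adapter would
plug in. A source whose window indices disagree with the clock aborts the
session (desync) rather than silently shifting alignment.

### Per-window conditioning

Each channel of each window passes through:

1. **Linear detrend** — subtract the least-squares line; removes DC and
   slow electrode drift exactly within the window.
2. **Bandpass** — 4th-order Butterworth, 0.1–100 Hz. "4th order" is the
   design parameter handed to the bandpass transform (a degree-8
   polynomial), the convention of the common scientific filter-design
   APIs.
3. **Notch** — Butterworth band-stop 58–62 Hz, order 4, against North
   American mains interference. The notch's exact width and order, and
   the bandpass→notch ordering, are not dictated by the estimator; both
   are fixed here (and recorded in the session config) for determinism.

Filtering is causal and per-window with zero initial state: windows are
independent, restartable units, at the accepted cost of a short edge
transient. Zero-phase (forward–backward) filtering would be preferable
offline but is impossible in a streaming setting, so it is deliberately
not offered — replay must reproduce the live path bit-for-bit.

Optionally the scalp channels are then re-referenced to linked ears,
`C3' = C3 − (A1+A2)/2` and `C4' = C4 − (A1+A2)/2`, dropping the ear
channels. Re-referencing is a linear operation applied after filtering;
it commutes with the (linear) conditioning stages, which the test suite
asserts numerically.

### Diagonal cross-bispectrum

For one cross-subject channel pair and window `l`, with full-length DFTs
`X_a`, `X_b`:

```
B[i] = log( max( |X_a[i] · X_b[i] · conj(X_c[2i])|, 1e-12 ) ),   i = 0 … 499
```

- **Diagonal slice.** The full bispectrum is a two-frequency object
  `B(f1, f2)`; restricting to `f1 = f2` gives one value per bin and keeps
  the per-window cost linear in the number of bins. Sensitivity to
  quadratic phase coupling (energy at `f` interacting with energy at
  `2f`) is retained, which is exactly the structure the synthetic
  generator injects.
- **Sum-frequency indexing.** `2i` is read from the *full-length* DFT, so
  for `i < N/2` the index is always valid and no aliasing rule is needed.
- **Which subject supplies the conjugated factor** is ambiguous in the
  underlying formulation (the factors are printed without subject
  subscripts); the package defaults to subject *b* (`conj_from = "b"`),
  mirroring the cross-bispectrum convention in prior hyperscanning work,
  and exposes `conj_from = "a"` as a config flag. The choice shifts which
  subject's harmonic structure is probed but not the detection logic.
- **Log and floor.** The natural log compresses the enormous dynamic
  range of the triple product; the magnitude is clamped at `1e-12` first
  so silent channels produce a finite floor instead of `-Inf`. The log
  base is immaterial downstream because normalization is scale-tolerant.

Rows are laid out in row-major combination order (subject-1 channel
slowest), so the per-window matrix is 16 × 500 for the raw montage and
4 × 500 referenced; CSV column order is stable across runs.

### Calibration and normalization

The first minute of post-discard windows (15 windows by default;
configurable, always a whole number of windows) is recorded while the
dyad is explicitly *not* interacting, and the element-wise mean of those
raw matrices becomes the baseline `B̄`. Each later window is normalized
element-wise:

```
n = (B − B̄) / (|B| + |B̄| + 1e-12)
```

This bounded relative difference is the package's choice of normalization
satisfying the estimator's stated output contract: `n` is strictly inside
(−1, 1), exactly 0 where `B = B̄`, and carries the sign of `B − B̄`. The
`1e-12` guard makes the all-zero corner well-defined. Normalization is
applied per-bin *before* band averaging, so band values are means of
bounded quantities and inherit the bound.

### Band aggregation

Normalized values are averaged over Delta (0.1–4), Theta (4–7), Alpha
(8–12), Beta (13–30) and Gamma (30–50 Hz). The printed band edges are
taken literally:

- Closed intervals; a bin on an edge shared by two bands (4 Hz, 30 Hz)
  goes to the **higher** band — a deterministic tie-break so band means
  are reproducible.
- The gaps 7–8 Hz and 12–13 Hz are genuinely unassigned (3 bins each at
  0.25 Hz): whether they are intentional or typographical in the source
  band table is unknowable from here, so they are excluded from every
  band mean rather than silently absorbed.

### The comparison grid

Per dyad and per (band, combination) cell, the per-window indices of two
task conditions are compared with one-sided Wilcoxon rank sum
(Mann–Whitney) tests — *unpaired*, because the two tasks contribute
independent window samples, not paired differences. The exact null
distribution is enumerated when the combined sample size is ≤ 12 with no
ties; otherwise the normal approximation with mid-rank tie correction and
continuity correction is used (both routes agree within 0.02 on tie-free
6+6 samples, which the suite cross-checks against an independent
enumeration oracle). Family-wise error is controlled by Bonferroni:
with 8 dyads × 5 bands × 4 combinations = 160 cells at α = 0.05 the
per-test threshold is 3.125 × 10⁻⁴. When several session directories are
compared per dyad, per-window values are pooled across repetitions by
default; per-repetition comparison is available by passing repetitions as
separate dyads.

## The synthetic dyad generator

Real validation data for this estimator requires two headsets and two
people; the generator exists so every stage is testable without either.
Each channel is a sum of:

- one band-limited oscillator per EEG band (2, 6, 10, 20, 40 Hz at
  20/10/15/8/5 µV — the usual decline of amplitude with frequency in
  scalp EEG), each with an independent random phase per subject and
  channel;
- pink (1/f) noise at 10 µV RMS, built by spectral shaping of seeded
  white noise;
- 60 Hz line contamination at 5 µV; and
- a 0.5 µV/s linear drift.

Cross-subject coupling is injected per segment as a shared oscillator at
`f0 = 35 Hz` plus a **phase-locked harmonic at 70 Hz** (half amplitude),
added to both subjects' C3 and C4 with a per-segment random phase common
to the dyad. The harmonic matters: the estimator's sum-frequency factor
`X(2f)` rewards exactly this f/2f structure, so the coupling amplitude κ
is a controllable ground truth for detection power. The default
κ = 25 µV is five times the gamma oscillator amplitude; 35 Hz keeps the
fundamental inside Gamma while the 70 Hz harmonic clears the 58–62 Hz
notch.

What the generator does **not** emulate: eye blinks, EMG bursts, volume
conduction, device dropout, or millisecond clock skew between headsets.
Passing tests therefore demonstrate the estimator's arithmetic and its
detection behaviour under controlled coupling — not robustness to
real-world artifacts.

## Study conditions used in simulations

The packaged experiments mirror the validation protocol the estimator was
built for: 60 s calibration (fifteen 4 s windows), 10-minute tasks (150
windows each), referenced 2-channel mode, eight dyads for the comparison
grid, with coupling present only in the collaboration-labelled task. The
`tiny` fixture preset (90 s: 1 discarded + 15 calibration + 6 task
windows) exists for fast round-trip checks, and the detection property is
additionally exercised at reduced scale (24 s calibration, 6+6 task
windows per run, 50 seeded runs) where the effect is still separable.

Two observations from these simulations, both recomputed by the
acceptance script rather than asserted as constants: with 150-window
tasks the per-dyad right-tailed detection of the coupled Gamma cell at
α = 0.05 is essentially certain, and some Beta-band cells also become
significant — the sum-frequency factor picks up the shared 35 Hz
component at `f = 17.5 Hz`, a genuine (and instructive) property of the
diagonal estimator, not a defect.

## Numerical choices and degenerate inputs

- Magnitude floor `1e-12` before the log; normalization guard `1e-12`.
- Windows with fewer than 2 samples cannot be detrended (error); filter
  corners at or above Nyquist are rejected at construction.
- An empty recording yields a zero-window source and the session refuses
  to calibrate; a session needs at least `1 + calibration` windows, and
  zero task windows after calibration is legal (empty band summary).
- A trailing partial window in a replay file is dropped and counted.
- All-zero windows propagate finitely: the bispectrum hits its log floor,
  normalization maps a window equal to the baseline to exactly 0.
- Determinism: a fixed seed drives every random draw (generator phases and
  noise); identical configs and inputs give byte-identical CSVs, which
  the suite checks by file hash.

## Known limitations

- The diagonal slice cannot see cross-frequency coupling off `f1 = f2`,
  and log-magnitude discards phase: coupling is detected through
  magnitude elevation relative to calibration, not through phase
  statistics proper.
- Per-window causal filtering leaves edge transients inside each window;
  they are identical across windows and cancel in the calibration
  contrast, but absolute raw bispectrum values include them.
- The normalization form is one of several satisfying the bounded/signed
  contract; absolute index values are not comparable across different
  normalizations, only within a pipeline.
- Millisecond-scale inter-device skew is out of scope for replay; the
  session aborts on index-level desync instead of attempting repair.
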