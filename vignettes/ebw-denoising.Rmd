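---
title: "Entropy-based wavelet denoising of frequency-scan ion-trap transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based wavelet denoising of frequency-scan ion-trap transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebwdenoise)
```

## The observation model

A charge-sensing detector in a frequency-scan linear ion trap records

$$S(t) = S_x(t) + N_{RF}(t) + N_{AC}(t) + N_w(t),$$

where $S_x$ is the noise-free ion signal, $N_{RF}$ and $N_{AC}$ are pickup
of the trap's swept RF drive and of the auxiliary resonance-ejection AC
field, and $N_w$ is zero-mean Gaussian white noise. The pickup is modelled
as linearly coupled sinusoids,

$$N_S(t) = \beta A_{RF}\sin\varphi_{RF}(t) + \gamma A_{AC}\sin\varphi_{AC}(t),$$

with dimensionless coupling coefficients $\beta,\gamma$ and drive
amplitudes $A_{RF}, A_{AC}$ in detector intensity units. The phases are
phase-continuous linear chirps,

$$\varphi(t) = 2\pi\left(f_0 t + \frac{(f_1-f_0)\,t^2}{2T}\right),$$

so the instantaneous frequency runs linearly from $f_0$ to $f_1$ over the
scan duration $T$ with no phase resets (stepwise frequency programming
produces jagged waveform edges and periodic baseline spikes; a continuous
phase scan is the standard remedy, and is assumed here since only the
linear proportionality of the pickup is pinned down physically). Scan
modes `RF`, `AC` and `RF+AC` zero the terms that are not driven.

The ion peaks themselves are modelled as Gaussians in sample index. No
analytic peak-shape model is implied by the physics of image-charge
detection at this level of description; a Gaussian with configurable width
is the conventional stand-in, and every downstream operation is agnostic
to the choice.

## Wavelet decomposition

The transient is decomposed along the dyadic approximation branch of a
two-channel filter bank (the octave-band path of a wavelet packet tree):
one approximation band $cA_J$ and detail bands $cD_1,\dots,cD_J$. Band
$cD_i$ covers the frequency octave $(f_s/2^{i+1}, f_s/2^i)$.

**Depth.** The theoretical maximum is $\lfloor\log_2 L\rfloor$ (17 for
$L = 200{,}000$). The operational default is $J = 11$: beyond that depth
the coefficient counts drop low enough that peak structure distorts, and
levels 12+ carry no interference. Both the default and the cap are
exposed.

**Padding.** The default boundary mode is *periodized*: odd-length bands
are extended by repeating the last sample, and filtering is circular, so
band lengths follow the $\lceil L/2\rceil$ recursion and $cD_i$ of a
200,000-point transient holds exactly $200{,}000/2^i$ coefficients at the
shallow levels ($cD_1$ has 100,000). Deeper down the recursion gives
98 coefficients for $cA_{11}$. A *symmetric* (half-point reflection) mode
is available for users who need better edge fidelity; its bands are
slightly longer ($\lfloor (L+F-1)/2\rfloor$ for filter length $F$).

**Catalogue.** 105 filter banks: Haar, Daubechies db1–db38, Symlets
sym2–sym20, Coiflets coif1–coif17, and the 15 biorthogonal spline pairs
with their reverse-biorthogonal twins. The filters are the standard
published coefficient tables, stored as plain text under `inst/extdata`;
reverse-biorthogonal banks swap the analysis/synthesis low-pass pair, and
high-pass filters follow the alternating-sign quadrature-mirror relations.
Every catalogue entry round-trips (decompose, then reconstruct) to better
than $10^{-8}$ relative error at all permitted depths; this is asserted in
the test suite. The discrete Meyer wavelet is deliberately absent: its
finite-impulse-response approximation is only approximately orthogonal
and reconstructs with roughly $10^{-3}$ relative error, which would break
the perfect-reconstruction contract.

**Numerical caveat.** For orthogonal families, band energies sum to the
signal energy (Parseval) *exactly* only when every level has even length.
The odd lengths that appear in the $\lceil L/2\rceil$ recursion of a
200,000-point transient (1563, 391, ...) duplicate one sample each, and
the accounting identity then holds only to about $10^{-5}$ relative. The
energy-conservation assertions therefore use dyadic lengths; nothing in
the denoising path depends on exact Parseval.

## Mother-wavelet selection by ESER

For each candidate wavelet and each detail level $i$ the band is turned
into a probability distribution $p_k = c_k^2 / \sum_k c_k^2$, and

$$E_i = \sum_k c_{i,k}^2, \qquad
  H_i = -\sum_k p_k \log_2 p_k, \qquad
  R_i = E_i / H_i .$$

High $R_i$ means the wavelet concentrates the band's energy in few
coefficients (high energy, low complexity): it represents the transient's
structure compactly, which is what makes thresholding selective. The
logarithm base only scales all entropies by a constant and cannot change
the ranking; bits are used. The approximation band is excluded from the
ranking: selection is driven by the detail coefficients, where the
noise-related microstructure lives.

Two aggregation policies turn the per-level table into one name:
`max-any-level` (default) picks the wavelet attaining the single highest
$R_i$ anywhere, mirroring per-level evidence with a highest-bar winner;
`sum-over-levels` ranks by $\sum_i R_i$. Both are exposed because neither
dominates conceptually; on strongly interference-laden transients they
typically agree. All-zero bands have $H = 0$, an undefined ratio; they are
flagged degenerate and excluded rather than treated as infinitely good.
Ties break lexicographically so that results are reproducible.

Selection is invariant to rescaling the input (all ratios scale by
$c^2$), which the suite checks, so detector gain does not influence the
chosen wavelet.

## Thresholding

Each filtered detail level receives the universal threshold with a
median-based scale,

$$T_i = \frac{\mathrm{median}(|c_i|)}{0.6745}\,\sqrt{2\ln N_i},$$

computed independently per level and applied as a rigid criterion: hard
filtering (default) zeroes $|c|\le T_i$ and keeps survivors untouched;
soft filtering additionally shrinks survivors by $T_i$. A coefficient
exactly at the threshold is zeroed under both rules (strict-inequality
keep), which makes results bit-reproducible. The median statistic is what
makes the rule adaptive in the interesting way:

* in a band **dominated by swept interference**, the median tracks the
  interference amplitude, $T_i$ exceeds essentially every coefficient,
  and the whole band is cleared — the interference is removed;
* in a **quiet band**, the median sits at the white-noise floor and $T_i$
  is the classical universal threshold, removing just the noise.

The default filtered levels are $cD_1$–$cD_6$. Swept RF/AC interference
concentrates there; extending filtering to all 11 levels buys a little
more S/N but can suppress the low-frequency components that carry the
peaks, distorting the spectrum, so the conservative six-level default is
the practical recommendation and the full range remains available.

The comparator implemented alongside (`wb_denoise`) is the classic
shallow scheme: db4, four detail levels, one *blind* global threshold
estimated from $cD_1$ alone and applied hard everywhere. Its failure mode
is structural: when the interference lives in bands other than $cD_1$,
the blind threshold is calibrated on white noise and cannot touch the
interference. The benchmark in the test suite exists to demonstrate
exactly that separation.

Any charge-to-voltage conversion applied before S/N computation is a
scalar gain; the improvement percentage is invariant to it, so the
package models it as an optional configurable scalar and nothing more.

## Baseline correction and S/N

The baseline estimate is a morphological opening: a running minimum
(erosion) followed by a running maximum (dilation) with a flat structuring
element, computed in O(n) by block prefix/suffix extrema, with edge
replication at the boundaries. Opening removes structures narrower than
the element and never exceeds the signal, so the corrected transient is
non-negative. The default window is 1% of the record length forced odd
(2,001 samples at $n = 200{,}000$): wide relative to peak widths, narrow
relative to baseline drift. Opening is idempotent, which the suite
asserts, and the vectorized implementation is checked against a direct
sliding min/max oracle.

S/N is estimated as (peak-window maximum minus noise-window median)
divided by the noise-window standard deviation, clamped at zero; a
zero-noise window is flagged as infinite S/N rather than an error. The
estimator and the window placement are deliberate package-level choices —
no standard definition exists at this level — and both windows are
explicit, configurable inputs. The improvement metric is

$$\Delta = 100\cdot\frac{S/N_{den} - S/N_{raw}}{S/N_{den}},$$

normalized by the *denoised* S/N; the three published raw/denoised pairs
(3.08 → 5.87, 9.62, 10.7 giving 47.5%, 68%, 71.21%) are all consistent
with this denominator and serve as exact arithmetic fixtures in the
suite.

## The synthetic study profile

`default_profile()` fixes the conditions used across the tests and the
benchmark:

| parameter | value | rationale |
|---|---|---|
| length / rate | 200,000 samples at 2 MHz (0.1 s) | operating record size; rate comfortably above the RF sweep |
| mass axis | 25–200 kDa, linear | annotation matching the scanned range |
| peaks | charge states +1..+5 of a 150 kDa analyte, amplitudes 1.0 → 0.3, width $\sigma$ = 300 samples | decreasing amplitude with charge; widths give ~10 Da-scale features |
| RF sweep | 480 → 60 kHz, coupled amplitude 0.4 | "hundreds to tens of kHz"; dominates bands $cD_2$/$cD_3$ |
| AC sweep | 240 → 30 kHz, coupled amplitude 0.15 | resonance-ejection AC tracking at half the RF frequency, weaker pickup |
| white noise | $\sigma = 0.05$ | raw single-charge S/N in the low single digits |
| noise window | samples 0.32–0.45 of the record | peak-free stretch where RF sits in $cD_2$ and AC in $cD_3$ |
| peak window | samples 0.70–0.73 | brackets the singly-charged peak |

The geometry is chosen on physical grounds: the sweep endpoints put the
interference's instantaneous frequency inside $cD_2$/$cD_3$ for most of
the scan, which is the regime in which a median threshold clears those
bands, while the peaks (far slower features) live at levels 9 and deeper,
untouched by six-level filtering.

What the simulator does **not** emulate: drive-waveform harmonics and
nonlinear pickup, detector ringing, non-Gaussian (shot-like) noise,
charge-state-dependent peak shapes, and the mass-dependent nonlinear
frequency-to-m/z mapping (the mass axis is a linear annotation only).
Passing the synthetic benchmark therefore demonstrates the machinery —
band accounting, adaptive thresholds, selection, reporting — under the
stated model, not performance on any particular instrument's raw data.

## Test and benchmark sizes

Unit tests run at lengths 16–65,536 so the whole suite stays fast;
transform contracts and the end-to-end benchmark run at the full 200,000
samples. The benchmark uses 20 seeded replicates of the default profile
and asserts: median S/N improvement of the entropy-based method positive
and at least the comparator's, and RMSE against the known clean signal
reduced in at least 95% of replicates. Transform correctness is pinned by
frozen coefficient fixtures computed with an independent reference DWT
implementation, by perfect-reconstruction sweeps over the catalogue, and
by Parseval checks for orthogonal families at dyadic lengths.

## Known limitations

* Hard thresholding with a median-based scale removes swept interference
  only from bands where it dominates the occupancy; interference that
  spends little time in a band survives there. This is intrinsic to the
  rule, not to the implementation; the default profile documents the
  regime where the method is effective.
* The universal-threshold constant $\sqrt{2\ln N}$ is the canonical
  choice; no level-dependent rescaling heuristics are offered.
* Periodized padding wraps the record ends; transients whose ends differ
  grossly should use the symmetric mode.
* The ESER aggregation rule (max vs. sum) is a genuine free choice; both
  are reported so users can inspect the full ranking rather than trust a
  single argmax.
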