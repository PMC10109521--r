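---
title: "Generalized phase locking analysis: model, estimation and significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized phase locking analysis: model, estimation and significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpla)
```

## The problem

Modern electrophysiology records spiking activity from dozens to hundreds of
units simultaneously with a comparable number of local field potential (LFP)
channels. Classical spike--field coupling analysis quantifies, one pair at a
time, how spike timing relates to the phase of a band-limited LFP
oscillation; with $n_s$ units and $n_c$ channels this produces
$n_s \times n_c$ complex numbers per frequency band, which quickly becomes
uninterpretable. This package implements a multivariate reduction of that
table: the full complex coupling matrix is summarized by its leading
singular triplet, giving one scalar coupling strength (the *generalized
phase locking value*, gPLV), one complex weight per LFP channel (the *LFP
vector*) and one per unit (the *spike vector*).

## Coupling statistics

For unit $m$ with pooled spike sample indices $\{t_j\}$ (over all trials)
and channel $n$ with band-limited analytic signal $L_n(t) = a_n(t)
e^{i\phi_n(t)}$, two pairwise statistics are available:

* **PLV mode** -- the phase locking value
  $\mathrm{PLV}_{nm} = \frac{1}{N_m}\sum_j e^{i\phi_n(t_j)}$:
  amplitude-blind, modulus bounded by 1, directly interpretable as locking
  strength and preferred phase.
* **c mode** -- $c_{nm} = \frac{1}{\sqrt{N_m}}\sum_j L_n(t_j)$: keeps the
  oscillation amplitude (spikes during strong oscillations count more) and
  uses the $1/\sqrt{N}$ normalization under which each entry has unit
  variance when spiking is independent of a whitened LFP. This is the form
  required by the analytical significance test.

The coupling matrix $C$ (channels $\times$ units) collects one statistic
per pair; its SVD $C = U D V^H$ gives the gPLV $d_1$ and the vector pair
$(u_1, v_1)$. Since $(u_1 e^{i\theta}, v_1 e^{i\theta})$ is an equally valid
factorization, the free global phase is fixed by rotating both vectors so
the mean LFP-vector coefficient has zero phase; the phase of the mean spike
vector then reads directly as the overall spike--LFP shift $\Phi_d$.
In c mode the spike vector is additionally divided entrywise by
$\sqrt{N_m}$ (undoing the count normalization) and renormalized, and the
LFP vector can be mapped back from whitened to electrode space with the
least-squares unwhitening operator.

## Preprocessing

LFP trials are band-pass filtered with a zero-phase (forward--backward)
Butterworth filter of order 4 per direction and converted to analytic
signals with the Hilbert transform. The filter family and order are not
essential to the method and are configurable; the band edges are the
scientifically meaningful choice, trading phase-estimation accuracy
(narrow band) against temporal fidelity (wide band). Because
forward--backward filtering and the Hilbert transform both distort trial
edges, a margin of 3 cycles of the band's lower edge (configurable) is
discarded from each trial end before any coupling is computed.

Whitening is a *reduced-rank* operation: the number of components
$n_c^{\mathrm{eff}}$ is chosen once, as the smallest rank explaining 99% of
the variance of the all-trial covariance (threshold configurable), and each
trial is then projected on the leading eigenvectors of *its own* covariance
and scaled by their inverse square-root eigenvalues. Truncation avoids
amplifying noise components, and per-trial eigendecompositions remove
across-trial variability; each whitened trial has exactly identity
covariance on the retained components. Whitening is optional: it is
required by the analytical test, while PLV-mode analyses with surrogate
testing run in the original channel space.

## Significance

Two tests are provided.

**Spike-jitter surrogates.** Each surrogate redraws spike times uniformly
within contiguous windows anchored at the trial start (`interval_jitter`),
or circularly shifts all units jointly per window
(`group_preserved_jitter`, which preserves the fine cross-unit spike
correlations while destroying locking to the LFP). The window defaults to
one cycle of the band's center frequency: rate fluctuations slower than one
cycle survive, locking in the analyzed band does not. The p-value uses the
add-one rule $p = (1 + \#\{d_1^{\mathrm{surr}} \ge d_1\})/(1 + n)$, so it
is never exactly zero. Window partitioning keeps the last, possibly
partial, window, whose spikes are jittered within the partial span; both
schemes preserve per-window, per-unit spike counts exactly.

**Analytical (random-matrix) test.** With whitened LFP and c-mode entries,
the null coupling matrix has approximately iid unit-variance complex
entries, so the eigenvalues of $S = \frac{1}{n_u} C C^H$ follow the
Marchenko--Pastur law with ratio
$\alpha_{\mathrm{eff}} = n_c^{\mathrm{eff}}/n_u$, supported on
$[(1-\sqrt{\alpha})^2, (1+\sqrt{\alpha})^2]$. Coupling is declared
significant when the largest eigenvalue exceeds the upper edge
$\theta_{DET} = (1+\sqrt{\alpha_{\mathrm{eff}}})^2$, i.e. when
$\mathrm{gPLV} > \sqrt{n_u\,\theta_{DET}}$. The number of eigenvalues above
$\theta_{DET}$ (counted downward, stopping at the first failure) estimates
the number of neuronal populations coupled to distinct rhythms. The test
costs one SVD -- no surrogates -- which is what makes it attractive for
large probes. The scaling of $S$ by $1/n_u$ is the one under which the
null spectrum matches the MP law in our null simulations and under which
the gPLV bound above is self-consistent.

## Synthetic benchmarks

The generators produce everything the validation studies need, so no
external data is required.

* `gen_lfp()` mixes unit-amplitude oscillatory components (optionally with
  a Tukey-windowed transient envelope) across channels with a weight
  matrix, plus white channel noise.
* `gen_locked_spikes()` draws inhomogeneous Poisson spikes with rate
  $\lambda(t) = \lambda_0 (1 + \kappa \cos(\phi(t) - \phi_0))$, clipped at
  zero. $\kappa = 0$ is no coupling, $\kappa = 1$ silences the
  anti-preferred phase ("perfect" coupling); for a constant envelope the
  exact pairwise coupling against the oscillation's own phasor is
  $\mathrm{PLV} = (\kappa/2) e^{i\phi_0}$, which serves as ground truth for
  signal-to-noise comparisons (`snr_of_estimate()`). Spike counts are drawn
  per LFP sample as Poisson variables with mean $\lambda(t)/f_s$, so the
  unit-variance null theory applies exactly.
* `gen_scenario()` builds the four canonical single-channel illustrations
  (global synchrony at the oscillation trough, a sequential discharge with
  phases spread over 180 degrees, three phase clusters, and an uncoupled
  control).
* `gen_multipop()` partitions units into non-overlapping assemblies, each
  locked to its own rhythm in a narrow range (11--15.5 Hz by default), with
  Gaussian mixing of all rhythms across channels. The noiseless coupling
  matrix has rank equal to the number of assemblies.

Two generator choices deserve comment. First, the benchmark LFP is
*oscillation-dominated* within the analysis band (default channel noise SD
0.1 against oscillation power $\approx 0.5$): the retained whitened rank
then stays close to the number of rhythms. This matters because the
analytical test's sensitivity is governed by the
Baik--Ben Arous--Péché-type transition: a planted coupling of squared
singular value $u \cdot n_u$ only separates from the bulk when $u >
\sqrt{\alpha_{\mathrm{eff}}}$. With broadband-noise-dominated LFP
(`noise_sd` around 0.5), $n_c^{\mathrm{eff}}$ grows to most of $n_c$ and
weak couplings (strength 0.05 at desk-scale spike counts) are
*undetectable in principle*; with oscillation-dominated mixtures the
benchmark reproduces majority detection at strength 0.05 with 240 s of
data at 20 Hz unit rates. Second, the per-sample Poisson draw means phases
are quantized at the sampling rate (125 Hz default, about 9 samples per
cycle in the benchmark band); the resulting attenuation of locking is
below 2% and ignored.

What these simulations do *not* emulate: refractoriness and bursting,
spike-sorting errors, non-Poisson count variability, nonstationary rates
(beyond the transient envelope), volume-conducted spike waveform leakage
into high-frequency LFP, and electrode geometry. Passing benchmarks
therefore validate the estimator and its calibration under the stated
generative model, not robustness to these real-data complications.

## Neural mass and field models

To interpret GPLA features mechanistically, the package ships linearized
two-population (excitatory/inhibitory) models.

`mass_phase_curves()` gives the closed-form frequency response of the
E--I loop with configurable synaptic kernels, and the phases of E and I
rates relative to a chosen LFP proxy (exogenous input, recurrent EPSP, or
IPSP). Two stereotyped configurations matter: with instantaneous synapses
(`mass2d_params()`) the E--I phase difference grows monotonically with
frequency and never changes sign, whereas an alpha-kernel lagged I--I
synapse (`massalpha_params()`) -- the interneuron-network-resonance
mechanism -- reverses the E--I lead--lag relation across the frequency
axis. The stability of a configuration is checked via the eigenvalues of
the augmented linear state matrix before any response is returned.

`simulate_field_2d()` integrates the sigmoid-rate field equations on a
15 x 15 grid (800 um spacing, 1.2 cm extent) with exponentially decaying
horizontal E-E connectivity (spatial scale 440 um), local inhibition, and
a synchronous exogenous drive with a 1.4 mm Gaussian spatial profile.
Design choices that were genuinely open:

* **Operating point.** The preset tables give sigmoid slopes
  (excitabilities) and thresholds but no operating point. Both populations
  receive a tonic depolarization placing them at mid-sigmoid (the leak
  reversal sits at the threshold), so the linearized coupling strengths
  are excitability-scaled synaptic weights and the four presets differ
  only through the inhibitory excitability, from weak (0.1) to strong
  (3.33) recurrent inhibition.
* **Synaptic efficacy and kernels.** A shared efficacy (`syn_gain`, default
  2.8) sets the dimensionless loop gains at the operating point, and the
  recurrent inhibitory loop carries a first-order synaptic filter
  (`tau_s`, 3 ms) while horizontal E-E transmission is treated as fast.
  These values place the strong-inhibition preset in a stable but
  underdamped regime (a spectral resonance near 15 Hz, verified against
  the eigenvalues of the linearization) while the weak preset remains
  overdamped; they were fixed once from that stability/resonance analysis.
* **Drive.** The exogenous input is an Ornstein-Uhlenbeck process (16 ms
  correlation time), i.e. broadband over the analysis range but with most
  power where the rate response is estimable at desk-scale durations. The
  drive amplitude keeps rate excursions well inside the sigmoid's linear
  range; pushing it further visibly distorts the spatial coupling profile
  through saturation of the strongly driven center.
* **Step size.** Forward Euler with `dt` capped at `tau/20` and `tau_s/8`
  (default 0.25 ms); LFP proxies and rates are box-averaged to the output
  rate.

The linear response to a separable drive predicts a rank-1 coupling matrix
(`model_rank1_prediction()`) whose spatial profiles can be compared
directly to the estimated LFP and spike vectors. The closed-form spatial
damping coefficient (`field_kernel_coeff()`) is the low-frequency limit;
the sign of its imaginary part -- positive (input site leads) for weak
recurrent inhibition, negative (input site lags) for strong -- is the
mechanistic signature behind the phase-versus-modulus regression of the
spike vector (`phase_modulus_regression()`). At the band of maximal
coupling the regression slope is reliably negative under strong
inhibition; its *significance* at a single desk-scale simulation is
variable (the spatial phase spread across a 1.2 cm array is a fraction of
a radian), which is why the validation pools the spike-vector coefficients
of two replicate 300 s simulations (each centered at its own circular mean
phase) before regressing.

## Numerical conventions and degenerate inputs

* Eigenvalue ordering ties are broken by the original channel index;
  eigenvector global phases are fixed by making the largest-modulus entry
  real positive.
* A unit with zero spikes yields a flagged missing coupling (never 0,
  which would mean "no locking"); units below the inclusion threshold
  (default 50 spikes total) are excluded with a report.
* A spike-vector rotation is skipped (with a warning) if the mean
  LFP-vector coefficient is numerically zero.
* The von Mises concentration estimate is capped at $10^4$ for degenerate
  (single-phase) samples; a numerically zero resultant returns
  $\kappa = 0$ with a `uniform` flag.
* Continuous spike times are rounded to the nearest sample with exact
  half-sample ties resolved toward the earlier sample.
* `normalize_gplv()` (division by $\sqrt{n_c n_s}$) is refused in c mode,
  where entries are unbounded.

## Problem sizes used in the validation suite

The shipped validation studies use 100 units x 100 channels with 20--60 s
recordings for calibration studies (type-I error, population counting),
240 s for the detection-sensitivity sweep, a 200 x 200 spectrum comparison
at 60 s, 500 repetitions of the 3-unit univariate comparison, and three
300 s field simulations. The population-counting study uses a single
continuous epoch per run (see below). These sizes were chosen so each study's
statistical target (e.g. count MSE below 0.015, majority detection at
strength 0.05) is met with margin under the generative model above.

## Known limitations

* The rank-1 summary discards all structure beyond the leading singular
  triplet; counting significant singular values is the only multi-rank
  readout provided.
* Per-trial whitening assumes the trial covariance eigenvectors are stable
  across trials. When several rhythms have nearly equal power the
  oscillation subspace is close to degenerate, its per-trial eigenbases
  rotate arbitrarily from trial to trial, and summing per-trial couplings
  can then split one assembly's coupling across singular components
  (observed as an undercount in the population-counting benchmark with
  short repeated trials). Prefer long continuous epochs, or few long
  trials, when counting populations with comparable rhythm power.
* The analytical test's conditions (whitening, $1/\sqrt{N}$ normalization,
  independence across units under the null) are required, not optional;
  for anything else use surrogates.
* Pairwise estimators other than PLV/c (bias-corrected, low-rate-robust
  variants) are not implemented.
* For laminar recordings an alternative sign convention anchored to the
  peri-somatic channel is sometimes preferred; only the zero-mean-LFP-phase
  convention is implemented.
* The mass/field models are small-signal linearizations around a chosen
  operating point; their qualitative signatures (phase-lag reversals, slope
  signs) are the intended outputs, not quantitative curve fits.
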