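# gpla

Multivariate spike–field coupling analysis for multichannel
electrophysiology: **g**eneralized **p**hase **l**ocking **a**nalysis.

## What it does

Given spike trains from many units and a multichannel local field
potential (LFP), the package

1. band-passes the LFP and forms its complex analytic signal
   $L_n(t) = a_n(t)e^{i\phi_n(t)}$ per channel (optionally followed by
   reduced-rank whitening),
2. builds the complex coupling matrix $C$ (channels × units) of pairwise
   statistics — either the phase locking value
   $\mathrm{PLV}_{nm} = \frac{1}{N_m}\sum_j e^{i\phi_n(t_j^m)}$ or the
   amplitude-weighted $c_{nm} = \frac{1}{\sqrt{N_m}}\sum_j L_n(t_j^m)$,
3. reduces it by SVD, $C = UDV^H \approx d_1 u_1 v_1^H$: the largest
   singular value $d_1$ is the **gPLV** (one number for the whole
   recording's coupling strength in the band), $u_1$ is the **LFP vector**
   (per-channel complex weights) and $v_1$ the **spike vector** (per-unit
   complex weights, whose phases give each unit's relative timing), and
4. assesses significance either with spike-jitter surrogates or with a
   fast analytical test: after whitening, the null squared singular values
   of $C/\sqrt{n_u}$ follow the Marchenko–Pastur law, so coupling is
   significant when $\mathrm{gPLV} > \sqrt{n_u}\,(1+\sqrt{n_c^{\rm eff}/n_u})$,
   and the count of singular values above the bound estimates how many
   neuronal populations couple to distinct rhythms.

Synthetic benchmark generators (oscillation-mixture LFPs, phase-locked
Poisson spike trains, multi-assembly designs) and linearized two-population
neural mass / 2-D neural field models (for mechanistic interpretation of
phase shifts and spatial phase gradients) are included; see the methods
vignette (`vignettes/gpla-methods.Rmd`).

## Worked example

Three cell assemblies, each locked to its own rhythm between 11 and
15.5 Hz, 100 units × 100 LFP channels:

```r
library(gpla)
set.seed(42)
d   <- gen_multipop(n_pops = 3, strength = 0.5, duration = 60, n_trials = 3)
fit <- gpla(d$lfp, d$spikes, band = d$band, mode = "c", whiten = TRUE)
fit$result
#> <gpla_result> gPLV = 50.94 (3 channels x 100 units, mode c, whitened)
#>   overall spike-LFP phase shift Phi_d = -0.639 rad
analytic_test(fit$coupling)
#> <significance_report> method = analytic
#>   largest eigenvalue of S = 25.95 vs threshold 1.376 -> significant
analytic_test(fit$coupling)$n_significant
#> [1] 3
```

The three rhythms dominate the band, so the reduced-rank whitening keeps
3 components, and the gPLV (50.9) is far above the Marchenko–Pastur bound
($\sqrt{100 \times 1.376} \approx 11.7$), so the coupling is significant
without any surrogate computation, and exactly 3 singular values exceed
the bound — the number of planted assemblies. The moduli of
`fit$result$spike_vector` separate coupled from uncoupled units, and its
phases recover each unit's locking phase relative to the LFP pattern in
`fit$result$lfp_vector`.

For file-based runs there is a configuration-driven pipeline
(`run_pipeline()`, spike CSV + LFP directory in, JSON/CSV out) and a thin
command-line wrapper:

```sh
Rscript inst/cli/gpla.R simulate --preset multipop --seed 1 --out sim/
Rscript inst/cli/gpla.R test --spikes sim/spikes.csv --lfp sim/lfp \
        --band 9.5,17 --method analytic
```

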