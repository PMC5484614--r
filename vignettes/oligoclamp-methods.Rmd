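---
title: "Models and methods behind oligoclamp"
author: "oligoclamp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oligoclamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoclamp)
```

`oligoclamp` quantifies AMPA-receptor signalling in oligodendrocyte
precursor cells (OPs) from whole-cell voltage-clamp recordings, and the
downstream consequences for oligodendrocyte (OL) numbers and myelin from
histology and electron-microscopy measurement tables. Because raw
recordings of this kind are rarely shared, the package pairs every
analysis stage with a synthetic-data generator whose genotype presets
plant the studied effect sizes; the tests then validate each stage by
parameter recovery. This vignette explains the models, the tunable
parameters, the numerical choices, and what the passing tests do — and do
not — establish about real data.

## The clamp circuit model

OPs at the ages studied are small and electrotonically compact
(membrane resistance above 1 GΩ, capacitance below 35 pF), so the
generator uses a single-compartment cell behind an access (series)
resistance:

$$C_m \frac{dV_m}{dt} = \frac{V_{cmd} - V_m}{R_s} - I_{ion}(V_m, t),
\qquad I_{rec} = \frac{V_{cmd} - V_m}{R_s},$$

with

$$I_{ion} = g_L (V_m - E_L) + g_{Na} m^3 h (V_m - E_{Na})
 + \big[g_A f(V_m) w_A(t) + g_K w_K(t) + g_{syn}(t) f(V_m)\big] V_m .$$

The recorded current is the pipette current, so capacitive transients and
series-resistance voltage errors appear in the synthetic sweeps exactly as
in recordings — downstream corrections are therefore tested against
realistic distortions, not idealized traces.

Component choices:

* **Na⁺ current** — Hodgkin–Huxley-style $m^3h$ with sigmoidal steady
  states ($V_{1/2,m} = -30$ mV, $k_m = 7$ mV, $\tau_m = 0.15$ ms;
  $V_{1/2,h} = -55$ mV, $k_h = 7$ mV, $\tau_h = 1.5$ ms, $E_{Na} = 60$
  mV) and peak conductances of 4–10 nS, giving transient inward currents
  of a few hundred pA. Only the presence and magnitude of I(Na) matter for
  the analyses (OP identification and passive subtraction); no kinetics
  are fitted.
* **Receptor conductances** — AMPAR ($g_A$) and kainate-receptor ($g_K$)
  limbs share a reversal potential of 0 mV. Bath agonist occupancy
  $w(t)$ follows first-order wash-in ($\tau$ = 20 s) and wash-out
  ($\tau$ = 60 s), typical of slice superfusion; the antagonist multiplies
  the AMPAR limb by $1 - b(t)$ with the same kinetics.
* **Rectification** — GluA2-lacking AMPARs are blocked by intracellular
  polyamines at depolarized potentials. The open fraction is a Boltzmann
  $f(V) = 1/(1 + e^{(V - V_h)/k})$ with $V_h = -20$ mV, $k = 15$ mV,
  applied only when the cell lacks GluA2 *and* the pipette contains
  spermine — reproducing near-full conduction at −63 mV with strong
  suppression at +17 mV.
* **Synaptic events** — Poisson onsets with biexponential conductance
  waveforms ($\tau_{rise}$ = 0.5 ms, $\tau_{decay}$ = 4 ms with 10%
  lognormal jitter), amplitudes Normal(20, 4) pA at −83 mV. The
  secretagogue (Ruthenium Red) raises the rate from a 0.02 Hz spontaneous
  baseline to the cell's plateau rate with a 60 s time constant, so the
  plateau is effectively reached by the third minute of application —
  matching the rationale for analyzing minutes 3–6.

**Integration.** The integrator (compiled, exponential Euler) is
unconditionally stable and exact for piecewise-constant conductances; it
sub-steps to 1/5 of the fastest gating time constant when Na⁺ channels are
engaged by depolarizing steps and to 50 µs when fast synaptic conductances
are present. Divergence of the membrane potential (|Vm| > 500 mV or
non-finite) aborts with an explicit error rather than returning corrupt
sweeps. Sampling rates follow the acquisition they emulate: 50 kHz for the
passive probe (τ ≈ 0.3–0.4 ms must be resolved), 20 kHz for step
protocols, 5 kHz for gap-free EPSC recordings, 1 kHz for slow bath
responses.

## Genotype presets

The presets plant the studied contrasts; everything else about a cell is
drawn identically regardless of genotype:

| parameter | control | dko | tko |
|---|---|---|---|
| kainate-evoked density (rel. control) | 1 | 0.53 | 0.122 |
| AMPAR (GYKI-blockable) fraction | 0.80 | 0.80 | 0.39 |
| rectifying with spermine | no | yes | no |
| RR-evoked EPSC rate (rel. control) | 1 | 0.30 | 0.01 |
| OL density effect (P7 / P14) | — | 22% / 27% | 22% / 27% |
| caspase fold-change | 1 | 1.194 | 1.242 |
| myelin-figure effect | — | 20% | 20% |

Two scales are free because only relative values are reported: the control
current density (10 pA/pF at −63 mV; arbitrary, all contrasts are ratios)
and the control RR plateau rate (2 Hz). The tko EPSC rate (0.01 of
control) encodes "almost none" and is a modelling choice. Cell-level
variability is lognormal: density CV 0.15, rate CV 0.2, quantal-amplitude
scale CV 0.15 (drawn independently of the preset, so the planted amplitude
distribution is genotype-invariant — the frequency, not the quantal size,
carries the genotype effect). The receptor fraction jitters by SD 0.03
(0.04 in tko).

Because all cell-level draws are preset-independent, generating two
genotypes from the same seed yields paired cells whose parameters differ
*exactly* by the planted multipliers. The cohort contrast functions
exploit this as a common-random-numbers design: the recovered contrast
then measures the fidelity of the analysis chain rather than the luck of
two independent 20-cell draws. With independent seeds the same estimators
are unbiased but carry a few percentage points of cohort-sampling
scatter.

## Analysis-side choices

* **Passive fit** — the probe transient is averaged across repeats and fit
  from 0.2 ms after step onset (clamp settle); $I_0$ is the fit's
  extrapolation to onset, robust to filtering, rather than the raw peak
  sample. $C_m = \tau (R_s + R_m)/(R_s R_m)$ (the parallel-resistance
  form; at $R_m \gg R_s$ it differs from $\tau/R_s$ by well under the
  test tolerances). A transient indistinguishable from the steady state
  ($I_0 = I_{ss}$) cannot resolve $R_s$ and is an error, as are negative
  resolved resistances.
* **QC** — "resistance changed by >50%" is interpreted as series
  resistance relative to its first measurement (the sentence's context is
  Rs monitoring). The Rs rules are bypassable (`ignore_rs = TRUE`) for
  analyses that include all cells and correct voltage errors
  arithmetically, as the kainate-density quantification does.
* **Rs correction** — both membrane potentials are reconstructed from the
  currents flowing before and during the response
  ($V_m = V_{cmd} - I R_s$); the leak-current change
  $(V_{m,during} - V_{m,before})/R_m$ is removed before rescaling by the
  driving-force ratio with $E_{rev} = 0$ mV. Using both currents makes
  the correction exact for an ohmic leak; rescaling alone leaves a
  residual bias of about $R_s/R_m$. Responses whose membrane potential
  approaches the reversal potential (|driving force| < 5 mV) are flagged
  unquantifiable.
* **Rectification index** — computed on raw (uncorrected) step
  differences as a ratio of current amplitudes, the −63 mV response
  entering as a magnitude, so an ohmic conductance gives +17/63 ≈ 0.27.
  The Rs correction largely cancels in this within-cell ratio.
* **EPSC detection** — 2 Hz zero-phase 2nd-order Butterworth high-pass;
  noise SD estimated iteratively (detect, mask ±20 ms, re-estimate; an
  estimate that has not converged within 10 iterations is an error, and a
  floor of 10⁻³ pA keeps noiseless traces finite). Candidates are runs
  above 3×SD (runs separated by <1 ms merge); acceptance requires ≥1 ms
  above threshold and a 20–80% rise time shorter than the decay-to-1/e
  time, both measured on a 0.6 ms-smoothed copy so single-sample noise
  dips cannot truncate a decay. Rejected candidates are retained with
  `accepted = FALSE` for audit — the manual accept/reject step of
  interactive analysis is replaced by these explicit rules for
  reproducibility. Amplitudes are measured against a 10 ms pre-event
  median baseline.
* **Minimal stimulation** — successes are classified on the smoothed
  trace at 4× the smoothed noise SD: with no duration criterion available
  in a 10 ms window, a 3×SD raw threshold misclassifies roughly one in
  ten failure trials on noise minima alone.
* **Paired-pulse ratio** — a single exponential is fit to the decay of
  the first response between its peak and the second stimulus and its
  extrapolation subtracted before measuring the second peak; the fit is
  skipped when the first response has decayed below 2% of its peak.
* **Step-down correction** — the multiplication rule (most significant
  p × N, next × N−1, …) is supplemented with a running maximum in sorted
  order, making it identical to the Holm procedure; the bare rule can
  invert the significance ordering. `literal = TRUE` disables the repair
  for exact replication. Tied p-values keep their individual rank
  multipliers.
* **Dunn's post-hoc test** is implemented directly (rank-sum z statistics
  with tie correction, Bonferroni-adjusted), as no installed package
  provides it.

## Cohort generators

Histology cohorts are littered: every litter contains both genotypes,
fields are 0.2 mm² with 3–4 per animal, and counts are Poisson around
planted densities (control OLs 1250/mm², OPs 800/mm² — about 250 OLs per
field, over 800 cells per animal). Biological variability is lognormal at
the litter (CV 4%) and animal (CV 5%) levels. The caspase generator plants
litter-level CV 10% and within-litter animal CV 6.6% around control means
of 22.7% (double-knockout experiment) or 24.8% (triple-knockout
experiment); litter normalization cancels the litter level by
construction, which is exactly why the procedure exists. Fiber geometry
uses lognormal axon diameters (median 0.8 µm), truncated-normal g-ratios
(0.78 ± 0.03; genotype-invariant by design), and one ~210 × 160 µm
counting field per animal at a control density of 0.0595 figures/µm²
(≈2000 per field, n = 5 animals per genotype). Internodes are persistent
3D random walks rescaled to exact planted arc lengths (median 50 µm),
with no genotype effect.

Problem sizes in the tests and the acceptance script follow the study
design they emulate: 20 cells per genotype for bath-agonist contrasts, 15
six-minute recordings per genotype for the RR analysis, 6 litters for the
caspase normalization, 14 animals per group at P14, 5 animals per group
for electron microscopy.

## What the tests show — and what they do not

Passing recovery tests establish that the analysis chain is faithful to
its own forward model: planted passive properties are recovered within 2%
at zero noise, the Rs correction recovers planted conductances within 2%
up to 30 MΩ, the detector reaches ≥95% recall at ≤0.05 Hz false positives
for events ≥5× the noise SD, and the planted genotype contrasts (47%
density reduction, 23% residual, 80%/39% block, 70% frequency reduction,
1.19× apoptosis, 27% OL density reduction, 0.80 myelin-figure ratio)
survive the full pipelines. They do not establish robustness to phenomena
the generator deliberately omits: electrotonically extended cells (a
single compartment cannot model dendritic filtering gradients),
non-stationary noise and electrode drift beyond a 2 Hz corner,
receptor desensitization during bath application, multi-vesicular or
correlated release, or segmentation error in the measured circumferences
(the generator produces measurement tables, not images). Paranodal
exclusion in g-ratio measurement is an acquisition rule and cannot be
enforced computationally here.

## Known limitations

* The kainate-receptor fraction scales down with the AMPAR knockouts
  exactly as the presets encode the reported block percentages; physically
  one might expect the KAR component to be unchanged. The presets follow
  the reported numbers; the tension is noted, not resolved.
* Whether the original rectification indices were computed on corrected or
  raw currents is not stated; raw is used here (the choice is nearly
  inconsequential for a within-cell ratio).
* "Rising phase faster than the decay" is operationalized as 20–80% rise
  time < decay-to-1/e time.
* Sweep sets serialize to CSV + JSON sidecars rather than HDF5/NWB; the
  layout is documented in `write_sweep_set()` and round-trips ground truth
  exactly.
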