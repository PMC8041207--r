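---
title: "A coupled lung circadian clock and acute inflammation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled lung circadian clock and acute inflammation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoclock)
library(dplyr)
library(ggplot2)
```

## The model

`immunoclock` simulates the circadian clock of the rodent lung coupled in
both directions to an acute inflammatory response to endotoxin (LPS), and
provides the calibration, experiment and sensitivity machinery around it.

### Clock block (12 variables)

Five genes are modelled at the level of one mRNA and one protein each —
*Per*, *Cry*, *Rev-Erb*, *Ror* and *Bmal1* — with isoforms pooled into a
single variable per family, plus two protein complexes: PER–CRY (`pc`) and
CLOCK–BMAL1 (`cb`). CLOCK protein is treated as constitutive, and no
post-translational modification or nuclear/cytoplasmic compartmentation is
represented: transport is fast on the circadian timescale.

Transcription is encoded with Hill kinetics:

* *Per*, *Cry*, *Rev-Erb*, *Ror*: activated by `cb`, repressed by `pc`,

  $$\frac{dM_i}{dt} = v_i\left(\beta_i + (1-\beta_i)
  \frac{cb^{h_i}}{K_i^{h_i}+cb^{h_i}}\right)
  \frac{K_{pc,i}^{p_i}}{K_{pc,i}^{p_i}+pc^{p_i}} - d_i M_i,$$

  with an additional REV-ERB repression factor on *Cry* only.
* *Bmal1*: activated by ROR protein and repressed by REV-ERB protein
  (competition for the RRE site reduced to a multiplicative
  activator × repressor form), and inhibited by the endotoxin filter:

  $$\frac{dM_B}{dt} = v_B\left(\beta_B + (1-\beta_B)
  \frac{P_{ror}^{n}}{K_{ror}^{n}+P_{ror}^{n}}\right)
  \frac{K_{rev}^{m}}{K_{rev}^{m}+P_{rev}^{m}}
  \cdot\frac{1}{1+k_L\,L(t)} - d_B M_B.$$

  The basal term sits inside the ROR bracket so that REV-ERB represses
  *Bmal1* transcription even with ROR absent; this keeps the
  REV-ERB→BMAL1 negative loop intact under a *Ror* knockout, which is the
  regime the knockout experiments probe.

Proteins follow linear translation and first-order degradation; PER and
CRY additionally associate into `pc` (mass action, reversible), BMAL1
into `cb` with the constant CLOCK level.

The endotoxin filter `L(t)` ([`lps_filter()`]) jumps to an amplitude
proportional to dose at the challenge (unit amplitude at 3 mg/kg) and
decays linearly over 24 h, matching the duration of clock suppression
seen during endotoxemia. It acts on the clock only through *Bmal1*;
cytokines have no direct transcriptional links back to clock genes.

### Immune block (8 variables)

Endotoxin `P` clears first-order (`dP/dt = -d_P P`). Activated phagocytes
`N` are recruited by endotoxin, TNF-α, IL-6 and the damage marker `D`,
and inhibited by IL-10 and a slow anti-inflammatory mediator `C_A`
(cortisol/TGF-β-like). `D` is produced by IL-6 (Hill) and directly by
endotoxin; it is a non-accessible severity index, not a cell type, and is
only ever reported relative to a comparison set. Cytokine production is
Hill in `N` (exponent 1.5, following the endotoxemia-model lineage this
block descends from), with TNF-α amplifying IL-6 and IL-6 amplifying
IL-10; IL-10 has a second, slower source through the tissue-driven
promoter `Y` and a constant source `s_IL10`; `C_A` has constant source
`s_CA`. The infection-free rest state (all zero except IL-10 and `C_A`
at source/decay baselines) is an exact equilibrium, so the uninfected
coupled system reduces to the clock alone.

### Clock→immune coupling

Four repressive Hill factors of the form $1/(1+(x/K)^h)$ multiply
cytokine production: CRY and ROR on TNF-α, REV-ERB on IL-6 and on IL-10.
Each equals 1 without its repressor and decreases strictly, so setting a
threshold to `Inf` removes the link.

The IL-10 brake by REV-ERB is the mechanistic pivot of the package's
timing results: REV-ERB protein crests at CT12 (this anchors the
circadian-time scale) while ROR bottoms out there. A challenge at CT12
therefore meets a strong early IL-10 brake and a weak TNF brake —
cytokines surge, damage is high, and IL-10 becomes biphasic: a weak early
peak while REV-ERB is still high, then a dominant late peak as the
LPS filter pulls *Bmal1* (hence REV-ERB) down and the damage-driven `Y`
pathway matures. At CT0 REV-ERB sits near its minimum, IL-10 spikes once
and early, and the inflammatory response is tempered.

## Circadian-time convention

CT0 is the onset of the rest phase and CT12 the onset of activity. The
model is free-running (no light input), so circadian time is anchored
operationally: the REV-ERB protein maximum on the limit cycle defines
CT12 — the only protein-phase anchor available. Chronic jet lag is
represented by its end state: an 8-h advance of the clock phase at the
challenge plus a sex-specific recalibrated parameter set, not by a
driven light schedule (the model has no light input to drive).

## Calibration

Calibration is two-step, mirroring the transient nature of acute
inflammation:

1. `fit_clock()` fits the infection-free clock alone to the five mRNA
   series by Nelder-Mead least squares on a per-series max-normalized
   residual, with a global phase shift profiled out at each evaluation
   (clock data are conventionally recorded from CT18 after release into
   darkness, which need not match the model's anchor). Manual
   restart-and-correct fitting is replaced by seeded multi-start
   (default 8 lognormal-perturbed starts, σ = 0.3), because a manual
   protocol is not reproducible. Parameter sets are not uniquely
   determined — different sets reach nearly the same cost — which is why
   the shipped nominal set is frozen once and distributed with the
   package rather than re-estimated per session.
2. `fit_immune()` fits the immune and coupling parameters to cytokine
   series at 3 and 12 mg/kg simultaneously (six cost components: three
   cytokines × two doses, each from a fresh coupled simulation), with
   every clock parameter and the literature/data-fixed `d_P`, `s_IL10`,
   `s_CA` frozen. Data at 6 mg/kg are scored as held-out validation and
   never fitted. Experimental error bars are not used in the cost.

The chronic-jet-lag variants are recalibrated with `fit_cjl()` against
24-h *mean* expression changes (the underlying measurements are
averages, not time courses): relative errors on
`mean_baseline * (1 + target)` are minimized over 6 free clock
parameters for males and 10 for females — the transcription maxima and
mRNA degradation rates of the targeted genes, plus translation rates to
round out the stated set sizes (`kp_rev`, `kp_per` for males; `kp_per`,
`kp_cry` for females). Relative (not absolute) errors weigh genes of
different scales equally. A fit is rejected unless every achieved change
lands within 5 percentage points of target and the model retains a limit
cycle with period in [20, 28] h.

## Synthetic data

The package ships no third-party measurements; `generate_clock_series()`
and `generate_cytokine_series()` emulate the *statistical shape* of the
real inputs instead, because every acceptance-level check here is
structural (periods, phase relations, peak counts, orderings, percent
changes) rather than point-wise:

* clock series: 48 h at 2-h sampling, 24-h cosinor curves with
  lung-typical phase order (*Bmal1* in antiphase to *Per*, *Rev-Erb*
  between them, *Ror* opposite *Rev-Erb*), or samples of a ground-truth
  model trajectory;
* cytokine series: sampling at 0.5–24 h post challenge (bracketing the
  1 h and 10–12 h features of endotoxemia cytokines), TNF-α peaking
  first, IL-6 later, IL-10 mono- or biphasic, peaks strictly increasing
  with dose across 3, 6, 12 mg/kg;
* noise: multiplicative lognormal, σ = 0.1 by default, matching the
  right-skewed positive errors of expression and immunoassay data.

What passing tests on these data do show: the pipeline recovers known
parameters from data it can explain, and the calibrated model reproduces
the qualitative immunology above. What they cannot show: agreement with
any particular animal dataset, absolute concentration scales (all units
are arbitrary and fixed by the synthetic calibration), or isoform-level
behaviour.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable, adaptive) with
  rtol 1e-8 / atol 1e-10; Hill systems with fast complex kinetics can be
  locally stiff. Halving tolerances moves reported summaries by well
  under 0.1%. States are clipped at zero against integrator undershoot
  at the tolerance level.
* Limit cycles: 60 simulated days, first 30 discarded, period = mean
  spacing of successive *Bmal1* mRNA maxima (parabolically refined) over
  the last 10 cycles; an amplitude below 1e-6 is reported as a damped
  clock, a period outside [20, 28] h as a rejected cycle.
* Peak counting: the sources this model family draws on never define
  "peak", so the package fixes one: local maxima in the 24 h after the
  challenge, topographic prominence at least 5% of the window maximum,
  minimum 2-h separation (higher peak wins), challenge sample excluded.
  The thresholds are deliberately permissive enough to keep the weak
  early IL-10 peak after a CT12 challenge while ignoring integrator
  ripple.
* Knockouts: zeroing one transcription maximum. *Bmal1* and *Rev-Erb*
  knockouts damp the clock; timed experiments then fall back to the
  knocked-out system's steady state before the challenge, with a
  warning.
* Optimization: Nelder-Mead (`stats::optim`) on log-transformed
  parameters — positivity for free, and multiplicative steps suit rate
  constants spanning decades.

## Nominal parameters

The equations above fix the network topology but not the rate constants.
The shipped nominal set was produced with the package's own machinery:
an oscillatory starting set was refined against the packaged synthetic
clock data and the phenotype battery (period, phase anchors, knockout
behaviour, peak structure, CT-sensitivity ordering, post-challenge
resolution), then time-rescaled so the free-running period is exactly
24 h — a one-parameter freedom of the equations (scaling all rate
constants scales time) that is fixed last, after all phase relations are
in place. The set is frozen in `inst/extdata/params_control.json`;
`fit_cjl()` derives the two CJL sets from it at run time (the shipped
`params_cjl_*.json` are those fits, frozen for convenience).

Problem sizes used in the shipped tests and the acceptance script —
60-day limit-cycle integrations, 36-h challenge horizons, 3-hourly CT
grids, Sobol' base samples of 512–2048 on analytic test functions, and
calibration runs with reduced free sets — were chosen so the full
pipeline runs on a laptop in minutes while leaving every measured
quantity integrator-converged (see the tolerance-halving property).

## Design choices where the ground was open

* **RRE competition** between ROR and REV-ERB on *Bmal1* is approximated
  by an activator × repressor product — the standard Hill reduction that
  preserves all signs — rather than an explicit competitive-binding
  denominator.
* **Filter amplitude** scales linearly with dose (unit at 3 mg/kg): the
  minimal assumption consistent with dose-dependent clock disruption.
  The filter takes its amplitude from the dose at the challenge; it does
  not track the decaying endotoxin level afterwards.
* **Severity** is the peak of the damage marker over the horizon, not
  its integral: time courses are compared by height. It is reported
  relative to the maximum across compared conditions.
* **`C_A` production** depends on `N` only; a damage-driven term would
  be equally defensible but adds an unidentifiable parameter.
* **Default horizon** is 36 h: the filter lasts 24 h and cytokine
  dynamics complete within ~24 h; damage peaks within the horizon.
* **CT grid** is 3-hourly (8 points): fine enough to rank CT9 against
  CT12 and to place CT18 against the grid median.

## Worked example

```{r example, eval = FALSE}
ps <- default_parameters("control")
lc <- find_limit_cycle(ps)
lc$period_h
autoplot(lc)

e0 <- run_experiment(experiment_spec(dose = 3, challenge_ct = 0), ps)
e12 <- run_experiment(experiment_spec(dose = 3, challenge_ct = 12), ps)
nrow(e0$il10_peaks); nrow(e12$il10_peaks)
autoplot(e12$trajectory)

grid <- ct_grid_experiment(ps, dose = 3)
autoplot(grid)

fit_m <- fit_cjl(generate_cjl_targets("male"), ps, sex = "male")
fit_m$achieved
```

## Known limitations

* The clock has no light input: entrainment dynamics, and chronic jet
  lag as a lighting protocol, are outside the model; only the end state
  (phase advance + altered parameters) is represented. Phase-shift
  lengths other than 8 h are untested.
* Cytokines do not feed back on clock transcription except through the
  aggregate LPS filter; direct TNF-α→clock links are not modelled.
* One baseline immune parameterization serves both sexes; sex enters
  only through the clock.
* Mortality is not modelled; the damage marker is a severity index with
  meaning only relative to compared conditions.
* Calibration is least-squares point estimation; parameter
  non-uniqueness is acknowledged and screened with Sobol' indices, not
  resolved with Bayesian or identifiability machinery.
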