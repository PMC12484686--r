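---
title: "Waveform-dependent period variability in clock-driven outputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Waveform-dependent period variability in clock-driven outputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(clockwave)
library(dplyr)
```

## The question

Circadian clocks drive downstream gene expression through clock-controlled
promoters. The driving waveform — how the synthesis rate of an output
protein varies over one clock cycle — differs widely between genes:
sinusoidal, sawtooth-like, or spike-like. Molecular noise inside the clock
makes every observed period fluctuate, and the size of those fluctuations,
measured as the coefficient of variation (CV = SD/mean of the
cycle-to-cycle period), is a property of the *output*, not only of the
clock. `clockwave` implements a complete computational study of how the
regulatory waveform shapes the output period CV, and of which waveforms
minimise it.

## Models

Two clock models drive the same linear reporter.

**Goodwin loop + reporter.** A three-variable transcriptional–translational
negative feedback loop (mRNA $u$, cytosolic protein $v$, nuclear protein
$w$; Hill repression $1/(1+w^m)$, degradation rates $k_u, k_v, k_w$) with
gene-expression noise $\epsilon\sqrt{D}\,\xi(t)$ on the $u$ equation only.
Time is rescaled by the loop's deterministic period $\tau$ so one cycle is
one "day". The reporter obeys $\dot x = \alpha + \beta g(\cdot) - kx$ with
a polynomial regulation $g$ of a chosen clock species.

The Hill coefficient is not a reported constant in the analyses this
package reproduces; the package defaults to $m = 10$, the smallest round
value above the classical oscillation threshold ($m > 8$ for near-equal
degradation rates), and *measures* $\tau$ from the deterministic loop at
construction instead of hard-coding it. With $k_u = k_v = k_w = 0.1$ the
measured period is $\tau = 39.7$, matching the value quoted with the
reference parameter set — which supports $m = 10$ being the right choice.
Construction fails with a diagnostic if the deterministic loop does not
sustain oscillations.

**Phase oscillator + reporter.** The clock reduces to a noisy phase,
$\dot\theta = \omega + \epsilon\sqrt{D}\,\xi(t)$, and the reporter to
$\dot x = \alpha + \beta f(\theta) - kx$ with $f$ a truncated Fourier
series $f(\theta)=\sum_{i=1}^H (A_i\cos i\theta + B_i\sin i\theta)$. The
synthesis rate $\alpha + \beta f(\theta)$ must stay non-negative
(`check_rate_positivity()`); with normalised coefficients and $\alpha = 3$,
$\beta = 1$ the bound $|f|\le\sqrt{H}$ certifies this for $H \le 9$.

Both models are integrated by Euler–Maruyama with $\Delta t = 10^{-3}$
(configurable), initial conditions $(0,0)$ and $(0,0,0,0)$, and periods
measured from $t = 100$. Simulation noise comes from the package's own
xoshiro256++ stream, so every run is bit-reproducible given its seed and
independent of R's global RNG state.

## Measuring the period CV

Period statistics need exactly one marker per cycle. Three marker types
are provided:

* **peaks** — local maxima of $x$, refined by quadratic interpolation
  through the three samples around each discrete maximum;
* **upward threshold crossings** of the midpoint of the noiseless
  oscillation range (linear interpolation), the "checkpoint" of the
  analytic theory;
* for generic data, crossings with a **refractory guard** (default a
  quarter period) merging jitter-induced double counts.

For the phase model the clock phase is part of the state, and the package
uses it to delimit cycles: one window per clock cycle, with boundaries
half a period away in phase from the marked feature of the noiseless limit
cycle, keeping the candidate nearest in phase to that feature. For
single-peaked waveforms this is identical to naive peak picking; for
waveforms whose output has several local maxima or midpoint crossings per
cycle it prevents the marker from hopping between near-equal features. The
alternative convention — windows delimited by upward midpoint crossings of
the trajectory with a refractory guard, keeping the largest maximum per
window — is retained as `window = "refractory"`; for random multi-harmonic
waveforms it lets markers hop between near-degenerate maxima and inflates
the measured CV by an order of magnitude, which is why it is not the
default. Marker-convention sensitivity is the main caveat when comparing
absolute CV summaries of random-waveform ensembles against published
values: summaries that average over many multi-peaked waveforms inherit
the convention, while single-peaked (sine-like) waveforms are
convention-free.

The Goodwin output is single-peaked per cycle even under noise, so its
peaks use the refractory-merge convention directly (amplitude wander under
gene-expression noise makes fixed-threshold cycle delimitation unreliable
there).

A `cv_estimate` reports the mean period, SD (sample, $n-1$), CV, interval
count, and the standard error $\mathrm{CV}/\sqrt{2n}$. Default run lengths
(4200 time units $\approx$ 4000 intervals) make that standard error about
0.03 percentage points, enough to resolve differences of 0.1 pp between
waveforms; scan-level experiments use the same length per function for the
same reason.

## The closed-form CV

For the phase model the output period CV defined by threshold checkpoints
has a closed form at leading order in $\epsilon$:

$$\mathrm{CV} = \frac{\epsilon}{\tau}\sqrt{R_{\Theta\Theta} + R_{hh} + 2R_{\Theta h}},
\qquad R_{\Theta\Theta} = \frac{D\tau^2}{2\pi\omega},$$

with $R_{hh}$ (amplitude autocorrelation) and $R_{\Theta h}$
(phase–amplitude cross-correlation, possibly negative) given by explicit
harmonic sums over the filter gains
$\sqrt{(A_i^2+B_i^2)/(k^2+(i\omega)^2)}$ and checkpoint phases
$\Phi_i(t_{\rm cp})$ (`cv_components()`, `phase_offsets()`). The package
transcribes these sums term by term; they truncate exactly at $H$.
Numerical conventions worth stating:

* $t_{\rm cp}$ is the upward midpoint crossing of the noiseless limit
  cycle $x^*(t)$; when several exist per period the steepest is used,
  which maximises the denominator $\sum_i i\omega C_i\cos\Phi_i$ — the
  best-conditioned checkpoint. A zero denominator raises an error rather
  than returning NaN.
* $\mathrm{sgn}(0) := +1$ in the $\Phi_i$ branch correction, the
  continuous limit from $i\omega A_i + kB_i \to 0^+$; the single-argument
  arctangent with explicit sign correction is kept as printed rather than
  replaced by `atan2`.
* extrema and crossings of $x^*$ are located on a 128-point grid per
  period with safeguarded-Newton refinement (tolerance $10^{-13}$).

The decomposition contains no $\alpha$ or $\beta$ and is invariant under
positive scaling of the coefficient vector — the analytic counterpart of
the simulated observation that basal synthesis and coupling strength leave
the CV unchanged. Both facts are asserted exactly in the test suite. At
the reference parameters ($k=10$, $\omega=2\pi$, $\epsilon=0.1$, $D=3$):

```{r analytic}
p <- phase_params()
glance(cv_components(p, fourier_regfun(0, 1)))
clock_cv(0.1, 3, 2 * pi) * 100 # the clock's own CV, percent
```

The closed form is validated against simulation (threshold-defined
periods): the gap shrinks as $\epsilon$ decreases, consistent with the
leading-order derivation — at $\epsilon = 0.05$ numeric and analytic CVs
agree to well within one Monte-Carlo standard error.

## Exploring waveform space

Three samplers search the coefficient cube $[-1,1]^{2H}$:

* `sample_random_functions()` — uniform draws, the baseline ensemble;
* `gibbs_sample()` — grid-conditional Gibbs sampling of
  $p(\mathbf{x}) \propto e^{-\mathrm{CV}(\mathbf{x})}$: each coordinate is
  redrawn from the discrete conditional obtained by evaluating
  $e^{-\mathrm{CV}}$ at $N+1$ grid atoms (exact cumulative-weight
  inversion); one sample per sweep, burn-in discarded;
* `evolve_minimum()` — truncation-selection evolutionary minimisation
  (population 64, Gaussian mutation $\sigma = 0.05$, elite quarter —
  package conventions, configurable).

Design choices that were genuinely open:

* **CV units in the Boltzmann weight.** $e^{-\mathrm{CV}}$ is
  unit-ambiguous. With fractional units the weight spans
  $e^{-0.026}$–$e^{-0.05}$ and the chain is almost uniform; only percent
  units produce the documented distribution shift of the sampled mean
  below the random-scan mean. Percent is the default; `cv_units =
  "fraction"` is available.
* **No renormalisation inside the chain.** Both evaluators are
  scale-invariant in the coefficients, so the chain samples raw
  coordinates in $[-1,1]$; normalisation is applied in reporting
  (`mean_harmonic_power()` normalises per record).
* **Noisy conditionals.** With the simulation evaluator each atom's CV
  carries Monte-Carlo noise (SE $\approx \mathrm{CV}/\sqrt{2n}$ with $n$
  the intervals per evaluation). Because the noise is redrawn at every
  conditional evaluation, its main effect is a mild flattening of the
  target and a small downward selection bias of the *recorded* CVs, of
  order the per-evaluation variance in percent units. Comparisons against
  the sine CV therefore re-measure a subsample of sampled functions at
  high precision rather than trusting the recorded values.
* **Desk-scale chain sizes.** Simulation-weighted chains default to 6000
  sweeps (1000 burn-in, $N = 20$, ~30 intervals per evaluation); analytic
  chains to 101000 sweeps ($N = 100$). The analytic grid resolution
  matters for tail quantities: how close the chain can approach the
  sine-optimal corner is limited by the 0.02 coordinate quantisation, so
  the fraction of samples beating the sine is smaller at $N = 100$ than
  at finer grids.

The evolutionary optimum of the closed-form CV at $H = 5$ is *slightly
below* the pure sine (2.48% vs 2.68%), with harmonic power concentrated on
the fundamental and a second-harmonic correction
($\langle r_1^2\rangle \approx 0.41$, $\langle r_2^2\rangle \approx
0.38$, the rest small) — sine-like, but not a pure sine; the same
low-harmonic concentration shows up in the low-CV tail of the Gibbs
chains.

## What the generators emulate — and what they do not

All inputs are generated internally: the two stochastic models *are* the
study system, with parameter sets
($k_u=k_v=k_w=0.1$, $\alpha=\beta=1$, $k=1$, $\epsilon=10^{-4}$, $D=1$,
$m=10$ for the Goodwin analyses; $\alpha=3$, $\beta=1$, $k=10$,
$\omega=2\pi$, $\epsilon=0.1$, $D=3$ for the phase-model analyses) fixed
as the reference conditions. The models capture period-fluctuation
transmission through a single noisy channel and a linear reporter. They do
not capture: multi-loop clock architectures, reporter maturation/delay
kinetics, discrete-molecule (Gillespie) noise, extrinsic noise shared
across the system, or entrainment by environmental cycles. Passing tests
therefore demonstrate properties of this model class, not of any
particular organism's data.

## Worked example

```{r example, fig.width = 6, fig.height = 3, eval = FALSE}
p <- phase_params()
sine <- fourier_regfun(0, 1)
tidy(phase_period_cv(p, sine, seed = 1))      # simulated peak-to-peak CV
100 * analytic_cv(p, sine)                    # closed form, percent

scan <- sample_random_functions(
  H = 5, n = 200,
  evaluator = cv_evaluator("simulation", p, sim_intervals = 400,
                           sim_discard = 100),
  seed = 1
)
glance(scan)
autoplot(scan, sine_cv = analytic_cv(p, sine),
         clock_cv = clock_cv(p$epsilon, p$D, p$omega))
```

## Known limitations

* Absolute CVs from peak markers depend on the cycle-window convention for
  waveforms with near-degenerate multiple maxima (see above); threshold
  (checkpoint) CVs and all sine-waveform results are convention-free.
* The closed form is leading-order in $\epsilon$; at $\epsilon = 0.2$ the
  systematic gap to simulation is already comparable to a 4000-interval
  Monte-Carlo standard error.
* The Goodwin loop near its oscillation threshold amplifies even tiny
  gene-expression noise into visible amplitude wander; CV values there are
  sensitive to $m$ and the degradation rates.
* Euler–Maruyama is first-order; the Goodwin clock equations carry the
  $\tau \approx 40$ time rescaling, so their effective step is
  $\tau\Delta t$ and deterministic trajectories carry a small $O(\Delta t)$
  period bias (the rescaled period is 1.013 rather than 1.000 at
  $\Delta t = 10^{-3}$). CV estimates, being ratios of interval statistics,
  are insensitive to this bias.
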