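---
title: "Detecting stochastic multiresonance with ordinal statistical complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stochastic multiresonance with ordinal statistical complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhnsmr)
```

## The model

`fhnsmr` simulates a small-world network of `N` FitzHugh–Nagumo (FHN)
neurons, each excitable and driven by a common weak periodic signal plus
independent Gaussian white noise, with a transmission delay in the coupling:

$$
\varepsilon \dot x_i = x_i - \tfrac{x_i^3}{3} - y_i
  + g \sum_{j} J_{ij}\,\bigl(x_j(t-\tau) - x_i(t)\bigr), \qquad
\dot y_i = x_i + a + A \sin\!\Bigl(\frac{2\pi t}{T_e}\Bigr) + D\,\xi_i(t),
$$

where $x_i$ is the fast membrane potential, $y_i$ the slow recovery
variable, and $J$ the symmetric 0/1 adjacency of a Watts–Strogatz graph
(ring of degree $k$, rewiring probability $p$). The defaults,

| parameter | value | meaning |
|---|---|---|
| $\varepsilon$ | 0.01 | time-scale separation fast/slow |
| $a$ | 1.1 | excitability ($|a|>1$: excitable, no self-sustained firing) |
| $A$, $T_e$ | 0.14, 14 | subthreshold drive amplitude and period |
| $g$ | 0.01 | coupling strength |
| $N$, $k$, $p$ | 100, 30, 0.15 | network size, ring degree, rewiring probability |
| $dt$ | 0.001 | explicit Euler step |

put each neuron in the excitable regime with a drive that cannot by itself
elicit a spike: `simulate_fhn` with `D = 0` produces a mean field that
oscillates weakly around rest ($x \approx -1.1$) and never crosses zero.
Noise makes the network fire, and at the right noise levels (or delays)
the firing locks to the drive — stochastic resonance. The analysis output
of interest is the mean field $X(t) = \frac1N \sum_i x_i(t)$.

## Numerical scheme

Integration is explicit Euler–Maruyama in compiled code:
$x \mathrel{+}= dt\,\dot x$ and
$y \mathrel{+}= dt\,\dot y_{\mathrm{det}} + \alpha\sqrt{dt}\,\eta$ with
$\eta \sim \mathcal N(0,1)$ i.i.d. per neuron per step. Initial values are
$x_i(0)=y_i(0)=0$, and the delay history for $t<\tau$ is that initial
state; $\tau$ must be an integer multiple of $dt$ (checked to $10^{-9}$).

**Noise convention.** The model equation writes the noise term as
$D\xi_i(t)$ with $\langle\xi\xi'\rangle=\delta(t-t')$, which at the
discretisation level can be read either as amplitude $\alpha = D$ or as
intensity $\alpha = \sqrt{2D}$. The package defaults to the literal
amplitude reading ($\alpha = D$, `sqrt2_noise = FALSE`), which we also
validated behaviourally: with it, the four firing classes (one to four
spikes per drive period at $D = 0.001, 0.04, 0.08, 0.14$) and an intrinsic
period near 3.5 all emerge at the documented parameter values, whereas the
$\sqrt{2D}$ reading produces much stronger effective noise and irregular
firing at those same values. The alternative convention remains available
as a switch.

Each simulation consumes a dedicated counter-seeded `mt19937_64` stream,
independent of R's RNG, so trajectories are bit-reproducible across
platforms for a given seed. A transient of 100 time units (long against
$T_e = 14$) is discarded before any spike extraction, removing the startup
excursion from the all-zero initial condition. The mean field is recorded
at every step; per-neuron rasters are optional and subsampled
(`record_stride`) to bound memory.

## Spike and interval extraction

The mean field swings from rest near $-1$ to spike peaks near $+2$, so
firings are detected as upward crossings of a threshold at 0 with a
refractory period of 1 time unit (shorter than the intrinsic period, so
genuine consecutive spikes are never merged; the exact threshold is not
critical and resonance-peak *positions* are robust to it). Inter-spike
intervals (ISIs) of the mean field form the series analysed everywhere
below. Long interval series are accumulated over independent realizations
with incrementing seeds (`accumulate_isis`); intervals never straddle a
realization boundary, and a condition whose first few realizations are all
silent is classified as non-firing early rather than running out the
realization cap.

## Ordinal complexity

For an interval series $\{T_s\}$ and embedding dimension $d$ (default 3),
every length-$d$ window is mapped to the permutation that sorts its values
ascending, ties broken by temporal order (`ordinal_pattern`), giving a
probability distribution $P$ over the $d!$ patterns in lexicographic order
(`pattern_distribution`). From $P$ the package computes

* the normalized Shannon entropy $H = S[P]/\ln d!$ (natural logs;
  $H$ is base-invariant),
* the disequilibrium $Q = Q_0\, J[P, P_e]$, the Jensen–Shannon divergence
  to the uniform distribution $P_e$, scaled by the constant $Q_0$ that
  maps the point-mass-vs-uniform divergence to exactly 1, and
* the statistical complexity $C = H \cdot Q$.

$C$ vanishes both for perfectly ordered series ($H = 0$) and for
structureless ones ($Q = 0$), and peaks for structured-but-nontrivial
firing — which is precisely what distinguishes resonant, drive-locked
firing patterns from both silence and noise-dominated firing. A worked
example:

```{r}
pd <- pattern_distribution(c(1.1, 3.5, 2.3, 4.7, 1.8, 5.6), d = 3)
pd$probs
scm(pd)
```

Conditions that never fire (or fire fewer than $d$ times, which cannot be
embedded) enter resonance curves with the convention $C = 0$, $H = 1$: an
unobservable pattern is maximally disordered and carries no structure.
Reliable estimation of $P$ wants $L \gg d!$; the functions warn below
$100\,d!$ windows.

## SNR

As a classical cross-check, `estimate_snr` computes a raw one-sided
periodogram (mean removed, rectangular window by default, Hann optional,
Parseval-normalised so bin powers sum to the series variance) and takes
$\mathrm{SNR} = P_S/P_N$: the mean power over the three bins centred on
the drive frequency $f_e = 1/T_e$ against the mean background over a
±20-bin flank excluding those three, averaged over independent
realizations (30 by default). The local background makes the estimate
robust to the sloped FHN spectrum; because the band conventions are a
choice, absolute SNR values are less meaningful than the positions of
their maxima.

## Resonance protocols

`sweep_resonance` runs the full pipeline per value of one control
parameter ($D$, $\tau$, $g$, $p$, $k$, $N$), with per-condition seeds
derived from the base seed and the control value, so the curve is
independent of execution order and stable under grid refinement. Local
extrema are detected on the unsmoothed curve: an interior point strictly
above both neighbours whose prominence (height above the higher flanking
valley) exceeds 5% of the curve range by default. Two regimes call for
non-default prominences. Identifying the delay-resonance *comb* (the maxima
at multiples of $T_e$) uses a high prominence (0.45 of range): the SCM-vs-
$\tau$ curve genuinely carries *small* secondary peaks between the comb
peaks, and a strong low-$\tau$ coherence peak, so a permissive filter
returns them all and the comb reading requires separating "prominent"
maxima from those bumps. Conversely, the weak noise resonance at
$D \approx 0.001$ has a prominence far *below* 5% of the noise-curve range
at desk-scale series lengths (its peak rides on a near-uniform ordinal
background an order of magnitude below the main peaks), so it is assessed
as a raw local maximum against its grid neighbours rather than through the
filter. The default noise grid
is 25 geometric points on $[5\times10^{-4}, 0.2]$ augmented with the
distinguished intensities $\{0.001, 0.02, 0.04, 0.065, 0.08, 0.14\}$; the
default delay grid is $0, 2, \dots, 100$.

The intrinsic period $T_0$ — the firing period sustained by noise alone —
is estimated with the drive off ($A = 0$) as the mode of the ISI histogram
at bin width 0.1 (`estimate_intrinsic_period`). It governs how many noise
levels can resonate with a drive of period $T_e$: if
$T_e \in (m T_0, (m+1) T_0)$ the curve supports $m$ resonances
(`predicted_resonance_count`; the boundary $T_e = m T_0$ resolves to $m$).
At the defaults ($D = 0.08$) the package estimates $T_0 \approx 3.9$,
just above the boundary $14/4 = 3.5$, so the rule predicts 3–4 resonances
depending on where in its histogram bin the true period lies; the noise
sweep itself exhibits the four-peak structure (the lowest peak, near
$D = 0.001$, is the period-1 lock of the drive itself). $T_0$ is mildly
$D$-dependent; the estimate is taken at $D = 0.08$ by convention.

## Surrogate generators

`generate_periodic_isi` (cyclic interval patterns with truncated-Gaussian
jitter; truncation rather than a lognormal keeps the requested mean
interpretable) and `generate_iid_isi` (positive i.i.d. intervals) emulate
the two poles of mean-field ISI structure: period-$k$ firing, as seen at
the resonant noise levels, and structureless firing. They validate the
discrimination property the whole analysis rests on — jittered periodic
patterns score systematically higher $C$ than i.i.d. intervals of the
same mean and spread, and $C$ degrades monotonically as jitter grows.
What the surrogates do *not* emulate is the continuous-time dynamics:
correlations between successive mean-field ISIs beyond the imposed cycle,
drive-phase locking, and amplitude information are absent, so surrogate
tests validate the ordinal pipeline, not the simulator.

## Problem sizes and scaled-down defaults

The study-scale analysis uses interval series of length $L = 60{,}000$ per
condition. Peak *positions* on both the noise and delay curves stabilise
at far shorter series, so the package defaults to a desk scale of
$L = 2000$ per condition (`L_target`), with realizations of 600 time
units each; the test suite drops to $L = 250\ldots1000$ and restricted
grids, which still resolve the four-peak noise structure and the
$T_e$-spaced delay comb, at the price of noisier peak heights. The
60,000-interval setting remains a plain configuration choice
(`L_target = 60000`) for study-scale runs.

## Known limitations

* Explicit Euler at $dt = 0.001$ is the scheme of record here
  ($dt/\varepsilon = 0.1$); no adaptive or higher-order integrators are
  provided, and coarser steps distort the fast variable.
* Only Watts–Strogatz topologies are built in.
* The firing criterion (threshold 0, refractory 1) is a convention;
  absolute SCM/SNR peak heights shift slightly under other conventions
  while peak positions are robust.
* Curves are estimated pointwise; no smoothing or uncertainty bands are
  attached to extrema detection beyond the prominence filter.
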