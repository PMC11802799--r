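---
title: "Singularity-response methods: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Singularity-response methods: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srclock)
```

## The circular limit-cycle model

`srclock` treats the circadian clock as a point on a circular limit cycle of
radius 1; a stimulus displaces every state in parallel by the complex vector
$F e^{i\Phi}$, so a state at phase $\theta_1$ lands at

$$\theta_2 = \arg\{e^{i\theta_1} + F e^{i\Phi}\},$$

and the phase response curve (PRC) is $g(\theta_1) = \theta_2 - \theta_1$,
wrapped to $(-\pi, \pi]$. The model has exactly two parameters: the stimulus
strength $F$ (in limit-cycle radii) and direction $\Phi$. Its key qualitative
fact is the singular point: for $F = 1$ and a displacement antiparallel to the
state vector ($\Phi = \theta_1 + \pi$) the state lands at the origin, where
phase is undefined. Below that strength the PRC is continuous (type 1, the
post-stimulus phase map $\theta_1 \mapsto \theta_2$ winds once around the
circle); above it the PRC is discontinuous (type 0, winding number zero).

Assumptions worth stating plainly: states sit **on** the cycle when stimulated
(relaxation during the stimulus is ignored — the Stuart-Landau module
quantifies the error of that idealization), the cycle is circular, and the
stimulus direction is phase-independent. Amplitude-dependent PRC families and
non-circular geometries are out of scope.

## SR parameters

The singularity response (SR) summarizes a PRC by the complex order parameter
of the post-stimulus phases,

$$R e^{i\Theta} = \frac{1}{2\pi}\int_0^{2\pi} e^{i\{\theta + g(\theta)\}}\,d\theta,$$

estimated three ways:

* `sr_from_prc()` — equal-weight quadrature over uniform phase nodes
  ($\theta_j = 2\pi j/n$), either from the model or from a sampled PRC whose
  own phases serve as nodes;
* `sr_from_cells()` — the finite-sample analogue
  $\frac{1}{N}\sum_j e^{i\{\theta_j + g(\theta_j)\}}$ over per-cell records,
  valid when cell phases at stimulation are approximately uniform;
* `measure_sr()` — the direct bulk route: detrend, then cosine-fit the
  post-stimulus rhythm (below).

$R \le 1$ always holds for the first two (means of unit vectors; floating-point
excursions above 1 are clamped at $10^{-9}$ tolerance). When $R$ falls below
`theta_floor` (default 0.02) the argument of the resultant is numerically
meaningless and $\Theta$ is reported `NA`. In the circular model $R$ depends
only on $F$ (not $\Phi$) and $\Theta = \Phi$ exactly, which is what makes the
pair a stable summary across the type transition.

## Direct measurement from bioluminescence

Raw luminescence $l_j$ is converted to a relative deviation from its centered
24-h moving average, $L_j = (l_j - \bar l_j)/\bar l_j$, with $n$ points per
half window (at the default 10-min sampling, $n = 72$, a 145-point window).
Edge points without a complete window are dropped rather than averaged over a
shrunken window: the fit window starts 24 h after the stimulus, so it is
interior by construction and shrinking windows would only add boundary bias.
Points with $\bar l_j \le 0$ are flagged; a series with more than 5% flagged
points is rejected.

The cosine fit is linear least squares of
$L = b + a_1\cos(\omega t') + a_2\sin(\omega t')$ with $t' = t - t_\mathrm{ref}$,
giving amplitude $\sqrt{a_1^2 + a_2^2} \ge 0$ and acrophase
$\mathrm{atan2}(-a_2, a_1)$ (negative amplitudes are folded into the
acrophase). With `period_mode = "free"` the period is profiled over
[20, 28] h by a 0.05-h grid search plus golden-section refinement of the
residual sum of squares — deterministic, no starting-value sensitivity. The
default is a fixed 24-h period: the bulk data the pipeline targets are 24-h
reporter rhythms, and the free mode exists for period checks. With
$t_\mathrm{ref}$ at the stimulus time the acrophase *is* the SR phase: a
population with order parameter $R e^{i\Theta}$ at the stimulus produces
collective output $\propto R\cos(\sigma(t - t_s) + \Theta)$, so no separate
back-extrapolation step is needed; phases are also reported in circadian hours
($\Theta \cdot 24/2\pi$). The default fit window is 24–48 h post-stimulus
(24–96 h is a documented option for slowly relaxing, SCN-like preparations).
Bulk amplitudes live on the detrended-luminescence scale, not the unit scale
of the order parameter; comparisons against same-plate vehicle controls and
max-normalization (below) handle that downstream.

## PRC reconstruction

`forward_amplitude()` evaluates the $F \mapsto R$ map by quadrature. The map is
strictly increasing, $R(0) = 0$, and approaches 1 asymptotically, so inversion
is a bracketed root-finding problem: `invert_amplitude()` uses derivative-free
bisection to a tolerance of $10^{-6}$ on $R$ (the squared error at the solution
is attached for reference against gradient-descent formulations). Amplitudes at
or above `forward_amplitude(f_max)` (default $F_{max} = 10^3$, ceiling
$\approx 0.9999997$) are reported unattainable rather than extrapolated.
`reconstruct_prc()` then sets $\Phi = \Theta$, $F = R^{-1}(\cdot)$ and
evaluates the model PRC; round trips PRC → SR → PRC are identity to quadrature
accuracy ($<10^{-2}$ rad at the defaults).

Two quadrature choices matter. First, the internal default is $10^4$ nodes,
not the 100-node rule historically used in spreadsheet solvers
(`legacy_quadrature = TRUE` restores it): 100 nodes shows visible bias near the
transition $F \approx 1$. Second, sampling must resolve the winding of the
post-stimulus phase map, whose slope grows like $1/|F-1|$ near the transition;
`classify_prc()` refuses (class `srclock_ambiguous`) when the wrapped winding
sum is farther than 0.25 turns from an integer, and `find_type_transition()`
uses $2^{15}$ phases so bisection is trustworthy down to $|F-1| \approx
2\times10^{-4}$, an order below its $10^{-3}$ stopping tolerance. A grid node
landing exactly on the singular pre-phase (possible only at $F = 1$) shifts
the grid by half a step with a warning — the singular input is measure-zero.

## Hill dose response and the phase line

SR amplitude versus concentration is fitted with
$H(x) = x^n/(x^n + \mathrm{EC}_{50}^n)$ by least squares in
$\log_{10}\mathrm{EC}_{50}$ (bounded to the dosed range $\times\,10^{\pm2}$)
with $n \in (0, 10]$, multi-started from a 5×4 grid of starts so no single
start can trap the fit. Zero-dose rows are excluded ($H(0) = 0$ exactly;
controls serve comparison, not fitting). Bulk dose tables whose ceiling sits
below 1 are first normalized by the largest per-concentration **mean**
response (a single noisy replicate must not set the ceiling); the recorded
`r_max` back-transforms predictions. Note the deliberate bias this buys:
normalizing by the top-dose mean divides by $H(x_{top}) < 1$, pulling the
fitted EC50 slightly low — accepted because the alternative (fitting a free
ceiling) is poorly identified on 5–6 dose designs. Non-monotone tables
(cytotoxic high doses) trigger a warning when the top-dose mean drops more
than 20% below the maximum; exclusions are an explicit user-supplied mask
(`exclude` column), mirroring how such points are handled in practice, never
an automatic rule.

The SR phase varies approximately linearly with SR amplitude for a given
stimulus. `fit_phase_line()` unwraps phases around their circular mean and
fits ordinary least squares $\Theta = a + bR$; a post-unwrap spread exceeding
$\pi$ aborts as wrap-ambiguous rather than silently fitting a line through a
cut. Circular regression is deliberately not used: the observed spans are
small and a straight line in the unwrapped coordinates is the model being
asserted. `predict_sr_at_dose()` composes the two fits — $R = r_{max}H(x)$,
$\Theta = a + bR$ — giving the four-parameter description of a stimulus from
which a PRC at any dose follows via `reconstruct_prc()`.

## Combination rules

* Different pathways: complex vector sum
  $R_{A+B}e^{i\Theta_{A+B}} = R_Ae^{i\Theta_A} + R_Be^{i\Theta_B}$. Reported
  amplitudes above 1 are capped at 1 with a flag, but the **uncapped** sum is
  retained: the phase always comes from it, and chained subtractions warn
  (`srclock_cap_bias`) instead of silently mixing capped and raw scales —
  whether to cap before or after subtraction is genuinely ambiguous, so the
  package flags rather than guesses.
* Same pathway: amplitudes are converted to equivalent doses by the
  closed-form inverse $x_{eq} = \mathrm{EC}_{50}(R/(1-R))^{1/n}$ and the
  mixture predicted as $H(x_{eq,A} + x_{eq,B})$ — saturation along the shared
  Hill curve, strictly subadditive for $n \le 1$. Amplitudes within $10^{-6}$
  of the ceiling are refused as saturated (infinite equivalent dose).
* Background: a same-type pre-treatment at concentration $x_{BK}$ attenuates
  an added dose to $H(d\,x_{BK} + x_{ADD}) - H(d\,x_{BK})$, with a
  multiplicative decay $d \in (0,1]$ of the background between administrations
  (presets `"none"`, `"half"`, `"third"`; decay is stimulus-specific, so the
  default is no decay). The textbook claim that this response decreases
  monotonically with background concentration holds for **concave** Hill
  curves ($n \le 1$ — the slope range actually observed for resetting
  stimuli); for $n > 1$ a mid-curve background can transiently amplify small
  additions, so the property is asserted only on $n \le 1$.
* Different-type backgrounds cancel: the added stimulus's SR is the vector
  difference of final and background responses.
* Competitive antagonists: when the final amplitude falls below the
  background's own ($R_{final} < R_{BK}$), the inhibitor's SR amplitude is the
  deficit $R_{BK} - R_{final}$ and its phase is opposite the inhibited
  target's reset phase ($\Theta_{target} + \pi$).

Phase prediction for same-pathway and background rules always takes an
explicit phase line; lines are per stimulus and tissue, and a hidden default
would silently mix conditions.

## The Stuart-Landau simulator and the synthetic plate generator

Single cells are Stuart-Landau oscillators with the imaginary nonlinearity set
to zero, so radius and angle decouple: $dR/dt = \alpha(A - R^2)R$,
$d\theta/dt = \sigma$. With $A = 1$ the limit cycle has radius 1 ($\sqrt A$ is
the cycle radius — the reading consistent with the radial equation's fixed
point) and $\sigma = 2\pi/24$ gives a 24-h clock. The radial equation is
logistic in $R^2$, so propagation is closed-form (`evolve()`), with no
integrator error; the recovery rate $\alpha$ is not specified by the source
experiments, so it defaults to 1 h⁻¹ and is exposed everywhere — the
fast-relaxation limit ($\alpha = 10$) reproduces the circular model to
$|\Delta R| < 0.02$, while slow relaxation ($\alpha = 0.05$) measurably
deviates, which is the circular approximation's main caveat.

`simulate_sr()` applies a stimulus to 100 oscillators at the uniform grid
$\theta_j = 2\pi j/100$, samples the collective output
$\overline{R_j\cos\theta_j}$, and cosine-fits 24–48 h post-stimulus — the
in-silico mirror of the bulk pipeline.

`generate_plate()` dresses this in measurement realism: per-oscillator periods
drawn from $\mathcal N(24, sd)$ (default sd = 1 h, fibroblast-like), a
multiplicative exponentially decaying baseline (default 1000 counts, 1%/h —
signal halves in ~3 days as substrate is consumed), modulation depth 1,
additive Gaussian noise (SD 5 counts), 10-min sampling over 168 h with the
stimulus at 96 h, all randomness from one recorded seed. Two initial
conditions are provided: the default `"uniform"` grid represents a culture
already desynchronized at stimulation (the state the SR measurement is
defined on, and the initial condition used for in-silico validation), and
`"synchronized"` starts all oscillators at one phase to exhibit the
spontaneous decay of the collective rhythm. Frequency heterogeneity — not
phase diffusion — is the desynchronization mechanism: it is the simplest
mechanism producing the decay, and stochastic dynamics are out of scope. Under
Gaussian dephasing the envelope falls like $\exp\{-(2\pi t\,sd/24^2)^2/2\}$,
i.e. to ~58% of initial by 96 h at sd = 1 h; claims of much faster decay
would require heterogeneity well outside the plausible range.

What a green end-to-end test establishes, and what it does not: the chain
generate → measure → invert recovers the programmed strength within 15% under
the validation condition (identical frequencies, uniform phases, noise and
baseline decay on). With heterogeneous periods the resynchronized bundle keeps
dephasing through the fit window, attenuating measured amplitude by
$\approx \exp\{-(2\pi\,sd\,\Delta t/24^2)^2/2\}$ (~7% mid-window at sd = 1 h)
plus a finite-ensemble random residual of order $\sqrt{1/3N}$ — real physics
of bulk measurement, asserted as a separate bias test, and one reason measured
bulk SR ceilings sit below 1 and get max-normalized in dose-response fits. The
generator also does not emulate cell death, drift in period over days, or
spatially coupled (SCN-like) tissue, so green tests say nothing about those.

## Degenerate inputs and error conventions

Singular stimuli raise `srclock_singularity` (tolerance $10^{-9}$ radii — the
singular set is measure-zero, so the tolerance only guards exact hits);
under-sampled PRCs raise `srclock_undersampled`/`srclock_ambiguous`; windows
with variance below $10^{-30}$ are `srclock_degenerate` (a zero-stimulus
simulation returns $R = 0$ rather than a fit); unattainable amplitudes are
`srclock_out_of_range`; saturated amplitudes `srclock_saturated`;
non-inhibitory inputs to the antagonist rule `srclock_not_inhibitory`. All
conditions carry classed errors so callers can branch without string matching.

## Known limitations

Phase-only resetting of on-cycle states; no coupled oscillators; no
pharmacokinetics beyond one decay factor; linear phase–amplitude relation
assumed over the fitted amplitude range only; ceiling-normalized Hill fits
carry the small deterministic EC50 bias described above; the CLI is a thin
wrapper and does not stream large plates.
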