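---
title: "A compartmental model of oral drug absorption with discrete gastric emptying"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental model of oral drug absorption with discrete gastric emptying}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsim)
```

## The model

`gutsim` simulates the journey of an orally administered drug through five
compartments: stomach, duodenum, jejunum, ileum–colon, and the peripheral
blood circulation. The model's deliberate economy — three free parameters,
everything else fixed physiology — makes it suited to early drug assessment,
when concentration–time data are scarce.

### Stomach and duodenum: continuous dynamics, discrete events

Both compartments are stirred tanks. Between events the stomach gains volume
from gastric juice secretion ($dV_s/dt = Q_{gj}$) and gains dissolved drug
from the tablet; the duodenum gains pancreatic juice ($dV_d/dt = Q_{pj}$).
Every $T_e = 600$ s a discrete emptying event fires: the duodenum first
discharges its entire content into the jejunum as a *bolus*, then the stomach
transfers $1/20$ of its current volume to the duodenum. Gastric drug
concentration is continuous across events, so the duodenum restarts at the
stomach's concentration. The stage ends when the gastric volume falls below a
configurable fraction (default 1%) of its initial value — with zero
secretions that takes exactly
$\lceil \ln 0.01 / \ln 0.95 \rceil = 90$ events — or at `t_max`.

The "1 s" duration of the physical discharge is treated as an instantaneous
state jump: at the model's time scale the post-event states are identical and
the integrator avoids a stiff pulse.

Tablet dissolution follows the Noyes–Whitney form with pH-dependent
solubility,
$$ S_s = S_0\,(1 + 10^{\,\mathrm{pH} - \mathrm{p}K_a}), \qquad
   k_{sd} = \frac{3 D S_s}{4\pi\rho}, \qquad
   \frac{dr_p}{dt} = -4\pi\rho\,r_p^2\,k_{sd}\,(S_s - C_s), $$
with the source term $k_{sd}(S_s - C_s)$ feeding the gastric drug balance.
Two printed equations of this family do not conserve mass jointly: the
solution source does not equal the time derivative of the mass implied by
the shrinking sphere. Both are therefore implemented exactly as stated, and
dissolution is *terminated* when either the cumulative dissolved mass
reaches the dose (a hard global mass cap) or the radius reaches zero,
whichever happens first; the triggering condition is logged. Note the
$r_p^2$ dependence means the radius decays hyperbolically and never reaches
zero in finite time, so in practice the dose cap is the binding stop. The
acid-form solubility scaling is applied to every drug, bases included, as
stated.

### Jejunum and ileum–colon: a bolus train against countercurrent blood

Each emission becomes a spherical bolus of volume $V_{bol}$ moving at
constant velocity $u$ ($x_i(t) = u\,(t - t_i)$). The intestinal wall
permeability varies axially as a Cauchy-shaped bump per segment,
$$ \alpha_l(x) = \frac{\lambda_l}{\pi\,\bigl(1 + (x - \tilde L_l)^2\bigr)},
   \qquad l \in \{j, ic\}, $$
with peaks at $\tilde L_j = L_j/3$ (jejunum) and
$\tilde L_{ic} = (L_j+L_i+L_c)/5$ measured *from the ileum inlet*. The
segment-local convention for the ileum–colon peak is a deliberate choice: a
global coordinate of 1.5 m would place that peak inside the jejunum, whereas
the segment-local reading puts it 3.5 m down the tract with its tail covering
the colon, matching the intended low colonic absorption. The quadratic term
carries an implicit 1 m² scale; the profile is used verbatim, without
renormalizing the truncated Cauchy mass over the finite segment.

Splanchnic blood flows countercurrent to the boluses and meets them in
sequence, most distal first. The chain is algebraic,
$$ C_b^i = C_b^{i-1} + K_i\,(C_i - C_b^{i-1}), \qquad
   K_i = \frac{\alpha_i V_{bol}}{\pi r_{bol}^2 (u + v_b)}, $$
solved by forward recursion inside the right-hand side, while each bolus
obeys $dC_i/dt = -\alpha_i (C_i - C_b^{i-1})$. The $K$ construction makes the
blood's per-contact mass gain exactly equal the bolus's loss; the simulator
asserts this identity numerically at every step and reports the worst
relative discrepancy (machine precision in practice). The chain order and
whether $\alpha_i$ tracks the moving bolus (default) or stays frozen at its
entry value are configuration switches.

The peripheral circulation is a stirred pool with delayed recirculation:
$$ V_b \frac{d\bar C_b}{dt} = Q_b\,(C_b^{out} - \bar C_b) - k_d \bar C_b V_b,
   \qquad C_b^0(t) = \bar C_b(t - \delta), $$
with history $\equiv 0$ for $t \le 0$.

### Numerical scheme

The gastro-duodenal stage uses an adaptive stiff-capable solver
(`deSolve::lsodar`, rtol $10^{-8}$, atol $10^{-12}$) between events, with a
root function stopping dissolution exactly at the dose cap. The intestinal
stage is a compiled fixed-step classical RK4 integrator whose step divides
the emptying period, so bolus entries and exits land on step boundaries; the
delay term is linearly interpolated from the stored history, with the step
bounded by $\delta/3$ so lagged lookups never run ahead of the history.
Because the estimation bounds admit exchange rates up to
$\alpha \approx 0.16\ \mathrm{s^{-1}}$ — far beyond the stability region of
an explicit step of 30 s — the stepper automatically subdivides each step so
that (fastest active rate × substep) stays below 0.8. Against an
independently coded dense-ODE reference the stepper agrees to better than
$10^{-8}$ relative (no delay) and $10^{-6}$ (90 s delay) at the test step
sizes.

Capacity bounds follow from the geometry: a segment of length $L$ holds at
most $\lfloor L f_e / u \rfloor$ boluses (45 for the whole intestine, 33 for
the ileum–colon, at defaults). Should a configuration exceed the bound the
oldest bolus is retired with its residual drug logged as unabsorbed.

## Parameters

| Symbol | Meaning | Default | Units |
|---|---|---|---|
| $T_e$ | emptying period | 600 | s |
| $f$ | emptied fraction per event | 1/20 | — |
| $\delta$ | peripheral transit delay | 90 | s |
| $u$ | bolus velocity | 1/3600 | m/s |
| $v_b$ | intestinal blood velocity | 0.21 | m/s |
| $Q_b$ | intestinal blood flow | 0.033 | L/s |
| $L_j, L_i, L_c$ | segment lengths | 2, 4, 1.5 | m |
| $V_b$ | peripheral blood volume | 4 | L |
| $r_{int}$ | intestinal radius | 0.01 | m |
| $Q_{gj}, Q_{pj}$ | juice secretion rates | 2.3e-5, 1.2e-5 | L/s |
| pH | gastric pH | 2.0 | — |

Sources differ on the emptying frequency (1.6 vs 1.66 mHz vs "every
600 s"); the event equations are defined on a 600 s cadence, so
$T_e = 600$ s exactly and tabulated frequencies are treated as rounded.
The secretion rates and gastric pH are not fixed by the reference parameter
set; the defaults correspond to roughly 2 L/day gastric and 1 L/day
pancreatic secretion and a fasted stomach, and all three are configurable
(setting the secretions to 0 recovers a pure-emptying model with exact
geometric volume decay). The initial gastric volume defaults to 1 L (meal
plus fluid). A molar mass per drug, needed only to express molar
solubilities in mg/L, ships with the fixtures; the normalized estimation
objective is insensitive to it.

The three free parameters are $\lambda_j$, $\lambda_{ic}$ (Cauchy scales,
m²/s; published tables use a $10^{-3}$ scale) and $k_d$ (peripheral
elimination, 1/s). Estimation bounds default to
$\lambda \in [10^{-7}, 0.5]$ m²/s and $k_d \in [10^{-7}, 10^{-3}]$ 1/s,
covering the span of published estimates with a wide margin.

## Estimation

The objective normalizes both curves by their own maximum over the $M$
observation instants,
$$ \phi = \sum_{y=1}^{M} \left(
   \frac{\bar C_{obs}(t_y)}{\max_y \bar C_{obs}}
 - \frac{\bar C_{sim}(t_y)}{\max_y \bar C_{sim}} \right)^2, $$
making it invariant to the units of the observations. The simulated curve is
interpolated to the observation instants with a monotone cubic spline, and
the normalizing maxima are taken over those instants, not the dense grid.
This is ordinary least squares on normalized curves: it weights the peak
region most and is least informative about the decay tail — a known
trade-off, kept as stated.

`fit_absorption()` minimizes $\phi$ by bounded Levenberg–Marquardt in
log-parameter space from `n_starts` log-uniform random starts (deterministic
given `seed`). Two structural features complicate the search. First, beyond
a saturation threshold the jejunal bump absorbs essentially the whole bolus
content, so the normalized curve becomes insensitive to $\lambda_j$ (and
similarly $\lambda_{ic}$): the objective develops wide, nearly flat plateaus
on which gradient steps stall. Second, the ileum–colon scale moves the curve
weakly everywhere. The fitter therefore follows the multistart stage with
coordinate profiling: each Cauchy scale in turn is swept on a 13-point log
grid (plus a zoom pass around the best cell) while the other two parameters
are refit, for two rounds, ending with a full three-parameter polish. On
noise-free synthetic curves this recovers generating triples drawn across
the published parameter range to ~$10^{-10}$ relative; with realistic noise
the Cauchy scales beyond the saturation threshold remain weakly identified —
users should read wide profile plateaus, not the point estimate, in that
regime. The gastro-duodenal stage does not depend on the three parameters,
so its bolus train is computed once per fit and reused by every objective
evaluation.

`predict_dose()` re-runs the forward model at a new dose with fitted
parameters unchanged (the initial tablet radius scales with the cube root of
the dose). With dissolution bypassed (`predissolved = TRUE`) the whole model
is linear in concentration and the curve scales exactly with the dose; with
the tablet ODE active the scaling is only approximate.

Effective intestinal permeability integrates the profile per segment,
$$ P_{eff} = \frac{r_{int}}{L_j} \int_0^{L_j} \alpha_j\,dx
 + \frac{r_{int}}{L_i + L_c} \int_{L_j}^{L_j+L_i+L_c} \alpha_{ic}\,dx, $$
evaluated in closed form via the arctangent antiderivative and reported in
cm/s; the tests cross-check it against adaptive quadrature to $10^{-10}$.

## The synthetic-observation generator

The clinical concentration–time curves used to estimate published parameters
come from the cited literature and are not redistributable, so
`generate_observations()` stands in for them: it runs the forward model at
known "true" parameters, samples at the requested instants, and applies
multiplicative Gaussian noise (`value * (1 + eps)`, `eps ~ N(0, cv)`,
clamped at 0), the CV form reflecting concentration-proportional assay
error. It emulates a single-subject mean curve; it does not emulate
inter-subject variability, study-level error bars, assay detection limits,
or sampling irregularities of real trials — passing recovery tests therefore
demonstrates the estimator's correctness on the model's own terms, not
clinical identifiability. The recovery study uses 15 sampling instants over
24 h (0.5–24 h, denser early) and five true triples drawn once, log-uniformly
across the span of the published estimates (a fixed list, independent of the
optimizer seed).

## Degenerate inputs and edge behavior

Zero-volume duodenal discharges (an empty duodenum at the first event) are
dropped; zero Cauchy scales give an identically zero blood curve; a bolus
reaching the end of the colon is frozen and its residual logged; tiny
negative concentrations from roundoff are clamped at zero. Supersaturation
($C_s > S_s$) cannot arise from the dynamics and is defensively clamped in
the radius law. The discrete train leaves a visible signature: each loaded
bolus leaving the colon drops the chain outlet step-wise, producing ripples
of up to ~1% of $C_{max}$ on the concentration curve. The curve is
single-peaked up to that ripple.

## Known limitations

Beyond the identifiability plateaus discussed above: no first-pass hepatic
extraction or upper-GI absorption; no meal-composition effects on
dissolution or emptying; no particle-size distribution (the dose is one
sphere); no population variability. The printed dissolution pair is used
verbatim despite its internal mass inconsistency (capped globally), and the
per-contact blood balance uses the flow-matched $K$ construction, which is
consistent per contact but — like the underlying model — does not equate the
splanchnic pickup flow $\pi r_{bol}^2 (u+v_b)$ with the peripheral inflow
$Q_b$; the mass audit reports both bookkeepings.

Test problem sizes: the suite simulates 2–24 h horizons at a 30 s step
(2.5–10 s where integrator accuracy itself is under test) and fits five
recovery triples at 6 multistarts; these sizes exercise every code path at
full fidelity.
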