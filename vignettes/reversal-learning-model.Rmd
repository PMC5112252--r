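---
title: "A gated-expert recurrent rate network for serial reversal learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A gated-expert recurrent rate network for serial reversal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revlearn)
```

## The problem

In a serial reversal task a subject first learns a stimulus–response
contingency, then the contingency is inverted, and later the original
contingency is re-instated.  Humans and animals re-acquire a previously
learned contingency faster than they acquired its reversal — behaviour that
a single monolithic value-learning network cannot produce, because the
reversal forces it to overwrite the very weights that encoded the earlier
strategy.  `revlearn` implements a hierarchical recurrent rate network in
which several *expert* modules share one sensory *basis* network and a
*dynamic control network* (DCN) releases exactly one expert per trial from
inhibition.  Because suppressed experts neither act nor (to first order)
learn, a strategy can survive a reversal inside a dormant expert and be
re-adopted quickly when its contingency returns.

## Unit dynamics

Each model unit is the mean state of a cortical column with membrane
potential $p$ and firing rate $g(p)$, driven by excitatory, inhibitory and
modulatory input through shunting dynamics

$$\dot p = -\alpha p + (\beta - p)\,I^{ex}\,(1 + \gamma I^{mod})
          - (\zeta + p)\,I^{inh},$$

with $g(p) = a + p$ for $p \ge 0$ and $a e^{p/a}$ for $p < 0$.  Defaults are
$\alpha = \beta = \zeta = 1$, $\gamma = 4$, and $a = 0.1$ (the rate-function
constant is not fixed by the model; $0.1$ gives a small positive spontaneous
rate and near-linear behaviour in the operating range).  Equilibrium
potentials are confined to $[-\zeta, \beta]$ for nonnegative inputs.
Modulatory input multiplies excitation and cannot drive a unit on its own.

`relax_network()` integrates the coupled system until the max-norm of
$\dot p$ falls below `tol` ($10^{-6}$).  The integrator is *exponential*
rather than forward Euler: with inputs frozen during one step the equation
is linear in $p$ and is integrated exactly over `dt` $= 0.1$.  Forward Euler
is unstable once the total drive exceeds $2/\mathrm{dt}$, which happens
routinely after weights have grown toward the cap of 4; the exponential step
has the same fixed points, is unconditionally stable, and preserves the
shunting bounds, so the convergence tolerance — not the step size — controls
accuracy.  Non-convergence within `max_steps` (5000) is reported via a flag
and the state reached is used, with a warning.

## Architecture

The default network is the simulated study condition: 10 binary input
features (five two-valued stimulus dimensions, one-of-two population code),
a 200-unit basis network split evenly over two layers, and experts of 50
units each (48 association units + 2 motor units); 3 experts in the
extended variant, 1 in the monolithic control.  Pathways: input excites
basis layer 1; layer 1 drives layer 2 (excitation and inhibition) and
receives modulatory feedback from it; layer-2 units compete through learned
lateral inhibition; layer 2 drives every expert's association layer, which
returns modulatory feedback; association drives the expert's two motor
units.  There are no connections between experts, so each expert can hold a
distinct stimulus–response strategy.

Two structural choices depart from a literal all-to-all wiring and are this
package's own:

* **Sparse random fan-in** (`fan_in = 5` presynaptic partners per target per
  block, `fan_input = 2` features per first-layer unit).  With all-to-all
  wiring at the stated initialization ranges the aggregate drive per unit is
  5–15, which saturates the shunting nonlinearity, and random dense
  projections average stimulus identity away (the across-stimulus contrast
  of basis-layer-2 rates falls to $\sim 0.1\%$), leaving nothing for reward
  learning to amplify within 160 trials.  Small random fan-in keeps the
  drive of order one and the contrast at several percent, while each drawn
  weight still comes verbatim from the stated uniform ranges ($[0, 0.2]$
  generally, $[0, 0.3]$ onto motor units, $[0, 0.1]$ for modulatory
  connections; cap 4).  Sparse input sampling additionally makes many
  first-layer units feature-selective, which seeds the task-relevant
  representation.  All-to-all wiring remains available (`fan_in = Inf`).
* **Expert-count-invariant feedback.**  Modulatory feedback onto basis
  layer 2 is sampled from the union of all association layers, so the
  aggregate feedback drive on the sensory stream is the same in the
  monolithic and extended variants and the two variants differ only in
  gating, not in sensory operating point.

## Learning

A trial has three phases.  (1) The network relaxes on the encoded stimulus
and an action is drawn by softmax over the released motor units' potentials
($\tau = 0.15$); the winning unit's equilibrium potential is the predicted
action value $Q_a$.  (2) An action-feedback signal propagates through the
accessory network: each unit's boost $\Delta p_l$ equals the sensitivity
$\partial p^\infty_a / \partial \xi_l$ of the winning unit's equilibrium to
a small additive current at unit $l$, obtained exactly by solving the
adjoint of the dynamics linearized at the equilibrium
(`propagate_accessory()`; verified against central finite differences to
relative error $< 10^{-3}$).  (3) The reward prediction error
$\delta = \varrho - Q_a$ (rewards $0.4$ / $0$) gates the three-factor update

$$\Delta W_{kl} = \eta\, \delta\, \Delta p_l\, f_l(p^\infty_l)\,
                  g(p^\infty_k),$$

with type-specific postsynaptic factors
$f^{ex} = (\beta - p)(1 + \gamma I^{mod})$,
$f^{mod} = \gamma (\beta - p) I^{ex}$, $f^{inh} = -(\zeta + p)$, heavy-ball
momentum 0.9, learning rate $\eta = 0.2$, clipping to $[0, 4]$ and the
structural masks.

The accessory boost is defined only up to a positive constant.  The exact
adjoint sensitivities attenuate roughly tenfold per processing stage, so
with a constant of 1 the sensory layers would receive about 1% of the motor
layer's credit and the basis representation could not reorganize within 160
trials.  We therefore scale the boost by a single global gain
(`accessory_gain`, default 20) and clip it to the unit activity bounds
$[-\zeta, \beta]$ — accessory units are shunting units, so their activity
saturates like any other unit's.  The clip leaves deep-layer credit at the
scaled sensitivity while preventing the (already large) motor-layer credit
from growing in proportion, which would otherwise make the value estimates
oscillate around their targets.  The gain was fixed once, together with the
fan-in defaults, by requiring the monolithic variant to acquire the initial
categorization within one 160-trial phase, and was not revisited
afterwards.

## The dynamic control network

Expert gating is competitive release from inhibition: a winner-take-all
(WTA) field of shunting units (self-excitation 0.8, uniform lateral
inhibition 0.4, constant background inhibition 0.15), driven by bias
weights $w$ from a tonic unit, plus per-trial uniform decision noise of
amplitude 0.1.  The most active unit suppresses its paired suppression
unit, releasing one expert's motor units; all rivals' motor units receive
inhibition of strength 4 and are effectively silent.  The bias learns from

$$\Delta w = p^\infty_B\,(p^\infty_{WTA} - w)
           + \sigma\, e\,(c - w) + e\, \nu,$$

with $\sigma = 0.9$, $c = 0.2$, $\nu \sim U[-0.01, 0.01]$, and the outstar
term tracking the WTA units' equilibrium firing rates.  Three quantities in
this rule are deliberately *not* taken at face value, because a literal
reading cannot reproduce the behaviour the rule is meant to produce:

* **Tonic bias activity** $p^\infty_B = 0.15$.  A shunting unit under
  constant drive equilibrates well below its ceiling; with $p^\infty_B = 1$
  the outstar term re-imprints the winner's advantage every trial faster
  than the error-driven attraction (at most $\sigma \cdot 0.4 = 0.36$) can
  erase it, and the selection can never reset — verified by fixed-point
  analysis of the coupled bias/field map.
* **Vigilance gating of the error signal** $e$.  The attraction and noise
  terms use the error magnitude only when it is *higher than usual*: a fast
  exponential trace of $|\delta|$ (rate 0.35) must exceed a baseline that
  tracks the best recently achieved error level (rising slowly at 0.02,
  falling at the fast rate) by more than 0.08.  The raw error cannot
  distinguish the large-but-falling errors of initial acquisition from the
  sudden error rise after a reversal, and isolated exploration errors
  would otherwise reset a well-working selection.  This is an orienting
  (match/mismatch) comparison in the spirit of adaptive resonance.
* **Bounded decision noise** in the selection stage (amplitude 0.1,
  distinct from the learning-rule noise $\nu$).  Its bounded support means
  a locked selection (bias gap $\gg 0.2$) can never flip spontaneously,
  while after a reset has collapsed the gap the winner is effectively
  re-drawn every trial, implementing the "random search" over experts.

With these choices one run shows the intended regimes: the selection locks
onto one expert during acquisition, a sustained error rise after a reversal
collapses the bias and the system hops between experts, and a re-instated
contingency re-captures its old expert because that expert's low errors
switch the vigilance off and the outstar ratchet locks it back in.

## Task and analyses

Stimuli are the 32 combinations of five binary dimensions; category is
determined by duration and modulation direction only (four categories of
eight stimuli; one category is the target, 25% of uniform draws).  The
schedule is three phases of 160 trials (Initial, REV01, REV02) with the
mapping reversed between phases, so phase 2 re-instates phase 0.  A run is a
*learner* if it answers strictly more than 70% correctly in every phase;
time to criterion is the first linear intersection of the per-block (40
trials) correct rate with the 80% level, in 1-based block ordinates, and is
undefined when never reached.  Group comparisons are two-sided paired
t-tests over learners (pairs with undefined times dropped); the paired
Wilcoxon variant used for experimental trial logs is also provided, as are
d' and an analysis entry point for external logs
(`analyze_trial_log()`).

Randomness is organized so that a master seed spawns one sub-seed per run,
and each run splits its stream into (network initialization), (stimulus
sequence) and (policy/control noise); the two model variants therefore see
identical stimulus sequences when run from the same master seed.

## What the simulations do and do not show

The synthetic task generator reproduces the design of the behavioural
experiments (binary dimension structure, 25% target rate, fixed 160-trial
phases, immediate deterministic reward).  It does not emulate stimulus
sampling constraints of the human protocol (pseudo-random balanced blocks
are available as an option), acoustic variability, motivation, or the
negative-reinforcement structure of the animal task; the package follows
the source analysis in treating avoidance learning as reward learning.

At this package's calibration the monolithic variant re-learns a reversed
mapping in place within roughly one 40-trial block, because value flips are
carried mainly by the motor-adjacent weights.  This makes the expert-reuse
advantage of the gated variant smaller than in the original report: learner
fractions fall below the published 53/100 and 73/100 (the conjunction of
three phases each strictly above 70% is marginal at our per-phase rates of
about 0.65–0.78), and the REV01-to-REV02 improvement of the gated variant,
visible in individual runs that re-instate their first expert, does not
reliably survive at the group level at desk-scale replication.  The mechanisms themselves — equilibrium
credit assignment matching finite-difference sensitivities, lock/reset
behaviour of the control network, and the emergence of task-specific basis
representations (high correlations among stimuli differing only in
irrelevant dimensions, low correlations across response categories) — are
all reproduced and tested.

## Numerical choices and degenerate inputs

Relaxations start from $p_0 = 0$ each trial (static inputs; no carry-over).
An ill-conditioned linearization in the accessory solve signals a
condition; the experiment loop logs it and skips that trial's weight
update.  Exact winner-take-all ties are broken uniformly at random.
Zero-variance basis activity vectors yield `NA` correlations with a
warning.  Degenerate paired tests (all differences zero, or fewer than two
complete pairs) are errors at the metric level and reported as `NULL` in
group summaries.  Problem sizes used by the acceptance analyses are 30–40
runs per variant (the original study used 100), which the binomial
tolerances of the checks account for.
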