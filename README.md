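# revlearn

Simulation of serial reversal learning in a recurrent shunting rate
network with gated expert modules.

## The scientific problem

In serial reversal experiments a subject learns a stimulus–response
contingency, the contingency is then inverted (REV01), and finally the
original mapping is re-instated (REV02).  Humans and animals reach
criterion faster in REV02 than in REV01 — they *re-use* the earlier
strategy instead of re-learning it.  A single value-learning network cannot
do this: the reversal overwrites the weights that encoded the first
strategy.  `revlearn` implements and tests a network architecture in which

* a shared **sensory basis network** (200 shunting rate units in two
  layers) learns task-relevant feature representations,
* several **expert networks** (50 units each: association layer + two motor
  units, no connections between experts) each hold one stimulus-to-action
  strategy, and
* a **dynamic control network** (DCN; tonic bias unit, winner-take-all
  field, suppression units) releases exactly one expert per trial from
  inhibition and re-learns its bias purely from the reward prediction
  error.

### The model in brief

Unit dynamics follow the shunting membrane equation
`dp/dt = -αp + (β-p)·I_ex·(1+γ·I_mod) - (ζ+p)·I_inh` with rate
`g(p) = a+p (p≥0), a·e^{p/a} (p<0)`.  Per trial: the network relaxes to a
stable state, an action is drawn by softmax over the released motor
potentials (`τ = 0.15`), and the winning unit's equilibrium potential is
the action value `Q_a`.  Credit assignment is by an accessory network whose
steady boost equals the adjoint sensitivity `∂p∞_a/∂ξ_l` of the winning
unit to input at unit *l*; the reward prediction error `δ = ϱ − Q_a`
(rewards 0.4 / 0) then gates the three-factor rule
`ΔW_kl = η·δ·Δp_l·f_l(p_l)·g(p_k)` with connection-type-specific
postsynaptic factors, momentum 0.9 and weight bounds [0, 4].  The DCN bias
learns `Δw = p_B·(p_WTA − w) + σ·e·(c − w) + e·ν` — outstar tracking while
the prediction error is usual, attraction toward `c` (reset) when a
sustained higher-than-usual error signals a contingency change.

## A worked example

One simulated subject of the extended (with-DCN) variant, full protocol
(3 phases x 160 trials):

```r
library(revlearn)
res <- run_experiment(default_config(dcn = TRUE), seed = 2)
round(res$metrics$phase_rates, 3)
#> phase0 phase1 phase2
#>  0.700  0.756  0.656
round(res$metrics$ttc, 2)
#> phase0 phase1 phase2
#>     NA   2.67   4.00
table(expert = res$trials$expert, phase = res$trials$phase)
#>       phase
#> expert   0   1   2
#>      1 155  14   0
#>      2   0  11   1
#>      3   5 135 159
```

Reading: the run answers 70.0% / 75.6% / 65.6% of trials correctly in the
three phases (a *learner* needs > 70% in all three, so this run narrowly is
not one).  `ttc` is the interpolated time to the 80% criterion in blocks of
40 trials — reached after 2.67 blocks in the first reversal, never reached
in phase 0.  The expert table shows the control network at work: expert 1
carries the initial phase, the first reversal triggers a reset and expert 3
takes over, and it is re-selected in the second reversal.

Group-level analyses (learner classification, per-phase time-to-criterion,
paired t/Wilcoxon comparisons) come from `run_group()` /
`analyze_trial_log()`; `basis_similarity()` computes the 32 x 32
correlation matrix of basis-network responses.  A command-line front end
with `run`, `group`, `analyze` and `similarity` subcommands is installed
under `inst/cli/revlearn`.

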