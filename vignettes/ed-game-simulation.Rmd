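---
title: "Simulating an emergency department dice game under traditional and TOC management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating an emergency department dice game under traditional and TOC management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgame)
```

## The model

`edgame` simulates a cooperative board game that reproduces, in stylised
form, patient flow through an emergency department (ED). The board has a
fixed flow graph: patients walk in, are registered, triaged, and assessed;
first assessment routes each patient to one of four specialized resources
(suture room, imaging, lab, medication) according to the patient's
treatment plan; after the specialized step the patient returns to medical
assessment to be discharged. Medical assessment therefore works twice per
patient — it is the system's capacity constraint until it is deliberately
exploited and elevated.

Time is discrete: a shift is 10 rounds of 48 minutes (8 hours). Each round
every *rolling area* — walk-in, registration, triage, medical assessment
and the four specialized resources — rolls a die: the value is the number
of patients that area may process this round (for walk-in, the number of
new arrivals). Capacity that meets an empty queue is lost; this interplay
of dependent stations and statistical fluctuation is the point of the game.

Two management regimes are modelled.

**Traditional.** The specialized resources run an efficiency-motivated
batching policy: they may roll only when at least `min_batch = 3` patients
wait. A round in which a non-empty specialized queue stays blocked earns
the resource a *delayed-care token*; once it holds two tokens, every
further blocked round with a non-empty queue makes one patient leave
without treatment (LWOT). Tokens clear whenever the resource may roll or
its queue is empty.

**Theory of constraints (TOC).** The batching policy is dropped
(`min_batch = 1`, hence provably zero LWOT), triage refers one low-urgency
patient per round to an external GP whenever its die shows 2+ (a proper
exit, not an LWOT), and the constraint's die is exploited: faces 1-3 are
remapped to 4-6, lifting the mean capacity from 3.5 to 5 (+43%) and
halving its spread. *Buffer management* prioritises the constraint's two
queues by buffer penetration: at most 6 waiting patients is green, 7-9
yellow, 10-12 red, 13+ black.

Six assessment strategies are compared (10,000 Monte Carlo shifts each in
the standard analysis): I random split of the assessment die between its
treat and discharge queues; II 50/50 with the odd point to treat; III
discharge priority; IV the full TOC rule set with buffer management; V as
IV plus a second die at assessment (elevation); VI the traditional rules
plus a second die — the "just buy more resources" counterfactual.

## Round semantics and numerical choices

The update is synchronous against start-of-round queue contents, in the
fixed order walk-in, registration, triage, assessment, then the four
specialized resources. A patient moved into a queue during a round is not
eligible for service there until the next round, so a round behaves like a
simultaneous physical turn; under this one-round-latency contract the
processing order is immaterial, which a property test verifies by
permuting it. All dice for a round are drawn up front in canonical order,
so the only mid-round randomness is strategy I's point assignment.

Walk-ins arriving in round *r* sit in the walk-in area and join the tail
of the registration queue at the start of round *r + 1*; this realises the
one-round latency for the board's entry point, which the published rules
leave implicit.

Queues are FIFO. An LWOT exit removes the longest-waiting patient of the
affected specialized queue. Buffer-management allocation is resolved point
by point with zone re-evaluation after every point; ties go to the treat
queue by default (`bm_tie_break = "discharge"` is available, since the
game's debriefing arguably prioritises discharging). Strategy I's
"randomly distributed" split is read as an independent fair coin per
capacity point (`random_split = "uniform"` gives the alternative reading).
All rules are work-conserving: capacity idles only when both queues are
empty.

Randomness is R's default RNG. A Monte Carlo batch derives the seed of run
*i* from the master seed as `(master * 10007 + i) mod (2^31 - 1)`, so any
subset of runs can be replayed in isolation. A `dice_script` replaces the
RNG entirely for replay and testing; the test suite contains a three-round
scenario whose every count was traced by hand and is matched exactly.

## Start-of-shift conditions

Every shift starts with 28 patients — the mean die roll (3.5) times the
eight rolling areas. The published board photograph fixes only this total,
not the per-area placement, so the package documents a default that
spreads the 28 in roughly that proportion:

```{r}
default_initial_allocation()
```

This choice matters. The downstream stock (assessment, specialized and
discharge-wait queues) can be discharged within a few rounds, while
upstream patients must traverse the whole pipeline first; sensitivity runs
show that shifting the same 28 patients upstream lowers discharge means by
2-4 patients and raises traditional-strategy LWOT means by 2-4. Results
produced with the default should therefore be read as conditional on this
placement. Treatment plans default to a single specialized stop, drawn
uniformly; multi-stop plans and non-uniform path probabilities are
supported via `path_probs` and per-patient plans but are not part of the
standard conditions.

## Measures

Per shift the package records discharges, GP referrals, their sum (proper
exits), LWOT, arrivals, end-of-shift WIP and the time-averaged WIP (mean
of end-of-round WIP over the rounds). Length of stay is estimated by
Little's Law, `LOS = WIP / output rate`, using the time-averaged WIP and
per-round output rates: proper exits per round for the discharge LOS, all
exits per round for the total LOS. A per-patient tracked LOS (entry round
to exit round) is also reported but deliberately labelled as an
alternative: within a 10-round window it cannot observe stays longer than
the window and is biased low in congested regimes, whereas the Little's
Law estimator correctly reflects the standing queue.

Across runs, `mc_summary()` reports mean, median, variance and sample
(n−1) standard deviation per measure, and for proper exits both a normal
approximation interval (mean ± 1.96 sd, the reported default) and the
empirical 2.5/97.5 percentiles. Strategy improvement is judged by
non-overlap of these intervals, as in the source analysis.

```{r}
set.seed(1)
s4 <- mc_summary(mc_measures(shift_config("IV"), n_runs = 300, master_seed = 1))
s3 <- mc_summary(mc_measures(shift_config("III"), n_runs = 300, master_seed = 1))
compare_strategies(list(s3, s4))
```

The 300-run batches above keep the vignette quick; the acceptance analysis
and `scripts/acceptance.R` use 10,000 runs per strategy, where each
strategy's mean is stable to about ±0.03 patients across master seeds.

## What the simulator does and does not show

The generator *is* the study system: dice capacities, a fixed flow graph,
single-stop plans, no clinical acuity, infinite bed capacity and no
inter-shift carryover (each shift restarts at 28 patients, which is what
makes runs comparable). Passing tests therefore validate the game's logic
and the comparative ordering of management policies under these stylised
conditions — batching causes LWOT, exploiting and subordinating to the
constraint roughly doubles throughput, adding resources without TOC helps
far less. They do not validate quantitative predictions for any real ED,
where arrivals are non-stationary, service times non-uniform and treatment
plans heterogeneous.

Two known limitations follow from under-determined rules rather than
implementation choices: the exact initial placement of the 28 patients
(see above) and the token-clearing convention for empty queues (tokens
clear here; if they persisted, starved resources would lose patients
faster under traditional rules). Both are configurable, and both shift
traditional-strategy LWOT and discharge means by a couple of patients
while leaving every qualitative conclusion — the strategy ordering, the
interval separations, zero LWOT under TOC — unchanged.
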