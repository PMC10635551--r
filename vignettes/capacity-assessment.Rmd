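---
title: "Assessing hospital capacity under stochastic treatment durations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing hospital capacity under stochastic treatment durations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shcapacity)
```

## The question the package answers

A hospital is a collection of *treatment areas* (wards, theatre suites)
partitioned into *treatment spaces* (beds, operating theatres).  Each space
`s` offers `T_s` time units over a planning horizon.  Patients arrive in a
fixed *case mix*: a proportion `mu1_g` of each patient type `g`, and within
each type a proportion `mu2_{g,p}` of sub-types, each sub-type following an
ordered care pathway of activities (e.g. preop → surgery → PACU → postop).
Every activity `a` has a random duration `t_a` and a set of candidate
spaces `S_a`.

For a total caseload of `N` patients the mix fixes all activity counts:
`n1_g = mu1_g N`, `n2_{g,p} = mu2_{g,p} n1_g`, and every activity on a
pathway occurs `n3_a = n2_{g,p}` times.  Counts are real-valued by default
— a fractional patient is one whose treatment completes in the next period
— with an optional integer mode.

The decision is the *allocation* `beta_{a,s}`: how many occurrences of
activity `a` are performed in space `s`, subject to
`sum_s beta_{a,s} = n3_a` and `beta_{a,s} = 0` outside `S_a`.  With random
durations the occupancy `U_s` of a space is itself random, so the capacity
question is posed with a chance constraint per space:

> maximise `N` such that an allocation exists with
> `Pr(U_s <= T_s) >= SL_s` for every space `s`,

where `SL_s` is the *service level* (its complement `RL_s = 1 - SL_s` is
the risk level).  A mean-value constraint `E[U_s] <= T_s` would tolerate
over-runs on roughly half of all realisations, which is why the chance
constraint — and the buffering it forces — is the point of the analysis.

## Duration models

Durations are represented by `shca_dist` objects: point masses, normals,
uniforms, and the workhorse *piecewise-constant* empirical family —
strictly increasing breakpoints whose adjacent pairs bound sub-intervals,
a probability weight per sub-interval, and uniform density within each.
Long right tails, ubiquitous in treatment-time data, are represented
without truncation.  Means are closed-form (`sum_j w_j (b_j + b_{j+1})/2`
for the piecewise family), sampling is inverse-CDF, and for all-normal or
all-standard-uniform spaces the service level has an exact closed form
(normal convolution, Irwin–Hall) that the Monte-Carlo machinery is tested
against.

## Sample average approximation and the scenario pool

`Pr(U_s <= T_s)` has no closed form for general duration mixes, so it is
estimated over `|I|` pre-generated scenarios: a pool stores realisations
`t_a^{i,n}` for every activity, scenario `i`, and realisation slot `n`.
One shared table per activity serves all candidate spaces — alternative
spaces are treated as identical — and the per-activity width is the
caseload bound plus 10% slack (lazily extendable).

The pool is generated once, up front, because a solution must always be
scored against the *same* scenarios; otherwise two evaluations of the same
allocation could disagree.  Each pool column is drawn from its own
sub-stream whose seed is derived deterministically from (master seed,
activity, column).  This makes the table bit-reproducible, independent of
generation or evaluation order, and lets the pool grow lazily without
disturbing existing values; it provides the same guarantee as per-(scenario,
activity) streams with a simpler growth story.

Fractional allocations are realised with per-slot weights: slot `n` counts
with weight 1 if `n <= floor(beta)`, with weight `beta - floor(beta)` at
`n = ceiling(beta)`, and 0 beyond.  Which slots a pair `(a, s)` uses is
pinned by its *lookup list* of pool indices with `|L| = ceiling(beta)`;
shrinking a list releases trailing indices, growing takes the lowest
unused index (a deterministic tie-break; any unused index would be
admissible).  Lists untouched by a move keep their indices, so evaluation
is invariant across unrelated perturbations — the property that makes
incremental re-evaluation exact, and that the test suite checks bit-wise
after thousands of random moves.

## The service-level violation score

Feasibility of an allocation is summarised by one number:

* deterministic mode: `SLV = sum_s max(E[U_s] - T_s, 0)`,
* stochastic mode: `SLV = sum_s max(SL_s - Phat(U_s <= T_s), 0)`,

with `Phat` the scenario frequency.  `SLV = 0` means every space meets its
constraint.  A scenario violates when `U_s^i > T_s + delta`;
`delta = 1e-9 T_s` approximates the strict inequality without a model
epsilon (the heuristic path never builds the big-M indicator constraints,
so the indicator epsilon of the exact model is absorbed into exact
floor/ceiling arithmetic).  Expected over-usage is reported conditional on
violating scenarios (zero when there are none), along with buffering
`B_s = T_s - E[U_s]` and the percentage utilisation/slackness.  Optional
managerial limits on `E[U_s]`, `E[O_s]`, or their ratio add further
`max(., 0)` penalty terms when supplied.  A per-scenario over-usage cap
`O_s^max` exists but is unbounded by default, since typical analyses leave
it open.

## Finding allocations: greedy construction plus annealing

For a trial caseload, a polynomial-time greedy pass assigns each activity
in pathway order: candidates ranked from largest to smallest free time
(ties to the lowest identifier), the top candidate filled as far as its
free time allows, fractional fills permitted, and — when no candidate has
free time left — the remainder forced onto the least-loaded candidate.
The worked two-activity example in the test-suite shows both faces of this
rule: one activity ordering ends at `SLV = 315`, the other at `SLV = 0`,
which is exactly why a repair step follows.

The repair is simulated annealing (SA) or threshold accepting (TA, the
default).  A move takes the space with the highest estimated
`Pr(U_s > T_s)` (deterministic mode: the largest over-usage), picks a
random assigned activity with an alternative candidate, and shifts
`min(O_obs / E[t_a], beta_{a,s})` of it — `O_obs` being the largest
observed over-utilisation, with a uniform fraction as fallback when
nothing is observed over — to the activity's least-risky candidate space
(random tie-break, chosen for fastest expected SLV descent; the
destination rule is otherwise open).  Improving moves are always accepted;
worse moves are accepted below a decaying control (TA) or with probability
`exp(-delta/control)` (SA).  The control starts at `lambda * SLV_0`
(default `lambda = 1e6`), decays by `exp(log(t_f/t_i)/n_controls)` after
every `steps` perturbations, and the run stops at `SLV = 0` or when the
control falls below `t_f = 0.001`.  Defaults are `steps = 300` and
`n_controls = 50`; the test suite uses smaller schedules (typically
`steps` 40–60, 15–25 controls) on its deliberately small instances.  Only
the two spaces a move touches are re-evaluated; the incremental score is
bit-identical to a full recomputation, which is tested.

## The outer search

`SLV = 0` holds for every caseload below the capacity and fails above it,
so the capacity is the location of a feasibility step and is found by
bisection: probe `N' = N_left + scale (N_right - N_left)`; a certified
`SLV(N') = 0` moves the left bound, anything else the right bound, until
the bracket is narrower than `tol` (default 0.5 patients).  The published
bound-update phrasing for this step is vacuous as written ("if
`N' >= N_left` then `N_left = N'`"); the implementation updates by probe
feasibility, which is what the surrounding description and the feasibility
picture require.  The weighted form of the upper objective
(`w1 N - w2 SLV` with `w2` of the order of the caseload bound) is realised
lexicographically — a probe only counts when its violation score is
exactly zero — with the weights retained in the report.

The bracket starts at `[0, Nhat]`, where
`Nhat = sum_s T_s / sum_a m_a E[t_a]` is a total-time relaxation that
ignores space compatibility.  It is provably no smaller than the
deterministic optimum and is used only for initialisation, so looseness
costs steps, not correctness.  The stochastic search brackets by the
deterministic capacity (a deterministic pre-solve), since buffering
normally pushes the stochastic capacity below it; when every probe up to
the bracket top is feasible the bracket expands (doubling, with a
warning).  The expansion cap uses the smallest sampled duration per
activity, because with lax service levels (`SL <= 0.5`, say) the
scenario-approximated capacity can legitimately exceed the mean-based
bound: only the favourable scenarios need to fit.  A failed annealing run
is treated as an infeasible probe, which makes the estimate one-sided
(conservative) — the known failure mode of this construction.

## Exact oracles

Two exact references certify the heuristic stack on tiny instances:

* **Deterministic LP** (`solve_det_lp`): `max N` under the balance and
  mean-occupancy constraints, solved with `pracma::linprog` and exportable
  in the standard LP text format.  Because a textbook simplex can cycle on
  degenerate instances, a second exact route is kept alongside: routing
  workloads `m_a E[t_a] N` into capacities `T_s` over the candidate
  structure is a transportation problem, feasible iff every activity
  subset's workload fits its candidate neighbourhood's total availability,
  so the optimum is the minimum neighbourhood-capacity-to-workload ratio
  over subsets.  The LP result is cross-checked against this cut condition
  in the tests, and the cut condition serves as fallback if the simplex
  fails.
* **Tiny SAA optimum** (`solve_saa_mip_tiny`): the sample-average
  deterministic equivalent is a mixed-integer program that is only
  tractable at demonstration scale.  At up to 2 activities, 2 spaces and 6
  scenarios it is solved *exactly* by enumerating the discrete structure —
  which scenarios each space may violate (at most
  `floor((1 - SL_s)|I|)`), and the integer floor of each allocation entry
  — and solving a small LP in `N` and the fractional parts for each
  combination.  Realisation indices follow a fixed block convention so the
  oracle's occupancy arithmetic is directly comparable with the
  scenario evaluator.  The big-M ceiling applied to violating scenarios is
  `T_s` plus the largest assignable samples, clipped at `10 T_s`.

The flagship certification instance has one activity with scenario
durations 40 and 80 (equiprobable): at `SL = 0.5` one of two scenarios may
violate and the optimum is `480/40 = 12`; at `SL = 1` it is `480/80 = 6`.
The heuristic stack reproduces both within the search tolerance.

## Synthetic instances and bundled reference objects

`generate_instance()` draws reproducible hospitals, pathways and mixes
with controllable shape: counts of areas/spaces/types/paths/activities,
availability and duration-mean ranges, a Dirichlet-style mix
concentration, and a `tail_heaviness` probability under which
piecewise-constant durations get a heavy right tail (99th percentile at
least three times the median — the regime observed in empirical
treatment-time data).  Generated instances always pass the domain
validations and round-trip through the YAML/JSON schema.

What the generator emulates is the *structure* of real data: compatible
space sets, mixed duration families, heavy tails, mix constraints.  What
it does not emulate: empirical duration shapes fitted to hospital records,
correlations between activities of one patient (durations are independent
here), arrival seasonality, or any scheduling granularity.  Passing tests
therefore certify the machinery — arithmetic, invariance, convergence
behaviour — not the clinical realism of any particular capacity figure.

Bundled reference objects (`fixture()`): the two-activity worked example
(`toy_4_3`), its single-pathway re-pose for capacity questions
(`toy_4_3_path`), a 21-specialty case mix with sub-type vectors
(`table2_mix`), a vector of reference capacity totals by risk level
(`table3_totals`), and a large hospital-shaped template
(`large_template`) whose duration models are synthetic placeholders —
its shape (≈1000 spaces, 65 ward areas, 19 theatres, 21 specialties),
not its numbers, is the point.

Three choices in the fixtures deserve a note.  First, the worked example's
counts `[10, 7]` cannot arise from one pathway (all activities on a
pathway share one count), so `toy_4_3` models two one-activity patient
types with mix `(10/17, 7/17)`, reproducing the counts at `N = 17`.
Second, sub-type vectors of length 1–4 in the reference mix are mapped to
pathway variants in listed order (day-of-surgery admission without/with
ICU, acute without/with ICU); this position-to-variant mapping is an
assumption.  Third, the reference mix is kept verbatim even though one
sub-type vector sums to 1.0001; the fixture validates at a 2e-4 tolerance,
and renormalisation exists behind an explicit flag rather than silently.

## Numerical choices and degenerate inputs

* Mix validation tolerance `1e-9`, renormalisation only on request.
* Floor/ceiling of allocation values use a `1e-9` tolerance so arithmetic
  like `1.9 + 0.3` lands on the intended lattice.
* `delta = 1e-9 T_s` for strict-inequality violation flags; the MIP
  epsilon is `1e-6` in the enumeration oracle.
* A zero starting SLV returns immediately from the annealer (the initial
  control would be degenerate).
* The empty caseload is always feasible, anchoring the left bracket.
* An in-demand activity with no candidate space is an infeasibility error
  at allocation time and pins the exact capacity at zero.
* Area-level mode pools each area's spaces into one resource
  (availability `sum_s T_s`, i.e. `T_w |S_w|` for homogeneous spaces) and
  requires a uniform service level within the area.

## Problem sizes in the test-suite experiments

The suite's stochastic experiments run on instances with 2–3 spaces, 2–4
activities and pools of 20–2000 scenarios, chosen so each property is
measured cleanly at interactive runtimes.  The scenario-count experiment
(mean capacity over 10 replications at `|I|` in {100, 500, 2000}) uses a
long-tailed instance with activity means 5–15 time units against
availabilities of 300–600 — deterministic capacity around 26 patients, so
the 0.5-patient search tolerance resolves the effect — at risk level 0.01,
where small pools visibly underestimate the extreme occupancy quantile and
the scenario count matters most.

## Known limitations

* The annealer provides a one-sided certificate: a positive SLV at exit is
  treated as infeasibility, so the capacity estimate can only err low.
* No scenario reduction or importance weighting; pools are plain i.i.d.
* The case-mix proportions are hard constraints; relaxing them (tolerance
  bands or explicit ranges on the mix) is a documented extension point,
  not implemented.
* Durations are independent across activities and patients; no
  within-patient correlation.
* Space-dependent durations `t_{a,s}` are not supported (the shared-pool
  convention assumes identical alternative spaces), and area-level mode is
  incompatible with them by construction.
* Golden-section/Fibonacci or adaptive-scale outer searches are not
  provided.
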