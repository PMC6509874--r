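---
title: "Screening two-target combinations in kinetic disease networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening two-target combinations in kinetic disease networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyscreen)
```

## The problem

A disease network — here a kinetic model of a metabolic pathway — sits in a
*disease state*: its standard parameters produce an abnormal amount of a
disease-related readout metabolite. A drug is modelled as a step change of
one enzyme pool's concentration at $t = 0$, and a therapy succeeds when it
drives the network into a *normal state*, defined as the cumulative
production of the readout over a fixed horizon falling below a fraction
$\theta$ of the disease-state output (default $\theta = 0.10$, i.e. a
ten-fold reduction over one hour).

`synergyscreen` implements a three-branch strategy for finding two-target
drug combinations in such models:

1. **Single-target classification.** For each candidate enzyme $i$ with
   initial concentration $E_{di}$, find the concentration $E_{hi}$ that
   *just* restores the normal state. The relative perturbation
   $\Delta E_i / E_{di}$, with $\Delta E_i = |E_{di} - E_{hi}|$, is the
   method's dose proxy. Targets with $\Delta E_i / E_{di} \le a$ (default
   $a = 1$) are *sensitive*; others are *insensitive*; targets for which no
   concentration within bounds reaches the criterion are *infeasible*.
2. **Sensitive pairs** are screened by Loewe combination-index
   isobolograms. For fractional doses of drug 1 and 2 relative to their
   single effective doses $(Dx)_1, (Dx)_2$, the combination index at an
   equal-effect point is
   $$CI = \frac{(D)_1}{(Dx)_1} + \frac{(D)_2}{(Dx)_2},$$
   with $CI < 1$ synergy, $CI = 1$ additivity, $CI > 1$ antagonism, and a
   *hybrid* verdict when different dose ratios fall on different sides.
   A semiquantitative grading table subdivides the CI axis from "very strong
   synergism" ($CI < 0.1$) to "very strong antagonism" ($CI \ge 10$); see
   `ci_grading_table()`.
3. **Insensitive pairs** are screened for joint feasibility: a combination
   is synergistic when a joint perturbation reaches the normal state with
   both relative doses $\le 1$, even though neither target can do so alone
   at an acceptable dose.
4. **Mixed pairs** implement $\alpha$-assisted dose reduction: the sensitive
   target's dose is cut to a fraction $\alpha$ (default $0.8$) of its single
   effective dose, $(\Delta E_j)^1 = \alpha\,(\Delta E_j)^2$, and the pair is
   synergistic when the insensitive partner can cover the remaining effect
   with $\Delta E_i / E_{di} \le 1$.

## The kinetic engine

Networks are specified as species (metabolites and enzyme pools) plus
reactions drawn from five rate-law families:
irreversible Michaelis–Menten catalysis
$v = K_{cat} [E_t][S] / (K_m + [S])$; the same with a competitive reversible
inhibitor, $K_m (1 + [I]/K_i)$ in the denominator; turnover activation by a
factor $(1 + [A]/KI)$; irreversible enzyme inactivation
$d[E]/dt = -K[E][I]$; and transcriptional up-regulation of an enzyme pool by
a metabolite signal, $d[E]/dt = k_{max} [g]^2 / ([g]^2 + k_{half}^2)$.
Catalytic fluxes are applied as $-v$ to the substrate and $+v$ to the
product with 1:1 stoichiometry; the two enzyme-pool laws act on the pool
itself. Units are model-declared and opaque to the engine — only internal
consistency matters. Each reaction has at most one substrate, product,
enzyme and modifier of each kind; multi-substrate kinetics, reversible
laws, events and compartments are out of scope.

The assembled ODE system is integrated with a stiff-capable adaptive method
(`deSolve::lsoda`) at `rtol = 1e-8`, `atol = 1e-12`, saving 201 evenly
spaced points. These tolerances keep the integration error orders of
magnitude below the 10% criterion resolution; the test suite verifies that
halving them moves cumulative outputs by less than 0.1% on all shipped
fixtures.

**Cumulative output.** "Cumulative production of the readout" is
operationalised as the time integral of the total synthesis flux *into* the
readout species, accumulated by an auxiliary ODE state (so it carries the
integrator's own accuracy rather than quadrature error on the saved grid).
This choice matters when the readout is itself consumed — in the shipped
arachidonic-acid model, LTB4 is degraded by CYP4F3 — because a
consumption-side drug can lower the readout *level* without touching its
*production*. The alternative reading (final readout concentration) remains
available via `readout_mode = "level"` in `screen_config()`.

**Positivity.** Rate laws are evaluated on the raw integrator state rather
than on values clipped at zero: the laws are smooth and self-correcting
through the $|S| \sim$ `atol`-sized negative excursions an adaptive solver
can take, whereas clipping introduces a derivative kink at zero that
provokes step-size collapse near substrate exhaustion. States are clipped at
zero only when trajectories are reported.

## Numerical choices in the searches

**Bisection for "just below".** The effective concentration is found by
bracketing plus bisection on the monotone dose–effect curve, terminating
when the achieved effect lies within `effect_tolerance` (default $10^{-3}$,
relative) *below* the threshold $\theta \cdot$ disease output. The returned
point therefore always satisfies the criterion, by at most 0.1% of the
threshold.

**Direction handling.** Whether an enzyme must be increased or decreased
depends on its position in the network (production-side versus
consumption- or diversion-side), so both directions are searched — decrease
within $[0, E_{di}]$, increase within $[E_{di}, E_{di} \cdot 10^{18}]$ by
doubling — and the cheaper (smaller-ratio) feasible direction is reported.
Decrease-direction ratios cannot exceed 1 by construction; any ratio above 1
implies an increase. An increase search is abandoned early when the effect
has moved away from the threshold for three consecutive doublings
(monotonicity is assumed, as isobologram methodology requires), or when the
integrator fails at an extreme dose, which is taken as the practical bound
of the searchable regime. Infeasibility is a classification outcome, not an
error, so batch screens stay total.

**Isobologram grid.** Fractional doses $f_1 \in \{0.1, 0.2, \dots, 0.9\}$
(`dose_grid_step = 0.1`); the endpoints reduce to single-target cases and
are excluded. The partner's dose is searched in the direction of its own
single-target solution so that fractional doses refer to a fixed axis.
Grid points whose completion is infeasible are dropped with a warning; an
isobologram with no feasible points is an error.

**Category and representative CI.** A pair is *additive* when all CI values
lie within the nearly-additive grading band $[0.90, 1.10]$, *synergistic*
(as a category) when all lie below it, *antagonistic* when all lie above
it, and *hybrid* otherwise. The representative CI is the minimum for
synergy, the maximum for antagonism, and both extremes (two graded entries)
for a hybrid pair. For the overall synergy tally a sensitive pair counts as
synergistic when its smallest CI is below 1 — the band governs the verbal
category, the additivity line governs the count. These two roles are kept
deliberately distinct: a pair can grade "nearly additive" at $CI = 0.92$
yet still count on the synergy side of the line.

**Insensitive-pair allocation.** The acceptance condition (both ratios
$\le 1$) does not say how the joint dose should be split between the two
targets — the single largest open choice in the method. The package applies
a common relative-dose scalar $s \in (0, 1]$ to both targets in each
target's cheaper direction (decrease: $E_{di}(1-s)$; increase:
$E_{di}(1+s)$, so the relative dose equals $s$ either way and the bound
holds by construction), bisects $s$ to the smallest feasible value, then
refines each axis separately. Direction assignments are tried in the order
suggested by the single-target searches, falling back over all four
combinations. This policy is deterministic and symmetric; other allocations
could find feasible points this one misses in strongly asymmetric networks,
which is why the per-axis refinement step is kept.

**Degenerate inputs.** A target whose unperturbed model already satisfies
the criterion gets dose 0 and ratio 0; a zero-reaction model simulates to
constant states with zero cumulative output; a target with $E_{di} = 0$
cannot be assigned a relative dose and is reported infeasible.

## What the fixtures emulate — and what they do not

The generators in `make_cascade()`, `make_additive_pair_model()`,
`make_insensitive_pair_model()` and `random_network()` produce monotone
enzyme-dose → readout responses so that every screening stage is testable
against independent oracles (closed forms, dense grid scans) without any
transcribed disease model:

* **Additive pair.** Two target pools of identical catalytic activity on a
  shared substrate: the dynamics depend only on the pool *total*, so Loewe
  additivity holds exactly and every isobologram point must give $CI = 1$ —
  the self-consistency check of the CI machinery. The readout is amplified
  through two squared transcriptional stages, making the effect scale as
  the fourth power of the pool total; this is what lets each pool reach the
  ten-fold criterion alone within the decrease direction (relative dose
  $\approx 1 - 0.1^{1/4} \cdot 2 \approx 0.88$ per pool). With unequal pool
  sizes the same construction yields one sensitive and one
  infeasible-alone target with closed-form joint doses, used to test the
  mixed branch.
* **Insensitive pair.** Two saturated parallel routes of equal capacity:
  either knockout alone leaves 50% of baseline, a joint 90% knockdown is
  needed — feasible only in combination.
* **Cascades and random DAGs** exercise validation, ranking and the
  bisection-versus-grid agreement on plain Michaelis–Menten chains.

These fixtures are *constructions*, not biology: they have exact symmetries
(perfect additivity, perfectly parallel routes) that real pathways lack, no
feedback regulation unless added, and no parameter uncertainty. Passing
tests on them demonstrates that the screening machinery is mathematically
correct — not that its verdicts on any particular real network are
biologically right.

## The synthetic arachidonic-acid model

`load_aa_model()` ships a 24-species model of arachidonic-acid metabolism
in human polymorphonuclear leukocytes: PLA2 liberates AA from membrane
phospholipid; the 5-LOX branch produces LTA4 and then LTB4 (the readout,
degraded by CYP4F3); the 15-LOX and 12-LOX branches produce hydroperoxides
reduced by PHGPx; the COX-2 branch produces PGH2, split by TXAS and PGES.
The model exercises all five law families: 15-HETE competitively inhibits
5-LOX, LTB4 feeds back as a PLA2 activator, 15-HPETE irreversibly
inactivates COX-2, and PGE2 drives COX-2 induction. Eight enzymes (PLA2,
5-LOX, 15-LOX, 12-LOX, TXAS, LTA4H, CYP4F3, PHGPx) are declared drug
targets; the horizon is 3600 s.

Its kinetic constants are **synthetic**: order-of-magnitude placeholders
chosen once for qualitatively realistic behaviour (micromolar
concentrations, $K_{cat}$ in the $10^{-2}\,\mathrm{s}^{-1}$ range, a
positive LTB4 baseline over one hour), recorded per constant in
`aa_model_provenance()`. The model is a realistic *workload* for the
screening pipeline — its size, stiffness and pathway structure — not a
fitted reproduction of measured PMN kinetics, and its screening verdicts
should be read as illustrations only. The unperturbed cumulative LTB4
production is pinned in the test suite as a transcription-regression guard.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `theta` | 0.10 | normal state: cumulative readout below this fraction of the disease output |
| `a` | 1 | sensitivity threshold on $\Delta E_i / E_{di}$ |
| `alpha` | 0.8 | mixed screen: fraction of the sensitive target's single dose retained |
| `dose_grid_step` | 0.1 | isobologram fractional-dose grid |
| `effect_tolerance` | $10^{-3}$ | relative "just below" tolerance of all bisections |
| `max_fold_increase` | $10^{18}$ | upper bound of increase-direction searches |
| `rtol`, `atol` | $10^{-8}$, $10^{-12}$ | integrator tolerances |
| `n_save` | 201 | saved trajectory points |
| `readout_mode` | `"flux"` | cumulative production vs final level |

## Problem sizes

The test suite runs on 3–9-species fixtures with horizons of 1–20 time
units, dense grid oracles of 1500 points, and the 24-species
arachidonic-acid model for loading, baseline and single-dose checks; the
full suite completes in about two minutes on one CPU. A full three-branch
screen of the 24-species model (`screen_all()`, 8 targets, 28 pairs) takes
a few minutes and is left to interactive use and the command-line
`screen` subcommand rather than the test suite.

## Worked example

```{r example}
model <- make_additive_pair_model()
config <- screen_config()
criterion <- disease_criterion(model, theta = 0.10, config = config)

rank_targets(model, criterion, config)

iso <- ci_isobologram(model, c("EP1", "EP2"), criterion, config)
iso
tidy(iso)
```

```{r plot, fig.width = 5, fig.height = 4}
autoplot(iso)
```

## Known limitations

* Single-substrate, irreversible rate laws only; no SBML import, no
  reversible kinetics, no compartments, no stochastic or spatial effects.
* Step perturbations at $t = 0$ stand in for dosing; there is no
  pharmacokinetics and no time-varying dosing profile.
* Monotone dose–effect is assumed by every bisection; detected
  non-monotonicity is handled by early abandonment of a direction rather
  than by a global search.
* Combinations of more than two targets are not screened.
* The insensitive-branch allocation policy is one defensible choice among
  several; its verdicts are existence proofs ("a feasible joint dose
  exists"), not optimality statements.
* CI values carry no statistical uncertainty; the grading bins are
  conventions, not inference.
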