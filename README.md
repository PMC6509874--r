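# synergyscreen

Screening two-target drug combinations in kinetic disease networks.

## The problem

Complex diseases are rarely controlled through a single target: disease
networks are robust, and a one-drug one-target intervention often cannot
move them out of their pathological operating point at an acceptable dose.
`synergyscreen` implements a systematic, simulation-based strategy for
finding *pairs* of enzyme targets whose combined perturbation restores a
kinetic disease network to a desired normal state — for pharmacologists and
systems biologists working with ODE models of disease-related pathways
(the shipped example is arachidonic-acid metabolism in human
polymorphonuclear leukocytes, readout LTB4).

## The method

A network state is scored by the cumulative production of a readout
metabolite over a horizon (default one hour); the *normal state* requires
this output to drop below a fraction θ (default 0.10) of the disease-state
baseline. A drug dose is a step change of an enzyme pool's concentration at
t = 0.

1. **Classify single targets.** For each target *i*, bisection finds the
   concentration *E<sub>hi</sub>* that just restores the normal state; the
   relative perturbation ΔE<sub>i</sub>/E<sub>di</sub>
   (ΔE<sub>i</sub> = |E<sub>di</sub> − E<sub>hi</sub>|) ranks the targets.
   Ratios ≤ *a* (default 1) mark *sensitive* targets, larger ratios
   *insensitive* ones.
2. **Sensitive pairs → Loewe combination index.** Along the equal-effect
   contour (isobologram), with (D)<sub>k</sub> the combined doses and
   (Dx)<sub>k</sub> the single doses of equal effect,

   CI = (D)₁/(Dx)₁ + (D)₂/(Dx)₂

   CI < 1 is synergy, CI = 1 additivity, CI > 1 antagonism; a Chou-style
   grading table subdivides the axis from "very strong synergism" to "very
   strong antagonism".
3. **Insensitive pairs → joint feasibility.** Synergistic iff a joint
   perturbation reaches the normal state with both relative doses ≤ 1.
4. **Mixed pairs → α-assisted dose reduction.** The sensitive target's dose
   is cut to α (default 0.8) of its single dose; synergistic iff the
   insensitive partner covers the remainder with a relative dose ≤ 1.

The kinetic engine supports Michaelis–Menten catalysis, competitive
inhibition, turnover activation, irreversible enzyme inactivation and
transcriptional up-regulation, integrated with `deSolve`. Models live in a
plain YAML schema (`read_network_model()` / `write_network_model()`).

## Worked example

Two enzyme pools of identical catalytic activity feed one readout through a
cooperative amplifier; the larger pool (`EP1`) can restore the normal state
alone, the smaller (`EP2`) cannot:

```r
library(synergyscreen)

model  <- make_additive_pair_model(e1 = 1.8, e2 = 0.2)
report <- screen_all(model, NULL, screen_config())
report
#> <screen_report> 2 targets (1 sensitive / 0 insensitive / 1 infeasible)
#>   synergistic pairs: 0 sensitive + 0 insensitive + 1 mixed = 1 total

report$targets[, c("rank", "target", "ratio", "direction", "classification")]
#>   rank target  ratio direction classification
#> 1    1    EP1 0.4863  decrease      sensitive
#> 2    2    EP2     NA      <NA>     infeasible

tidy(report)[, c("target_1", "target_2", "branch", "synergistic",
                 "sensitive_ratio_reduced", "insensitive_ratio")]
#>   target_1 target_2 branch synergistic sensitive_ratio_reduced insensitive_ratio
#> 1      EP1      EP2  mixed        TRUE                  0.3891             0.876
```

Reading the numbers: `EP1` alone needs a 48.6% knockdown
(ΔE/E = 0.4863) to cut the readout ten-fold, while no dose of `EP2` alone
suffices. Cutting `EP1`'s dose by 20% (α = 0.8, reduced relative dose
0.389), `EP2` can cover the remaining effect at a relative dose of 0.876 ≤ 1
— the pair is a synergistic mixed combination.

For sensitive pairs, `ci_isobologram()` returns the dose points and graded
CI (with `tidy()`, `glance()` and `autoplot()` methods); the symmetric
additive fixture `make_additive_pair_model()` yields CI = 1.000 at every
grid point, the Loewe self-consistency case. The shipped 24-species
arachidonic-acid pathway model (`load_aa_model()`; synthetic rate
constants, see `aa_model_provenance()`) provides a realistic workload:

```r
m <- load_aa_model()
rank_targets(m)   # ranks PLA2, 5-LOX, 15-LOX, 12-LOX, TXAS, LTA4H, CYP4F3, PHGPx
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/synergyscreen.R rank   --model model.yaml --out ranks.csv
Rscript inst/cli/synergyscreen.R screen --model model.yaml --mode all --out out_dir
Rscript inst/cli/synergyscreen.R fixtures --kind random --size 6 --seed 1 --out fixture.yaml
```

## Documentation

The methods vignette (`vignettes/screening-methods.Rmd`) documents the
model assumptions, the numerical choices (tolerances, direction handling,
the insensitive-pair allocation policy, category vs tally conventions) and
what passing the fixture-based tests does and does not demonstrate about
real networks.
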