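# rpacirc

Simulation and analysis of a synthetic **robust perfect adaptation (RPA)**
gene circuit: a two-node transcriptional negative-feedback loop — buffer
node B activates output node A, A represses B — coupled with a *linear
weak positive feedback* of B on itself. Perfect adaptation means the
output responds transiently to a step in the inducer input and then
returns to (nearly) its pre-stimulus level; the linearity of the
buffer-node self-activation is the design constraint that makes this
robust.

The package is aimed at systems/synthetic biologists who want to explore
why this topology adapts, how precisely, and how the property degrades
when the circuit is perturbed or its structure is broken.

## The model

With Hill regulation kernels combined multiplicatively (AND logic):

    dA/dt = alpha1 * D(I) * H+(B; K_BA, n_BA, beta_BA) - gammaA * A
    dB/dt = alpha2 * H-(A; K_AB, n_AB, beta_AB) * S(B)  - gammaB * B

where `D(I) = 1/(1 + (K_TFtot/(1 + I/K_IR))^n_RA) + beta_RA` is the
(indirect) inducer drive and `S(B)` the buffer-node self-activation. In
the weak linear limit (`S = B/K_BB`, zero B-equation leaks,
`alpha2 > gammaB*K_BB`) the B balance pins the repression factor and the
steady-state output is the input-independent closed form

    A* = K_AB * (alpha2/(gammaB*K_BB) - 1)^(1/n_AB)

Adaptation precision is quantified by `AErr = |Output1 - Output2|/Output1`
(post-step settled output vs unswitched control), plus pulse metrics
(peak fold-change over baseline and peak time).

What the package covers: step-response simulation with stiff ODE
integration; steady-state, fixed-point and stability analysis (including
the bistable cooperative-feedback variant); the AErr/pulse metrics and an
adaptation classifier; single-edge perturbation sweeps and topology
disruptions (null positive feedback, repression deletion); a seeded
parameter-cassette robustness screen; Hill and full-circuit least-squares
fitting with promoter-substitution prediction; and a cytometry-like
synthetic-data generator (triplicate means, multiplicative log-normal
noise) so the whole pipeline runs without external data.

## Worked example

Simulate a 2 → 200 μM inducer step on the analytically solvable
reference circuit and quantify its adaptation:

```r
library(rpacirc)

p  <- defaults_v1("ideal_linear")            # leaks 0.01
ex <- step_experiment(2, 200, seq(0, 24, by = 0.5))
r  <- adaptation_result(simulate_step(ex, p))
r
#> Adaptation summary: AErr = 0.04198 (output1 = 1.107, output2 = 1.061)
#>   peak 1.5-fold at t = 1.20 h; adapts: FALSE (sens_min = 0.5, aerr_max = 0.1)
rpa_setpoint(p)
#> [1] 1
```

The output pulses to 1.5× baseline about 1.2 h after the step, then
settles back to within ~4% of the unswitched control (the residual error
comes from the 0.01 promoter leaks; in the leak-free limit AErr < 1e-6,
the closed-form set-point `A* = 1`). The strict default classifier
demands a ≥ 50% pulse, which this 1.4999-fold response misses by a hair —
thresholds are explicit everywhere for exactly this reason.

The numbered scripts under `analysis/` run the full study on synthetic
data and write their tables to `results/`: `01_promoter_panel.R`
(activation-curve panel over a 150-fold activity range, Hill fits
recover coefficients ≈ 1.0–1.3), `02_fit_predict.R` (fit the circuit to
noisy time courses, then predict promoter substitutions without
refitting), `03_perturbations.R` (edge sweeps and topology disruptions),
`04_robustness_screen.R` (200-cassette paired screen: linear weak
positive feedback vs constitutive replacement).

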