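# vncua

Lifetime cost-utility microsimulation of voretigene neparvovec (VN) —
the one-time subretinal gene-augmentation therapy for biallelic
RPE65-mediated inherited retinal degeneration — against standard of care
(SoC), from a German societal perspective. The package is aimed at health
economists and modellers who want a fully reproducible, configurable
implementation of an individual patient sampling model for a one-time
gene therapy with lifetime consequences.

## The model

Each simulated patient is tracked through annual cycles of a two-state
(alive/dead) Markov framework until death or age 100. While alive, two
visual-function states evolve:

* **BCVA** (best-corrected visual acuity, logMAR): constant until a
  per-patient onset age in [15, 20] years, then +0.0436 logMAR/year up to
  a cap of 2.3;
* **VF** (Goldmann III4e visual field, sum total degrees): −25
  degrees/year down to 0.

In cycle 1 both arms receive their trial-observed treatment effect (VN:
−0.163 logMAR, +302.1 degrees on average; SoC: −0.312 logMAR, −76.7
degrees). In the base case the treated state is then frozen for life; a
waning scenario instead decays the effect exponentially to the patient's
counterfactual SoC trajectory between years 10 and 20 after treatment.

Per cycle, utility is linear in normalised acuity and field scores,

    u = u_min + (u_max − u_min) · (w_va · s_va + w_vf · s_vf),
    s_va = clamp((2.3 − BCVA)/2.3, 0, 1),  s_vf = clamp(VF/1000, 0, 1),

and costs accrue: the €831,660 two-eye treatment bundle in the VN first
year, a €220 annual check otherwise, plus indirect costs by
decimal-acuity band (10^−BCVA): €39,864/year below 0.02, €22,432 in
[0.02, 0.05), €13,336 in [0.05, 0.3). Costs and QALYs are discounted at
3%/year. A Monte Carlo ensemble (1000 replicates × 70 patients, equal
arms) yields incremental QALYs ΔQ, incremental cost ΔC, and the
incremental cost-utility ratio ICUR = mean(ΔC)/mean(ΔQ), along with the
cost-effectiveness plane and the acceptability curve (net monetary
benefit rule). Because the published utility coefficients are unknown,
`calibrate_utility()` anchors the mapping to a known base-case ΔQ.

## Worked example

```r
library(vncua)

config <- scenario_config(n_sims = 200, master_seed = 1)
ensemble <- run_monte_carlo(config)
summarize_ensemble(ensemble)
#>   scenario delta_qaly delta_cost   icur icur_defined icur_mean_of_ratios
#> 1     base      3.923     601487 153337         TRUE              160569

ceac(ensemble, c(100000, 125000, 150000, 200000))
#>   threshold fraction_cost_effective
#> 1    100000                   0.015
#> 2    125000                   0.155
#> 3    150000                   0.480
#> 4    200000                   0.865
```

At the default utility weights, a 200-replicate run estimates that VN
buys about 3.9 additional QALYs per patient at about €601k additional
lifetime cost — an ICUR of roughly €153k per QALY — and that 48% of
replicates are cost effective at a €150k/QALY willingness to pay.
`run_sensitivity_suite(config)` adds the waning-effect, 0%-discount,
±10%-direct-cost and alternative-VF-slope scenarios under common random
numbers, and `plot_ce_plane()` / `plot_ceac()` draw the standard figures.

Configurations are plain YAML (empty file = all published defaults):

```yaml
progression:
  vf_slope: -24.3
costs:
  discount: {rate_costs: 0.0, rate_qalys: 0.0}
```

loaded with `load_config("my_scenario.yaml")`; every run is fully
determined by the config fingerprint and the master seed.

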