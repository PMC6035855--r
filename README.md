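# dischargesim

Discrete-event simulation and Six Sigma analytics for the hospital
inpatient discharge process.

## The problem

Discharging a medical inpatient is a multi-actor coordination process: it
starts when the specialist signs the discharge order and ends when the
patient leaves the room.  In the ward this package models, shadowing of 38
discharges measured a mean of 215.7 minutes with an SD of 67 minutes —
three and a half hours during which a bed is blocked.  The durations form
two populations: *standard* discharges (medication, counseling,
accounting) and *complex* ones needing equipment, outpatient supplies or
add-on medication orders.

`dischargesim` is for health-systems engineers and quality-improvement
teams who want to reproduce, stress or extend this kind of DMAIC
(Define–Measure–Analyze–Improve–Control) study entirely in code: a
calibrated discrete-event model of the ward, a menu of improvement
scenarios evaluated with common random numbers, and the statistical
process control toolkit used around it.

## The model

The workflow is an acyclic activity network with FIFO resource pools
(porter, clinical pharmacist, pharmacy work streams, medical-records
officers, accountants).  Two chains run in parallel from the signed order:

* **medication** — prescription (+38 min), pharmacy preparation
  (mean 88 min), porter delivery, nurse phone call, pharmacist counseling;
* **paperwork** — medical-records processing (Weibull(1.7374, 22.091)),
  porter transport, a wait for the family to settle the bill, accounting
  (Normal(1.1087, 1.43610) delay + Lognormal(2.39750, 2.24560) attention),
  clearance return.

Conditional branches cover narcotics prescriptions (40%, 43 min),
equipment (16%, 134 min), an end-of-stay outpatient supplies trip (5%,
195 min) and add-on orders that repeat the pharmacy loop (16%, +83 min).
A patient's total time is the completion of the last enabled branch.
Durations the study did not print are free parameters fitted by simulated
method of moments (`calibrate()`) against the observed baseline moments
and the five reported single-intervention reductions.

The SPC layer implements individuals/moving-range charts
(limits `x̄ ± 2.66 MR̄`, `3.267 MR̄`), normal-model process capability
against a 150-minute upper specification limit
(`z_bench = (USL − μ)/σ`, `SQL = z_bench + 1.5`), the sample-size rule
`n = ⌈(z s / e)²⌉`, and a two-component Gaussian-mixture classifier for
duration-only data.

## Worked example

```r
library(dischargesim)

g <- build_default_graph()          # shipped calibrated configuration
suite <- run_scenario_suite(g, n_replications = 100, seed = 1)
print(suite, digits = 4)
```

```
              scenario mean_minutes delta_vs_baseline_minutes
1             baseline        208.8                     0.000
2     all_improvements        107.8                   100.940
3           fast_track        166.4                    42.412
4 pharmacist_transport        183.7                    25.038
5         extra_porter        199.3                     9.479
6    supplies_to_floor        200.5                     8.317
7      early_equipment        203.8                     5.004
  percent_of_total_reduction
1                         NA
2                         NA
3                     46.994
4                     27.743
5                     10.503
6                      9.215
7                      5.545
```

Read: the simulated baseline discharge takes ~209 minutes on average
(validating against the study's 213.38 ± replication noise; the observed
mean was 215.7, a relative error ~1–3%).  A pharmacy fast track (30-minute
preparation instead of 88) saves ~42 minutes; letting the clinical
pharmacist carry the medication saves ~25; a second porter ~9; on-floor
supplies delivery ~8; next-day equipment announcement ~5.  Applied
together the bundle cuts the mean to ~108 minutes — a ~101-minute (~48%)
reduction, superadditive relative to the 90-minute sum of the singles
because parallel branches absorb single cuts and release them when removed
jointly (see the methods vignette).

Capability before/after:

```r
capability(215.7, usl = 150, sigma = 67)   # Z_bench -0.98, SQL 0.52
sql_from_zbench(-0.78)                     # 0.72, the study's reported level
sql_from_zbench(1.17)                      # 2.67 after improvement
required_sample_size(1.96, 67, 30)         # 20 shadowed patients suffice
```

A command-line front end is installed under `inst/cli/dischargesim`
(subcommands `simulate`, `scenario-suite`, `calibrate`, `spc`,
`generate-data`, `report`).

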