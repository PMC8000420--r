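# kneeflow

Simulation and analysis of local antibiotic delivery in a draining knee.

After revision surgery for periprosthetic joint infection, local antibiotic
depots — antibiotic-loaded PMMA spacers, absorbable calcium sulfate beads
(CSB), or a vancomycin powder bolus — are placed to reach concentrations high
enough to kill biofilm bacteria. The joint drains, though: post-operative
exudate carries drug out at a rate that starts near 3.5 mL/min and falls off
as a power law over 48 h. `kneeflow` models the joint as a constant-volume,
well-mixed flow reactor (a CSTR) and asks what concentration profile each
administration method actually sustains.

Per antibiotic the model integrates

    V dC/dt = R(t) − Q(t) C,     C(0) = M0 / V

with `V = 75 mL`, `Q(t)` a stepwise pump schedule discretized from the
clinical drainage trendline `Q = 3.1269 t^−1.019` (mL/min, t in hours,
capped at 3.5 mL/min), `R(t)` the summed depot release rate, and `M0` any
instantaneously dissolved mass. An exact exponential-step integrator makes
constant-flow cases match their closed forms to machine precision and
handles the `1/√t` Higuchi release-rate singularity.

On top of the simulator the package provides the full measurement-and-
analysis pipeline: a seeded synthetic effluent generator (23-point bench
sampling schedule, multiplicative lognormal assay noise, 0.98 µg/mL limit of
detection with censored values recorded at the LOD), geometric-mean log10
summaries, trapezoidal AUC over 2/12/24/48 h windows, between-arm log
differences and equal-variance t-tests, time above the 100–750 µg/mL
biofilm-eradication band, and a zone-of-inhibition calibration predicting
disc-diffusion potency against *P. aeruginosa* PAO1 and *S. aureus* UAMS-1.

## Worked example

```r
library(kneeflow)

# the clinical drainage schedule: trendline capped at 3.5 mL/min,
# stepped down at the effluent sampling times
sched <- build_stepwise_schedule(drainage_trendline())

# a 1000 mg vancomycin powder bolus in the 75 mL reactor
sim <- simulate_reactor(reactor_config(default_depots("vp_bolus"), sched,
                                       arm = "vp_bolus"))
sim
#> Reactor simulation [vp_bolus] over 48 h (V = 75 mL)
#>   vancomycin: released 1000.0 mg, washed out 1000.0 mg, final 0.01 ug/mL

washout_half_time(sim, "vancomycin")
#> [1] 14.85321
```

The bolus starts at 1000 mg / 75 mL = 13,333 µg/mL and halves in ~14.9 min
(the closed form `V ln2 / Q` at the capped initial flow): high drainage
washes a powder bolus out almost immediately.

Comparing all three arms through the synthetic assay:

```r
fx <- generate_arm_fixtures(seed = 1)          # 3 arms x 3 replicates
es <- exposure_summary(fx)

# geometric-mean vancomycin AUC (ug*h/mL) per window
#>               arm window_h geo_auc
#>   csb_plus_spacer        2    1649
#>       spacer_only        2     619
#>          vp_bolus        2    3985
#>   csb_plus_spacer       12   12736
#>          vp_bolus       12    4064
#>   csb_plus_spacer       48   67753
#>       spacer_only       48   14728
#>          vp_bolus       48    4100
```

The bolus delivers the greatest early exposure (AUC at 2 h) but plateaus
once washed out; the spacer-plus-beads arm overtakes it by 12 h and
dominates the spacer alone at every window. `es$threshold` shows only the
depot arms sustain the 100–750 µg/mL combined band for 24 h
(`satisfied = TRUE`); the bolus stays above it for under 2 h. `es$log_diff`
and `es$tests` give the per-timepoint log10 differences and t-tests between
the bead-augmented arm and the spacer alone.

A full run — schedule, simulations, synthetic dataset, exposure and potency
summaries, JSON manifest — is one call:

```r
run_pipeline(run_config(seed = 1, out_dir = "out"))
```

or, from a shell, via the thin CLI at `inst/cli/kneeflow.R`
(`Rscript kneeflow.R run --seed 1 --out out`).

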