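# cyclekin

Cell-cycle kinetics of asynchronously cycling progenitor populations from
cumulative S-phase-labelling experiments, with a synthetic-data generator
that makes the whole pipeline testable without external data.

## The problem

In a cumulative labelling experiment, a thymidine analogue (such as BrdU)
is delivered repeatedly so that every cell passing through S phase during
the exposure window becomes permanently label-positive. Counting the
labelled fraction — the *labelling index* LI — at increasing exposure
times T traces out how fast the population cycles. Under
*single-population kinetics* (all cycling cells share one cycle time) and
uniform cycle-position occupancy, the expected labelling index is

    LI(T) = min( GF * (Ts + T) / Tc ,  GF )

where `Tc` is the total cell-cycle time, `Ts` the S-phase duration and
`GF` the growth fraction (the proportion of cells cycling at all). The
curve rises linearly from the intercept `LI_0 = GF * Ts / Tc` (cells in S
at T = 0) and plateaus at `LI_m = GF` once every cycling cell has transited
S, at `T = Tc - Ts`. Inverting these identities,

    Tc = LI_m * T_plateau / (LI_m - LI_0),      Ts = Tc * LI_0 / LI_m.

When labelling never plateaus within the observation window, the last
sampled time bounds `T_plateau` from below and the same identities yield a
*minimum estimate* of `Tc`.

The package implements this model and its estimator (segmented linear-rise
/ plateau regression with an SSE-minimising breakpoint and a one-sided
slope test for plateau validity), plus the two companion readouts such
studies report: cell-cycle phase fractions gated from DNA-content
(propidium-iodide) histograms, and pooled-variance two-sample t statistics
for morphometric group comparisons, computable from raw values or from
printed `mean ± SD, n` summaries. A simulator generates all of these
measurements from known ground truth: cycling populations, per-section
BrdU/DAPI counts, flow-cytometry events and Gaussian morphometry.

Intended users: developmental biologists and quantitative methodologists
who want reproducible cumulative-labelling analysis, or a ground-truthed
sandbox for studying the estimator's behaviour.

## Worked example

A noiseless series from the control kinetics (`Tc` 10.5 h, `Ts` 5 h,
`GF` 0.11) sampled at the six experimental exposure times:

```r
library(cyclekin)
params <- kinetic_params(tc = 10.5, ts = 5, gf = 0.11)
times  <- c(0.5, 2.5, 4.5, 6.5, 8.5, 10.5)
series <- data.frame(time_h = times, li = expected_li(params, times))
fit_cumulative(series)
#> Cumulative-labelling fit [plateau_reached]
#>   rising: LI = 0.05238 + 0.010476 * T  (R^2 = 1.0000, n = 3)
#>   plateau LI_m = 0.1100 (growth fraction), reached at 5.50 h
#>   Tc = 10.50 h, Ts = 5.00 h
```

The fitter recovers the generative truth exactly: an 11% growth fraction,
plateau at 5.5 h, and a 10.5-h cycle. The same pipeline on a *simulated
experiment* (binomially noisy counts, 3 retinas × 500 cells per time):

```r
sections <- simulate_experiment(params, seed = 20)
li <- labelling_index(sections)
fit_cumulative(li)
#> Cumulative-labelling fit [plateau_reached]
#>   rising: LI = 0.05500 + 0.008667 * T  (R^2 = 1.0000, n = 2)
#>   plateau LI_m = 0.1008 (growth fraction), reached at 5.29 h
#>   Tc = 11.63 h, Ts = 6.35 h
```

— about 11% off in `Tc` at this counting depth, which is typical: see the
methods vignette for the estimator's measured noise sensitivity.

DNA-content gating against the simulator's truth (1e6 events, 3% CV):

```r
pop    <- simulate_population(1e6, preset_kinetics("control"), seed = 20)
events <- simulate_dna_content(pop, c2_level = 50, cv = 0.03, seed = 21)
estimate_phase_fractions(events)
#> phase fractions: G1(+G0) 91.8%  S 6.9%  G2-M 1.3%
phase_fractions_true(preset_kinetics("control"))
#> phase fractions: G1(+G0) 93.6%  S 5.7%  G2-M 0.7%
```

Morphometric comparison from printed summaries (mitotic pHH3+ counts per
section, mean ± SD with n = 3 per group):

```r
t_test_from_summary(group_summary("control", 15.3, 4.7, 3),
                    group_summary("morphant", 28.0, 3.4, 3))
#> two-sample t test (pooled): t = 3.792, df = 4.00, p = 0.01924
```

## Command line

Every stage is invocable through the bundled CLI (installed under
`exec/`, or call `cyclekin::cyclekin_cli()` directly):

```sh
cyclekin simulate --config cfg.json --out data/      # counts.csv, fluor.csv, morpho.csv
cyclekin index    --counts data/counts.csv --out li.csv
cyclekin fit      --li li.csv --out fit.json
cyclekin flow     --fluor data/fluor.csv --out phases.json
cyclekin morpho   --morpho data/morpho.csv --out morpho.json
cyclekin run      --config cfg.json --out report.json
```

Configs are nested JSON (`default_run_config()` writes a template via
`write_run_config()`); logs go to stderr, results to files.

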