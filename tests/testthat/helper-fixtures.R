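# Shared fixtures: the two study groups and noiseless forward-model series.

control_labelling <- function() kinetic_params(tc = 10.5, ts = 5, gf = 0.11)

exp_times <- function() c(0.5, 2.5, 4.5, 6.5, 8.5, 10.5)

noiseless_series <- function(params, times = exp_times()) {
  data.frame(time_h = times, li = expected_li(params, times))
}

# Random valid kinetic parameters whose plateau falls inside the sampled
# window with >= 2 rising and >= 2 plateau points.
random_params_in_window <- function() {
  ts <- runif(1, 1, 10)
  t_plateau <- runif(1, 2.6, 8.4)  # strictly between 2.5 and 8.5
  kinetic_params(tc = ts + t_plateau, ts = ts, gf = runif(1, 0.05, 1))
}
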