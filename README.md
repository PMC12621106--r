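# tdeflow

Spiking time-difference encoders (TDEs) for motion detection from
event-camera data, in R.

Event cameras emit asynchronous ON/OFF events when per-pixel log-intensity
changes exceed a contrast threshold; under constant illumination those
events are produced by motion. A TDE is a bio-inspired spiking motion
detector built on a current-based leaky integrate-and-fire neuron: input to
a *facilitator* pixel starts a decaying gain, input to a *trigger* pixel a
delay later converts that gain into an injected current, and the resulting
spike count / inter-spike interval (ISI) encode the local speed along the
facilitator→trigger axis. The classical two-point detector (TDE-2) loses
direction selectivity in textured scenes, because motion against its tuning
leaves residual gain that later edges convert. The three-point detector
(TDE-3) adds an *inhibitor* pixel on the far side of the trigger whose
activation resets the gain:

    i[t] = alpha_i * i[t-1] + g[t-1] * Tr[t]
    g[t] = (alpha_g * g[t-1] + w_g * Fac[t]) * (1 - Inh[t])    # TDE-3
    v[t] = alpha_v * v[t-1] + i[t];  s[t] = H(v[t] - theta);  v <- (1-s) v

This makes direction selectivity architectural: on moving three-level bar
textures, the fraction of spikes fired in the preferred direction (the
direction-selectivity index, DSI) is exactly 1 for the TDE-3 under *any*
parameter draw, against roughly 0.3 for the TDE-2.

The package provides, as a single modelling workflow:

* a synthetic event-camera simulator (log-intensity frame differencing at
  threshold ±0.15) with moving bar-texture and step-edge stimuli and
  Poisson background-activity noise (`simulate_events()`,
  `make_bar_stimulus()`, `make_edge_stimulus()`,
  `inject_background_noise()`);
* a spatio-temporal correlation filter for event denoising with a
  trainable pass threshold (`stcf_filter()`);
* batched TDE-2/TDE-3 dynamics (Rcpp kernels) and grid-level networks in
  four direction channels (`tde_run()`, `run_tde_network()`);
* supervised training of the detector's decay constants, gain weight, and
  the filter threshold by backpropagation-through-time with surrogate
  gradients, for spike-count or ISI decoding (`tde_fit()`, a classed model
  object with `print`/`summary`/`coef`/`predict`/`plot`/`simulate`/
  `residuals` methods);
* velocity decoding by windowed spike count or by exact inversion of a
  low-pass spike trace (`spike_count_velocity()`, `isi_velocity()`);
* optical-flow assembly from opposing channels, eccentric compartment
  spacing, yaw-rate pooling, and a hue/brightness flow colormap
  (`decode_flow()`, `build_eccentric_layout()`, `estimate_yaw_rate()`,
  `flow_to_rgb()`);
* the evaluation-metric suite: DSI, fraction of true activity, angular and
  endpoint flow errors, yaw-rate and relative-rotation errors, plus the
  runnable experiment protocols (`run_dsi_experiment()`,
  `run_inference_benchmark()`).

## Worked example

Train a TDE-3 to map the wide velocity range (0.1–1 px/timestep) onto its
spike count, then decode fresh stimuli:

```r
library(tdeflow)

fit <- tde_fit(mode = "count", range = "wide", seed = 1)
print(fit)
#> TDE fit (TDE3): wide-range 1-edge task, count inference
#>   300 epochs x 100 examples; loss 0.8000 -> 0.1083
#> <tde_params>
#>   alpha (g, i, v): 0.653, 0.824, 0.913  (tau 2.3, 5.2, 11.0 steps)
#>   w_g = 1.825, theta = 1.000, dt = 10 ms

aggregate(estimate ~ velocity, predict(fit, seed = 7), mean)
#>   velocity estimate
#> 1     0.10      0.0
#> 2     0.20      0.1
#> 3     0.33      0.2
#> 4     0.50      0.4
#> 5     1.00      0.6
```

The decoded estimates rise monotonically with the true velocity (the loss
is scale-free, so the map's shape, not its absolute scale, is what
training pins down); pooled over a fresh evaluation batch the Pearson
correlation between true and decoded velocity is 0.97:

```r
evaluate_tde(fit, "count", n_per_velocity = 20, seed = 7)$correlation
#> [1] 0.9738936
```

And the architectural headline — TDE-3 direction selectivity on randomized
textures is exact:

```r
dsi3 <- run_dsi_experiment("TDE3", n_rounds = 40, n_stimuli = 200, seed = 1)
c(mean = dsi3$mean, sd = dsi3$sd)
#> mean   sd
#>    1    0
```

A thin command-line interface over the same functions lives at
`inst/cli/tdeflow.R` (`simulate`, `train`, `dsi`, `bench`, `flow`, `yaw`
subcommands; events as `x,y,t_us,polarity` CSV).

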