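# Shared fixtures: tiny deterministic inputs built in code.

# constant-intensity clip
const_frames <- function(n_t = 4, h = 2, w = 2, value = 1) {
  intensity_sequence(array(value, dim = c(n_t, h, w)))
}

# single-pixel grid with events at given (bin, polarity) pairs
grid_with_events <- function(n_t, h, w, events, dt_ms = 10) {
  counts <- array(0, dim = c(n_t, 2, h, w))
  for (e in events) counts[e[1], e[2], e[3], e[4]] <- counts[e[1], e[2], e[3], e[4]] + 1
  event_grid(counts, dt_ms)
}

# straight-line reference simulation of the detector recurrence, written
# independently of the package internals (scalar loop, no batching)
reference_tde <- function(fac, tr, inh, a_g, a_i, a_v, w_g, theta, tde3) {
  T_ <- length(fac)
  g <- i <- v <- 0
  spikes <- current <- numeric(T_)
  for (t in seq_len(T_)) {
    i <- a_i * i + g * tr[t]
    g <- a_g * g + w_g * fac[t]
    if (tde3) g <- g * (1 - inh[t])
    v <- a_v * v + i
    s <- as.numeric(v - theta >= 0)
    v <- (1 - s) * v
    spikes[t] <- s
    current[t] <- i
  }
  list(spikes = spikes, current = current)
}

params_from_alphas <- function(a_g, a_i, a_v, w_g, theta = 1) {
  tde_params(alpha_g = a_g, alpha_i = a_i, alpha_v = a_v, w_g = w_g,
             theta = theta)
}
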