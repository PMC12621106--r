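test_that("spike function is threshold-inclusive Heaviside", {
  expect_equal(spike_fn(-1), 0)
  expect_equal(spike_fn(1), 1)
  expect_equal(spike_fn(0), 1)
})

test_that("surrogate derivative is peaked at zero and strictly positive", {
  expect_gt(surrogate_grad(0), surrogate_grad(5))
  expect_gt(surrogate_grad(0), surrogate_grad(-5))
  expect_gt(surrogate_grad(5), 0)
  expect_gt(surrogate_grad(-5), 0)
  expect_equal(surrogate_grad(0), 1)
})

test_that("states decay geometrically and silently without input", {
  p <- params_from_alphas(0.8, 0.6, 0.5, w_g = 2, theta = 1)
  st <- list(g = 1, i = 1, v = 0.5)
  out <- tde_step(st, 0, 0, 0, p)
  expect_equal(out$state$g, 0.8)
  expect_equal(out$state$i, 0.6)
  expect_equal(out$state$v, 0.5 * 0.5 + 0.6)
  expect_equal(out$spike, 0)
})

test_that("TDE-3 zeroes the gain when facilitator and inhibitor coincide", {
  p <- params_from_alphas(0.9, 0.9, 0.9, w_g = 5)
  out <- tde_step(list(g = 0.3, i = 0, v = 0), fac = 1, tr = 0, inh = 1, p)
  expect_equal(out$state$g, 0)
})

test_that("delayed trigger injects w_g * alpha_g^(d-1)", {
  # hand-unrolled recurrence: gain set at t0, read (as g[t-1]) at t0 + d
  p <- params_from_alphas(0.8, 0.5, 0.5, w_g = 2, theta = 10)
  d <- 3
  fac <- c(1, numeric(5)); tr <- numeric(6); tr[1 + d] <- 1
  run <- tde_run(fac, tr, NULL, p)
  expect_equal(run$current[1, 1 + d], 2 * 0.8^(d - 1))
})

test_that("trigger without prior facilitation leaves the detector silent", {
  p <- params_from_alphas(0.9, 0.9, 0.9, w_g = 10, theta = 0.5)
  run <- tde_run(numeric(10), rep(1, 10), NULL, p)
  expect_equal(sum(run$current), 0)
  expect_equal(sum(run$spikes), 0)
})

test_that("batched kernel matches the straight-line reference simulation", {
  set.seed(31)
  for (rep in 1:20) {
    T_ <- sample(10:60, 1)
    fac <- rbinom(T_, 1, 0.3); tr <- rbinom(T_, 1, 0.3); inh <- rbinom(T_, 1, 0.2)
    a <- runif(3, 0.05, 0.98); w <- runif(1, 0.5, 8); th <- runif(1, 0.5, 2)
    tde3 <- rep %% 2 == 0
    p <- tde_params(alpha_g = a[1], alpha_i = a[2], alpha_v = a[3], w_g = w,
                    theta = th)
    run <- tde_run(fac, tr, inh, p, if (tde3) "TDE3" else "TDE2")
    ref <- reference_tde(fac, tr, inh, a[1], a[2], a[3], w, th, tde3)
    expect_equal(run$spikes[1, ], ref$spikes, tolerance = 1e-12)
    expect_equal(run$current[1, ], ref$current, tolerance = 1e-12)
  }
})

test_that("TDE-2 and TDE-3 agree whenever the inhibitor is silent", {
  set.seed(32)
  for (rep in 1:10) {
    T_ <- 40
    fac <- rbinom(T_, 1, 0.4); tr <- rbinom(T_, 1, 0.4)
    p <- params_from_alphas(runif(1, .5, .95), runif(1, .5, .95),
                            runif(1, .5, .95), w_g = runif(1, 1, 6))
    r2 <- tde_run(fac, tr, numeric(T_), p, "TDE2")
    r3 <- tde_run(fac, tr, numeric(T_), p, "TDE3")
    expect_identical(r2$spikes, r3$spikes)
    expect_identical(r2$gain, r3$gain)
  }
})

test_that("gain stays non-negative and voltage resets to zero after spikes", {
  set.seed(33)
  for (rep in 1:10) {
    T_ <- 50
    fac <- rbinom(T_, 1, 0.5); tr <- rbinom(T_, 1, 0.5); inh <- rbinom(T_, 1, 0.3)
    p <- params_from_alphas(runif(1, .5, .95), runif(1, .5, .95),
                            runif(1, .5, .95), w_g = runif(1, 1, 6))
    run <- tde_run(fac, tr, inh, p, "TDE3")
    expect_true(all(run$gain >= 0))
    # post-reset voltage: (1 - s) * u must be 0 wherever s = 1
    v_post <- (1 - run$spikes) * run$voltage
    expect_true(all(v_post[run$spikes == 1] == 0))
  }
})

test_that("TDE-3 never spikes for null or orthogonal bar-texture motion", {
  set.seed(34)
  for (rep in 1:8) {
    v <- sample(c(0.1, 0.2, 0.33, 0.5, 1), 1)
    p <- tde_params(tau_g = exp(runif(1, log(20), log(200))),
                    tau_i = exp(runif(1, log(10), log(100))),
                    tau_v = exp(runif(1, log(10), log(100))),
                    w_g = exp(runif(1, 0, log(10))), theta = 1)
    for (dir in c("R-L", "T-B", "B-T")) {
      ser <- tdeflow:::bar_detector_series(v, dir, gray_fraction = runif(1, 0, 0.8))
      run <- tde_run(ser$fac, ser$tr, ser$inh, p, "TDE3")
      expect_equal(sum(run$spikes), 0)
    }
    ser <- tdeflow:::bar_detector_series(v, "L-R", gray_fraction = 0.3)
    run <- tde_run(ser$fac, ser$tr, ser$inh, p, "TDE3")
    expect_gte(sum(run$spikes), 0)
  }
})

test_that("the fast DSI stimulus path matches the full simulator", {
  for (dir in c("L-R", "R-L", "T-B", "B-T")) {
    set.seed(77)
    ser <- tdeflow:::bar_detector_series(0.5, dir, gray_fraction = 0.3)
    set.seed(77)
    stim <- make_bar_stimulus(0.5, dir, gray_fraction = 0.3, field = c(3, 3))
    occ <- tdeflow:::merge_polarities(simulate_events(stim))
    T_ <- min(length(ser$fac), dim(occ)[1])
    expect_equal(ser$fac[1:T_], occ[1:T_, 2, 1])
    expect_equal(ser$tr[1:T_], occ[1:T_, 2, 2])
    expect_equal(ser$inh[1:T_], occ[1:T_, 2, 3])
  }
})

test_that("a network only spikes in the channel of a moving edge", {
  p <- params_from_alphas(0.9, 0.9, 0.9, w_g = 3)
  lay <- make_layout(5, 8, spacing = 1)
  # static scene
  g0 <- grid_with_events(10, 5, 8, list())
  rec0 <- run_tde_network(g0, lay, p, "TDE3")
  expect_equal(sum(rec0$spikes), 0)
  # rightward-moving full-height edge
  stim <- make_edge_stimulus(1, width = 8, height = 5, t_extra = 5)
  rec <- run_tde_network(simulate_events(stim), lay, p, "TDE3")
  by_ch <- tapply(rowSums(rec$spikes), rec$layout$channel, sum)
  expect_gt(by_ch[["L-R"]], 0)
  expect_equal(unname(by_ch[["R-L"]]), 0)
  expect_equal(unname(by_ch[["T-B"]]), 0)
  expect_equal(unname(by_ch[["B-T"]]), 0)
})

test_that("TDE-2 fires on the second of two edges moving against its tuning", {
  # R-L motion on an L-R detector: each edge hits inhibitor, trigger,
  # facilitator in turn; the first edge leaves residual gain that the second
  # edge's trigger converts (TDE-2 only; TDE-3 resets it)
  T_ <- 40
  fac <- tr <- inh <- numeric(T_)
  d <- 2; gap <- 10
  for (t0 in c(5, 5 + gap)) {
    inh[t0] <- 1; tr[t0 + d] <- 1; fac[t0 + 2 * d] <- 1
  }
  p <- params_from_alphas(0.95, 0.9, 0.9, w_g = 5)
  r2 <- tde_run(fac, tr, inh, p, "TDE2")
  r3 <- tde_run(fac, tr, inh, p, "TDE3")
  expect_gt(sum(r2$spikes), 0)
  expect_equal(sum(r3$spikes), 0)
  # and the TDE-2 spikes come with the second edge, not the first
  expect_equal(sum(r2$spikes[1, 1:(5 + gap + d - 1)]), 0)
})

test_that("layout coordinates outside the grid are rejected", {
  lay <- make_layout(5, 5, spacing = 1)
  g <- grid_with_events(5, 3, 3, list())
  expect_error(run_tde_network(g, lay, tde_params()), "outside")
})
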