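test_that("onsets mark strict current increases only", {
  expect_equal(segment_onsets(c(1, 0.8, 0.6, 0.4)), c(1, 0, 0, 0))
  cur <- c(0, 0, 0, 0, 0, 0, 2, 1.5, 1)
  expect_equal(which(segment_onsets(cur) == 1), 7L)
  expect_equal(segment_onsets(numeric(6)), numeric(6))
})

test_that("wide-range count decoding scales spikes by 0.1 px/timestep", {
  cur <- c(0, 1, 0.5, 0.25, 0.1, 0.05, 0)
  cfg <- inference_config("count", "wide")
  sp <- c(0, 1, 0, 0, 0, 0, 0)
  vs <- spike_count_velocity(list(spikes = sp, current = cur), cfg)
  expect_equal(vs$estimates[2], 0.1)
  sp3 <- c(0, 1, 1, 1, 0, 0, 0)
  vs3 <- spike_count_velocity(list(spikes = sp3, current = cur), cfg)
  expect_equal(vs3$estimates[2], 0.3)
  expect_equal(sum(vs3$estimates != 0), 1)   # estimate sits at the onset only
})

test_that("narrow-range count decoding is bias + resolution * count", {
  cur <- c(0, 1, rep(0, 8))
  cfg <- inference_config("count", "narrow")
  one <- c(0, 1, rep(0, 8))
  vs <- spike_count_velocity(list(spikes = one, current = cur), cfg)
  expect_equal(vs$estimates[2], 0.024 + 0.001)
  none <- numeric(10)
  vs0 <- spike_count_velocity(list(spikes = none, current = cur), cfg)
  expect_equal(vs0$estimates[2], 0)
})

test_that("spikes beyond the counting window are excluded", {
  T_ <- 30
  cur <- numeric(T_); cur[3] <- 1; cur[4:T_] <- 0.9^(1:(T_ - 3))
  sp <- numeric(T_); sp[c(3, 5, 12, 13)] <- 1   # 13 > 3 + 10 - 1
  cfg <- inference_config("count", "wide", win = 10)
  vs <- spike_count_velocity(list(spikes = sp, current = cur), cfg)
  expect_equal(vs$estimates[3], 0.1 * 3)
})

test_that("a new onset restarts the count for the new edge", {
  T_ <- 20
  cur <- numeric(T_); cur[3] <- 1; cur[4] <- 0.9; cur[8] <- 1.5; cur[9:T_] <- 0.5
  sp <- numeric(T_); sp[c(3, 6, 8, 9)] <- 1
  cfg <- inference_config("count", "wide", win = 10)
  vs <- spike_count_velocity(list(spikes = sp, current = cur), cfg)
  expect_equal(which(vs$onsets == 1), c(3L, 8L))
  expect_equal(vs$estimates[3], 0.1 * 2)   # spikes at 3 and 6 only
  expect_equal(vs$estimates[8], 0.1 * 2)   # spikes at 8 and 9
})

test_that("ISI decoding inverts the low-pass trace exactly", {
  cfg <- inference_config("isi", "wide", tau_f = 5, gamma = 1)
  T_ <- 30
  cur <- numeric(T_); cur[2] <- 1; cur[3:T_] <- 0.5
  # second spike 3 steps after the first -> ISI 3, estimate gamma / 3
  sp <- numeric(T_); sp[c(4, 7)] <- 1
  vs <- isi_velocity(list(spikes = sp, current = cur), cfg)
  expect_equal(vs$estimates[2], 1 / 3)
  # adjacent spikes -> ISI 1 -> estimate gamma
  sp1 <- numeric(T_); sp1[c(4, 5)] <- 1
  vs1 <- isi_velocity(list(spikes = sp1, current = cur), cfg)
  expect_equal(vs1$estimates[2], 1)
})

test_that("ISI recovery is exact for all gaps 1-50 and tau_f in {1, 5, 20}", {
  for (tau_f in c(1, 5, 20)) {
    cfg <- inference_config("isi", "wide", tau_f = tau_f, gamma = 1)
    lam <- exp(-1 / tau_f)
    for (k in c(1:10, 25, 50)) {
      T_ <- 60 + k
      cur <- numeric(T_); cur[2] <- 1; cur[3:T_] <- 0.5
      sp <- numeric(T_); sp[c(5, 5 + k)] <- 1
      vs <- isi_velocity(list(spikes = sp, current = cur), cfg)
      # closed form: x = x0 * lam^(k-1) => elapsed = k - 1, ISI = k
      expect_equal(vs$estimates[2], 1 / k, tolerance = 1e-10)
    }
  }
})

test_that("fewer than two post-onset spikes give a vanishing estimate", {
  cfg <- inference_config("isi", "wide", isi_fallback = 1e4)
  T_ <- 20
  cur <- numeric(T_); cur[2] <- 1; cur[3:T_] <- 0.5
  sp <- numeric(T_); sp[5] <- 1
  vs <- isi_velocity(list(spikes = sp, current = cur), cfg)
  expect_equal(vs$estimates[2], 1e-4)
  cfgn <- inference_config("isi", "narrow", isi_fallback = 1e4)
  vsn <- isi_velocity(list(spikes = sp, current = cur), cfgn)
  expect_lt(vsn$estimates[2], 1e-4)   # no bias for an undecodable train
})

test_that("count estimates are non-decreasing in the spike count", {
  cfg <- inference_config("count", "wide")
  cur <- c(0, 1, rep(0.5, 10))
  prev <- -Inf
  for (n_sp in 0:8) {
    sp <- numeric(12); if (n_sp > 0) sp[2:(1 + n_sp)] <- 1
    vs <- spike_count_velocity(list(spikes = sp, current = cur), cfg)
    expect_gte(vs$estimates[2], prev)
    prev <- vs$estimates[2]
  }
})

test_that("decoders are pure functions of spikes and current", {
  set.seed(41)
  sp <- rbinom(30, 1, 0.3)
  cur <- cumsum(rnorm(30))
  rec <- list(spikes = sp, current = cur)
  for (cfg in list(inference_config("count", "wide"),
                   inference_config("isi", "narrow"))) {
    a <- decode_velocity(rec, cfg)
    b <- decode_velocity(rec, cfg)
    expect_identical(a, b)
  }
})

test_that("matrix records decode row-wise", {
  cur <- rbind(c(0, 1, 0.5, 0.2), c(0, 0, 1, 0.5))
  sp <- rbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  vs <- spike_count_velocity(list(spikes = sp, current = cur),
                             inference_config("count", "wide"))
  expect_equal(vs$estimates[1, 2], 0.2)
  expect_equal(vs$estimates[2, 3], 0.2)
})
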