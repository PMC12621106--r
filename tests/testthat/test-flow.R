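make_vs <- function(est) {
  structure(list(estimates = est, onsets = (est != 0) * 1),
            class = "velocity_series")
}

test_that("opposing-channel subtraction gives signed flow in px/s", {
  lay <- make_layout(3, 3, spacing = 1)
  est <- matrix(0, nrow(lay), 4)
  mid <- which(lay$channel == "L-R" & lay$y == 2 & lay$x == 2)
  est[mid, 2] <- 0.2
  flow <- decode_flow(make_vs(est), lay, dims = c(3, 3), dt_ms = 50)
  expect_equal(flow[2, 2, 2, 1], 0.2 * 1 * 1000 / 50)   # +4 px/s
  expect_equal(sum(flow != 0), 1)
  # equal opposing estimates cancel
  rl <- which(lay$channel == "R-L" & lay$y == 2 & lay$x == 2)
  est[rl, 2] <- 0.2
  flow2 <- decode_flow(make_vs(est), lay, dims = c(3, 3), dt_ms = 50)
  expect_equal(sum(flow2 != 0), 0)
})

test_that("decode_flow is antisymmetric under channel swap", {
  set.seed(71)
  lay <- make_layout(4, 4, spacing = 1)
  est <- matrix(0, nrow(lay), 3)
  est[lay$channel %in% c("L-R", "R-L"), ] <-
    matrix(runif(sum(lay$channel %in% c("L-R", "R-L")) * 3, 0, 0.5),
           ncol = 3)
  f1 <- decode_flow(make_vs(est), lay, c(4, 4), 50)
  est_sw <- est
  est_sw[lay$channel == "L-R", ] <- est[lay$channel == "R-L", ]
  est_sw[lay$channel == "R-L", ] <- est[lay$channel == "L-R", ]
  f2 <- decode_flow(make_vs(est_sw), lay, c(4, 4), 50)
  expect_equal(f2[, , , 1], -f1[, , , 1])
})

test_that("eccentric spacing grows with distance from center", {
  ecc <- build_eccentric_layout(20, 20, spacings = c(1, 2, 3, 4, 6, 8))
  m <- ecc$map
  cy <- 10.5; cx <- 10.5
  r <- sqrt(outer((1:20 - cy)^2, (1:20 - cx)^2, `+`))
  # spacing is a non-decreasing function of radius
  ord <- order(as.vector(r))
  expect_true(all(diff(as.vector(m)[ord]) >= 0 |
                    diff(as.vector(r)[ord]) == 0))
  expect_equal(m[10, 10], 1)
  expect_equal(max(m), 8)
  expect_error(build_eccentric_layout(10, 10, spacings = c(1, 8)), "half")
})

test_that("uniform spacing-2 layout places every detector at spacing 2", {
  lay <- make_layout(6, 6, spacing = 2)
  expect_true(all(lay$spacing == 2))
  lr <- lay[lay$channel == "L-R", ]
  expect_true(all(lr$fac_x == lr$x - 2 & lr$inh_x == lr$x + 2))
})

test_that("doubling the spacing doubles the encoded velocity", {
  # the detector only sees the facilitator-to-trigger delay (spacing /
  # velocity): an edge at 2v through a spacing-2 detector reproduces the
  # spike train of an edge at v through a spacing-1 detector
  p <- params_from_alphas(0.9, 0.9, 0.9, w_g = 3)
  run_edge <- function(velocity, spacing) {
    stim <- make_edge_stimulus(velocity, width = 9, height = 3, t_extra = 40)
    lay <- make_layout(3, 9, spacing = spacing, directions = "L-R")
    lay <- lay[lay$y == 2 & lay$x == 5, ]
    sum(run_tde_network(simulate_events(stim), lay, p, "TDE3")$spikes)
  }
  expect_equal(run_edge(1, 2), run_edge(0.5, 1))
  expect_equal(run_edge(0.5, 2), run_edge(0.25, 1))
})

test_that("yaw pooling: zero for balanced channels, anchored scaling, sign", {
  lr <- matrix(0, 2, 5); rl <- matrix(0, 2, 5)
  lr[1, ] <- c(0, 2, 4, 2, 0); rl[1, ] <- c(0, 2, 4, 2, 0)
  y0 <- estimate_yaw_rate(lr, rl, gt_max = 30)
  expect_true(all(y0$deg_per_s == 0))
  rl[1, ] <- 0
  y1 <- estimate_yaw_rate(lr, rl, gt_max = 30)
  expect_equal(max(y1$deg_per_s), 30)          # max |raw| maps to gt_max
  expect_true(all(y1$deg_per_s >= 0))          # L-R excess -> positive yaw
  y2 <- estimate_yaw_rate(rl, lr, gt_max = 30)
  expect_equal(min(y2$deg_per_s), -30)
})

test_that("flow colormap: zero flow black, antiparallel complementary hues", {
  flow <- array(0, dim = c(2, 2, 2))
  rgb0 <- flow_to_rgb(flow)
  expect_true(all(rgb0 == 0))
  flow[1, 1, ] <- c(1, 0); flow[2, 2, ] <- c(-1, 0)
  rgb <- flow_to_rgb(flow)
  c1 <- rgb[1, 1, ]; c2 <- rgb[2, 2, ]
  h1 <- grDevices::rgb2hsv(matrix(c1 * 255, 3))[1]
  h2 <- grDevices::rgb2hsv(matrix(c2 * 255, 3))[1]
  expect_equal(abs(h1 - h2) %% 1, 0.5, tolerance = 1e-6)
  # equal direction, different magnitude: same hue, different brightness
  flow[2, 2, ] <- c(0.5, 0)
  rgb2 <- flow_to_rgb(flow)
  v1 <- grDevices::rgb2hsv(matrix(rgb2[1, 1, ] * 255, 3))[3]
  v2 <- grDevices::rgb2hsv(matrix(rgb2[2, 2, ] * 255, 3))[3]
  expect_gt(v1, v2)
})

test_that("a rightward texture decodes to flow within 20 degrees of 0", {
  p <- params_from_alphas(0.92, 0.9, 0.9, w_g = 2)
  set.seed(72)
  stim <- make_bar_stimulus(0.33, "L-R", gray_fraction = 0.2,
                            texture_length = 30, texture_width = 8,
                            bar_width = 4, field = c(8, 10))
  g <- simulate_events(stim)
  lay <- make_layout(8, 10, spacing = 1)
  rec <- run_tde_network(g, lay, p, "TDE3")
  vs <- spike_count_velocity(rec, inference_config("count", "wide"))
  flow <- decode_flow(vs, lay, c(8, 10), dt_ms = 10)
  fx <- flow[, , , 1]; fy <- flow[, , , 2]
  nz <- fx != 0 | fy != 0
  expect_gt(sum(nz), 0)
  ang <- atan2(mean(fy[nz]), mean(fx[nz])) * 180 / pi
  expect_lt(abs(ang), 20)
})

test_that("TDE-3 networks spike no more than TDE-2 on multi-edge input", {
  p <- params_from_alphas(0.95, 0.9, 0.9, w_g = 3)
  for (seed in 1:4) {
    set.seed(seed)
    stim <- make_bar_stimulus(sample(c(0.2, 0.5, 1), 1),
                              sample(c("L-R", "R-L"), 1),
                              gray_fraction = 0.3, texture_length = 40,
                              texture_width = 3, field = c(3, 6))
    g <- simulate_events(stim)
    lay <- make_layout(3, 6, spacing = 1)
    s2 <- sum(run_tde_network(g, lay, p, "TDE2")$spikes)
    s3 <- sum(run_tde_network(g, lay, p, "TDE3")$spikes)
    expect_lte(s3, s2)
  }
})
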