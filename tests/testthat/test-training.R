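test_that("velocity loss: perfect scaled fit and zero spikes give zero", {
  est <- c(2, 4, 6); truth <- c(1, 2, 3)       # proportional: scale removed
  expect_equal(velocity_loss(est, truth, spikes = c(0, 0, 0)), 0)
})

test_that("velocity loss with zero estimates is the mean normalized truth", {
  truth <- c(1, 2, 4)
  l <- velocity_loss(c(0, 0, 0), truth, spikes = c(0, 0, 0))
  expect_equal(l, mean(truth / 4), tolerance = 1e-6)
})

test_that("regularization: 10 total spikes in one example cost 0.05", {
  expect_equal(velocity_loss(1, 1, spikes = 10), 0.05)
})

test_that("the trainer's cached inputs match the full event simulation", {
  task <- tdeflow:::make_task("wide", edges = 2)
  for (k in c(1, 7, 20)) {
    ck <- task$cache[[k]]
    stim <- make_edge_stimulus(ck$v, n_edges = 2, spacings = ck$s,
                               width = 16, height = 1)
    occ <- tdeflow:::merge_polarities(simulate_events(stim))
    T_ <- min(task$T, dim(occ)[1])
    expect_equal(ck$fac[1:T_], occ[1:T_, 1, 3])
    expect_equal(ck$tr[1:T_], occ[1:T_, 1, 4])
    expect_equal(ck$inh[1:T_], occ[1:T_, 1, 5])
  }
})

test_that("surrogate-backward loss gradient matches finite differences in sign", {
  # 5-timestep toy, two detectors (trigger delays 1 and 3): the estimate is
  # the total spike count scaled by beta, the loss the usual normalized L1
  # plus sparsity term
  a <- c(0.9, 0.9, 0.9); theta <- 1; beta <- 0.1; eps <- 1e-8
  fac <- rbind(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0))
  tr <- rbind(c(0, 1, 0, 0, 0), c(0, 0, 0, 1, 0))
  inh <- fac * 0
  truth <- c(1, 0.3)
  loss_at <- function(w) {
    fw <- tdeflow:::tde_forward_cpp(fac, tr, inh, a[1], a[2], a[3], w, theta,
                                    TRUE)
    velocity_loss(beta * rowSums(fw$s), truth, spikes = rowSums(fw$s))
  }
  w0 <- 1.5
  fd <- vapply(c(0.3, 0.5), function(h)
    (loss_at(w0 + h) - loss_at(w0 - h)) / (2 * h), numeric(1))
  expect_true(all(fd != 0))
  # surrogate-backward pass at w0 (same entry gradients as the trainer,
  # including the path through the batch max)
  fw <- tdeflow:::tde_forward_cpp(fac, tr, inh, a[1], a[2], a[3], w0, theta,
                                  TRUE)
  est <- beta * rowSums(fw$s)
  m_e <- max(abs(est)) + eps; m_t <- max(abs(truth)) + eps
  dn <- est / m_e - truth / m_t
  dest <- sign(dn) / (2 * m_e)
  j <- which.max(abs(est))
  dest[j] <- dest[j] - sum(sign(dn) * est) / (2 * m_e^2) * sign(est[j])
  s_tot <- rowSums(fw$s)
  dreg <- 0.05 * 1e-2 * s_tot / (2 * sqrt(1e-2 * mean(s_tot^2)))
  ds <- matrix(dest * beta, 2, 5) + matrix(dreg, 2, 5)
  bw <- tdeflow:::tde_backward_cpp(fac, tr, inh, fw$g, fw$i, fw$u, fw$s,
                                   ds, ds * 0, a[1], a[2], a[3], w0, theta,
                                   TRUE, 10)
  expect_true(bw$d_wg != 0)
  expect_true(all(sign(bw$d_wg) == sign(fd)))
})

test_that("training reduces the loss on the wide-range single-edge task", {
  fit <- tde_fit("count", "wide", epochs = 60, seed = 5)
  h <- fit$history
  expect_lt(min(h$selection_loss, na.rm = TRUE), h$loss[1])
  expect_lt(h$loss[60], h$loss[1])
})

test_that("identical seeds and configs give bitwise-identical histories", {
  f1 <- tde_fit("count", "wide", epochs = 25, seed = 11)
  f2 <- tde_fit("count", "wide", epochs = 25, seed = 11)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
})

test_that("stronger sparsity regularization never increases spiking", {
  spikes_at <- vapply(c(0.01, 0.05, 0.5), function(rw) {
    fit <- tde_fit("count", "wide", epochs = 80, seed = 9, reg_weight = rw)
    ev <- evaluate_tde(fit, "count", n_per_velocity = 4, seed = 55)
    ev$mean_spikes
  }, numeric(1))
  expect_true(all(diff(spikes_at) <= 0.5))   # monotone within tolerance
  expect_lt(spikes_at[3], spikes_at[1])
})

test_that("fitted objects expose the modelling interface", {
  fit <- tde_fit("count", "wide", epochs = 40, seed = 2)
  expect_s3_class(fit, "tde_fit")
  co <- coef(fit)
  expect_named(co, c("alpha_g", "alpha_i", "alpha_v", "w_g", "theta"))
  expect_true(all(co[c("alpha_g", "alpha_i", "alpha_v")] > 0 &
                    co[c("alpha_g", "alpha_i", "alpha_v")] < 1))
  pr <- predict(fit, n_per_velocity = 2, seed = 5)
  expect_true(all(c("velocity", "estimate") %in% names(pr)))
  expect_equal(sort(unique(pr$velocity)), tdeflow:::velocity_set("wide"))
  res <- residuals(fit, n_per_velocity = 2, seed = 5)
  expect_equal(res, pr$velocity - pr$estimate)
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "event_grid")
  expect_output(print(fit), "TDE fit")
})
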