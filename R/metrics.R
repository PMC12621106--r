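#' Direction-selectivity index
#'
#' Fraction of a detector's spikes emitted during preferred-direction motion:
#' `PD / (PD + ND + OD1 + OD2)`.
#'
#' @param pd,nd,od1,od2 spike counts accumulated during preferred-, null- and
#'   the two orthogonal-direction presentations.
#' @return the DSI in `[0, 1]`; errors if no spikes were fired at all.
#' @export
dsi <- function(pd, nd = 0, od1 = 0, od2 = 0) {
  tot <- pd + nd + od1 + od2
  if (any(c(pd, nd, od1, od2) < 0)) stop("spike counts must be non-negative")
  if (tot == 0) stop("DSI undefined: no spikes fired")
  pd / tot
}

#' Fraction of true activity
#'
#' Share of the summed decoded velocity attributable to the actual stimulus:
#' estimates whose onset coincides (within `tol` timesteps) with a true edge
#' appearance count as stimulus-driven. A zero total estimate returns 1 by
#' convention (there was no false activity).
#'
#' @param estimates velocity-estimate series (zero except at onsets).
#' @param truth_mask binary series marking true edge-appearance timesteps.
#' @param tol attribution tolerance in timesteps (default 1).
#' @return the FTA in `[0, 1]`.
#' @export
fta <- function(estimates, truth_mask, tol = 1) {
  if (length(estimates) != length(truth_mask)) stop("series must be aligned")
  tot <- sum(estimates)
  if (tot == 0) return(1)
  tb <- which(truth_mask > 0)
  on <- which(estimates != 0)
  good <- if (length(tb)) on[vapply(on, function(t0) min(abs(t0 - tb)) <= tol,
                                    logical(1))] else integer(0)
  sum(estimates[good]) / tot
}

as_flow_matrix <- function(a) {
  d <- dim(a)
  if (is.null(d)) stop("flow must be a matrix or array with a trailing 2-dim")
  if (length(d) == 2 && d[2] == 2) return(a)
  if (d[length(d)] != 2) stop("last dimension of a flow array must be 2")
  matrix(array(a, dim = c(prod(d[-length(d)]), 2)), ncol = 2)
}

#' Optical-flow error metrics
#'
#' Average angular error (AAE, degrees), average endpoint error (AEE) and
#' relative average endpoint error (rAEE) between an estimated and a ground
#' truth flow field. AAE is averaged over vector pairs where both estimate
#' and ground truth are nonzero (zero estimates are not counted); rAEE over
#' pairs with nonzero ground truth.
#'
#' @param v estimated flow: an `N x 2` matrix or any array with a trailing
#'   dimension of 2 (e.g. `(T, H, W, 2)`).
#' @param u ground-truth flow, same shape.
#' @return list with `aae_deg`, `aee`, `raee`, and `n_aae` (pairs entering
#'   the AAE).
#' @export
flow_errors <- function(v, u) {
  v <- as_flow_matrix(v); u <- as_flow_matrix(u)
  if (!all(dim(v) == dim(u))) stop("flow fields must be aligned")
  nv <- sqrt(rowSums(v^2)); nu <- sqrt(rowSums(u^2))
  ok <- nv > 0 & nu > 0
  aae <- if (any(ok)) {
    cosang <- pmin(pmax(rowSums(v * u)[ok] / (nv[ok] * nu[ok]), -1), 1)
    mean(acos(cosang)) * 180 / pi
  } else NA_real_
  ee <- sqrt(rowSums((v - u)^2))
  raee <- if (any(nu > 0)) mean(ee[nu > 0] / nu[nu > 0]) else NA_real_
  list(aae_deg = aae, aee = mean(ee), raee = raee, n_aae = sum(ok))
}

# Rotation angle (radians) of a proper rotation matrix: the 2-norm of its
# matrix logarithm, extracted via acos((tr R - 1) / 2).
rotation_angle <- function(R) {
  acos(min(max((sum(diag(R)) - 1) / 2, -1), 1))
}

yaw_matrix <- function(psi_rad) {
  c1 <- cos(psi_rad); s1 <- sin(psi_rad)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}

#' Rotation-rate error metrics
#'
#' Mean angular velocity error (AVE), Pearson correlation, and average
#' relative rotation error (ARRE) between ground-truth and estimated yaw-rate
#' series. For yaw-only motion ARRE reduces to `AVE * dt` (degrees converted
#' to radians); when per-frame orientation matrices `P` and `G` are supplied,
#' the full matrix-logarithm ARRE (mean rotation angle of `P_t' G_t`) is
#' computed as well.
#'
#' @param gt,est yaw-rate series in degrees/s.
#' @param dt_s integration interval in seconds.
#' @param P,G optional lists of 3x3 relative-rotation matrices per frame
#'   (estimate and ground truth).
#' @return list with `mean_ave_deg_s`, `correlation`, `arre_yaw_rad`, and
#'   (when matrices are given) `arre_full_rad`.
#' @export
rotation_errors <- function(gt, est, dt_s, P = NULL, G = NULL) {
  if (length(gt) != length(est)) stop("series must be aligned")
  if (dt_s <= 0) stop("dt_s must be positive")
  ave <- mean(abs(gt - est))
  corr <- if (stats::sd(gt) > 0 && stats::sd(est) > 0) stats::cor(gt, est)
  else NA_real_
  out <- list(mean_ave_deg_s = ave, correlation = corr,
              arre_yaw_rad = ave * dt_s * pi / 180)
  if (!is.null(P) && !is.null(G)) {
    if (length(P) != length(G)) stop("P and G must be aligned")
    out$arre_full_rad <- mean(vapply(seq_along(P), function(t)
      rotation_angle(t(P[[t]]) %*% G[[t]]), numeric(1)))
  }
  out
}

#' IMU-derived ground-truth event displacement
#'
#' Displaces event locations according to camera rotation rates: a
#' translation `T = k (yaw, pitch)` followed by a roll rotation about the IMU
#' center, `e' = R (e - e0 + T) + e0`.
#'
#' @param points `N x 2` matrix of pixel locations (x, y).
#' @param rates list with `x` (pitch), `y` (yaw), `z` (roll) rotation rates
#'   in degrees/frame, `e0` the IMU-center pixel `c(x, y)`, and `k` the
#'   degree-to-pixel scale (default 4.25 px/degree).
#' @return the displaced `N x 2` matrix.
#' @export
imu_flow_ground_truth <- function(points, rates) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  k <- if (is.null(rates$k)) 4.25 else rates$k
  if (k <= 0) stop("k must be positive")
  e0 <- rates$e0
  tv <- k * c(rates$y, rates$x)
  z <- rates$z * pi / 180
  R <- matrix(c(cos(z), sin(z), -sin(z), cos(z)), 2, 2)
  shifted <- sweep(points, 2, e0) + matrix(tv, nrow(points), 2, byrow = TRUE)
  sweep(shifted %*% t(R), 2, e0, `+`)
}

# --- DSI experiment ---------------------------------------------------------

# Detector input series (fac, tr, inh) for the standard textured-bar DSI
# protocol: a left-right tuned detector reading three adjacent pixels
# (spacing 1) of a 3-px-wide field that the texture sweeps through. For
# vertical motion all three pixels see the same signal (the bars span the
# field orthogonally). Equivalent to extracting the detector pixels from
# simulate_events(make_bar_stimulus(...)); kept direct for speed.
bar_detector_series <- function(velocity, direction, gray_fraction,
                                texture_length = 80, bar_width = 4,
                                threshold = 0.15) {
  tex <- bar_texture_profile(texture_length, bar_width, gray_fraction)
  span <- 3L
  n_t <- ceiling((texture_length + span + 1) / velocity) + 2L
  forward <- direction %in% c("L-R", "T-B")
  prof <- sweep_texture_profile(tex, velocity, n_t, span, forward = forward,
                                background = bar_levels[["white"]])
  ev <- rbind(0, (abs(diff(log(prof))) > threshold) * 1)   # (T, 3)
  if (direction %in% c("L-R", "R-L")) {
    list(fac = ev[, 1], tr = ev[, 2], inh = ev[, 3])
  } else {
    # vertical motion: the three columns of the L-R detector share one axis
    # coordinate (the center row), hence identical input series
    mid <- ev[, 2]
    list(fac = mid, tr = mid, inh = mid)
  }
}

#' Randomized-texture direction-selectivity experiment
#'
#' Measures the DSI of a left-right tuned detector under textured-bar motion
#' in the four cardinal directions. Each testing round draws all detector
#' parameters log-uniformly over a `param_range_factor`-fold range
#' (time constants from 20/10/10 timesteps upward, gain weight from 1,
#' threshold fixed at 1) and presents `n_stimuli` textures with random
#' direction, velocity and gray-bar fraction.
#'
#' @param variant `"TDE3"` or `"TDE2"`.
#' @param n_rounds number of testing rounds.
#' @param n_stimuli stimulus presentations per round.
#' @param param_range_factor fold-range of the per-round parameter draw.
#' @param seed RNG seed.
#' @return list with `dsi` (per-round values, NA for rounds without spikes),
#'   `mean`, `sd`, and `n_excluded` (spikeless rounds).
#' @export
run_dsi_experiment <- function(variant = c("TDE3", "TDE2"), n_rounds = 40,
                               n_stimuli = 200, param_range_factor = 10,
                               seed = 1) {
  variant <- match.arg(variant)
  if (n_rounds < 1 || n_stimuli < 1) stop("need at least one round and stimulus")
  set.seed(seed)
  dirs <- c("L-R", "R-L", "T-B", "B-T")
  vels <- velocity_set("wide")
  centers <- c(tau_g = 20, tau_i = 10, tau_v = 10, w_g = 1)
  f <- param_range_factor
  dsi_rounds <- rep(NA_real_, n_rounds)
  for (r in seq_len(n_rounds)) {
    draw <- exp(stats::runif(4, log(centers), log(centers * f)))
    params <- tde_params(tau_g = draw[1], tau_i = draw[2], tau_v = draw[3],
                         w_g = draw[4], theta = 1)
    stim_dir <- sample(dirs, n_stimuli, replace = TRUE)
    stim_vel <- sample(vels, n_stimuli, replace = TRUE)
    stim_gf <- stats::runif(n_stimuli, 0, 0.8)
    series <- lapply(seq_len(n_stimuli), function(s)
      bar_detector_series(stim_vel[s], stim_dir[s], stim_gf[s]))
    t_max <- max(vapply(series, function(s) length(s$fac), integer(1)))
    pad <- function(x) c(x, numeric(t_max - length(x)))
    fac <- t(vapply(series, function(s) pad(s$fac), numeric(t_max)))
    tr <- t(vapply(series, function(s) pad(s$tr), numeric(t_max)))
    inh <- t(vapply(series, function(s) pad(s$inh), numeric(t_max)))
    run <- tde_run(fac, tr, inh, params, variant)
    spk <- rowSums(run$spikes)
    by_dir <- vapply(dirs, function(d) sum(spk[stim_dir == d]), numeric(1))
    if (sum(by_dir) > 0)
      dsi_rounds[r] <- dsi(by_dir[["L-R"]], by_dir[["R-L"]],
                           by_dir[["T-B"]], by_dir[["B-T"]])
  }
  ok <- !is.na(dsi_rounds)
  list(dsi = dsi_rounds, mean = mean(dsi_rounds[ok]), sd = stats::sd(dsi_rounds[ok]),
       n_excluded = sum(!ok))
}

#' Train-and-test velocity-inference benchmark
#'
#' Trains a detector with [tde_fit()] under the requested stimulus ensemble
#' and training inference, then evaluates on freshly generated stimuli with
#' the requested test inference.
#'
#' @param range `"wide"` or `"narrow"`.
#' @param edges 1 or 2.
#' @param noise_rate background-activity rate in Hz/px.
#' @param train_mode,test_mode `"count"` or `"isi"`.
#' @param seed RNG seed (training; evaluation uses `seed + 1`).
#' @param epochs training epochs (NULL = mode default).
#' @param n_per_velocity evaluation examples per velocity.
#' @return list with `correlation`, `correlation_second_edge`,
#'   `relative_error_pct`, `mean_spikes`, `fta_pct`, the fitted model `fit`,
#'   and the raw evaluation `eval`.
#' @export
run_inference_benchmark <- function(range = c("wide", "narrow"), edges = 1,
                                    noise_rate = 0,
                                    train_mode = c("count", "isi"),
                                    test_mode = c("count", "isi"),
                                    seed = 1, epochs = NULL,
                                    n_per_velocity = 20) {
  range <- match.arg(range)
  train_mode <- match.arg(train_mode)
  test_mode <- match.arg(test_mode)
  fit <- tde_fit(mode = train_mode, range = range, edges = edges,
                 noise_rate = noise_rate, epochs = epochs, seed = seed)
  ev <- evaluate_tde(fit, test_mode = test_mode,
                     n_per_velocity = n_per_velocity, seed = seed + 1)
  list(correlation = ev$correlation,
       correlation_second_edge = ev$correlation_second_edge,
       relative_error_pct = ev$relative_error_pct,
       mean_spikes = ev$mean_spikes,
       fta_pct = ev$fta_pct,
       fit = fit, eval = ev)
}
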