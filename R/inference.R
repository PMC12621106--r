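#' Inference configuration for velocity decoding
#'
#' Decoding constants shared by the spike-count and ISI decoders. Two
#' ready-made schemes correspond to the wide (10-fold) and narrow (1.5-fold)
#' stimulus dynamic ranges:
#'
#' * wide / count: `estimate = beta * count` with `beta = 0.1` px/timestep per
#'   spike, so the slowest stimulus (0.1 px/timestep) is encoded by a single
#'   spike; counting window 10 timesteps.
#' * narrow / count: `estimate = bias + resolution * count` for `count >= 1`
#'   (`bias = 0.024`, `resolution = 0.001` px/timestep), so 0.025 px/timestep
#'   costs one spike instead of 25.
#' * wide / ISI: `estimate = gamma / ISI` with `gamma = 1` (the fastest
#'   stimulus maps to ISI 1).
#' * narrow / ISI: `estimate = bias + isi_scale / ISI` with
#'   `isi_scale = 0.016`, the additive-bias analog of the count scheme.
#'
#' @param mode `"count"` or `"isi"`.
#' @param range `"wide"` or `"narrow"`; fills the defaults below.
#' @param win spike-counting window in timesteps.
#' @param beta count-to-velocity scale (px/timestep per spike).
#' @param bias additive bias (px/timestep) of the narrow-range schemes.
#' @param resolution narrow-range velocity resolution (px/timestep per spike).
#' @param tau_f spike-trace time constant in timesteps; the trace decays by
#'   `exp(-1/tau_f)` per step so the logarithmic ISI inversion is exact.
#' @param gamma ISI-to-velocity scale.
#' @param isi_scale narrow-range ISI scale (px/timestep).
#' @param isi_fallback ISI assigned when fewer than two spikes follow an
#'   onset, in `[1e3, 1e6]`; the decoded velocity is then effectively zero.
#' @return an object of class `inference_config`.
#' @export
inference_config <- function(mode = c("count", "isi"),
                             range = c("wide", "narrow"),
                             win = NULL, beta = 0.1, bias = 0.024,
                             resolution = 0.001, tau_f = 5, gamma = 1,
                             isi_scale = 0.016, isi_fallback = 1e4) {
  mode <- match.arg(mode)
  range <- match.arg(range)
  if (is.null(win)) win <- if (range == "wide") 10L else 50L
  if (win < 1) stop("win must be >= 1")
  if (tau_f <= 0) stop("tau_f must be positive")
  if (isi_fallback < 1e3 || isi_fallback > 1e6)
    stop("isi_fallback must lie in [1e3, 1e6]")
  structure(list(mode = mode, range = range, win = as.integer(win),
                 beta = beta, bias = bias, resolution = resolution,
                 tau_f = tau_f, gamma = gamma, isi_scale = isi_scale,
                 isi_fallback = isi_fallback),
            class = "inference_config")
}

#' Motion-segmentation onsets from the TDE current
#'
#' An onset is any strict increase of the current trace (`i[t] > i[t-1]`,
#' with `i[0] = 0`). Every trigger activation raises the current, so onsets
#' mark the passage of a new edge and restart the decoders.
#'
#' @param current numeric vector (one detector's current trace) or matrix
#'   (`B x T`, row-wise).
#' @return binary vector/matrix of onsets, same shape.
#' @export
segment_onsets <- function(current) {
  if (is.matrix(current)) {
    prev <- cbind(0, current[, -ncol(current), drop = FALSE])
    return((current > prev) * 1)
  }
  prev <- c(0, current[-length(current)])
  (current > prev) * 1
}

# Onset bookkeeping for one detector: returns integer vector of onset times.
onset_times <- function(current) which(segment_onsets(current) == 1)

# Map a spike count to a velocity under the configured scheme.
count_to_velocity <- function(count, cfg) {
  if (cfg$range == "wide") cfg$beta * count
  else ifelse(count >= 1, cfg$bias + cfg$resolution * count, 0)
}

# Map an ISI to a velocity under the configured scheme. The additive bias of
# the narrow scheme applies only to measured ISIs: an undecodable train
# (fewer than two spikes, ISI = isi_fallback) must read as a vanishing
# velocity, not as the bottom of the encoded range.
isi_to_velocity <- function(isi, cfg) {
  if (cfg$range == "wide") return(cfg$gamma / isi)
  ifelse(isi >= cfg$isi_fallback, cfg$isi_scale / isi,
         cfg$bias + cfg$isi_scale / isi)
}

#' Spike-count velocity decoding
#'
#' For each onset of the current trace, counts output spikes from the onset
#' until the end of the counting window (or until the next onset, whichever
#' comes first: a new onset means a new edge and restarts the count), and
#' converts the count to a velocity estimate placed at the onset timestep.
#' All other timesteps carry a zero estimate.
#'
#' @param rec a `spike_record`, or a list with `spikes` and `current`
#'   (vectors for one detector, or `B x T` matrices).
#' @param cfg an [inference_config()] with `mode = "count"`.
#' @return for vector input, a list (`velocity_series`) with `estimates` and
#'   `onsets`; for matrix input, the same with `B x T` matrices.
#' @export
spike_count_velocity <- function(rec, cfg = inference_config("count")) {
  if (cfg$mode != "count") stop("cfg$mode must be 'count'")
  decode_rows(rec, function(s, i) decode_count_one(s, i, cfg))
}

decode_count_one <- function(spikes, current, cfg) {
  T_ <- length(spikes)
  est <- numeric(T_)
  on <- onset_times(current)
  if (length(on)) {
    ends <- c(on[-1] - 1L, T_)
    for (k in seq_along(on)) {
      hi <- min(on[k] + cfg$win - 1L, ends[k])
      cnt <- sum(spikes[on[k]:hi])
      est[on[k]] <- count_to_velocity(cnt, cfg)
    }
  }
  onsets <- numeric(T_); onsets[on] <- 1
  structure(list(estimates = est, onsets = onsets), class = "velocity_series")
}

#' Inter-spike-interval velocity decoding
#'
#' Maintains a low-pass spike trace `x[t] = exp(-1/tau_f) x[t-1] + s[t]`,
#' reset to zero at each onset. The ISI between the first two post-onset
#' spikes is recovered by inverting the trace: with `x0` the trace at the
#' first spike and `x` its value at the timestep preceding the second spike,
#' the elapsed time is `tau_f * log(x0 / x)` and `ISI = elapsed + 1`. The
#' estimate `gamma / ISI` (or its narrow-range analog) is placed at the onset
#' timestep. Fewer than two post-onset spikes yield `ISI = isi_fallback`
#' (a vanishing velocity).
#'
#' @inheritParams spike_count_velocity
#' @param cfg an [inference_config()] with `mode = "isi"`.
#' @return as [spike_count_velocity()].
#' @export
isi_velocity <- function(rec, cfg = inference_config("isi")) {
  if (cfg$mode != "isi") stop("cfg$mode must be 'isi'")
  decode_rows(rec, function(s, i) decode_isi_one(s, i, cfg))
}

decode_isi_one <- function(spikes, current, cfg) {
  T_ <- length(spikes)
  est <- numeric(T_)
  on <- onset_times(current)
  if (length(on)) {
    ends <- c(on[-1] - 1L, T_)
    lam <- exp(-1 / cfg$tau_f)
    for (k in seq_along(on)) {
      seg <- on[k]:ends[k]
      sp <- seg[spikes[seg] == 1]
      if (length(sp) >= 2) {
        t1 <- sp[1]; t2 <- sp[2]
        # trace restarted at the onset: x0 = 1 at the first spike,
        # x = lam^(t2 - 1 - t1) at the timestep preceding the second spike
        x0 <- 1
        x <- lam^(t2 - 1 - t1)
        if (x <= 0) stop("non-positive trace at ISI readout")
        isi <- cfg$tau_f * log(x0 / x) + 1
      } else {
        isi <- cfg$isi_fallback
      }
      est[on[k]] <- isi_to_velocity(isi, cfg)
    }
  }
  onsets <- numeric(T_); onsets[on] <- 1
  structure(list(estimates = est, onsets = onsets), class = "velocity_series")
}

# Apply a per-detector decoder over vector or matrix records.
decode_rows <- function(rec, f) {
  s <- rec$spikes; i <- rec$current
  if (is.null(s) || is.null(i)) stop("rec must contain spikes and current")
  if (!is.matrix(s)) return(f(s, i))
  out_e <- matrix(0, nrow(s), ncol(s))
  out_o <- matrix(0, nrow(s), ncol(s))
  for (b in seq_len(nrow(s))) {
    vs <- f(s[b, ], i[b, ])
    out_e[b, ] <- vs$estimates
    out_o[b, ] <- vs$onsets
  }
  structure(list(estimates = out_e, onsets = out_o), class = "velocity_series")
}

#' Decode velocities with either scheme
#'
#' Convenience dispatcher over [spike_count_velocity()] and [isi_velocity()].
#'
#' @inheritParams spike_count_velocity
#' @export
decode_velocity <- function(rec, cfg) {
  if (cfg$mode == "count") spike_count_velocity(rec, cfg) else isi_velocity(rec, cfg)
}
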