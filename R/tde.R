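#' @useDynLib tdeflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' TDE parameters
#'
#' Trainable parameters of a time-difference encoder. The per-step decay
#' multipliers of the gain, current and voltage compartments are
#' `alpha = sigmoid(p)` with unconstrained reals `p_g, p_i, p_v`, so they stay
#' in (0, 1) during gradient training. Time constants are reported through the
#' standard leaky-integrator discretization `alpha = exp(-dt / tau)`.
#'
#' Specify either the multipliers (`alpha_*`) or time constants in timesteps
#' (`tau_*`); `tau` wins if both are given.
#'
#' @param alpha_g,alpha_i,alpha_v decay multipliers in (0, 1) for gain,
#'   current and membrane voltage.
#' @param tau_g,tau_i,tau_v optional time constants in timesteps
#'   (`alpha = exp(-1 / tau)`).
#' @param w_g synaptic weight of the facilitator (gain) input, >= 0.
#' @param theta firing threshold (> 0); the neuron fires when `v - theta >= 0`.
#' @param dt_ms timestep duration in ms (bookkeeping only; dynamics are per
#'   timestep).
#' @return an object of class `tde_params`.
#' @export
tde_params <- function(alpha_g = 0.95, alpha_i = 0.9, alpha_v = 0.9,
                       tau_g = NULL, tau_i = NULL, tau_v = NULL,
                       w_g = 1, theta = 1, dt_ms = 10) {
  if (!is.null(tau_g)) alpha_g <- exp(-1 / tau_g)
  if (!is.null(tau_i)) alpha_i <- exp(-1 / tau_i)
  if (!is.null(tau_v)) alpha_v <- exp(-1 / tau_v)
  a <- c(alpha_g, alpha_i, alpha_v)
  if (any(a <= 0 | a >= 1)) stop("decay multipliers must lie in (0, 1)")
  if (w_g < 0) stop("w_g must be non-negative")
  if (theta <= 0) stop("theta must be positive")
  structure(list(p_g = logit(alpha_g), p_i = logit(alpha_i), p_v = logit(alpha_v),
                 w_g = w_g, theta = theta, dt_ms = dt_ms),
            class = "tde_params")
}

tde_alphas <- function(params) {
  c(g = sigmoid(params$p_g), i = sigmoid(params$p_i), v = sigmoid(params$p_v))
}

#' @export
print.tde_params <- function(x, ...) {
  a <- tde_alphas(x)
  tau <- -1 / log(a)
  cat("<tde_params>\n")
  cat(sprintf("  alpha (g, i, v): %.3f, %.3f, %.3f  (tau %.1f, %.1f, %.1f steps)\n",
              a[1], a[2], a[3], tau[1], tau[2], tau[3]))
  cat(sprintf("  w_g = %.3f, theta = %.3f, dt = %g ms\n", x$w_g, x$theta, x$dt_ms))
  invisible(x)
}

#' Heaviside spike function
#'
#' Forward value of the spiking nonlinearity: 1 when `x >= 0`, else 0
#' (threshold-inclusive). During training its derivative is replaced by
#' [surrogate_grad()].
#'
#' @param x numeric.
#' @return 0/1 numeric of the same shape.
#' @export
spike_fn <- function(x) (x >= 0) * 1

#' Surrogate derivative of the spike function
#'
#' Fast-sigmoid surrogate `1 / (1 + beta |x|)^2`: peaked at 0, strictly
#' positive everywhere, decaying polynomially. Used in place of the (almost
#' everywhere zero) Heaviside derivative in the backward pass.
#'
#' @param x numeric.
#' @param beta steepness (default 10).
#' @return the surrogate derivative, same shape as `x`.
#' @export
surrogate_grad <- function(x, beta = 10) 1 / (1 + beta * abs(x))^2

#' One timestep of TDE dynamics
#'
#' Reference (scalar) implementation of the discrete-time update, in the
#' canonical order: current first (the trigger converts the *previous* gain),
#' then gain (with multiplicative inhibitory reset for TDE-3), then voltage,
#' spike, and post-spike voltage reset.
#'
#' @param state list with elements `g`, `i`, `v` (numeric scalars).
#' @param fac,tr,inh binary inputs to facilitator, trigger, inhibitor
#'   (`inh` is ignored for TDE-2).
#' @param params a [tde_params()] object.
#' @param variant `"TDE3"` or `"TDE2"`.
#' @return list with the updated `state` and the emitted `spike` (0/1).
#' @export
tde_step <- function(state, fac, tr, inh, params, variant = c("TDE3", "TDE2")) {
  variant <- match.arg(variant)
  a <- tde_alphas(params)
  i_new <- a[["i"]] * state$i + state$g * tr
  g_new <- a[["g"]] * state$g + params$w_g * fac
  if (variant == "TDE3") g_new <- g_new * (1 - inh)
  v_new <- a[["v"]] * state$v + i_new
  s <- spike_fn(v_new - params$theta)
  v_new <- (1 - s) * v_new
  list(state = list(g = g_new, i = i_new, v = v_new), spike = s)
}

#' Run TDE dynamics over input spike trains
#'
#' Batched simulation of the full recurrence: rows of the input matrices are
#' independent detectors/examples, columns are timesteps.
#'
#' @param fac,tr,inh binary matrices (or vectors) of facilitator, trigger and
#'   inhibitor input, `B x T`.
#' @param params a [tde_params()] object.
#' @param variant `"TDE3"` or `"TDE2"`.
#' @return list with `B x T` matrices `spikes`, `current`, `gain`, and
#'   `voltage` (pre-reset membrane voltage).
#' @export
tde_run <- function(fac, tr, inh = NULL, params = tde_params(),
                    variant = c("TDE3", "TDE2")) {
  variant <- match.arg(variant)
  if (is.vector(fac)) fac <- matrix(fac, nrow = 1)
  if (is.vector(tr)) tr <- matrix(tr, nrow = 1)
  if (is.null(inh)) inh <- fac * 0
  if (is.vector(inh)) inh <- matrix(inh, nrow = 1)
  stopifnot(all(dim(fac) == dim(tr)), all(dim(fac) == dim(inh)))
  a <- tde_alphas(params)
  fw <- tde_forward_cpp(fac, tr, inh, a[["g"]], a[["i"]], a[["v"]],
                        params$w_g, params$theta, variant == "TDE3")
  list(spikes = fw$s, current = fw$i, gain = fw$g, voltage = fw$u)
}

#' Detector layout over a pixel grid
#'
#' Places one detector per direction channel at every pixel whose facilitator
#' and inhibitor fall inside the grid. For a channel with unit direction `d`
#' and spacing `s`, the trigger sits at the pixel, the facilitator at
#' `-s * d` and the inhibitor at `+s * d` (the facilitator is hit first under
#' preferred-direction motion). x grows rightward, y downward; `"L-R"` means
#' motion toward increasing x.
#'
#' @param height,width grid size in px.
#' @param spacing compartment spacing in px: a scalar or an `H x W` matrix
#'   (per-pixel spacing, e.g. from [build_eccentric_layout()]).
#' @param directions channels to build.
#' @return a data.frame of class `detector_layout` with one row per detector:
#'   `channel`, `y`, `x` (trigger pixel), `spacing`, and facilitator /
#'   inhibitor coordinates.
#' @export
make_layout <- function(height, width, spacing = 1,
                        directions = c("L-R", "R-L", "T-B", "B-T")) {
  dirs <- list("L-R" = c(0, 1), "R-L" = c(0, -1),
               "T-B" = c(1, 0), "B-T" = c(-1, 0))
  if (!all(directions %in% names(dirs))) stop("unknown direction channel")
  sp <- if (is.matrix(spacing)) spacing else
    matrix(spacing, nrow = height, ncol = width)
  if (any(sp < 1)) stop("spacing must be >= 1 px")
  grid <- expand.grid(y = seq_len(height), x = seq_len(width))
  out <- do.call(rbind, lapply(directions, function(ch) {
    d <- dirs[[ch]]
    s <- sp[cbind(grid$y, grid$x)]
    fy <- grid$y - s * d[1]; fx <- grid$x - s * d[2]
    iy <- grid$y + s * d[1]; ix <- grid$x + s * d[2]
    ok <- fy >= 1 & fy <= height & fx >= 1 & fx <= width &
      iy >= 1 & iy <= height & ix >= 1 & ix <= width
    data.frame(channel = ch, y = grid$y[ok], x = grid$x[ok], spacing = s[ok],
               fac_y = fy[ok], fac_x = fx[ok], inh_y = iy[ok], inh_x = ix[ok])
  }))
  class(out) <- c("detector_layout", class(out))
  out
}

#' Run a TDE network over an event grid
#'
#' Applies the detectors of a layout to a (possibly noisy) event grid. ON and
#' OFF polarities are pooled (logical OR per pixel-bin) before entering the
#' detectors.
#'
#' @param grid an `event_grid`.
#' @param layout a [make_layout()] / [build_eccentric_layout()] layout.
#' @param params a [tde_params()] object.
#' @param variant `"TDE3"` or `"TDE2"`.
#' @return a `spike_record`: list with `spikes` and `current` (`n_detector x
#'   T` matrices), the `layout`, and `dt_ms`.
#' @export
run_tde_network <- function(grid, layout, params = tde_params(),
                            variant = c("TDE3", "TDE2")) {
  variant <- match.arg(variant)
  occ <- merge_polarities(grid)                  # (T, H, W)
  d <- dim(occ); T_ <- d[1]; H <- d[2]; W <- d[3]
  bad <- layout$y < 1 | layout$y > H | layout$x < 1 | layout$x > W
  if (any(bad)) stop("layout coordinates outside the grid")
  pick <- function(y, x) {
    # series for each (y, x) pair: returns n x T matrix
    flat <- matrix(occ, nrow = T_)               # T x (H*W), column-major (y fastest)
    t(flat[, (x - 1) * H + y, drop = FALSE])
  }
  fac <- pick(layout$fac_y, layout$fac_x)
  tr <- pick(layout$y, layout$x)
  inh <- pick(layout$inh_y, layout$inh_x)
  run <- tde_run(fac, tr, inh, params, variant)
  structure(list(spikes = run$spikes, current = run$current,
                 layout = layout, dt_ms = grid$dt_ms),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d detectors x %d bins, %d spikes\n",
              nrow(x$spikes), ncol(x$spikes), sum(x$spikes)))
  invisible(x)
}
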