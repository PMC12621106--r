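#' Eccentric detector layout
#'
#' Assigns compartment spacings that grow with distance from the image
#' center: concentric annuli of equal radial extent receive the entries of
#' `spacings` from the center outward. A detector with spacing `n` encodes
#' `n`-fold higher velocities than a spacing-1 detector with the same
#' parameters, so the set of spacings multiplies the network's velocity
#' coverage without retraining.
#'
#' @param height,width grid size (px).
#' @param spacings ascending spacings in px (default `c(1, 2, 3, 4, 6, 8)`).
#' @param directions channels to build.
#' @return list with `layout` (a [make_layout()] layout using the per-pixel
#'   spacings) and `map` (the `H x W` spacing matrix).
#' @export
build_eccentric_layout <- function(height, width,
                                   spacings = c(1, 2, 3, 4, 6, 8),
                                   directions = c("L-R", "R-L", "T-B", "B-T")) {
  if (is.unsorted(spacings)) stop("spacings must be ascending")
  if (max(spacings) > floor(min(height, width) / 2))
    stop("largest spacing exceeds half the image")
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  r <- sqrt((yy - cy)^2 + (xx - cx)^2)
  r_max <- max(r)
  k <- length(spacings)
  band <- pmin(pmax(ceiling(k * r / max(r_max, 1e-9)), 1), k)
  map <- matrix(spacings[band], height, width)
  list(layout = make_layout(height, width, spacing = map,
                            directions = directions),
       map = map)
}

#' Signed optical flow from opposing direction channels
#'
#' Combines the four direction channels of a decoded spike record into a
#' per-pixel, per-frame signed flow field: `v_x = est(L-R) - est(R-L)` and
#' `v_y = est(T-B) - est(B-T)`, each estimate converted from px/timestep (at
#' the detector's compartment spacing) to px/s.
#'
#' @param vs a `velocity_series` from [decode_velocity()] applied to a
#'   [run_tde_network()] record (rows aligned with the layout).
#' @param layout the `detector_layout` the record was produced with.
#' @param dims `c(H, W)` of the pixel grid.
#' @param dt_ms bin duration in ms.
#' @return a `(T, H, W, 2)` flow array in px/s (x-component last-dim 1,
#'   y-component 2); zero wherever no detector reported.
#' @export
decode_flow <- function(vs, layout, dims, dt_ms) {
  est <- vs$estimates
  if (!is.matrix(est) || nrow(est) != nrow(layout))
    stop("estimates must be one row per layout detector")
  T_ <- ncol(est); H <- dims[1]; W <- dims[2]
  chan <- function(ch) {
    a <- array(0, dim = c(T_, H, W))
    rows <- which(layout$channel == ch)
    for (j in rows) {
      scale <- layout$spacing[j] * 1000 / dt_ms
      a[, layout$y[j], layout$x[j]] <- est[j, ] * scale
    }
    a
  }
  lr <- chan("L-R"); rl <- chan("R-L"); tb <- chan("T-B"); bt <- chan("B-T")
  flow <- array(0, dim = c(T_, H, W, 2))
  flow[, , , 1] <- lr - rl
  flow[, , , 2] <- tb - bt
  flow
}

#' Yaw-rate estimate from horizontal direction channels
#'
#' Pools left-right detector spikes with positive sign and right-left spikes
#' with negative sign per frame, then scales the pooled series so that the
#' frame of maximal absolute activity maps to the supplied maximal angular
#' velocity.
#'
#' @param spikes_lr,spikes_rl spike matrices (`detectors x T`) or per-frame
#'   count vectors.
#' @param gt_max maximal angular velocity in degrees/s used as the scaling
#'   anchor.
#' @return data.frame with `frame`, `raw` (signed spike sum) and `deg_per_s`.
#' @export
estimate_yaw_rate <- function(spikes_lr, spikes_rl, gt_max) {
  pool <- function(s) if (is.matrix(s)) colSums(s) else as.numeric(s)
  lr <- pool(spikes_lr); rl <- pool(spikes_rl)
  if (length(lr) != length(rl)) stop("channel series must be aligned")
  raw <- lr - rl
  m <- max(abs(raw))
  deg <- if (m > 0) raw / m * gt_max else raw * 0
  data.frame(frame = seq_along(raw), raw = raw, deg_per_s = deg)
}

#' Flow-field visualization colors
#'
#' Encodes flow direction as hue and magnitude as brightness (normalized by
#' the frame maximum); zero flow is black.
#'
#' @param flow an `(H, W, 2)` flow frame.
#' @return an `(H, W, 3)` RGB array in `[0, 1]`.
#' @export
flow_to_rgb <- function(flow) {
  d <- dim(flow)
  if (length(d) != 3 || d[3] != 2) stop("flow must be (H, W, 2)")
  vx <- flow[, , 1]; vy <- flow[, , 2]
  mag <- sqrt(vx^2 + vy^2)
  mx <- max(mag)
  val <- if (mx > 0) mag / mx else mag
  hue <- (atan2(vy, vx) / (2 * pi)) %% 1
  cols <- grDevices::hsv(h = hue, s = 1, v = val)
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, dim = c(d[1], d[2], 3))
  out[, , 1] <- matrix(rgb[1, ], d[1], d[2])
  out[, , 2] <- matrix(rgb[2, ], d[1], d[2])
  out[, , 3] <- matrix(rgb[3, ], d[1], d[2])
  out
}
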