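#' Spatio-temporal correlation filter configuration
#'
#' @param n spike threshold: an event passes only if the summed event count in
#'   its 3x3 spatial neighborhood (both polarities, including the pixel
#'   itself) within the temporal window reaches `n`. `n = 0` passes
#'   everything. May be real-valued during training; rounded at inference.
#' @param window_ms temporal window in ms; `NULL` means one bin (the grid's
#'   own `dt`).
#' @return an object of class `stcf_config`.
#' @export
stcf_config <- function(n = 0, window_ms = NULL) {
  if (n < 0) stop("n must be non-negative")
  structure(list(n = n, window_ms = window_ms), class = "stcf_config")
}

# Neighborhood event sums per (bin, pixel): for each t and (y, x), the total
# event count over both polarities in the 3x3 neighborhood (zero padding)
# within the last ceil(window / dt) bins ending at t. Returns a (T, H, W)
# array.
stcf_neighbor_sums <- function(grid, window_ms = NULL) {
  cts <- grid$counts
  d <- dim(cts)                                  # (T, 2, H, W)
  T_ <- d[1]; H <- d[3]; W <- d[4]
  tot <- array(cts[, 1, , , drop = FALSE] + cts[, 2, , , drop = FALSE],
               dim = c(T_, H, W))
  nb <- array(0, dim = c(T_, H, W))
  for (dy in -1:1) for (dx in -1:1) {
    ys <- seq_len(H) + dy; xs <- seq_len(W) + dx
    ok_y <- ys >= 1 & ys <= H; ok_x <- xs >= 1 & xs <= W
    nb[, ok_y, ok_x] <- nb[, ok_y, ok_x] +
      tot[, ys[ok_y], xs[ok_x], drop = FALSE]
  }
  w_bins <- if (is.null(window_ms)) 1L else max(1L, ceiling(window_ms / grid$dt_ms))
  if (w_bins > 1L) {
    cs <- apply(nb, c(2, 3), cumsum)             # (T, H, W)
    lag <- cs * 0
    if (T_ > w_bins) lag[(w_bins + 1):T_, , ] <- cs[1:(T_ - w_bins), , ]
    nb <- cs - lag
  }
  nb
}

#' Spatio-temporal correlation filtering of an event grid
#'
#' Denoises an event grid: an event at a pixel survives only if the event
#' count in the pixel's 3x3 neighborhood (both polarities, center included,
#' zero padding at borders) within the temporal window is at least `cfg$n`.
#' Output is binary occupancy per polarity; the filter never creates events.
#'
#' @param grid an `event_grid`.
#' @param cfg an `stcf_config` (or a number, taken as `n` with a one-bin
#'   window).
#' @return the filtered `event_grid` (binary counts).
#' @export
stcf_filter <- function(grid, cfg) {
  if (!inherits(cfg, "stcf_config")) cfg <- stcf_config(n = cfg)
  nb <- stcf_neighbor_sums(grid, cfg$window_ms)
  d <- dim(grid$counts)
  pass <- nb >= round(cfg$n)                     # (T, H, W)
  out <- array(0, dim = d)
  out[, 1, , ] <- (grid$counts[, 1, , ] > 0 & pass) * 1
  out[, 2, , ] <- (grid$counts[, 2, , ] > 0 & pass) * 1
  event_grid(out, grid$dt_ms)
}
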