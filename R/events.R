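#' Intensity sequence
#'
#' A grayscale stimulus clip: a `(T, H, W)` array of strictly positive light
#' intensities (arbitrary units) sampled every `dt_ms` milliseconds. The
#' event-camera model is logarithmic, so zero or negative intensities are
#' rejected at construction.
#'
#' @param frames numeric array of dimension `(T, H, W)`, all values > 0.
#' @param dt_ms timestep duration in milliseconds.
#' @return an object of class `intensity_sequence`.
#' @export
intensity_sequence <- function(frames, dt_ms = 10) {
  if (length(dim(frames)) != 3L)
    stop("frames must be a (T, H, W) array")
  if (any(!is.finite(frames)) || any(frames <= 0))
    stop("all intensities must be positive and finite (log-intensity model)")
  if (dt_ms <= 0) stop("dt_ms must be positive")
  structure(list(frames = frames, dt_ms = dt_ms), class = "intensity_sequence")
}

#' @export
print.intensity_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<intensity_sequence> %d frames of %d x %d px, dt = %g ms\n",
              d[1], d[2], d[3], x$dt_ms))
  invisible(x)
}

#' Event grid
#'
#' Time-binned event counts: a `(T, 2, H, W)` array of non-negative integers,
#' polarity slice 1 = ON (+1), slice 2 = OFF (-1). Bins are half-open
#' `[k dt, (k+1) dt)`.
#'
#' @param counts array `(T, 2, H, W)` of counts >= 0.
#' @param dt_ms bin width in milliseconds.
#' @return an object of class `event_grid`.
#' @export
event_grid <- function(counts, dt_ms = 10) {
  if (length(dim(counts)) != 4L || dim(counts)[2] != 2L)
    stop("counts must be a (T, 2, H, W) array")
  if (any(counts < 0)) stop("event counts must be non-negative")
  structure(list(counts = counts, dt_ms = dt_ms), class = "event_grid")
}

#' @export
print.event_grid <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<event_grid> %d bins x %d x %d px, dt = %g ms, %d events\n",
              d[1], d[3], d[4], x$dt_ms, sum(x$counts)))
  invisible(x)
}

#' Dimensions of an event grid as (T, 2, H, W)
#' @param grid an `event_grid`.
#' @export
grid_dim <- function(grid) dim(grid$counts)

#' Convert an intensity sequence to events
#'
#' Memoryless frame-difference event-camera model: an ON event is emitted at
#' pixel (y, x) and bin t whenever `log I_t - log I_{t-1} > threshold`, an OFF
#' event whenever the log-difference is below `-threshold`. There is no
#' per-pixel reference level; each frame pair is thresholded independently.
#' Bin 1 (no predecessor frame) is always empty, keeping event bins aligned
#' with the frames that produced them.
#'
#' @param frames an `intensity_sequence` (>= 2 frames).
#' @param threshold contrast threshold on the log-intensity step (default
#'   0.15, applied symmetrically as +/- threshold).
#' @return an `event_grid` of binary occupancy counts.
#' @export
simulate_events <- function(frames, threshold = 0.15) {
  if (!inherits(frames, "intensity_sequence")) frames <- intensity_sequence(frames)
  if (threshold <= 0) stop("threshold must be positive")
  f <- frames$frames
  d <- dim(f)
  if (d[1] < 2L) stop("need at least 2 frames")
  lf <- log(f)
  dl <- lf[-1, , , drop = FALSE] - lf[-d[1], , , drop = FALSE]
  counts <- array(0, dim = c(d[1], 2L, d[2], d[3]))
  counts[-1, 1, , ] <- (dl > threshold) * 1
  counts[-1, 2, , ] <- (dl < -threshold) * 1
  event_grid(counts, frames$dt_ms)
}

# Nearest-integer pixel placement with deterministic half-up ties, so that a
# velocity of 0.5 px/timestep advances exactly 1 px every 2 timesteps
# (base R round() would alternate via round-half-to-even).
round_half_up <- function(x) floor(x + 0.5)

# Three-level bar intensities. Chosen so every pairwise log-contrast
# (black<->gray 0.92, gray<->white 0.69, black<->white 1.61) clears the
# default event threshold of 0.15.
bar_levels <- c(black = 0.2, gray = 0.5, white = 1.0)

# Draw per-bar intensity levels for a three-level texture: each bar is gray
# with probability gray_fraction, otherwise black or white with equal odds.
draw_bar_levels <- function(n_bars, gray_fraction) {
  gray <- stats::runif(n_bars) < gray_fraction
  bw <- sample(c(bar_levels[["black"]], bar_levels[["white"]]), n_bars,
               replace = TRUE)
  ifelse(gray, bar_levels[["gray"]], bw)
}

# 1-D texture profile (intensity per pixel along the motion axis).
bar_texture_profile <- function(texture_length, bar_width, gray_fraction) {
  n_bars <- ceiling(texture_length / bar_width)
  lev <- draw_bar_levels(n_bars, gray_fraction)
  rep(lev, each = bar_width)[seq_len(texture_length)]
}

#' Moving three-level bar texture stimulus
#'
#' A texture of white/gray/black bars oriented orthogonally to the motion
#' axis, translated rigidly through a small field of view at a constant
#' velocity. Sub-pixel positions are rendered by nearest-integer placement:
#' the texture offset at frame t is `round(velocity * (t - 1))` pixels.
#'
#' The default texture is 80 px along the motion axis and 3 px orthogonal to
#' it; pixels not covered by the texture see the white background.
#'
#' @param velocity motion speed in px/timestep (> 0).
#' @param direction one of `"L-R"`, `"R-L"`, `"T-B"`, `"B-T"` (x grows
#'   rightward, y downward).
#' @param gray_fraction expected fraction of gray bars, in `[0, 0.8]`.
#' @param texture_length texture extent along the motion axis (px).
#' @param texture_width texture extent orthogonal to motion (px).
#' @param bar_width width of one bar along the motion axis (px).
#' @param field `c(H, W)` field of view; the texture must fit orthogonally.
#' @param dt_ms timestep duration (ms).
#' @param seed optional RNG seed for the bar levels.
#' @return an `intensity_sequence` with attributes `velocity` and `direction`.
#' @export
make_bar_stimulus <- function(velocity, direction = c("L-R", "R-L", "T-B", "B-T"),
                              gray_fraction = 0, texture_length = 80,
                              texture_width = 3, bar_width = 4,
                              field = c(3, 3), dt_ms = 10, seed = NULL) {
  direction <- match.arg(direction)
  if (velocity <= 0) stop("velocity must be positive")
  if (gray_fraction < 0 || gray_fraction > 0.8)
    stop("gray_fraction must lie in [0, 0.8]")
  H <- field[1]; W <- field[2]
  horiz <- direction %in% c("L-R", "R-L")
  ortho_span <- if (horiz) H else W
  if (texture_width > ortho_span)
    stop("texture wider than the field of view")
  if (!is.null(seed)) set.seed(seed)
  tex <- bar_texture_profile(texture_length, bar_width, gray_fraction)
  span <- if (horiz) W else H
  n_t <- ceiling((texture_length + span + 1) / velocity) + 2L
  prof <- sweep_texture_profile(tex, velocity, n_t, span,
                                forward = direction %in% c("L-R", "T-B"),
                                background = bar_levels[["white"]])
  # prof is (T, span): intensity along the motion axis; replicate orthogonally
  frames <- array(bar_levels[["white"]], dim = c(n_t, H, W))
  ortho_idx <- seq_len(texture_width) + (ortho_span - texture_width) %/% 2
  if (horiz) {
    for (y in ortho_idx) frames[, y, ] <- prof
  } else {
    for (x in ortho_idx) frames[, , x] <- prof
  }
  out <- intensity_sequence(frames, dt_ms)
  attr(out, "velocity") <- velocity
  attr(out, "direction") <- direction
  out
}

# Intensity profile (T x span matrix) of a 1-D texture sweeping through
# `span` pixels. forward = motion toward increasing axis coordinate. At t = 1
# the texture is entirely outside the field and enters on the next offsets.
sweep_texture_profile <- function(tex, velocity, n_t, span, forward = TRUE,
                                  background = 1.0) {
  L <- length(tex)
  off <- round_half_up(velocity * (seq_len(n_t) - 1))
  q <- seq_len(span)
  if (forward) {
    # right end of the texture at axis coordinate off(t); pixel q shows
    # tex[L - off + q] while that index is in 1..L
    idx <- outer(-off, q, `+`) + L          # (T, span)
  } else {
    # mirrored entry from the high end of the axis
    idx <- outer(off, q, `+`) - span        # tex index 1 when q = span + 1 - off
    idx <- L + 1L - idx
  }
  valid <- idx >= 1L & idx <= L
  prof <- matrix(background, n_t, span)
  prof[valid] <- tex[idx[valid]]
  prof
}

#' Moving step-edge stimulus
#'
#' One or two step edges on a homogeneous background, translating
#' left-to-right at a constant velocity with nearest-integer placement. With
#' `n_edges = 2` the stimulus is a bright bar whose width (the inter-edge
#' distance) is drawn uniformly from `spacings`; the leading edge then emits
#' ON events and the trailing edge OFF events at each pixel crossing.
#'
#' @param velocity speed in px/timestep.
#' @param n_edges 1 or 2.
#' @param spacings candidate inter-edge distances in px (used when
#'   `n_edges = 2`).
#' @param width field width in px (height is 1 px plus `height - 1` copies).
#' @param height field height in px.
#' @param dt_ms timestep duration (ms).
#' @param t_extra extra still frames appended after the sweep (lets detector
#'   dynamics play out).
#' @param seed optional RNG seed for the spacing draw.
#' @return an `intensity_sequence` with attributes `velocity` and `spacing`.
#' @export
make_edge_stimulus <- function(velocity, n_edges = 1, spacings = c(3, 4, 5, 7, 10),
                               width = 12, height = 1, dt_ms = 10,
                               t_extra = 0, seed = NULL) {
  if (velocity <= 0) stop("velocity must be positive")
  if (!n_edges %in% c(1, 2)) stop("n_edges must be 1 or 2")
  if (n_edges == 2 && length(spacings) == 0) stop("empty spacing set")
  if (!is.null(seed)) set.seed(seed)
  spacing <- if (n_edges != 2) Inf
  else if (length(spacings) == 1) spacings else sample(spacings, 1)
  i_lo <- 0.2; i_hi <- 1.0
  travel <- width + (if (is.finite(spacing)) spacing else 0) + 1
  n_t <- ceiling(travel / velocity) + as.integer(t_extra)
  off <- round_half_up(velocity * (seq_len(n_t) - 1))
  x <- seq_len(width)
  behind <- outer(off, x, `>=`)                       # leading edge has passed
  if (is.finite(spacing)) {
    gone <- outer(off - spacing, x, `>=`)             # trailing edge has passed
    bright <- behind & !gone
  } else {
    bright <- behind
  }
  prof <- ifelse(bright, i_hi, i_lo)                  # (T, W)
  frames <- array(NA_real_, dim = c(n_t, height, width))
  for (y in seq_len(height)) frames[, y, ] <- prof
  out <- intensity_sequence(frames, dt_ms)
  attr(out, "velocity") <- velocity
  attr(out, "spacing") <- spacing
  out
}

#' First bin at which a moving edge crosses a pixel column
#'
#' Companion to [make_edge_stimulus()]: with nearest-integer placement, the
#' leading edge crosses pixel column `x` at the first frame t where
#' `round(velocity (t-1)) >= x`; the event lands in that bin.
#'
#' @param velocity px/timestep.
#' @param x pixel column (1-based).
#' @param n_t number of frames simulated.
#' @return the bin index, or NA if the edge never reaches the column.
#' @export
edge_crossing_bin <- function(velocity, x, n_t) {
  off <- round_half_up(velocity * (seq_len(n_t) - 1))
  hit <- which(off >= x)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Inject Poisson background-activity noise
#'
#' Adds independent Poisson-distributed spurious events to every pixel, bin
#' and polarity of an event grid, with mean `rate * dt / 1000` per cell
#' (rate in Hz per pixel per polarity). The original events are preserved.
#'
#' @param grid an `event_grid`.
#' @param rate noise rate in Hz/px (>= 0).
#' @param seed optional RNG seed.
#' @return an `event_grid` with noise added.
#' @export
inject_background_noise <- function(grid, rate, seed = NULL) {
  if (rate < 0) stop("noise rate must be non-negative")
  if (rate == 0) return(grid)
  if (!is.null(seed)) set.seed(seed)
  lam <- rate * grid$dt_ms / 1000
  noise <- array(stats::rpois(length(grid$counts), lam), dim = dim(grid$counts))
  event_grid(grid$counts + noise, grid$dt_ms)
}

# Merge polarities to binary occupancy: (T, H, W) array of 0/1.
merge_polarities <- function(grid) {
  cts <- grid$counts
  d <- dim(cts)
  m <- cts[, 1, , , drop = FALSE] + cts[, 2, , , drop = FALSE]
  array((m > 0) * 1, dim = d[c(1, 3, 4)])
}
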