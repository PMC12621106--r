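#' @export
print.tde_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("TDE fit (%s): %s-range %d-edge task, %s inference%s\n",
              cfg$variant, cfg$range, cfg$edges, cfg$mode,
              if (cfg$noise_rate > 0)
                sprintf(", noise %g Hz/px", cfg$noise_rate) else ""))
  h <- x$history
  cat(sprintf("  %d epochs x %d examples; loss %.4f -> %.4f\n",
              cfg$epochs, cfg$batch, h$loss[1], h$loss[nrow(h)]))
  print(x$params)
  if (!is.null(x$stcf_n))
    cat(sprintf("  STCF threshold n = %.2f (rounds to %d)\n",
                x$stcf_n, round(x$stcf_n)))
  invisible(x)
}

#' @export
coef.tde_fit <- function(object, ...) {
  a <- tde_alphas(object$params)
  out <- c(alpha_g = unname(a["g"]), alpha_i = unname(a["i"]),
           alpha_v = unname(a["v"]), w_g = object$params$w_g,
           theta = object$params$theta)
  if (!is.null(object$stcf_n)) out <- c(out, stcf_n = object$stcf_n)
  out
}

#' Predict velocities from a fitted detector
#'
#' Generates a fresh, velocity-balanced batch from the fit's stimulus
#' ensemble, runs the detector, decodes, and returns one row per stimulus
#' edge with the true and estimated velocity.
#'
#' @param object a [tde_fit()] object.
#' @param test_mode decoding scheme (defaults to the training mode).
#' @param n_per_velocity examples per stimulus velocity.
#' @param seed RNG seed for the evaluation batch.
#' @param ... unused.
#' @return a data.frame with columns `example`, `edge`, `velocity`,
#'   `estimate`.
#' @export
predict.tde_fit <- function(object, test_mode = NULL, n_per_velocity = 10,
                            seed = 99, ...) {
  ev <- evaluate_tde(object, test_mode = test_mode,
                     n_per_velocity = n_per_velocity, seed = seed)
  ev$detail
}

#' @export
residuals.tde_fit <- function(object, ...) {
  d <- predict(object, ...)
  d$velocity - d$estimate
}

#' @export
summary.tde_fit <- function(object, ...) {
  ev <- evaluate_tde(object, n_per_velocity = 10, seed = 99)
  out <- list(fit = object,
              correlation = ev$correlation,
              relative_error_pct = ev$relative_error_pct,
              mean_spikes = ev$mean_spikes,
              fta_pct = ev$fta_pct)
  class(out) <- "summary.tde_fit"
  out
}

#' @export
print.summary.tde_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf(paste0("  held-out: r = %.3f, relative error %.2f%%, ",
                     "%.2f spikes/stimulus, FTA %.1f%%\n"),
              x$correlation, x$relative_error_pct, x$mean_spikes, x$fta_pct))
  invisible(x)
}

#' Plot a fitted detector
#'
#' Left panel: training loss per epoch. Right panel: velocity tuning curve
#' (mean decoded estimate per stimulus velocity) against the identity line.
#'
#' @param x a [tde_fit()] object.
#' @param seed evaluation-batch seed.
#' @param ... unused.
#' @export
plot.tde_fit <- function(x, seed = 99, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "loss", main = "training loss")
  d <- predict(x, seed = seed)
  agg <- stats::aggregate(estimate ~ velocity, data = d, FUN = mean)
  graphics::plot(agg$velocity, agg$estimate, type = "b", pch = 19,
                 xlab = "true velocity (px/timestep)",
                 ylab = "estimate (px/timestep)", main = "velocity tuning")
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate stimuli from a fitted detector's ensemble
#'
#' Draws `nsim` stimuli from the fit's training ensemble (velocity, spacing
#' and noise as configured) and returns them as event grids.
#'
#' @param object a [tde_fit()] object.
#' @param nsim number of stimuli.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a list of `event_grid` objects with `velocity` attributes.
#' @export
simulate.tde_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- object$config
  vels <- velocity_set(cfg$range)
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    v <- sample(vels, 1)
    stim <- make_edge_stimulus(v, n_edges = cfg$edges, width = 12, height = 3,
                               dt_ms = cfg$dt_ms, t_extra = 20)
    g <- simulate_events(stim)
    if (cfg$noise_rate > 0) g <- inject_background_noise(g, cfg$noise_rate)
    attr(g, "velocity") <- v
    attr(g, "spacing") <- attr(stim, "spacing")
    out[[k]] <- g
  }
  out
}
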