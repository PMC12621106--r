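#' Read an event file into an event grid
#'
#' Events are stored as CSV with header `x,y,t_us,polarity`: 0-based integer
#' pixel coordinates, integer microsecond timestamps, polarity 1 (ON) or -1
#' (OFF). Binning is half-open: an event at time t lands in bin
#' `floor(t / (dt_ms * 1000)) + 1`.
#'
#' @param path CSV file path.
#' @param dt_ms bin width in ms.
#' @param dims optional `c(H, W)`; inferred from the data when omitted
#'   (required for an empty file).
#' @param n_bins optional number of bins; inferred when omitted.
#' @return an `event_grid`.
#' @export
load_events <- function(path, dt_ms = 10, dims = NULL, n_bins = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  if (!identical(names(df), c("x", "y", "t_us", "polarity")))
    stop("malformed header: expected x,y,t_us,polarity")
  if (nrow(df) == 0) {
    if (is.null(dims) || is.null(n_bins))
      stop("empty event file: dims and n_bins must be declared")
    return(event_grid(array(0, dim = c(n_bins, 2, dims[1], dims[2])), dt_ms))
  }
  bad <- which(!df$polarity %in% c(1, -1))
  if (length(bad))
    stop(sprintf("record %d: polarity must be 1 or -1 (got %s)",
                 bad[1], df$polarity[bad[1]]))
  bad <- which(df$t_us < 0)
  if (length(bad)) stop(sprintf("record %d: negative timestamp", bad[1]))
  if (is.null(dims)) dims <- c(max(df$y) + 1, max(df$x) + 1)
  bad <- which(df$x < 0 | df$x >= dims[2] | df$y < 0 | df$y >= dims[1])
  if (length(bad))
    stop(sprintf("record %d: coordinates outside the %dx%d grid",
                 bad[1], dims[1], dims[2]))
  bins <- floor(df$t_us / (dt_ms * 1000)) + 1
  if (is.null(n_bins)) n_bins <- max(bins)
  if (any(bins > n_bins)) stop("timestamps exceed the declared n_bins")
  counts <- array(0, dim = c(n_bins, 2, dims[1], dims[2]))
  pol <- ifelse(df$polarity == 1, 1, 2)
  idx <- cbind(bins, pol, df$y + 1, df$x + 1)
  for (r in seq_len(nrow(idx)))
    counts[idx[r, 1], idx[r, 2], idx[r, 3], idx[r, 4]] <-
      counts[idx[r, 1], idx[r, 2], idx[r, 3], idx[r, 4]] + 1
  event_grid(counts, dt_ms)
}

#' Write an event grid to an event file
#'
#' Inverse of [load_events()] on the binned representation: each count
#' becomes one CSV row timestamped at its bin start, sorted by time.
#'
#' @param grid an `event_grid`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
save_events <- function(grid, path) {
  d <- dim(grid$counts)
  idx <- which(grid$counts > 0, arr.ind = TRUE)
  rows <- if (nrow(idx)) {
    n <- grid$counts[idx]
    rep_idx <- idx[rep(seq_len(nrow(idx)), n), , drop = FALSE]
    data.frame(x = rep_idx[, 4] - 1,
               y = rep_idx[, 3] - 1,
               t_us = as.integer((rep_idx[, 1] - 1) * grid$dt_ms * 1000),
               polarity = ifelse(rep_idx[, 2] == 1, 1, -1))
  } else {
    data.frame(x = integer(0), y = integer(0), t_us = integer(0),
               polarity = integer(0))
  }
  rows <- rows[order(rows$t_us, rows$y, rows$x, rows$polarity), , drop = FALSE]
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

run_config_keys <- c("seed", "verbose", "out",
                     "stcf.n", "stcf.window_ms",
                     "tde.variant", "tde.p_g", "tde.p_i", "tde.p_v",
                     "tde.tau_g", "tde.tau_i", "tde.tau_v",
                     "tde.w_g", "tde.theta", "tde.dt_ms",
                     "layout.spacing",
                     "infer.mode", "infer.range", "infer.win", "infer.beta",
                     "infer.bias", "infer.resolution", "infer.tau_f",
                     "infer.gamma", "infer.isi_scale", "infer.isi_fallback",
                     "train.mode", "train.range", "train.edges",
                     "train.noise_rate", "train.epochs", "train.batch",
                     "train.lr")

#' Load a run configuration
#'
#' Reads a flat JSON object of dotted configuration keys (e.g. `"tde.w_g"`,
#' `"infer.mode"`); unknown keys are rejected.
#'
#' @param path JSON file path.
#' @return a named list.
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg
}

#' Serialize fitted detector parameters
#'
#' Writes/reads the trained parameters as a flat JSON record of named
#' scalars.
#'
#' @param fit a [tde_fit()] object (or a [tde_params()] object).
#' @param path JSON file path.
#' @return `save_params`: the path, invisibly; `load_params`: a
#'   [tde_params()] object plus `stcf_n` attribute when present.
#' @export
save_params <- function(fit, path) {
  p <- if (inherits(fit, "tde_fit")) fit$params else fit
  a <- tde_alphas(p)
  rec <- list(alpha_g = unname(a["g"]), alpha_i = unname(a["i"]),
              alpha_v = unname(a["v"]), w_g = p$w_g, theta = p$theta,
              dt_ms = p$dt_ms)
  if (inherits(fit, "tde_fit") && !is.null(fit$stcf_n))
    rec$stcf_n <- fit$stcf_n
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- tde_params(alpha_g = rec$alpha_g, alpha_i = rec$alpha_i,
                  alpha_v = rec$alpha_v, w_g = rec$w_g, theta = rec$theta,
                  dt_ms = rec$dt_ms)
  if (!is.null(rec$stcf_n)) attr(p, "stcf_n") <- rec$stcf_n
  p
}
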