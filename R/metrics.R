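#' Normalized curve-mapping discrepancy between two curves
#'
#' Unit-independent discrepancy used as the calibration objective.  Both
#' curves are resampled to a common uniform grid over their overlapping time
#' window and treated as polylines in (t, value) space.  The time axis is
#' normalized by the window length and the value axis by the mean of the two
#' curves' value ranges (making the score symmetric); the discrepancy is the
#' area enclosed between the two normalized polylines (trapezoidal rule).
#' The score is 0 iff the curves are identical after normalization and is
#' invariant under a common affine re-scaling of both curves' value axes
#' (a change of measurement units).
#'
#' @param model,target single channels as returned by [channel()] (data
#'   frames with `time_ms` and `value`).
#' @param n_grid number of resampling points on the common grid.
#' @return an object of class `curve_mapping_score`: list with `value` (>= 0)
#'   and `normalization` (the per-axis scales applied).
#' @export
curve_mapping_error <- function(model, target, n_grid = 301) {
  t0 <- max(min(model$time_ms), min(target$time_ms))
  t1 <- min(max(model$time_ms), max(target$time_ms))
  stop_if(t1 <= t0, "curves have no overlapping time window")
  grid <- seq(t0, t1, length.out = n_grid)
  mv <- stats::approx(model$time_ms, model$value, xout = grid)$y
  tv <- stats::approx(target$time_ms, target$value, xout = grid)$y
  rng_m <- diff(range(mv))
  rng_t <- diff(range(tv))
  vscale <- (rng_m + rng_t) / 2
  if (vscale <= 0) vscale <- max(abs(tv), abs(mv), 1e-12)
  tscale <- t1 - t0
  dm <- (mv - tv) / vscale
  th <- (grid - t0) / tscale
  area <- sum(diff(th) * (abs(dm[-n_grid]) + abs(dm[-1])) / 2)
  structure(list(value = area,
                 normalization = list(time_scale_ms = tscale,
                                      value_scale = vscale)),
            class = "curve_mapping_score")
}

#' @export
print.curve_mapping_score <- function(x, ...) {
  cat(sprintf("<curve_mapping_score> %.6g\n", x$value))
  invisible(x)
}

#' CORA-style corridor + correlation rating
#'
#' Combines a corridor sub-score with three correlation sub-scores into a
#' 0-1 agreement rating over an evaluation window.  Corridors are built from
#' the target curve: half-widths equal to `inner_pct` and `outer_pct` of the
#' target's peak absolute value over the window (default 5% and 50%).  A
#' point scores 1 inside the inner corridor, 0 outside the outer corridor,
#' with a linear fall-off in between; the corridor sub-score is the mean.
#' Correlation sub-scores: phase from the best cross-correlation lag, shape
#' from the correlation coefficient at that lag, size from the ratio of the
#' two curves' absolute areas.  The total is the configured weighted mean.
#' Sub-weights are configuration (defaults: corridor/correlation 0.5/0.5,
#' shape/size/phase equal); the rating is CORA-style, not bit-compatible
#' with any closed-source implementation.
#'
#' @param model,target single channels as returned by [channel()].
#' @param window evaluation window `(t_start, t_end)` in ms; defaults to the
#'   overlapping window.
#' @param inner_pct,outer_pct corridor half-widths as fractions of the
#'   target's peak absolute value.
#' @param weights list with `corridor`, `shape`, `size`, `phase` weights.
#' @param max_lag_frac cross-correlation lag search limit as a fraction of
#'   the window length.
#' @param min_corridor absolute corridor half-width floor used when the
#'   target has zero variance over the window (flagged in the result).
#' @return an object of class `cora_score` with sub-scores, `total`,
#'   `window`, and corridor metadata.
#' @export
cora_rating <- function(model, target, window = NULL,
                        inner_pct = 0.05, outer_pct = 0.50,
                        weights = list(corridor = 0.5, shape = 1/6,
                                       size = 1/6, phase = 1/6),
                        max_lag_frac = 0.2, min_corridor = 1e-9) {
  t0 <- max(min(model$time_ms), min(target$time_ms))
  t1 <- min(max(model$time_ms), max(target$time_ms))
  if (!is.null(window)) {
    stop_if(window[1] < t0 - 1e-9 || window[2] > t1 + 1e-9,
            "window not contained in both channels")
    t0 <- window[1]; t1 <- window[2]
  }
  stop_if(t1 <= t0, "empty evaluation window")
  ng <- 301
  grid <- seq(t0, t1, length.out = ng)
  mv <- stats::approx(model$time_ms, model$value, xout = grid)$y
  tv <- stats::approx(target$time_ms, target$value, xout = grid)$y

  peak <- max(abs(tv))
  degenerate <- peak <= min_corridor || stats::sd(tv) == 0
  if (degenerate) peak <- max(peak, min_corridor)
  inner <- inner_pct * peak
  outer <- outer_pct * peak
  dev <- abs(mv - tv)
  pt <- ifelse(dev <= inner, 1,
               ifelse(dev >= outer, 0, (outer - dev) / (outer - inner)))
  corridor <- mean(pt)

  # cross-correlation: best lag within the search window
  max_lag <- max(1L, floor(max_lag_frac * ng))
  lags <- -max_lag:max_lag
  ccors <- vapply(lags, function(L) {
    if (L >= 0) { a <- mv[seq_len(ng - L)]; b <- tv[seq_len(ng - L) + L] }
    else { a <- mv[seq_len(ng + L) - L]; b <- tv[seq_len(ng + L)] }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-1)
    stats::cor(a, b)
  }, numeric(1))
  best <- which.max(ccors)
  phase <- max(0, 1 - abs(lags[best]) / max_lag)
  shape <- max(0, ccors[best])
  am <- mean(abs(mv)); at <- mean(abs(tv))
  size <- if (max(am, at) == 0) 1 else min(am, at) / max(am, at)

  w <- unlist(weights)
  total <- sum(w * c(corridor, shape, size, phase)) / sum(w)
  structure(list(corridor = corridor, correlation_shape = shape,
                 correlation_size = size, correlation_phase = phase,
                 total = total, window = c(t0, t1),
                 inner_pct = inner_pct, outer_pct = outer_pct,
                 degenerate_target = degenerate),
            class = "cora_score")
}

#' @export
print.cora_score <- function(x, ...) {
  cat(sprintf(paste0("<cora_score> total %.3f (corridor %.3f, shape %.3f, ",
                     "size %.3f, phase %.3f), window [%g, %g] ms\n"),
              x$total, x$corridor, x$correlation_shape, x$correlation_size,
              x$correlation_phase, x$window[1], x$window[2]))
  invisible(x)
}
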