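# Downstream propagation of water-quality disturbances (SL_LE): DO sag
# detection across a sonde array, longitudinal decay of sag magnitude, the
# impact-threshold crossing distance, and the Horton's-law stream-order model.

#' Detect multi-station dissolved-oxygen sag events
#'
#' Per station, a candidate sag is a contiguous run of samples at least
#' `min_duration_h` long with DO below (station baseline - prominence); the
#' station baseline is the series median. Candidates are grouped into events
#' across stations by time proximity (`group_window_h` between consecutive
#' minima); an event is kept only if it spans at least `min_stations`
#' stations with times of minimum strictly increasing downstream (consistent
#' temporal lags). Each per-station sag is flagged `exceedance` when its
#' minimum falls below the aquatic-life water-quality standard.
#'
#' @param series_list List of [sonde_series()].
#' @param min_stations Minimum stations with a clear sag (default 3).
#' @param exceedance_standard Water-quality standard in mg/L (default 5.4).
#' @param prominence Detection prominence below baseline, mg/L (default 0.5).
#' @param min_duration_h Minimum below-threshold run length in hours
#'   (default 1).
#' @param group_window_h Maximum gap between consecutive station minima
#'   within one event, hours (default 48).
#' @return Data frame (event_id, station_id, distance_km, baseline_do,
#'   min_do, delta_do, t_min, exceedance); zero rows when nothing qualifies.
#' @export
detect_sag_events <- function(series_list, min_stations = 3,
                              exceedance_standard = 5.4,
                              prominence = 0.5, min_duration_h = 1,
                              group_window_h = 48) {
  stopifnot(length(series_list) >= min_stations)
  cands <- list()
  for (ser in series_list) {
    base <- stats::median(ser$do_mgl)
    below <- ser$do_mgl < (base - prominence)
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      dur <- as.numeric(difftime(ser$time[i1], ser$time[i0], units = "hours"))
      if (dur < min_duration_h) next
      imin <- i0 + which.min(ser$do_mgl[i0:i1]) - 1
      cands[[length(cands) + 1]] <- data.frame(
        station_id = ser$station_id, distance_km = ser$distance_km,
        baseline_do = base, min_do = ser$do_mgl[imin],
        delta_do = base - ser$do_mgl[imin],
        t_min = ser$time[imin], stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(event_id = integer(), station_id = character(),
                      distance_km = numeric(), baseline_do = numeric(),
                      min_do = numeric(), delta_do = numeric(),
                      t_min = as.POSIXct(character()), exceedance = logical(),
                      stringsAsFactors = FALSE)
  if (!length(cands)) return(empty)
  cand <- do.call(rbind, cands)
  cand <- cand[order(cand$t_min, cand$distance_km), , drop = FALSE]
  # group by time gaps between consecutive minima; a repeat station or a
  # too-large gap starts a new group (overlapping candidates merge into the
  # running group and the merge is messaged)
  gid <- integer(nrow(cand))
  gid[1] <- 1L
  seen <- cand$station_id[1]
  merged <- 0L
  for (i in seq_len(nrow(cand))[-1]) {
    gap <- as.numeric(difftime(cand$t_min[i], cand$t_min[i - 1], units = "hours"))
    if (gap <= group_window_h && !(cand$station_id[i] %in% seen)) {
      gid[i] <- gid[i - 1]
      seen <- c(seen, cand$station_id[i])
      if (gap <= 0) merged <- merged + 1L
    } else {
      gid[i] <- gid[i - 1] + 1L
      seen <- cand$station_id[i]
    }
  }
  if (merged > 0)
    message("detect_sag_events: merged ", merged,
            " overlapping candidate sag(s) into their running event window")
  cand$event_id <- gid
  keep <- vapply(split(seq_len(nrow(cand)), gid), function(idx) {
    g <- cand[idx, ]
    g <- g[order(g$distance_km), ]
    length(idx) >= min_stations && all(diff(as.numeric(g$t_min)) > 0)
  }, logical(1))
  cand <- cand[keep[as.character(gid)], , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand$event_id <- match(cand$event_id, unique(cand$event_id))
  cand$exceedance <- cand$min_do < exceedance_standard
  rownames(cand) <- NULL
  cand[order(cand$event_id, cand$distance_km),
       c("event_id", "station_id", "distance_km", "baseline_do", "min_do",
         "delta_do", "t_min", "exceedance")]
}

#' Sag magnitude within an event window
#'
#' The magnitude is the pre-sag baseline minus the minimum DO inside the
#' window; the baseline is the median of the `baseline_hours` of record
#' immediately preceding the window.
#'
#' @param series A [sonde_series()].
#' @param window POSIXct length-2 vector (event start, event end).
#' @param baseline_hours Pre-event baseline window length (default 24 h).
#' @return One-row data frame (station_id, distance_km, baseline_do, min_do,
#'   delta_do, t_min).
#' @export
sag_magnitude <- function(series, window, baseline_hours = 24) {
  stopifnot(inherits(series, "sonde_series"), length(window) == 2)
  pre <- series$time < window[1] &
    series$time >= window[1] - baseline_hours * 3600
  if (!any(pre)) stop("no samples in the pre-event baseline window")
  inw <- series$time >= window[1] & series$time <= window[2]
  if (!any(inw)) stop("no samples in the event window")
  base <- stats::median(series$do_mgl[pre])
  imin <- which(inw)[which.min(series$do_mgl[inw])]
  data.frame(station_id = series$station_id, distance_km = series$distance_km,
             baseline_do = base, min_do = series$do_mgl[imin],
             delta_do = base - series$do_mgl[imin], t_min = series$time[imin],
             stringsAsFactors = FALSE)
}

#' Fit the two-component exponential longitudinal decay
#'
#' Nonlinear least squares of sag magnitude versus downstream distance,
#' `delta(x) = a1 exp(-k1 x) + a2 exp(-k2 x)`, with all four parameters
#' bounded below by zero. Initialisation is multi-start (a log-linear
#' single-component start plus fast/slow component splits); among starts
#' whose residual sum of squares ties the best within 1e-10 relative, the
#' fit with the smallest secondary amplitude wins, and near-equal rates are
#' collapsed into component 1. A pure single-exponential model is available
#' via `model = "single"`.
#'
#' @param distance_km,delta_do Numeric vectors (n >= 5 for the two-component
#'   model, n >= 3 for single; distances must span > 0).
#' @param model "double" (default) or "single".
#' @return List of class `decay_fit`: a1, k1, a2, k2, r_squared, n_points,
#'   sse, degenerate flag, vcov (4x4, for parametric bootstrap), model.
#' @export
fit_decay <- function(distance_km, delta_do, model = c("double", "single")) {
  model <- match.arg(model)
  x <- as.numeric(distance_km); y <- as.numeric(delta_do)
  stopifnot(length(x) == length(y))
  need <- if (model == "double") 5 else 3
  if (length(x) < need) stop("fit_decay needs n >= ", need, " points")
  if (diff(range(x)) <= 0) stop("distances must span > 0")
  n <- length(x)

  if (stats::sd(y) < 1e-12) {
    # flat data: k1 = k2 = 0, amplitudes sum to the constant
    cvc <- matrix(0, 4, 4, dimnames = rep(list(c("a1", "k1", "a2", "k2")), 2))
    return(structure(list(a1 = mean(y), k1 = 0, a2 = 0, k2 = 0,
                          r_squared = NA_real_, n_points = n, sse = 0,
                          degenerate = TRUE, vcov = cvc, model = model),
                     class = "decay_fit"))
  }

  pred <- function(p) p[1] * exp(-p[2] * x) + p[3] * exp(-p[4] * x)
  sse <- function(p) sum((y - pred(p))^2)

  # log-linear start for a single component (positive y only)
  pos <- y > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(y[pos]) ~ x[pos])
    a0 <- exp(unname(stats::coef(lf)[1]))
    k0 <- max(0, -unname(stats::coef(lf)[2]))
  } else {
    a0 <- max(y); k0 <- 1 / max(x)
  }
  span <- diff(range(x))
  starts <- list(
    c(a0, k0, 0, 0),
    c(a0 / 2, k0 / 2, a0 / 2, min(2 * k0 + 1 / span, 0.5)),
    c(max(y), 1 / span, max(y) / 4, 5 / span),
    c(max(y) / 2, 0.5 / span, max(y) / 2, 2 / span))
  if (model == "single") starts <- lapply(starts, function(s) c(s[1:2], 0, 0))

  best <- NULL
  fits <- list()
  for (st in starts) {
    par0 <- if (model == "double") st else st[1:2]
    obj <- if (model == "double") sse else function(p) sse(c(p, 0, 0))
    opt <- try(stats::optim(par0, obj, method = "L-BFGS-B",
                            lower = rep(0, length(par0)),
                            upper = c(Inf, Inf, Inf, Inf)[seq_along(par0)],
                            control = list(maxit = 500, factr = 1e4)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    p <- if (model == "double") opt$par else c(opt$par, 0, 0)
    fits[[length(fits) + 1]] <- list(par = p, sse = opt$value)
  }
  if (!length(fits)) stop("fit_decay: no start converged")
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  smin <- min(sses)
  tied <- which(sses <= smin * (1 + 1e-10) + 1e-18)
  # among ties prefer the smallest secondary amplitude (cleanest model)
  a2s <- vapply(fits[tied], function(f) min(f$par[1], f$par[3]), numeric(1))
  p <- fits[[tied[which.min(a2s)]]]$par

  # canonical order: component 1 is the slower-decaying (smaller k)
  if (p[3] > 0 && (p[1] == 0 || p[4] < p[2])) p <- p[c(3, 4, 1, 2)]
  # collapse near-equal rates or negligible second amplitude
  if (p[3] > 0 && (abs(p[2] - p[4]) <= 1e-6 * max(p[2], p[4], 1e-12))) {
    p <- c(p[1] + p[3], p[2], 0, 0)
  }
  if (p[3] <= 1e-10 * max(p[1], 1)) p[3:4] <- 0

  fitted_sse <- sse(p)
  r2 <- 1 - fitted_sse / sum((y - mean(y))^2)
  active <- if (model == "double" && p[3] > 0) 1:4 else 1:2
  vc <- decay_vcov(p, x, y, active)
  degenerate <- (p[2] == 0 && p[4] == 0)
  structure(list(a1 = p[1], k1 = p[2], a2 = p[3], k2 = p[4],
                 r_squared = r2, n_points = n, sse = fitted_sse,
                 degenerate = degenerate, vcov = vc, model = model),
            class = "decay_fit")
}

# Gauss-Newton covariance sigma^2 (J'J)^-1 over the active parameters,
# embedded in a 4x4 matrix (zeros elsewhere)
decay_vcov <- function(p, x, y, active) {
  nm <- c("a1", "k1", "a2", "k2")
  vc <- matrix(0, 4, 4, dimnames = list(nm, nm))
  n <- length(x)
  dof <- n - length(active)
  if (dof <= 0) return(vc)
  J <- cbind(exp(-p[2] * x), -p[1] * x * exp(-p[2] * x),
             exp(-p[4] * x), -p[3] * x * exp(-p[4] * x))[, active, drop = FALSE]
  res <- y - (p[1] * exp(-p[2] * x) + p[3] * exp(-p[4] * x))
  s2 <- sum(res^2) / dof
  jtj <- crossprod(J)
  inv <- try(solve(jtj), silent = TRUE)
  if (inherits(inv, "try-error")) inv <- MASS::ginv(jtj)
  vc[active, active] <- s2 * inv
  (vc + t(vc)) / 2
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit %s> delta(x) = %.4g e^(-%.4g x) + %.4g e^(-%.4g x), R^2 = %.3f, n = %d%s\n",
              x$model, x$a1, x$k1, x$a2, x$k2, x$r_squared, x$n_points,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Predicted sag magnitude at distance x
#' @param fit A `decay_fit`.
#' @param x Distance(s) in km.
#' @return Predicted delta-DO, mg/L.
#' @export
predict_decay <- function(fit, x) {
  fit$a1 * exp(-fit$k1 * x) + fit$a2 * exp(-fit$k2 * x)
}

#' Downstream extent of impact: threshold-crossing distance
#'
#' Solves `delta(x) = threshold` by bisection to 1e-6 km; the decay is
#' strictly decreasing whenever a rate is positive, so the root is unique.
#' Returns 0 (flagged by a warning) when the source magnitude is already at
#' or below the threshold.
#'
#' @param fit A `decay_fit`.
#' @param threshold Impact threshold in mg/L (default 0.5).
#' @return Extent in km with attribute `flagged` when 0.
#' @export
solve_extent <- function(fit, threshold = 0.5) {
  stopifnot(threshold > 0)
  d0 <- predict_decay(fit, 0)
  if (d0 <= threshold) {
    warning("source magnitude ", signif(d0, 4),
            " mg/L does not exceed the threshold; extent 0")
    return(structure(0, flagged = TRUE))
  }
  if (fit$degenerate || (fit$k1 == 0 && fit$k2 == 0))
    stop("degenerate fit (k1 = k2 = 0): extent unbounded")
  floor_val <- fit$a1 * (fit$k1 == 0) + fit$a2 * (fit$k2 == 0)
  if (floor_val >= threshold) {
    warning("non-decaying component at/above the threshold; extent unbounded")
    return(structure(Inf, flagged = TRUE))
  }
  hi <- 1
  while (predict_decay(fit, hi) > threshold) hi <- hi * 2
  lo <- 0
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (predict_decay(fit, mid) > threshold) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Horton's-law longitudinal extent for a given top stream order
#'
#' Geometric series of mean stream lengths for an in-series path from order
#' 1 up to order `omega`: `sum_{i=1..omega} L1 * R_L^(i-1)`, which for
#' R_L != 1 equals `L1 (1 - R_L^omega) / (1 - R_L)`; the R_L = 1 limit is
#' `omega * L1`.
#'
#' @param params A [horton_params()] (uses `mean_l1` and `r_l`).
#' @param omega Top Strahler order reached, integer >= 1.
#' @return Extent in km.
#' @export
horton_sl_le <- function(params, omega) {
  stopifnot(inherits(params, "horton_params"), omega >= 1)
  l1 <- params$mean_l1; rl <- params$r_l
  if (abs(rl - 1) < 1e-12) return(omega * l1)
  l1 * (1 - rl^omega) / (1 - rl)
}

#' Invert the Horton extent model for the stream order reached
#'
#' Solves the geometric series for omega and rounds to the nearest integer:
#' `omega = round(log(1 + sl_le (R_L - 1) / L1) / log(R_L))` for R_L != 1,
#' `round(sl_le / L1)` at R_L = 1.
#'
#' @param sl_le_km Longitudinal extent in km; must be >= `mean_l1`.
#' @param params A [horton_params()].
#' @return Integer Strahler order >= 1.
#' @export
horton_invert <- function(sl_le_km, params) {
  stopifnot(inherits(params, "horton_params"))
  l1 <- params$mean_l1; rl <- params$r_l
  if (sl_le_km < l1) stop("sl_le_km must be >= mean first-order length")
  omega <- if (abs(rl - 1) < 1e-12) sl_le_km / l1
           else log(1 + sl_le_km * (rl - 1) / l1) / log(rl)
  max(1L, as.integer(round(omega)))
}

#' One-call SL_LE estimate from fitted decay and Horton parameters
#'
#' @param fit A `decay_fit`.
#' @param params A [horton_params()].
#' @param threshold Impact threshold, mg/L.
#' @return List of class `propagation_estimate`: sl_le_km, threshold_mgl,
#'   reached_order.
#' @export
estimate_propagation <- function(fit, params, threshold = 0.5) {
  ext <- solve_extent(fit, threshold)
  ord <- if (ext >= params$mean_l1) horton_invert(as.numeric(ext), params) else 1L
  structure(list(sl_le_km = as.numeric(ext), threshold_mgl = threshold,
                 reached_order = ord),
            class = "propagation_estimate")
}
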