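# Reporting: combine SL_BA and SL_LE under the conservative upscaling
# SL_LE ~ SL_BA, propagate fit uncertainty to the combined percentages, and
# assemble machine-readable run summaries.

#' Upscale per-ecoregion SL_BA with the SL_LE ~ SL_BA assumption
#'
#' Sets each ecoregion's longitudinal extent equal to its burned-length
#' total, so the combined impacted length is exactly twice SL_BA, and
#' expresses it as a percentage of the region's total stream + river length.
#'
#' @param slba_km Named numeric vector: per-ecoregion SL_BA totals (km).
#' @param network_km Named numeric vector: per-ecoregion total stream +
#'   river length (km); names must cover `names(slba_km)`.
#' @param multiplier SL_LE : SL_BA multiplier (default 1).
#' @return Data frame of class `upscaled_summary` (ecoregion, sl_ba_km,
#'   sl_le_km, total_km, network_km, pct_of_network) plus a "study" total
#'   row.
#' @export
upscale <- function(slba_km, network_km, multiplier = 1) {
  stopifnot(!is.null(names(slba_km)), all(names(slba_km) %in% names(network_km)),
            multiplier >= 0, all(slba_km >= 0), all(network_km > 0))
  regions <- names(slba_km)
  sl_le <- multiplier * slba_km
  total <- slba_km + sl_le
  net <- network_km[regions]
  out <- data.frame(ecoregion = c(regions, "study"),
                    sl_ba_km = c(slba_km, sum(slba_km)),
                    sl_le_km = c(sl_le, sum(sl_le)),
                    total_km = c(total, sum(total)),
                    network_km = c(net, sum(net)),
                    stringsAsFactors = FALSE)
  out$pct_of_network <- 100 * out$total_km / out$network_km
  rownames(out) <- NULL
  class(out) <- c("upscaled_summary", "data.frame")
  out
}

#' Bootstrap 95% CI on the SL_LE : SL_BA multiplier and combined percentages
#'
#' Parametric bootstrap: decay-fit parameters are drawn from a multivariate
#' normal with the fit's covariance (negative draws truncated at 0), the
#' threshold-crossing extent is re-solved per draw, and the draw's
#' multiplier is its extent relative to the point-estimate extent. The
#' multiplier CI propagates multiplicatively to per-ecoregion combined
#' lengths and percentages.
#'
#' @param fit A `decay_fit` with covariance.
#' @param summary An `upscaled_summary` from [upscale()].
#' @param threshold Impact threshold, mg/L.
#' @param n_draws Bootstrap draws (default 1000).
#' @param seed RNG seed.
#' @param level Confidence level (default 0.95).
#' @return List: `multiplier_ci` (low, high), and `summary` with added
#'   ci95_low / ci95_high percentage columns.
#' @export
upscale_ci <- function(fit, summary, threshold = 0.5, n_draws = 1000,
                       seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "decay_fit"), inherits(summary, "upscaled_summary"))
  set.seed(seed)
  p_hat <- c(fit$a1, fit$k1, fit$a2, fit$k2)
  ext_hat <- as.numeric(solve_extent(fit, threshold))
  if (ext_hat <= 0) stop("point-estimate extent is 0; CI undefined")
  active <- which(diag(fit$vcov) > 0)
  mult <- rep(1, n_draws)
  if (length(active)) {
    draws <- MASS::mvrnorm(n_draws, mu = p_hat[active],
                           Sigma = fit$vcov[active, active, drop = FALSE])
    draws <- pmax(draws, 0)
    for (b in seq_len(n_draws)) {
      p <- p_hat
      p[active] <- draws[b, ]
      f <- fit
      f$a1 <- p[1]; f$k1 <- p[2]; f$a2 <- p[3]; f$k2 <- p[4]
      f$degenerate <- (p[2] == 0 && p[4] == 0)
      ext <- if (predict_decay(f, 0) <= threshold) 0
             else if (f$degenerate) Inf
             else as.numeric(suppressWarnings(solve_extent(f, threshold)))
      mult[b] <- ext / ext_hat
    }
  }
  a <- (1 - level) / 2
  ci <- stats::quantile(mult, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  out <- summary
  out$ci95_low <- 100 * out$sl_ba_km * (1 + ci[1]) / out$network_km
  out$ci95_high <- 100 * out$sl_ba_km * (1 + ci[2]) / out$network_km
  list(multiplier_ci = ci, summary = out)
}

#' Assemble the pipeline report
#'
#' Collects module outputs into one machine-readable structure: per-fire
#' records, annual summaries, trend and regression results, decay fit,
#' propagation estimate, and the upscaled percent-of-network table, together
#' with provenance (seed, config echo, package version). The Clean Water
#' Assessment impairment ranking is included only when an external CWA
#' source table is supplied.
#'
#' @param fire_impacts Data frame from [compute_fire_impacts()] (optional).
#' @param annual Data frame from [aggregate_annual()] (optional).
#' @param trend A `trend_result` (optional).
#' @param regression A `regression_result` (optional).
#' @param fit A `decay_fit` (optional).
#' @param propagation A `propagation_estimate` (optional).
#' @param upscaled An `upscaled_summary` (optional).
#' @param seed Seed used for the run (provenance echo).
#' @param config Arbitrary config list to echo.
#' @param cwa_table Optional data frame (source, impaired_km) of impairment
#'   sources; when given, the combined wildfire total is ranked against it.
#' @return List of class `fluvialfire_report`; serialise with
#'   [write_report_json()].
#' @export
report <- function(fire_impacts = NULL, annual = NULL, trend = NULL,
                   regression = NULL, fit = NULL, propagation = NULL,
                   upscaled = NULL, seed = NULL, config = list(),
                   cwa_table = NULL) {
  totals <- list(
    n_fires = if (!is.null(fire_impacts)) nrow(fire_impacts) else 0L,
    sl_ba_km = if (!is.null(fire_impacts)) sum(fire_impacts$sl_ba_km) else 0,
    burned_area_km2 = if (!is.null(fire_impacts))
      sum(fire_impacts$burned_area_km2) else 0)
  rep_ <- list(
    provenance = list(package = "fluvialfire",
                      version = as.character(utils::packageVersion("fluvialfire")),
                      seed = seed, config = config,
                      r_version = R.version.string),
    totals = totals,
    fire_impacts = fire_impacts, annual = annual,
    trend = if (!is.null(trend)) unclass(trend),
    regression = if (!is.null(regression)) unclass(regression),
    decay_fit = if (!is.null(fit))
      list(a1 = fit$a1, k1 = fit$k1, a2 = fit$a2, k2 = fit$k2,
           r_squared = fit$r_squared, n_points = fit$n_points),
    propagation = if (!is.null(propagation)) unclass(propagation),
    upscaled = upscaled)
  if (!is.null(cwa_table) && !is.null(upscaled)) {
    comb <- upscaled$total_km[upscaled$ecoregion == "study"]
    rank <- 1 + sum(cwa_table$impaired_km > comb)
    rep_$cwa_rank <- list(combined_km = comb, rank = rank,
                          n_sources = nrow(cwa_table) + 1)
  }
  structure(rep_, class = "fluvialfire_report")
}

#' Write a report as JSON
#' @param rep A `fluvialfire_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(rep, path) {
  jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", POSIXt = "ISO8601",
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @export
print.fluvialfire_report <- function(x, ...) {
  cat("<fluvialfire_report>\n")
  cat("  fires:", x$totals$n_fires,
      " SL_BA:", round(x$totals$sl_ba_km, 1), "km",
      " burned:", round(x$totals$burned_area_km2, 1), "km^2\n")
  if (!is.null(x$trend))
    cat(sprintf("  trend: %.3g km/yr (MK p = %.3g, %s)\n", x$trend$slope,
                x$trend$p_value, significance_tier(x$trend$p_value)))
  if (!is.null(x$propagation))
    cat(sprintf("  SL_LE: %.1f km to order %d (threshold %.2g mg/L)\n",
                x$propagation$sl_le_km, x$propagation$reached_order,
                x$propagation$threshold_mgl))
  if (!is.null(x$upscaled)) {
    st <- x$upscaled[x$upscaled$ecoregion == "study", ]
    cat(sprintf("  combined: %.1f km = %.1f%% of network\n",
                st$total_km, st$pct_of_network))
  }
  invisible(x)
}
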