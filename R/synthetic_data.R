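# Seeded synthetic-input generators: Horton-law stream networks, burn scars
# with severity patches, ecoregion partitions, and multi-station DO series.

#' Generate a synthetic stream network obeying Horton's laws
#'
#' Builds a Strahler-ordered tree top-down: the single stream of order
#' `max_order` drains to the region edge, and every stream of order w > 1 is
#' formed by the junction of its tributaries of order w - 1 at its upstream
#' end. Tributary counts are `max(2, round(r_b))` in the deterministic regime
#' (`length_cv = 0`) and `max(2, rpois(1, r_b))` otherwise; at least two
#' equal-order tributaries are required for the Strahler order to increment,
#' so assigned orders always equal recomputed orders. Stream lengths are
#' `mean_l1 * r_l^(w-1)` exactly when `length_cv = 0`, otherwise lognormal
#' with that mean and CV `length_cv`. Geometry is piecewise linear with
#' bearing jitter inside nested angular wedges; embeddings with segment
#' crossings or vertices outside `region` are rejection-sampled.
#'
#' @param params A [horton_params()] object.
#' @param region Bounding box `c(xmin, xmax, ymin, ymax)` in km, or NULL to
#'   auto-size a box that comfortably embeds the tree.
#' @param seed Integer RNG seed.
#' @param max_attempts Embedding retries before declaring the region
#'   infeasible.
#' @return A [stream_network()].
#' @export
generate_network <- function(params, region = NULL, seed = 1,
                             max_attempts = 60) {
  stopifnot(inherits(params, "horton_params"))
  set.seed(seed)
  # mainstem extent: sum of mean lengths root..leaf, with slack for jitter
  extent <- params$mean_l1 * sum(params$r_l^(seq_len(params$max_order) - 1))
  if (is.null(region)) {
    half <- 1.6 * extent * (1 + 2 * params$length_cv) + params$mean_l1
    region <- c(-half, half, 0, 2 * half)
  }
  deterministic <- params$length_cv == 0
  sdlog <- sqrt(log(1 + params$length_cv^2))
  draw_len <- function(order) {
    mu <- params$mean_l1 * params$r_l^(order - 1)
    if (deterministic) mu
    else stats::rlnorm(1, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  }
  draw_ntrib <- function() {
    if (deterministic) max(2L, as.integer(round(params$r_b)))
    else max(2L, stats::rpois(1, params$r_b))
  }
  jitter_sd <- if (deterministic) 0 else 6 * pi / 180

  root_mouth <- c((region[1] + region[2]) / 2, region[3] + 0.02 * (region[4] - region[3]))

  for (attempt in seq_len(max_attempts)) {
    segs <- list()
    nid <- 0L
    ok <- TRUE
    # recursive embed: stream of `order` from `mouth` within wedge [a1, a2]
    embed <- function(order, mouth, wedge, parent_id) {
      nid <<- nid + 1L
      id <- sprintf("s%04d", nid)
      len <- draw_len(order)
      bearing <- mean(wedge)
      npiece <- max(2L, min(6L, order + 1L))
      step <- len / npiece
      pts <- matrix(NA_real_, npiece + 1, 2)
      pts[1, ] <- mouth
      b <- bearing
      for (i in seq_len(npiece)) {
        if (jitter_sd > 0) {
          b <- b + stats::rnorm(1, 0, jitter_sd)
          b <- min(max(b, wedge[1]), wedge[2])
        }
        pts[i + 1, ] <- pts[i, ] + step * c(cos(b), sin(b))
      }
      if (any(pts[, 1] < region[1] | pts[, 1] > region[2] |
              pts[, 2] < region[3] | pts[, 2] > region[4])) {
        ok <<- FALSE
        return(invisible(NULL))
      }
      segs[[length(segs) + 1L]] <<- list(
        segment_id = id, parent_id = parent_id,
        strahler_order = as.integer(order), coords = cbind(x = pts[, 1], y = pts[, 2]))
      if (order > 1 && ok) {
        ntrib <- draw_ntrib()
        tip <- pts[npiece + 1, ]
        span <- wedge[2] - wedge[1]
        edges <- seq(wedge[1], wedge[2], length.out = ntrib + 1)
        for (k in seq_len(ntrib)) {
          if (!ok) break
          sub <- c(edges[k] + 0.12 * span / ntrib, edges[k + 1] - 0.12 * span / ntrib)
          embed(order - 1, tip, sub, id)
        }
      }
      invisible(NULL)
    }
    spread <- 100 * pi / 180
    embed(params$max_order, root_mouth,
          c(pi / 2 - spread / 2, pi / 2 + spread / 2), NA_character_)
    if (!ok) next
    if (network_self_intersects(segs)) next
    net <- stream_network(segs, region)
    return(net)
  }
  stop("infeasible embedding: could not place the network inside the region ",
       "after ", max_attempts, " attempts (region too small?)")
}

# any improper crossing between segments that do not share a junction vertex
network_self_intersects <- function(segs) {
  n <- length(segs)
  if (n < 2) return(FALSE)
  bbox <- t(vapply(segs, function(s) c(range(s$coords[, 1]), range(s$coords[, 2])),
                   numeric(4)))
  for (i in seq_len(n - 1)) {
    ci <- segs[[i]]$coords
    for (j in (i + 1):n) {
      if (bbox[i, 2] < bbox[j, 1] || bbox[j, 2] < bbox[i, 1] ||
          bbox[i, 4] < bbox[j, 3] || bbox[j, 4] < bbox[i, 3]) next
      cj <- segs[[j]]$coords
      shared <- c(segs[[i]]$parent_id %in% segs[[j]]$segment_id,
                  segs[[j]]$parent_id %in% segs[[i]]$segment_id,
                  identical(segs[[i]]$parent_id, segs[[j]]$parent_id))
      for (a in seq_len(nrow(ci) - 1)) {
        for (b in seq_len(nrow(cj) - 1)) {
          p1 <- ci[a, ]; p2 <- ci[a + 1, ]; p3 <- cj[b, ]; p4 <- cj[b + 1, ]
          if (any(shared)) {
            # ignore contact at a shared junction endpoint
            if (max(abs(p1 - p3)) < 1e-12 || max(abs(p1 - p4)) < 1e-12 ||
                max(abs(p2 - p3)) < 1e-12 || max(abs(p2 - p4)) < 1e-12) next
          }
          if (segments_intersect(p1, p2, p3, p4)) return(TRUE)
        }
      }
    }
  }
  FALSE
}

#' Generate synthetic burn scars
#'
#' Fire areas are lognormal, perimeters are random convex polygons scaled to
#' the drawn area, and severity patches split each perimeter into convex
#' pieces whose areas realise `severity_fractions` exactly (so patch areas
#' partition the perimeter area). Fire years are uniform over `year_range`.
#'
#' @param region Bounding box `c(xmin, xmax, ymin, ymax)` (km); scars are
#'   placed with their centres inside it.
#' @param spec A [burn_gen_spec()].
#' @param seed Integer RNG seed.
#' @return List of [burn_scar()] objects.
#' @export
generate_burn_scars <- function(region, spec, seed = 1) {
  stopifnot(inherits(spec, "burn_gen_spec"))
  set.seed(seed)
  out <- vector("list", spec$n_fires)
  if (spec$n_fires == 0) return(out)
  for (i in seq_len(spec$n_fires)) {
    area <- stats::rlnorm(1, spec$area_log_mean, spec$area_log_sd)
    rad <- sqrt(area / pi) * 1.6
    cx <- stats::runif(1, region[1] + rad, region[2] - rad)
    cy <- stats::runif(1, region[3] + rad, region[4] - rad)
    if (!is.finite(cx) || !is.finite(cy) || region[1] + rad > region[2] - rad) {
      # scar larger than region: centre it
      cx <- (region[1] + region[2]) / 2; cy <- (region[3] + region[4]) / 2
    }
    perim <- random_convex_polygon(c(cx, cy), area)
    pieces <- split_polygon_by_fractions(perim, spec$severity_fractions)
    names(pieces) <- names(spec$severity_fractions)
    year <- if (spec$year_range[1] == spec$year_range[2]) spec$year_range[1]
            else sample(seq(spec$year_range[1], spec$year_range[2]), 1)
    out[[i]] <- burn_scar(sprintf("fire%04d", i), year, perim, pieces)
  }
  out
}

#' Generate a synthetic ecoregion partition
#'
#' Recursive rectangular splits: the largest rectangle is repeatedly split
#' along its longer side at a random position, yielding `n_regions`
#' rectangles that partition `region` exactly. Regions are named "E01",
#' "E02", ... in a deterministic order.
#'
#' @param region Bounding box `c(xmin, xmax, ymin, ymax)` (km).
#' @param n_regions Number of regions, >= 1.
#' @param seed Integer RNG seed.
#' @return An [ecoregion_map()].
#' @export
generate_ecoregions <- function(region, n_regions, seed = 1) {
  if (n_regions < 1) stop("n_regions must be >= 1")
  set.seed(seed)
  rects <- list(region)
  while (length(rects) < n_regions) {
    areas <- vapply(rects, function(r) (r[2] - r[1]) * (r[4] - r[3]), numeric(1))
    i <- which.max(areas)
    r <- rects[[i]]
    f <- stats::runif(1, 0.35, 0.65)
    if ((r[2] - r[1]) >= (r[4] - r[3])) {
      cut <- r[1] + f * (r[2] - r[1])
      new <- list(c(r[1], cut, r[3], r[4]), c(cut, r[2], r[3], r[4]))
    } else {
      cut <- r[3] + f * (r[4] - r[3])
      new <- list(c(r[1], r[2], r[3], cut), c(r[1], r[2], cut, r[4]))
    }
    rects <- c(rects[-i], new)
  }
  polys <- lapply(rects, function(r) rect_polygon(r[1], r[2], r[3], r[4]))
  names(polys) <- sprintf("E%02d", seq_along(polys))
  ecoregion_map(polys, region)
}

#' Generate multi-station dissolved-oxygen sonde series
#'
#' Each event injects a sag pulse at every station. The pulse reaches the
#' station `distance / celerity` hours after the event starts, ramps down
#' over 2 h, holds its minimum for a 2 h plateau, and recovers over 4 h; the
#' sag depth at distance x is `a1*exp(-k1*x) + a2*exp(-k2*x)`. With
#' `noise_sd = 0` the minimum DO at a station therefore equals
#' `baseline_do - depth(x)` exactly, and times of minimum increase strictly
#' with distance. Values are clipped at 0 mg/L (anoxia); the number of
#' clipped samples is attached as attribute `n_clipped` and messaged.
#'
#' @param spec A [do_sag_spec()].
#' @param seed Integer RNG seed.
#' @param pad_hours Hours of record kept before the first and after the last
#'   event (length-2 vector).
#' @return List of [sonde_series()], one per station, with attribute
#'   `n_clipped`.
#' @export
generate_do_series <- function(spec, seed = 1, pad_hours = c(48, 72)) {
  stopifnot(inherits(spec, "do_sag_spec"))
  set.seed(seed)
  co <- spec$components
  t0 <- min(spec$event_times) - pad_hours[1] * 3600
  max_lag <- max(spec$station_distances) / spec$celerity
  t1 <- max(spec$event_times) + (max_lag + pad_hours[2]) * 3600
  times <- seq(t0, t1, by = spec$sample_interval * 60)
  pulse <- function(u) {  # u in hours since arrival; peak value 1 on [2,4]
    ifelse(u < 0, 0,
    ifelse(u < 2, u / 2,
    ifelse(u < 4, 1,
    ifelse(u < 8, (8 - u) / 4, 0))))
  }
  n_clipped <- 0L
  out <- vector("list", length(spec$station_distances))
  for (s in seq_along(spec$station_distances)) {
    x <- spec$station_distances[s]
    depth <- co["a1"] * exp(-co["k1"] * x) + co["a2"] * exp(-co["k2"] * x)
    do <- rep(spec$baseline_do, length(times))
    for (ev in spec$event_times) {
      u <- as.numeric(difftime(times, ev, units = "hours")) - x / spec$celerity
      do <- do - depth * pulse(u)
    }
    if (spec$noise_sd > 0) do <- do + stats::rnorm(length(do), 0, spec$noise_sd)
    clip <- do < 0
    n_clipped <- n_clipped + sum(clip)
    do[clip] <- 0
    out[[s]] <- sonde_series(sprintf("S%d", s), x, times, do)
  }
  if (n_clipped > 0)
    message("generate_do_series: clipped ", n_clipped, " samples at 0 mg/L (anoxia)")
  attr(out, "n_clipped") <- n_clipped
  out
}
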