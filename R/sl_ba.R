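# SL_BA: stream + river length impacted within burned areas.
#
# Pipeline per fire: severity filter -> footprint area -> minimum-area filter
# -> clip network length -> assign ecoregion; then annual / ecoregion
# aggregation and the drainage-density comparison table.

#' Severity-filter a burn scar to its burned footprint
#'
#' Keeps only the low, moderate, and high severity patches, dropping areas
#' coded unburned, increased greenness, or masked. The result is the burned
#' footprint used for area and stream-length accounting.
#'
#' @param scar A [burn_scar()].
#' @return Multipolygon (list of disjoint convex polygon matrices); empty
#'   list when no patch has a retained class.
#' @export
severity_filter <- function(scar) {
  stopifnot(inherits(scar, "burn_scar"))
  keep <- scar$severity_patches[retained_severity_classes()]
  Filter(Negate(is.null), keep)
}

#' Remove fires below the minimum burned-area threshold
#'
#' Fires burning less than the threshold (default ~4.1 km^2) are removed;
#' fires at exactly the threshold are retained. Input order is preserved.
#'
#' @param records Data frame with a `burned_area_km2` column (e.g. from
#'   [compute_fire_impacts()] with `min_area = 0`).
#' @param threshold_km2 Minimum burned area in km^2, >= 0.
#' @return The filtered data frame.
#' @export
apply_min_area_filter <- function(records, threshold_km2 = 4.1) {
  if (threshold_km2 < 0) stop("threshold_km2 must be >= 0")
  records[records$burned_area_km2 >= threshold_km2, , drop = FALSE]
}

#' Stream length inside a burned footprint
#'
#' Clips every network segment against the footprint polygon and sums the
#' in-polygon length. Additive over disjoint footprint pieces; the
#' whole-region polygon returns the full network length.
#'
#' @param network A [stream_network()].
#' @param footprint Simple polygon matrix or multipolygon list of disjoint
#'   pieces.
#' @return Clipped length in km.
#' @export
clip_length <- function(network, footprint) {
  stopifnot(inherits(network, "stream_network"))
  if (is.null(footprint) || (is.list(footprint) && length(footprint) == 0))
    return(0)
  pieces <- if (is.list(footprint)) footprint else list(footprint)
  for (p in pieces) {
    if (!is_simple_polygon(p))
      stop("invalid footprint: self-intersecting polygon ring (",
           nrow(p), " vertices)")
  }
  # bbox prefilter per piece
  pb <- t(vapply(pieces, function(p) c(range(p[, 1]), range(p[, 2])), numeric(4)))
  total <- 0
  for (s in network$segments) {
    cr <- c(range(s$coords[, 1]), range(s$coords[, 2]))
    for (k in seq_along(pieces)) {
      if (cr[2] < pb[k, 1] || cr[1] > pb[k, 2] ||
          cr[4] < pb[k, 3] || cr[3] > pb[k, 4]) next
      total <- total + polyline_length_in_polygon(s$coords, pieces[[k]])
    }
  }
  total
}

#' Assign a fire to the ecoregion holding most of its burned footprint
#'
#' Ecoregion assignment is by largest intersected burned area so each fire
#' id maps to a single ecoregion; exact ties break lexicographically by
#' region name. A footprint intersecting no region returns "unassigned".
#'
#' @param footprint Polygon matrix or multipolygon list.
#' @param map An [ecoregion_map()] (regions must be convex; the generator's
#'   rectangles are).
#' @return Ecoregion name, or "unassigned".
#' @export
assign_ecoregion <- function(footprint, map) {
  stopifnot(inherits(map, "ecoregion_map"))
  areas <- vapply(map$polygons, function(rp)
    intersection_area_convex(footprint, rp), numeric(1))
  if (all(areas <= 1e-12)) return("unassigned")
  best <- max(areas)
  cands <- sort(names(areas)[areas >= best - 1e-9])
  cands[1]
}

#' Fraction of burned area attributed to a different ecoregion
#'
#' For each ecoregion: of the burned-footprint area physically inside it,
#' the fraction belonging to fires whose single assigned ecoregion is a
#' different one.
#'
#' @param records Data frame from [compute_fire_impacts()] (needs fire_id,
#'   ecoregion).
#' @param scars The list of [burn_scar()] objects the records came from.
#' @param map An [ecoregion_map()].
#' @return Data frame (ecoregion, burned_area_km2, misattributed_km2,
#'   fraction) with fraction in [0, 1] (NA where no burned area).
#' @export
misattribution_fraction <- function(records, scars, map) {
  scar_ids <- vapply(scars, function(s) s$fire_id, character(1))
  regions <- names(map$polygons)
  inside <- stats::setNames(numeric(length(regions)), regions)
  mis <- inside
  for (i in seq_len(nrow(records))) {
    scar <- scars[[match(records$fire_id[i], scar_ids)]]
    fp <- severity_filter(scar)
    for (rg in regions) {
      a <- intersection_area_convex(fp, map$polygons[[rg]])
      inside[rg] <- inside[rg] + a
      if (records$ecoregion[i] != rg) mis[rg] <- mis[rg] + a
    }
  }
  data.frame(ecoregion = regions,
             burned_area_km2 = unname(inside),
             misattributed_km2 = unname(mis),
             fraction = unname(ifelse(inside > 0, mis / inside, NA_real_)),
             stringsAsFactors = FALSE)
}

#' Compute per-fire impact records
#'
#' Runs the full SL_BA pipeline: severity filter, burned-area computation,
#' minimum-area filter, stream-length clipping, ecoregion assignment.
#'
#' @param network A [stream_network()].
#' @param scars List of [burn_scar()] objects.
#' @param map An [ecoregion_map()].
#' @param min_area Minimum burned area in km^2 (default 4.1); fires below it
#'   are dropped.
#' @param area_basis "footprint" (default) reports the severity-filtered
#'   footprint area per fire; "perimeter" reports the raw perimeter area.
#'   Filtering and clipping always use the footprint.
#' @return Data frame (fire_id, year, ecoregion, burned_area_km2, sl_ba_km).
#' @export
compute_fire_impacts <- function(network, scars, map, min_area = 4.1,
                                 area_basis = c("footprint", "perimeter")) {
  area_basis <- match.arg(area_basis)
  rows <- lapply(scars, function(scar) {
    fp <- severity_filter(scar)
    fp_area <- polygon_area(fp)
    area <- if (area_basis == "footprint") fp_area else polygon_area(scar$perimeter)
    data.frame(fire_id = scar$fire_id, year = scar$year,
               ecoregion = if (fp_area > 0) assign_ecoregion(fp, map) else "unassigned",
               burned_area_km2 = area,
               sl_ba_km = NA_real_, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  if (is.null(records))
    return(data.frame(fire_id = character(), year = integer(),
                      ecoregion = character(), burned_area_km2 = numeric(),
                      sl_ba_km = numeric(), stringsAsFactors = FALSE))
  records <- apply_min_area_filter(records, min_area)
  scar_ids <- vapply(scars, function(s) s$fire_id, character(1))
  records$sl_ba_km <- vapply(records$fire_id, function(id)
    clip_length(network, severity_filter(scars[[match(id, scar_ids)]])),
    numeric(1))
  rownames(records) <- NULL
  records
}

#' Aggregate fire impacts by year and ecoregion
#'
#' Produces the full year x ecoregion grid: combinations with no retained
#' fires appear as explicit zero rows flagged `no_fires = TRUE` (the "gray
#' squares").
#'
#' @param records Data frame from [compute_fire_impacts()].
#' @param years Optional integer vector of years for the grid (default:
#'   observed range).
#' @param ecoregions Optional character vector of region names (default:
#'   observed).
#' @return Data frame (year, ecoregion, burned_area_km2, sl_ba_km, n_fires,
#'   no_fires).
#' @export
aggregate_annual <- function(records, years = NULL, ecoregions = NULL) {
  if (is.null(years)) {
    years <- if (nrow(records)) seq(min(records$year), max(records$year)) else integer()
  }
  if (is.null(ecoregions)) ecoregions <- sort(unique(records$ecoregion))
  grid <- expand.grid(year = years, ecoregion = ecoregions,
                      stringsAsFactors = FALSE)
  if (nrow(records)) {
    key <- paste(records$year, records$ecoregion)
    ba <- tapply(records$burned_area_km2, key, sum)
    sl <- tapply(records$sl_ba_km, key, sum)
    nf <- tapply(records$fire_id, key, length)
    gk <- paste(grid$year, grid$ecoregion)
    grid$burned_area_km2 <- unname(ifelse(gk %in% names(ba), ba[gk], 0))
    grid$sl_ba_km <- unname(ifelse(gk %in% names(sl), sl[gk], 0))
    grid$n_fires <- unname(ifelse(gk %in% names(nf), nf[gk], 0L))
  } else {
    grid$burned_area_km2 <- numeric(nrow(grid))
    grid$sl_ba_km <- numeric(nrow(grid))
    grid$n_fires <- integer(nrow(grid))
  }
  grid$no_fires <- grid$n_fires == 0
  grid[order(grid$year, grid$ecoregion), , drop = FALSE]
}

#' Per-ecoregion drainage density versus burn-impact ratio
#'
#' Compares each region's drainage density (total stream length / region
#' area, km/km^2) with its SL_BA : burned-area ratio. Regions with no burned
#' area get an NA ratio.
#'
#' @param map An [ecoregion_map()].
#' @param network A [stream_network()].
#' @param annual Data frame from [aggregate_annual()].
#' @return Data frame (ecoregion, drainage_density, slba_ba_ratio).
#' @export
drainage_ratio_table <- function(map, network, annual) {
  regions <- names(map$polygons)
  dens <- vapply(regions, function(rg) {
    poly <- map$polygons[[rg]]
    clip_length(network, poly) / polygon_area(poly)
  }, numeric(1))
  ba <- vapply(regions, function(rg)
    sum(annual$burned_area_km2[annual$ecoregion == rg]), numeric(1))
  sl <- vapply(regions, function(rg)
    sum(annual$sl_ba_km[annual$ecoregion == rg]), numeric(1))
  data.frame(ecoregion = regions,
             drainage_density = unname(dens),
             slba_ba_ratio = unname(ifelse(ba > 0, sl / ba, NA_real_)),
             stringsAsFactors = FALSE)
}

#' Strahler stream orders from network topology
#'
#' Leaves are order 1; where tributaries join, the order increments only if
#' at least two tributaries share the maximum order, otherwise the maximum
#' carries through.
#'
#' @param topology Data frame with columns `segment_id` and `parent_id`
#'   (NA for outlets); must be a forest.
#' @return Named integer vector of orders, indexed by segment_id.
#' @export
strahler_orders <- function(topology) {
  ids <- as.character(topology$segment_id)
  parents <- as.character(topology$parent_id)
  n <- length(ids)
  order_of <- stats::setNames(rep(NA_integer_, n), ids)
  children <- split(ids, factor(parents, levels = ids))
  # process leaves upward
  remaining <- ids
  guard <- 0L
  while (length(remaining)) {
    guard <- guard + 1L
    if (guard > n + 1L) stop("topology is not a forest (cycle detected)")
    ready <- remaining[vapply(remaining, function(id) {
      ch <- children[[id]]
      length(ch) == 0 || all(!is.na(order_of[ch]))
    }, logical(1))]
    if (!length(ready)) stop("topology is not a forest (cycle detected)")
    for (id in ready) {
      ch <- children[[id]]
      if (length(ch) == 0) {
        order_of[id] <- 1L
      } else {
        m <- max(order_of[ch])
        order_of[id] <- if (sum(order_of[ch] == m) >= 2) m + 1L else m
      }
    }
    remaining <- setdiff(remaining, ready)
  }
  order_of
}

#' Extract the topology table of a stream network
#' @param network A [stream_network()].
#' @return Data frame (segment_id, parent_id, strahler_order).
#' @export
network_topology <- function(network) {
  data.frame(
    segment_id = vapply(network$segments, function(s) s$segment_id, character(1)),
    parent_id = vapply(network$segments, function(s)
      as.character(s$parent_id %||% NA_character_), character(1)),
    strahler_order = vapply(network$segments, function(s)
      as.integer(s$strahler_order), integer(1)),
    stringsAsFactors = FALSE)
}
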