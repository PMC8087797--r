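# Domain type constructors and validators (S3).

#' Horton's-law network parameters
#'
#' Describes a fluvial network through Horton's laws: the bifurcation ratio
#' \code{r_b} (mean tributary count per stream), the length ratio \code{r_l}
#' (mean length of order-(w+1) streams over order-w streams; field values run
#' 1.5-3.5 and average about 2), and the mean first-order stream length
#' \code{mean_l1} (km). Mean stream length at order w is
#' \code{mean_l1 * r_l^(w-1)}.
#'
#' @param r_b Bifurcation ratio, > 1.
#' @param r_l Length ratio, > 0 (1.5-3.5 in the emulated regime).
#' @param mean_l1 Mean first-order stream length in km, > 0.
#' @param max_order Largest Strahler order to generate, integer >= 1.
#' @param length_cv Coefficient of variation of stream lengths, >= 0. Zero
#'   switches the generator into its fully deterministic regime.
#' @return An object of class `horton_params`.
#' @export
horton_params <- function(r_b = 2, r_l = 2, mean_l1 = 1.3, max_order = 4,
                          length_cv = 0) {
  stopifnot(r_b > 1, r_l > 0, mean_l1 > 0, max_order >= 1, length_cv >= 0)
  structure(list(r_b = r_b, r_l = r_l, mean_l1 = mean_l1,
                 max_order = as.integer(max_order), length_cv = length_cv),
            class = "horton_params")
}

#' Burn-scar generator specification
#'
#' @param n_fires Number of fires, >= 0.
#' @param area_log_mean,area_log_sd Lognormal (natural-log scale) parameters
#'   of fire area in km^2.
#' @param severity_fractions Named proportions over the six severity classes
#'   (unburned, low, moderate, high, increased_greenness, masked); must sum
#'   to 1.
#' @param year_range Inclusive integer year interval, length 2.
#' @return An object of class `burn_gen_spec`.
#' @export
burn_gen_spec <- function(n_fires,
                          area_log_mean = log(30), area_log_sd = 1,
                          severity_fractions = c(unburned = 0.15, low = 0.35,
                                                 moderate = 0.25, high = 0.15,
                                                 increased_greenness = 0.05,
                                                 masked = 0.05),
                          year_range = c(1984L, 2014L)) {
  stopifnot(n_fires >= 0, length(year_range) == 2,
            year_range[1] <= year_range[2])
  if (!setequal(names(severity_fractions), severity_classes()))
    stop("severity_fractions must be named by the six severity classes")
  if (abs(sum(severity_fractions) - 1) > 1e-9)
    stop("severity_fractions must sum to 1")
  if (any(severity_fractions < 0)) stop("severity_fractions must be >= 0")
  structure(list(n_fires = as.integer(n_fires),
                 area_log_mean = area_log_mean, area_log_sd = area_log_sd,
                 severity_fractions = severity_fractions[severity_classes()],
                 year_range = as.integer(year_range)),
            class = "burn_gen_spec")
}

#' The six burn-severity classes
#' @return Character vector of class names.
#' @export
severity_classes <- function() {
  c("unburned", "low", "moderate", "high", "increased_greenness", "masked")
}

#' Severity classes retained as "burned" by the severity filter
#' @return Character vector.
#' @export
retained_severity_classes <- function() c("low", "moderate", "high")

#' Dissolved-oxygen sag generator specification
#'
#' Stations sit at increasing along-channel distances below a disturbance
#' source. Each event injects a DO sag whose magnitude decays downstream as
#' \code{a1*exp(-k1*x) + a2*exp(-k2*x)} and whose arrival lags by
#' \code{distance / celerity}.
#'
#' @param station_distances Strictly increasing along-channel distances (km).
#' @param baseline_do Baseline dissolved oxygen, mg/L.
#' @param components Named vector (a1, k1, a2, k2); a in mg/L, k in 1/km, all
#'   >= 0.
#' @param event_times POSIXct (or numeric hours from `origin`) event start
#'   times at the source.
#' @param noise_sd Gaussian sensor noise, mg/L.
#' @param sample_interval Sampling interval in minutes.
#' @param celerity Disturbance travel speed, km/h.
#' @param origin POSIXct origin used when `event_times` is numeric hours.
#' @return An object of class `do_sag_spec`.
#' @export
do_sag_spec <- function(station_distances,
                        baseline_do = 7.2,
                        components = c(a1 = 5, k1 = 0.01, a2 = 0, k2 = 0),
                        event_times = as.POSIXct("2011-07-15 00:00:00", tz = "UTC"),
                        noise_sd = 0.1,
                        sample_interval = 15,
                        celerity = 2,
                        origin = as.POSIXct("2011-07-01 00:00:00", tz = "UTC")) {
  stopifnot(length(station_distances) >= 1,
            all(diff(station_distances) > 0),
            all(station_distances > 0),
            baseline_do > 0, noise_sd >= 0, sample_interval > 0, celerity > 0)
  comp <- components[c("a1", "k1", "a2", "k2")]
  if (anyNA(comp) || any(comp < 0)) stop("components (a1,k1,a2,k2) must be >= 0")
  if (is.numeric(event_times)) event_times <- origin + event_times * 3600
  structure(list(station_distances = station_distances,
                 baseline_do = baseline_do, components = comp,
                 event_times = sort(event_times), noise_sd = noise_sd,
                 sample_interval = sample_interval, celerity = celerity),
            class = "do_sag_spec")
}

#' Stream network container
#'
#' @param segments List of segments; each has `segment_id`, `parent_id`
#'   (NA at a root/outlet), `strahler_order`, and a coordinate matrix `coords`
#'   (columns x, y, km).
#' @param region Bounding box `c(xmin, xmax, ymin, ymax)` in km.
#' @return An object of class `stream_network` with derived `total_length_km`
#'   and `region_area_km2`.
#' @export
stream_network <- function(segments, region) {
  stopifnot(length(region) == 4, region[2] > region[1], region[4] > region[3])
  for (s in segments) {
    if (nrow(s$coords) < 2) stop("segment ", s$segment_id, ": needs >= 2 vertices")
  }
  lens <- vapply(segments, function(s) polyline_length(s$coords), numeric(1))
  if (any(lens <= 0)) stop("degenerate zero-length segment")
  ids <- vapply(segments, function(s) s$segment_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate segment ids")
  parents <- vapply(segments, function(s) as.character(s$parent_id %||% NA_character_),
                    character(1))
  if (any(!is.na(parents) & !(parents %in% ids)))
    stop("parent_id refers to an unknown segment")
  structure(list(segments = segments,
                 total_length_km = sum(lens),
                 region = region,
                 region_area_km2 = (region[2] - region[1]) * (region[4] - region[3])),
            class = "stream_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stream_network <- function(x, ...) {
  ords <- vapply(x$segments, function(s) s$strahler_order, integer(1))
  cat("<stream_network> ", length(x$segments), " streams, max order ",
      max(ords), ", total length ", round(x$total_length_km, 2), " km\n", sep = "")
  invisible(x)
}

#' Burn scar (fire perimeter with severity patches)
#'
#' @param fire_id Character id.
#' @param year Integer fire year.
#' @param perimeter Simple polygon matrix (km).
#' @param severity_patches Named list (by severity class) of polygon matrices
#'   or NULL entries; patches must lie within the perimeter and partition it.
#' @return An object of class `burn_scar`.
#' @export
burn_scar <- function(fire_id, year, perimeter, severity_patches) {
  if (!is_simple_polygon(perimeter)) stop("perimeter is not a simple polygon")
  bad <- setdiff(names(severity_patches), severity_classes())
  if (length(bad)) stop("unknown severity classes: ", paste(bad, collapse = ", "))
  structure(list(fire_id = as.character(fire_id), year = as.integer(year),
                 perimeter = perimeter, severity_patches = severity_patches),
            class = "burn_scar")
}

#' Ecoregion map (a polygon partition of the region)
#'
#' @param polygons Named list of polygon matrices partitioning `region`.
#' @param region Bounding box `c(xmin, xmax, ymin, ymax)`.
#' @return An object of class `ecoregion_map`.
#' @export
ecoregion_map <- function(polygons, region) {
  stopifnot(length(polygons) >= 1, !is.null(names(polygons)),
            !anyDuplicated(names(polygons)))
  structure(list(polygons = polygons, region = region),
            class = "ecoregion_map")
}

#' Sonde time series at one station
#'
#' @param station_id Character id.
#' @param distance_km Along-channel distance from the disturbance source.
#' @param time POSIXct vector, strictly increasing.
#' @param do_mgl Dissolved oxygen, mg/L, >= 0.
#' @return An object of class `sonde_series`.
#' @export
sonde_series <- function(station_id, distance_km, time, do_mgl) {
  stopifnot(length(time) == length(do_mgl), all(diff(as.numeric(time)) > 0),
            all(do_mgl >= 0))
  structure(list(station_id = as.character(station_id),
                 distance_km = distance_km,
                 time = time, do_mgl = do_mgl),
            class = "sonde_series")
}
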