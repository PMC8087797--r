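# Plain-text interchange: GeoJSON FeatureCollections for networks, scars and
# ecoregions (planar km coordinates, pre-projected), tidy CSV for sonde data.

geojson_ring <- function(poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

#' Write a stream network as GeoJSON
#'
#' LineString features with properties segment_id, strahler_order, and
#' parent_id; the bounding region is stored in the collection `bbox`.
#'
#' @param network A [stream_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_geojson <- function(network, path) {
  feats <- lapply(network$segments, function(s) list(
    type = "Feature",
    properties = list(segment_id = s$segment_id,
                      strahler_order = s$strahler_order,
                      parent_id = if (is.na(s$parent_id %||% NA)) NULL else s$parent_id),
    geometry = list(type = "LineString",
                    coordinates = lapply(seq_len(nrow(s$coords)), function(i)
                      c(s$coords[i, 1], s$coords[i, 2])))))
  fc <- list(type = "FeatureCollection", bbox = network$region, features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a stream network from GeoJSON
#' @param path File written by [write_network_geojson()] (or matching schema).
#' @return A [stream_network()].
#' @export
read_network_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  segs <- lapply(fc$features, function(f) {
    cm <- do.call(rbind, lapply(f$geometry$coordinates, function(p)
      c(p[[1]], p[[2]])))
    list(segment_id = f$properties$segment_id,
         parent_id = f$properties$parent_id %||% NA_character_,
         strahler_order = as.integer(f$properties$strahler_order),
         coords = cbind(x = cm[, 1], y = cm[, 2]))
  })
  stream_network(segs, unlist(fc$bbox))
}

#' Write burn scars as GeoJSON
#'
#' One Polygon feature per scar perimeter (properties fire_id, year,
#' severity_class = "perimeter") plus one per severity patch.
#'
#' @param scars List of [burn_scar()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scars_geojson <- function(scars, path) {
  feats <- list()
  for (s in scars) {
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      properties = list(fire_id = s$fire_id, year = s$year,
                        severity_class = "perimeter"),
      geometry = list(type = "Polygon",
                      coordinates = list(geojson_ring(s$perimeter))))
    for (cls in names(s$severity_patches)) {
      p <- s$severity_patches[[cls]]
      if (is.null(p)) next
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(fire_id = s$fire_id, year = s$year,
                          severity_class = cls),
        geometry = list(type = "Polygon",
                        coordinates = list(geojson_ring(p))))
    }
  }
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read burn scars from GeoJSON
#' @param path File with the [write_scars_geojson()] schema.
#' @return List of [burn_scar()] objects.
#' @export
read_scars_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  by_fire <- split(fc$features, vapply(fc$features, function(f)
    f$properties$fire_id, character(1)))
  out <- lapply(by_fire, function(fl) {
    ring_of <- function(f) {
      cm <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(p)
        c(p[[1]], p[[2]])))
      cm <- cm[-nrow(cm), , drop = FALSE]  # drop closing vertex
      cbind(x = cm[, 1], y = cm[, 2])
    }
    classes <- vapply(fl, function(f) f$properties$severity_class, character(1))
    perim <- ring_of(fl[[which(classes == "perimeter")[1]]])
    patches <- stats::setNames(vector("list", length(severity_classes())),
                               severity_classes())
    for (i in which(classes != "perimeter"))
      patches[[classes[i]]] <- ring_of(fl[[i]])
    burn_scar(fl[[1]]$properties$fire_id, fl[[1]]$properties$year, perim, patches)
  })
  out[order(names(out))]
}

#' Write an ecoregion map as GeoJSON
#' @param map An [ecoregion_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecoregions_geojson <- function(map, path) {
  feats <- lapply(names(map$polygons), function(nm) list(
    type = "Feature", properties = list(name = nm),
    geometry = list(type = "Polygon",
                    coordinates = list(geojson_ring(map$polygons[[nm]])))))
  fc <- list(type = "FeatureCollection", bbox = map$region, features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an ecoregion map from GeoJSON
#' @param path File with the [write_ecoregions_geojson()] schema.
#' @return An [ecoregion_map()].
#' @export
read_ecoregions_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  polys <- stats::setNames(lapply(fc$features, function(f) {
    cm <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(p)
      c(p[[1]], p[[2]])))
    cm <- cm[-nrow(cm), , drop = FALSE]
    cbind(x = cm[, 1], y = cm[, 2])
  }), vapply(fc$features, function(f) f$properties$name, character(1)))
  ecoregion_map(polys, unlist(fc$bbox))
}

#' Write sonde series as tidy CSV
#'
#' Columns: station_id, distance_km, timestamp (ISO-8601 UTC), do_mgl.
#'
#' @param series_list List of [sonde_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sonde_csv <- function(series_list, path) {
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(station_id = s$station_id, distance_km = s$distance_km,
               timestamp = format(s$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               do_mgl = s$do_mgl, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read sonde series from tidy CSV
#' @param path File with the [write_sonde_csv()] schema.
#' @return List of [sonde_series()], ordered by distance.
#' @export
read_sonde_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$station_id), function(d) {
    d <- d[order(d$timestamp), ]
    sonde_series(d$station_id[1], d$distance_km[1],
                 as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC"),
                 d$do_mgl)
  })
  out[order(vapply(out, function(s) s$distance_km, numeric(1)))]
}
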