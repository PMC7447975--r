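# Readers and writers for the pipeline's table and GeoJSON formats.
# CSV dialect: UTF-8, comma separator, "." decimal, ISO-8601 datetimes.
# GeoJSON coordinates are in the configured planar metric CRS.

#' Read a collision table
#'
#' Validates the schema, removes rows with age under five (counted, not
#' silently dropped), and quarantines rows with invalid coordinates or
#' malformed datetimes instead of failing the run.
#'
#' @param path CSV file path.
#' @param required columns that must be present.
#' @return collision data.frame with attributes `n_under5` (removed) and
#'   `quarantine` (bad rows with a `reason` column).
#' @export
read_collisions <- function(path,
                            required = c("event_id", "x", "y", "datetime",
                                         "fatal", "sex", "age")) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    attr(df, "n_under5") <- 0L
    attr(df, "quarantine") <- df
    return(df)
  }
  reason <- rep(NA_character_, nrow(df))
  bad_xy <- !is.finite(df$x) | !is.finite(df$y)
  reason[bad_xy] <- "invalid coordinates"
  dt <- as.POSIXct(df$datetime, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad_dt <- is.na(dt) & is.na(reason)
  reason[bad_dt] <- "malformed datetime"
  quarantine <- cbind(df[!is.na(reason), , drop = FALSE],
                      reason = reason[!is.na(reason)])
  df <- df[is.na(reason), , drop = FALSE]
  under5 <- !is.na(df$age) & df$age < 5
  out <- df[!under5, , drop = FALSE]
  if (!"year" %in% names(out) && nrow(out) > 0)
    out$year <- as.integer(substr(out$datetime, 1, 4))
  if (!"month" %in% names(out) && nrow(out) > 0)
    out$month <- as.integer(substr(out$datetime, 6, 7))
  rownames(out) <- NULL
  attr(out, "n_under5") <- sum(under5)
  attr(out, "quarantine") <- quarantine
  out
}

#' Write a collision table
#' @param collisions collision data.frame.
#' @param path CSV destination.
#' @export
write_collisions <- function(collisions, path) {
  utils::write.csv(collisions, path, row.names = FALSE)
  invisible(path)
}

#' Write a zone map as GeoJSON
#' @param zones a `zone_map`.
#' @param path destination file.
#' @param crs EPSG code recorded in the file (planar metric CRS).
#' @export
write_zones_geojson <- function(zones, path, crs = "local-metric") {
  feats <- lapply(zones$zones, function(z) {
    ring <- rbind(z$polygon, z$polygon[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(zone_id = z$zone_id,
                           income_stratum = z$income_stratum),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))))
  })
  obj <- list(type = "FeatureCollection", crs = crs,
              window = as.numeric(zones$window), features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a zone map from GeoJSON
#' @param path GeoJSON file written by [write_zones_geojson()].
#' @return a `zone_map`.
#' @export
read_zones_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  zones <- lapply(obj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    ring <- ring[-nrow(ring), , drop = FALSE]
    colnames(ring) <- c("x", "y")
    list(zone_id = f$properties$zone_id, polygon = ring,
         income_stratum = f$properties$income_stratum)
  })
  structure(list(zones = zones, window = as.numeric(unlist(obj$window))),
            class = "zone_map")
}

#' Write a road network as GeoJSON
#' @param network a `road_network`.
#' @param path destination file.
#' @export
write_network_geojson <- function(network, path) {
  nd <- network$nodes
  feats <- lapply(seq_len(nrow(network$edges)), function(i) {
    e <- network$edges[i, ]
    ia <- match(e$node_a, nd$node_id); ib <- match(e$node_b, nd$node_id)
    list(type = "Feature",
         properties = as.list(e),
         geometry = list(type = "LineString",
                         coordinates = list(c(nd$x[ia], nd$y[ia]),
                                            c(nd$x[ib], nd$y[ib]))))
  })
  obj <- list(type = "FeatureCollection",
              nodes = nd, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a road network from GeoJSON
#' @param path file written by [write_network_geojson()].
#' @return a `road_network`.
#' @export
read_network_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- do.call(rbind, lapply(
    if (is.data.frame(obj$features)) seq_len(nrow(obj$features)) else
      seq_along(obj$features),
    function(i) {
      p <- if (is.data.frame(obj$features)) obj$features$properties[i, ]
           else as.data.frame(obj$features[[i]]$properties)
      p
    }))
  structure(list(nodes = as.data.frame(obj$nodes), edges = as.data.frame(edges)),
            class = "road_network")
}

#' Write survey tables as one CSV
#' @param surveys list of survey tables.
#' @param path destination file.
#' @export
write_surveys <- function(surveys, path) {
  utils::write.csv(do.call(rbind, surveys), path, row.names = FALSE)
  invisible(path)
}

#' Read survey tables from CSV
#' @param path file written by [write_surveys()].
#' @return list of survey tables, one per year.
#' @export
read_surveys <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split(df, df$year)
}

#' Write and read an exposure panel
#' @param panel exposure panel data.frame.
#' @param path CSV path.
#' @export
write_exposure <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exposure
#' @export
read_exposure <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Write ground truth to JSON
#'
#' Smooth log-odds functions are serialized as value grids; everything
#' else round-trips exactly.
#'
#' @param truth a `ground_truth`.
#' @param path destination file.
#' @export
write_ground_truth <- function(truth, path) {
  sm <- lapply(names(truth$smooth_log_odds), function(nm) {
    g <- switch(nm, time_of_day = seq(0, 24, length.out = 97),
                age = seq(5, 85, length.out = 81),
                seq(0, 10, length.out = 101))
    list(name = nm, x = g, y = truth$smooth_log_odds[[nm]](g))
  })
  obj <- truth
  obj$smooth_log_odds <- sm
  obj$risk$smooth <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
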