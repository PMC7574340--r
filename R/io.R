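## Plain-text interchange: GeoJSON region polygons, edge-list CSV,
## coordinate-form W, and region tables.

#' Read region polygons from a GeoJSON FeatureCollection
#'
#' One feature per region; Polygon and MultiPolygon geometries are
#' supported (only exterior and interior rings' coordinates are kept,
#' which is all contiguity detection needs). Planar coordinates assumed.
#'
#' @param path GeoJSON file.
#' @param id_property name of the feature property holding the region id.
#' @return named list of polygons suitable for [queen_adjacency()].
#' @export
read_geojson_regions <- function(path, id_property = "id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a FeatureCollection")
  polys <- list()
  for (f in gj$features) {
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature without property '", id_property, "'")
    geom <- f$geometry
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    rings <- switch(
      geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly)
        lapply(poly, ring_mat)), recursive = FALSE),
      stop("unsupported geometry type '", geom$type, "' for region ", id))
    polys[[as.character(id)]] <- rings
  }
  polys
}

#' Write / read an adjacency edge list as two-column CSV
#'
#' @param graph a [region_graph()].
#' @param path CSV file.
#' @return `write_edge_csv` invisibly returns the edge data frame;
#'   `read_edge_csv` returns a [region_graph()] (region ids must be
#'   supplied so isolated regions survive the round trip).
#' @export
write_edge_csv <- function(graph, path) {
  idx <- which(upper.tri(graph$W) & graph$W == 1, arr.ind = TRUE)
  df <- data.frame(from = graph$region_ids[idx[, 1]],
                   to = graph$region_ids[idx[, 2]],
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @param region_ids full ordered id vector for `read_edge_csv`.
#' @rdname write_edge_csv
#' @export
read_edge_csv <- function(path, region_ids) {
  df <- read.csv(path, colClasses = "character")
  adjacency_from_edges(region_ids, df)
}

#' Write W in coordinate (row, col, value) CSV form
#'
#' @param graph a [region_graph()].
#' @param path CSV file.
#' @export
write_w_coo <- function(graph, path) {
  idx <- which(graph$W == 1, arr.ind = TRUE)
  df <- data.frame(row = graph$region_ids[idx[, 1]],
                   col = graph$region_ids[idx[, 2]],
                   value = 1L, stringsAsFactors = FALSE)
  df <- df[order(match(df$row, graph$region_ids),
                 match(df$col, graph$region_ids)), ]
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write / read a region table CSV
#'
#' Plain `write.csv`/`read.csv` wrappers fixing `region_id` to character
#' so identifiers round-trip losslessly.
#'
#' @param table region data frame.
#' @param path CSV file.
#' @export
write_region_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(table)
}

#' @rdname write_region_csv
#' @export
read_region_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("region_id" %in% names(df)) df$region_id <- as.character(df$region_id)
  df
}
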