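## Spatial adjacency (the W matrix): construction, validation, pruning.

#' Construct a region adjacency graph
#'
#' A `region_graph` holds an ordered set of region identifiers and the
#' symmetric binary first-order adjacency matrix W used by all CAR models:
#' `w[i, j] = 1` when regions i and j are neighbours, zero diagonal
#' (a region is not its own neighbour).
#'
#' @param W square numeric matrix with entries in \{0, 1\}, symmetric,
#'   zero diagonal.
#' @param region_ids character or integer vector of unique identifiers,
#'   one per row of `W`. Defaults to rownames of `W` or `1:n`.
#' @return An object of class `region_graph`: a list with `region_ids`,
#'   `W`, and `neighbor_counts` (the per-region degree, i.e. row sums of W).
#' @export
region_graph <- function(W, region_ids = NULL) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (ncol(W) != n) stop("W must be square")
  if (is.null(region_ids)) {
    region_ids <- rownames(W)
    if (is.null(region_ids)) region_ids <- as.character(seq_len(n))
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != n) stop("region_ids length must match nrow(W)")
  if (anyDuplicated(region_ids))
    stop("duplicate region ids: ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "))
  if (!all(W %in% c(0, 1))) stop("W entries must be exactly 0 or 1")
  if (!isTRUE(all.equal(W, t(W)))) stop("W must be symmetric")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  dimnames(W) <- list(region_ids, region_ids)
  structure(
    list(region_ids = region_ids, W = W,
         neighbor_counts = unname(rowSums(W))),
    class = "region_graph"
  )
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region_graph:", length(x$region_ids), "regions,",
      sum(x$W) / 2, "adjacency pairs,",
      sum(x$neighbor_counts == 0), "isolated\n")
  invisible(x)
}

n_regions <- function(graph) length(graph$region_ids)

## neighbor index list (1-based), used by the samplers
neighbor_list <- function(graph) {
  apply(graph$W > 0, 1, which, simplify = FALSE)
}

#' Queen-contiguity adjacency from polygons
#'
#' Builds the binary first-order adjacency matrix under the Queen criterion:
#' two regions are neighbours when their boundaries share at least one
#' point (an edge segment or a single corner vertex), like the reach of a
#' chess Queen on a grid. A Rook option restricts neighbourhood to shared
#' boundary segments of positive length (corner-only contact is not
#' adjacency), for sensitivity checks.
#'
#' Contact is detected by segment-segment proximity within `tolerance`
#' (coordinate units), which absorbs the floating-point slivers common in
#' polygonised boundary files. Planar coordinates are assumed.
#'
#' @param polygons named list, one element per region; each element is a
#'   ring (two-column coordinate matrix, closed or open) or a list of rings
#'   for multi-part regions. Names are the region ids. See
#'   [read_geojson_regions()] for building this from a GeoJSON file.
#' @param criterion `"queen"` (default) or `"rook"`.
#' @param tolerance contact tolerance in coordinate units.
#' @return A [region_graph()].
#' @examples
#' sq <- function(x, y) cbind(c(x, x + 1, x + 1, x), c(y, y, y + 1, y + 1))
#' g <- queen_adjacency(list(a = sq(0, 0), b = sq(1, 0), c = sq(2, 0)))
#' g$W  # strip of 3 squares: (a,b) and (b,c) adjacent, (a,c) not
#' @export
queen_adjacency <- function(polygons, criterion = c("queen", "rook"),
                            tolerance = 1e-9) {
  criterion <- match.arg(criterion)
  if (length(polygons) == 0) stop("empty polygon collection")
  ids <- names(polygons)
  if (is.null(ids)) ids <- as.character(seq_along(polygons))
  if (anyDuplicated(ids))
    stop("duplicate region ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  rings <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    if (is.matrix(p)) p <- list(p)
    if (!is.list(p) || !all(vapply(p, is.matrix, logical(1))))
      stop("invalid geometry for region '", ids[i],
           "': expected a coordinate matrix or list of matrices")
    for (ring in p) {
      if (ncol(ring) != 2 || nrow(ring) < 3 || anyNA(ring))
        stop("invalid geometry for region '", ids[i], "'")
    }
    p
  })

  segs <- lapply(rings, polygon_segments)
  boxes <- t(vapply(segs, function(s)
    c(min(s[, 1], s[, 3]), min(s[, 2], s[, 4]),
      max(s[, 1], s[, 3]), max(s[, 2], s[, 4])), numeric(4)))

  n <- length(polygons)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (boxes[i, 1] > boxes[j, 3] + tolerance ||
          boxes[j, 1] > boxes[i, 3] + tolerance ||
          boxes[i, 2] > boxes[j, 4] + tolerance ||
          boxes[j, 2] > boxes[i, 4] + tolerance) next
      touch <- cpp_segments_touch(segs[[i]], segs[[j]], tolerance,
                                  criterion == "rook")
      if (touch) W[i, j] <- W[j, i] <- 1
    }
  }
  region_graph(W, ids)
}

## closed boundary segments of a region: matrix (x1, y1, x2, y2) per row
polygon_segments <- function(ringlist) {
  do.call(rbind, lapply(ringlist, function(ring) {
    # close the ring if open
    if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    m <- nrow(ring)
    cbind(ring[-m, 1], ring[-m, 2], ring[-1, 1], ring[-1, 2])
  }))
}

#' Adjacency graph from an explicit edge list
#'
#' Alternate input path so the pipeline can run from a plain edge list
#' with no geometry files.
#'
#' @param region_ids vector of unique region identifiers (defines the
#'   ordering used by all downstream matrices).
#' @param edges two-column matrix or data frame of id pairs, one row per
#'   unordered adjacency pair; may have zero rows.
#' @return A [region_graph()].
#' @export
adjacency_from_edges <- function(region_ids, edges) {
  region_ids <- as.character(region_ids)
  if (anyDuplicated(region_ids)) stop("duplicate region ids")
  n <- length(region_ids)
  W <- matrix(0, n, n)
  if (NROW(edges) > 0) {
    edges <- as.matrix(edges)
    a <- match(as.character(edges[, 1]), region_ids)
    b <- match(as.character(edges[, 2]), region_ids)
    if (anyNA(a) || anyNA(b)) {
      bad <- unique(c(edges[is.na(a), 1], edges[is.na(b), 2]))
      stop("unknown region id in edges: ", paste(bad, collapse = ", "))
    }
    if (any(a == b))
      stop("self-loop forbidden for region ",
           paste(unique(region_ids[a[a == b]]), collapse = ", "))
    W[cbind(a, b)] <- 1
    W[cbind(b, a)] <- 1
  }
  region_graph(W, region_ids)
}

#' Remove isolated regions from a graph
#'
#' Regions with no neighbours cannot carry an intrinsic CAR effect (the
#' conditional mean over an empty neighbour set is undefined), so they are
#' removed before spatial modelling, mirroring standard practice for
#' island/non-contiguous areal units.
#'
#' @param graph a [region_graph()].
#' @return list with `graph` (the subgraph of regions with degree >= 1,
#'   re-indexed consistently) and `removed_ids`.
#' @export
find_and_remove_isolated <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  keep <- graph$neighbor_counts >= 1
  if (!any(keep)) stop("all regions are isolated; no analyzable graph")
  removed <- graph$region_ids[!keep]
  if (length(removed) == 0) return(list(graph = graph, removed_ids = character(0)))
  list(
    graph = region_graph(graph$W[keep, keep, drop = FALSE],
                         graph$region_ids[keep]),
    removed_ids = removed
  )
}

## connected components by BFS; returns integer component label per region
graph_components <- function(graph) {
  nb <- neighbor_list(graph)
  n <- n_regions(graph)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in nb[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

#' Build the adjacency graph for a rectangular grid of unit squares
#'
#' Convenience constructor used by the synthetic-study generator and in
#' tests: cells are laid out row-major on an `nrow x ncol` lattice and
#' connected under the Queen (default) or Rook criterion. `n_cells` can
#' truncate the lattice to its first cells (row-major) so any region count
#' is reachable.
#'
#' @param nrow,ncol lattice dimensions.
#' @param n_cells optional number of cells to keep (<= nrow * ncol).
#' @param criterion `"queen"` or `"rook"`.
#' @return A [region_graph()].
#' @export
grid_graph <- function(nrow, ncol, n_cells = nrow * ncol,
                       criterion = c("queen", "rook")) {
  criterion <- match.arg(criterion)
  stopifnot(n_cells >= 1, n_cells <= nrow * ncol)
  idx <- seq_len(n_cells) - 1L
  r <- idx %/% ncol
  c <- idx %% ncol
  edges <- NULL
  steps <- if (criterion == "queen")
    list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  else list(c(0L, 1L), c(1L, 0L))
  for (s in steps) {
    r2 <- r + s[1]
    c2 <- c + s[2]
    ok <- r2 >= 0 & r2 < nrow & c2 >= 0 & c2 < ncol
    j <- r2 * ncol + c2
    ok <- ok & j < n_cells
    if (any(ok)) edges <- rbind(edges, cbind(idx[ok] + 1L, j[ok] + 1L))
  }
  adjacency_from_edges(seq_len(n_cells), edges)
}
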