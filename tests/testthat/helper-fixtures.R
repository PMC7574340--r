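# Shared fixtures: simple geometries, small graphs, and independent oracles.

# unit square with lower-left corner (x, y)
unit_square <- function(x, y) {
  cbind(c(x, x + 1, x + 1, x), c(y, y, y + 1, y + 1))
}

# grid of unit-square polygons, row-major, ids "1".."n"
grid_polygons <- function(nrow, ncol) {
  polys <- list()
  k <- 0
  for (r in seq_len(nrow) - 1) {
    for (c in seq_len(ncol) - 1) {
      k <- k + 1
      polys[[as.character(k)]] <- unit_square(c, r)
    }
  }
  polys
}

# independently enumerated Queen edge list for a nrow x ncol grid
# (loops over cell pairs, compares row/col offsets)
grid_queen_edges <- function(nrow, ncol) {
  n <- nrow * ncol
  rows <- (seq_len(n) - 1) %/% ncol
  cols <- (seq_len(n) - 1) %% ncol
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (abs(rows[i] - rows[j]) <= 1 && abs(cols[i] - cols[j]) <= 1)
        out <- rbind(out, c(i, j))
    }
  }
  out
}

# path graph 1-2-3-...-n
path_graph <- function(n) {
  adjacency_from_edges(seq_len(n), cbind(seq_len(n - 1), seq(2, n)))
}

# pairwise-difference sum over adjacent pairs (each pair once)
icar_pairsum <- function(u, W) {
  sum(W * outer(u, u, "-")^2) / 2
}

# oracle: joint ICAR log density in pairwise-difference form (up to const)
icar_joint_logdens <- function(u, W, tau2) {
  -icar_pairsum(u, W) / (2 * tau2)
}

# oracle: closed-form inverse-gamma moments for shape a, rate b
invgamma_moments <- function(a, b) {
  list(mean = b / (a - 1), var = b^2 / ((a - 1)^2 * (a - 2)))
}

# Moran's I with binary weights W for a centred field
morans_i <- function(x, W) {
  z <- x - mean(x)
  (length(x) / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}
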