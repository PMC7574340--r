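test_that("queen adjacency matches shared-boundary enumeration on strips and blocks", {
  # 1x3 strip: only consecutive squares touch
  strip <- queen_adjacency(list(a = unit_square(0, 0), b = unit_square(1, 0),
                                c = unit_square(2, 0)))
  expect_equal(strip$W[lower.tri(strip$W)], c(1, 0, 1),
               ignore_attr = TRUE)
  expect_equal(unname(strip$neighbor_counts), c(1, 2, 1))

  # 2x2 block: all 6 unordered pairs adjacent (diagonals share a corner)
  block <- queen_adjacency(grid_polygons(2, 2))
  expect_equal(sum(block$W) / 2, 6)

  # single polygon: 1x1 zero matrix
  solo <- queen_adjacency(list(only = unit_square(0, 0)))
  expect_equal(solo$W, matrix(0, 1, 1, dimnames = list("only", "only")))
  expect_equal(unname(solo$neighbor_counts), 0)
})

test_that("rook criterion drops corner-only contact that queen keeps", {
  # diagonal squares: share exactly one point
  diag2 <- list(a = unit_square(0, 0), b = unit_square(1, 1))
  expect_equal(queen_adjacency(diag2)$W["a", "b"], 1)
  expect_equal(queen_adjacency(diag2, criterion = "rook")$W["a", "b"], 0)
  # edge-sharing squares are neighbours under both
  side2 <- list(a = unit_square(0, 0), b = unit_square(1, 0))
  expect_equal(queen_adjacency(side2, criterion = "rook")$W["a", "b"], 1)
})

test_that("queen degrees on rectangular grids follow the interior-8 edge-5 corner-3 rule", {
  for (dims in list(c(3, 3), c(4, 6))) {
    nr <- dims[1]; nc <- dims[2]
    g <- queen_adjacency(grid_polygons(nr, nc))
    rows <- (seq_len(nr * nc) - 1) %/% nc
    cols <- (seq_len(nr * nc) - 1) %% nc
    on_r <- rows == 0 | rows == nr - 1
    on_c <- cols == 0 | cols == nc - 1
    expected <- ifelse(on_r & on_c, 3, ifelse(on_r | on_c, 5, 8))
    expect_equal(unname(g$neighbor_counts), expected)
  }
})

test_that("polygon-based and edge-list adjacency agree on an enumerated grid", {
  g_poly <- queen_adjacency(grid_polygons(3, 4))
  g_edges <- adjacency_from_edges(seq_len(12), grid_queen_edges(3, 4))
  expect_equal(unname(g_poly$W), unname(g_edges$W))
  # and the packaged grid constructor agrees too
  expect_equal(unname(grid_graph(3, 4)$W), unname(g_edges$W))
})

test_that("adjacency_from_edges builds symmetric binary W and rejects bad input", {
  g <- adjacency_from_edges(1:3, cbind(1, 2))
  expect_equal(unname(g$W), rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  g0 <- adjacency_from_edges(1:2, matrix(numeric(0), ncol = 2))
  expect_equal(sum(g0$W), 0)
  expect_equal(unname(g0$neighbor_counts), c(0, 0))
  expect_error(adjacency_from_edges(1:3, cbind(1, 1)), "self-loop")
  expect_error(adjacency_from_edges(1:3, cbind(1, 9)), "unknown region id")
})

test_that("region_graph validates structure and queen_adjacency names offenders", {
  expect_error(region_graph(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(region_graph(matrix(c(1, 1, 1, 0), 2)), "diagonal")
  expect_error(region_graph(matrix(c(0, 2, 2, 0), 2)), "0 or 1")
  expect_error(queen_adjacency(list()), "empty")
  expect_error(
    queen_adjacency(list(a = unit_square(0, 0), a = unit_square(1, 0))),
    "duplicate")
  expect_error(
    queen_adjacency(list(a = unit_square(0, 0), bad = cbind(0, 1))),
    "bad")
})

test_that("isolated-region removal keeps a consistent subgraph", {
  g <- adjacency_from_edges(1:3, cbind(1, 2))
  res <- find_and_remove_isolated(g)
  expect_equal(res$removed_ids, "3")
  expect_equal(res$graph$region_ids, c("1", "2"))
  expect_equal(unname(res$graph$W), rbind(c(0, 1), c(1, 0)))

  # fully connected: identity case
  full <- grid_graph(2, 2)
  res2 <- find_and_remove_isolated(full)
  expect_length(res2$removed_ids, 0)
  expect_equal(res2$graph$W, full$W)

  # all isolated: no analyzable graph
  expect_error(
    find_and_remove_isolated(adjacency_from_edges(1:2,
                                                  matrix(numeric(0), ncol = 2))),
    "isolated")

  # symmetry and zero diagonal hold after removal
  expect_true(isSymmetric(res$graph$W))
  expect_true(all(diag(res$graph$W) == 0))
})

test_that("a synthetic graph with 23 isolated regions keeps 335 of 358", {
  st <- generate_study(335, n_isolated = 23, seed = 11)
  expect_equal(nrow(st$data), 358)
  res <- find_and_remove_isolated(st$graph)
  expect_length(res$removed_ids, 23)
  expect_equal(length(res$graph$region_ids), 335)
})
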