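test_that("edge-list reading parses, dedups and round-trips", {
  f <- withr::local_tempfile()
  writeLines(c("1 2", "2 3"), f)
  g <- readEdgelist(f)
  expect_setequal(igraph::V(g)$name, c("1", "2", "3"))
  expect_equal(igraph::ecount(g), 2)

  writeLines(c("1 2", "1 2", "1 1"), f)
  expect_message(expect_message(g2 <- readEdgelist(f), "self-loop"),
                 "duplicate")
  expect_equal(igraph::ecount(g2), 1)

  writeLines(c("# header", "a b  # trailing comment", "", "b c"), f)
  g3 <- readEdgelist(f)
  expect_equal(igraph::ecount(g3), 2)

  writeLines(c("1 2", "3"), f)
  expect_error(readEdgelist(f), "line 2")
  writeLines(c("# only a comment"), f)
  expect_error(readEdgelist(f), "empty")

  ## round trip preserves the edge set exactly
  fig2 <- fixtureFig2()
  writeEdgelist(fig2, f)
  back <- readEdgelist(f)
  expect_identical(sort(edgeKey(as.data.frame(igraph::as_edgelist(back)) |>
                                  setNames(c("from", "to")))),
                   sort(edgeKey(as.data.frame(igraph::as_edgelist(fig2)) |>
                                  setNames(c("from", "to")))))
})

test_that("GML input is read and directed GML is rejected unless symmetrized", {
  f <- withr::local_tempfile(fileext = ".gml")
  igraph::write_graph(fixtureFig2(), f, format = "gml")
  g <- readEdgelist(f, format = "gml")
  expect_equal(igraph::vcount(g), 9)
  expect_equal(igraph::ecount(g), 12)

  d <- igraph::make_graph(c("a", "b", "b", "c"), directed = TRUE)
  igraph::write_graph(d, f, format = "gml")
  expect_error(readEdgelist(f, format = "gml"), "directed")
  gs <- readEdgelist(f, format = "gml", symmetrize = TRUE)
  expect_false(igraph::is_directed(gs))
  expect_equal(igraph::ecount(gs), 2)
})

test_that("adjacency matrix is symmetric, binary, unit-diagonal", {
  a1 <- buildAdjacency(igraph::make_graph(c("a", "b"), directed = FALSE))
  expect_equal(unname(a1), matrix(1, 2, 2))

  fig2 <- fixtureFig2()
  a <- buildAdjacency(fig2)
  expect_identical(a, t(a))
  expect_equal(diag(a), setNames(rep(1, 9), as.character(1:9)))
  expect_equal(sum(a) - 9, 24)          # 12 edges -> 24 off-diagonal ones
  expect_true(all(a %in% c(0, 1)))
})

test_that("network statistics match the reference karate values", {
  st <- as.data.frame(networkStats(fixtureKarate()))
  expect_equal(st$N, 34)
  expect_equal(st$E, 78)
  expect_equal(round(st$mean_k, 4), 4.5882)
  expect_equal(st$k_max, 17)
  expect_equal(round(st$H_k, 4), 1.6933)
  expect_equal(round(st$r, 4), -0.4756)
  expect_equal(round(st$C, 4), 0.5706)
})

test_that("regular graphs have heterogeneity 1 and undefined assortativity", {
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- as.character(1:6)
  expect_warning(st <- networkStats(ring), "assortativity")
  df <- as.data.frame(st)
  expect_equal(df$H_k, 1)
  expect_true(is.nan(df$r))

  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- as.character(1:3)
  df <- suppressWarnings(as.data.frame(networkStats(tri)))
  expect_equal(df$C, 1)
  expect_equal(df$mean_k, 2)
})

test_that("the 9-node fixture has the documented topology", {
  g <- fixtureFig2()
  expect_equal(igraph::vcount(g), 9)
  expect_equal(igraph::ecount(g), 12)
  deg <- igraph::degree(g)
  expect_equal(unname(deg["5"]), 4)
  expect_equal(unname(deg[c("2", "3", "6", "9")]), rep(2, 4))
  expect_true(igraph::is_connected(g))
})

test_that("planted partition respects probabilities, seeds and ground truth", {
  ## degenerate probabilities: two disjoint K5
  g0 <- generatePlantedPartition(5, 1.0, 0.0, seed = 7)
  expect_equal(igraph::ecount(g0), 2 * choose(5, 2))
  expect_equal(igraph::components(g0)$no, 2)
  expect_equal(nrow(plantedInterEdges(g0)), 0)

  ## determinism
  gA <- generatePlantedPartition(12, 0.4, 0.05, seed = 3)
  gB <- generatePlantedPartition(12, 0.4, 0.05, seed = 3)
  expect_identical(igraph::as_edgelist(gA), igraph::as_edgelist(gB))

  ## inter-block edge count ~ Binomial(nPerBlock^2, pOut); 4 sigma band
  g <- generatePlantedPartition(40, 0.3, 0.02, seed = 1)
  nInter <- nrow(plantedInterEdges(g))
  expect_lt(abs(nInter - 0.02 * 1600), 4 * sqrt(1600 * 0.02 * 0.98))

  expect_error(generatePlantedPartition(10, 0.2, 0.5, seed = 1), "pOut < pIn")
})

test_that("barbell graphs consist of two cliques and one bridge", {
  b <- generateBarbell(3)
  expect_equal(igraph::vcount(b), 6)
  expect_equal(igraph::ecount(b), 7)
  bridges <- igraph::bridges(b)
  expect_length(bridges, 1)
  deg <- sort(unname(igraph::degree(b)))
  expect_equal(deg, c(2, 2, 2, 2, 3, 3))

  b4 <- generateBarbell(4)
  cut <- igraph::delete_edges(b4, igraph::get_edge_ids(b4, c("4", "5")))
  expect_equal(sort(igraph::components(cut)$csize), c(4, 4))
})
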