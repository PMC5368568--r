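scoreMap <- function(tab) {
  sc <- edgeScores(tab)
  setNames(sc$score, edgeKey(sc))
}

test_that("edge betweenness matches hand-computed small cases", {
  path3 <- igraph::make_graph(c("a", "b", "b", "c"), directed = FALSE)
  s <- scoreMap(edgeBetweenness(path3))
  expect_equal(unname(s["a b"]), 2)   # pairs {a,b}, {a,c}

  ring4 <- igraph::make_ring(4)
  igraph::V(ring4)$name <- as.character(1:4)
  expect_equal(unname(scoreMap(edgeBetweenness(ring4))), rep(2, 4))

  b3 <- generateBarbell(3)
  s <- scoreMap(edgeBetweenness(b3))
  expect_equal(unname(s["3 4"]), 9)   # all 3x3 cross pairs use the bridge
})

test_that("edge betweenness agrees with exhaustive path enumeration", {
  cases <- list(generateBarbell(3), fixtureFig2())
  sizes <- c(5, 6, 7, 8, 5, 6, 7, 8)
  for (i in 1:8)
    cases[[length(cases) + 1]] <- randomConnectedGraph(sizes[i], 0.4, seed = i)
  for (g in cases) {
    got <- scoreMap(edgeBetweenness(g))
    want <- oracleEdgeBetweenness(g)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("degree product follows (kx ky)^theta", {
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- as.character(1:4)
  expect_equal(unname(scoreMap(degreeProduct(star))), rep(3, 3))

  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- as.character(1:3)
  expect_equal(unname(scoreMap(degreeProduct(tri))), rep(4, 3))
  expect_equal(unname(scoreMap(degreeProduct(tri, theta = 0))), rep(1, 3))
  expect_equal(unname(scoreMap(degreeProduct(tri, theta = 2))), rep(16, 3))
})

test_that("bridgeness matches its definition and the brute-force oracle", {
  b3 <- generateBarbell(3)
  s <- scoreMap(bridgeness(b3))
  expect_equal(unname(s["3 4"]), 1.5)          # sqrt(3*3)/2
  expect_equal(unname(s["1 2"]), 1)            # inside a K3

  lone <- igraph::make_graph(c("a", "b"), directed = FALSE)
  expect_equal(unname(scoreMap(bridgeness(lone))), 1)

  for (i in 1:5) {
    g <- randomConnectedGraph(8 + (i %% 3), 0.45, seed = 100 + i)
    got <- scoreMap(bridgeness(g))
    want <- oracleCliqueSizes(g)
    el <- igraph::as_edgelist(g, names = TRUE)
    keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    expected <- sqrt(want$node[el[, 1]] * want$node[el[, 2]]) /
      want$edge[keys]
    expect_equal(got[keys], setNames(expected, keys))
  }
})

test_that("clique search on a large sparse graph times out with advice", {
  big <- withr::with_seed(9, igraph::sample_gnp(3000, 0.002))
  igraph::V(big)$name <- as.character(seq_len(igraph::vcount(big)))
  expect_error(bridgeness(big, timeout = 0.5), "skip the bridgeness")
})

test_that("diffusion importance counts links leaving the closed neighborhood", {
  lone <- igraph::make_graph(c("a", "b"), directed = FALSE)
  expect_equal(unname(scoreMap(diffusionImportance(lone))), 0)

  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- as.character(1:3)
  expect_equal(unname(scoreMap(diffusionImportance(tri))), rep(0, 3))

  b3 <- generateBarbell(3)
  s <- scoreMap(diffusionImportance(b3))
  expect_equal(unname(s["3 4"]), 2)   # two outside links per endpoint
})

test_that("topological overlap handles cliques, bridges and leaf-leaf edges", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- as.character(1:3)
  expect_equal(unname(scoreMap(topologicalOverlap(tri))), rep(1, 3))

  lone <- igraph::make_graph(c("a", "b"), directed = FALSE)
  expect_equal(unname(scoreMap(topologicalOverlap(lone))), 0)  # 0/0 -> 0

  b3 <- generateBarbell(3)
  s <- scoreMap(topologicalOverlap(b3))
  expect_equal(unname(s["3 4"]), 0)   # no common neighbors across the bridge
})

test_that("ERW-Kpath walks are seeded, bounded and symmetric", {
  lone <- igraph::make_graph(c("a", "b"), directed = FALSE)
  expect_equal(unname(scoreMap(erwKpath(lone, k = 1, rho = 200, seed = 1))), 1)

  path3 <- igraph::make_graph(c("a", "b", "b", "c"), directed = FALSE)
  rho <- 4000
  s <- scoreMap(erwKpath(path3, k = 20, rho = rho, seed = 2))
  ## both edges estimate the same traversal probability; 3 sigma MC band
  phat <- mean(s)
  expect_lt(abs(s[["a b"]] - s[["b c"]]),
            3 * sqrt(2 * phat * (1 - phat) / rho) + 1e-9)

  t1 <- erwKpath(fixtureFig2(), k = 20, rho = 500, seed = 7)
  t2 <- erwKpath(fixtureFig2(), k = 20, rho = 500, seed = 7)
  expect_identical(edgeScores(t1), edgeScores(t2))
})

test_that("ERW-Kpath estimates tighten as the walk count grows", {
  path3 <- igraph::make_graph(c("a", "b", "b", "c"), directed = FALSE)
  spread <- function(rho) {
    ests <- vapply(1:8, function(s)
      scoreMap(erwKpath(path3, k = 20, rho = rho, seed = s))[["a b"]],
      numeric(1))
    stats::sd(ests)
  }
  ## sd ~ 1/sqrt(rho): a 16x larger sample should shrink sd roughly 4x
  expect_lt(spread(1600), spread(100))
})

test_that("the method dispatcher validates names and forwards parameters", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- as.character(1:3)
  expect_equal(unname(scoreMap(scoreMethod(tri, "degree_product"))),
               rep(4, 3))
  expect_error(scoreMethod(tri, "pagerank"), "valid methods")

  k1 <- scoreMethod(fixtureFig2(), "kpath", k = 20, rho = 300, seed = 1)
  k2 <- scoreMethod(fixtureFig2(), "kpath", k = 20, rho = 300, seed = 1)
  expect_identical(edgeScores(k1), edgeScores(k2))
  expect_equal(scoreParams(k1)$rho, 300)
})

test_that("all indices are nonnegative and endpoint-symmetric by table shape", {
  g <- randomConnectedGraph(9, 0.4, seed = 55)
  for (m in c("betweenness", "degree_product", "bridgeness", "diffusion",
              "overlap")) {
    tab <- scoreMethod(g, m)
    sc <- edgeScores(tab)
    expect_equal(nrow(sc), igraph::ecount(g))
    expect_true(all(sc$score >= 0))
    expect_setequal(edgeKey(sc),
                    paste(pmin(igraph::as_edgelist(g)[, 1],
                               igraph::as_edgelist(g)[, 2]),
                          pmax(igraph::as_edgelist(g)[, 1],
                               igraph::as_edgelist(g)[, 2])))
  }
})
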