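test_that("edge-list loading merges duplicates and drops self-loops", {
  f <- writeTempEdgeList(c("A\tB", "B\tA", "B\tC"))
  net <- suppressMessages(loadEdgeList(f))
  expect_equal(networkSize(net), 3L)
  expect_equal(networkEdgeCount(net), 2L)

  # self-loop: edge dropped, node retained
  f2 <- writeTempEdgeList(c("A\tA", "A\tB"))
  net2 <- suppressMessages(loadEdgeList(f2))
  expect_setequal(proteins(net2), c("A", "B"))
  expect_equal(networkEdgeCount(net2), 1L)
  expect_equal(net2@metadata$selfLoopsRemoved, 1L)
})

test_that("identifier mapping collapses nodes and re-merges edges", {
  f <- writeTempEdgeList(c("1\t2", "2\t3"))
  net <- suppressMessages(loadEdgeList(f, idMap = c("1" = "A", "2" = "B", "3" = "A")))
  expect_setequal(proteins(net), c("A", "B"))
  expect_equal(networkEdgeCount(net), 1L)

  # unmapped ids are dropped with a count
  net2 <- suppressMessages(loadEdgeList(f, idMap = c("1" = "A", "2" = "B")))
  expect_equal(net2@metadata$unmappedRows, 1L)
  expect_equal(networkEdgeCount(net2), 1L)
})

test_that("malformed rows are rejected with their line number", {
  f <- writeTempEdgeList(c("# comment", "A\tB", "A\tB\tC"))
  expect_error(loadEdgeList(f), "line 3")
  f2 <- writeTempEdgeList("# only a comment")
  expect_error(loadEdgeList(f2), "no data rows")
})

test_that("write + reload of the normalized edge list is idempotent", {
  net <- randomNet(25, p = 0.2, seed = 11)
  f <- tempfile(fileext = ".tsv")
  writeEdgeList(net, f)
  net2 <- suppressMessages(loadEdgeList(f))
  f2 <- tempfile(fileext = ".tsv")
  writeEdgeList(net2, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_setequal(proteins(net2), proteins(net))
  expect_equal(networkEdgeCount(net2), networkEdgeCount(net))
})

test_that("BFS shortest paths match the Floyd-Warshall oracle on random graphs", {
  for (s in 1:30) {
    n <- sample(5:30, 1)
    ed <- randomEdgeTable(n, p = 0.12, seed = 100 + s)
    net <- InteractionNetwork(ed)
    nodes <- proteins(net)
    got <- shortestPathLengths(net, nodes, nodes)
    want <- oracleFloydWarshall(nodes, ed)[nodes, nodes]
    expect_identical(got, want)
  }
})

test_that("shortest paths honour identity, path graphs and input contracts", {
  net <- makePathNet(c("A", "B", "C", "D"))
  expect_equal(shortestPathLengths(net, "A", "D")[1, 1], 3)
  expect_equal(shortestPathLengths(net, "B", "B")[1, 1], 0)
  expect_error(shortestPathLengths(net, character(0), "A"), "nonempty")
  expect_error(shortestPathLengths(net, "Z", "A"), "not in network")
  # unreachable pairs carry the explicit Inf marker
  net2 <- InteractionNetwork(data.frame(a = c("A", "X"), b = c("B", "Y")))
  expect_identical(shortestPathLengths(net2, "A", "Y")[1, 1], Inf)
})

test_that("neighborsOf returns the union of adjacency lists", {
  net <- makePathNet(c("A", "B", "C"))
  expect_setequal(neighborsOf(net, "B"), c("A", "C"))
  star <- makeStarNet(5)
  expect_setequal(neighborsOf(star, "hub"), sprintf("l%d", 1:5))
  expect_identical(neighborsOf(net, character(0)), character(0))
  # isolated node (self-loop survivor) has no neighbors
  iso <- InteractionNetwork(
    igraph::simplify(igraph::graph_from_data_frame(
      data.frame(a = c("A", "B"), b = c("A", "C")), directed = FALSE
    ))
  )
  expect_identical(neighborsOf(iso, "A"), character(0))
})

test_that("degree binning partitions nodes with every bin at least minBinSize", {
  cyc <- makeCycleNet(8)
  b1 <- buildDegreeBins(cyc, 1)
  expect_length(b1@bins, 1L)
  expect_setequal(b1@bins[[1]], proteins(cyc))

  # two well-populated, well-separated degree classes stay in distinct bins
  blocks <- lapply(1:20, function(i) {
    s <- sprintf("b%d_%d", i, 1:5)
    data.frame(a = s, b = c(s[-1], s[1])) # 5-cycles: degree 2
  })
  hubs <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(a = sprintf("HUB%d", i), b = sprintf("x%d_%d", i, 1:50)) # degree 50
  }))
  net <- InteractionNetwork(do.call(rbind, c(blocks, list(hubs))))
  bins <- buildDegreeBins(net, 10)
  deg <- degreeOf(net)
  binOfDeg2 <- unique(bins@binOf[names(deg)[deg == 2]])
  binOfDeg50 <- unique(bins@binOf[names(deg)[deg == 50]])
  expect_length(binOfDeg2, 1L)
  expect_length(binOfDeg50, 1L)
  expect_false(binOfDeg50 == binOfDeg2)

  # partition invariants on a random graph
  rn <- randomNet(60, p = 0.1, seed = 3)
  for (mbs in c(5, 15, networkSize(rn))) {
    bb <- buildDegreeBins(rn, mbs)
    expect_setequal(unlist(bb@bins), proteins(rn))
    expect_false(anyDuplicated(unlist(bb@bins)) > 0)
    expect_true(all(lengths(bb@bins) >= mbs))
  }
  expect_length(buildDegreeBins(rn, networkSize(rn))@bins, 1L)
  expect_error(buildDegreeBins(rn, networkSize(rn) + 1), "exceeds")
})

test_that("restrictToNetwork drops off-network members and errors when empty", {
  net <- makePathNet(c("A", "B"))
  S <- WeightedProteinSet(c(A = 0.5, X = 0.9))
  r <- suppressMessages(restrictToNetwork(net, S))
  expect_identical(proteinWeights(r), c(A = 0.5))
  expect_equal(r@metadata$nDropped, 1L)

  inside <- WeightedProteinSet(c(A = 0.5, B = 1))
  expect_identical(proteinWeights(restrictToNetwork(net, inside)), proteinWeights(inside))
  expect_error(restrictToNetwork(net, WeightedProteinSet(c(Z = 1))), "metrics undefined")
})

test_that("network and weighted-set validity contracts hold", {
  expect_error(WeightedProteinSet(c(A = 0)), "0, 1")
  expect_error(WeightedProteinSet(c(A = 1.2)), "0, 1")
  expect_error(WeightedProteinSet(stats::setNames(0.5, "")), "named")
  expect_error(InteractionNetwork(data.frame(a = "A", b = "B", c = "C")), "2 columns")
  expect_error(InteractionNetwork(data.frame(a = character(0), b = character(0))), "empty")
})
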