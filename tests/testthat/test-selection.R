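sevenNetAtlas <- function() syntheticAtlas(100, seed = 1)

test_that("network selection enumeration yields 1 + m + C(m,2) + m + m masks", {
  at <- sevenNetAtlas()
  sels <- enumerateNetworkSelections(at)
  expect_length(sels, 43)
  expect_length(grep("^between:", names(sels)), 21)
  # two-network atlas: 8 selections
  at2 <- NodeAtlas(rep(c("A", "B"), each = 5))
  expect_length(enumerateNetworkSelections(at2), 8)
})

test_that("within/between masks partition the whole-brain mask", {
  at <- sevenNetAtlas()
  sels <- enumerateNetworkSelections(at)
  parts <- sels[grep("^(within|between):", names(sels))]
  total <- Reduce(`+`, lapply(parts, selectionMask))
  expect_true(all(total == 1))   # disjoint cover
  expect_equal(sum(vapply(parts, selectionSize, numeric(1))),
               nEdges(at))
})

test_that("within/between edge counts follow the membership arithmetic", {
  at <- NodeAtlas(rep(c("A", "B", "C"), times = c(10, 15, 5)))
  expect_equal(selectionSize(withinNetworkEdges("A", at)), 45)
  expect_equal(selectionSize(betweenNetworkEdges("A", "B", at)), 150)
  expect_error(betweenNetworkEdges("A", "A", at), "distinct")
})

test_that("excluding a network removes exactly the edges touching it", {
  at <- sevenNetAtlas()
  sels <- enumerateNetworkSelections(at)
  net <- sort(unique(networks(at)))[1]
  excl <- selectionMask(sels[[paste0("exclude:", net)]])
  netAll <- selectionMask(sels[[paste0("network_all:", net)]])
  whole <- selectionMask(sels$whole_brain)
  expect_true(all(xor(excl, netAll) == whole))
  expect_equal(sum(netAll),
               sum(whole) - nConnections(sum(networks(at) != net)))
})

test_that("theory selection maps coordinates to nearest nodes", {
  at <- syntheticAtlas(50, seed = 2)
  cen <- centroids(at)
  # coordinate exactly at a node centroid selects that node
  sel1 <- theorySelection(cen[7, , drop = FALSE], at, name = "one")
  expect_identical(attr(sel1, "nodes"), 7L)
  expect_equal(selectionSize(sel1), 0)   # a single node has no edges
  # 8 distinct coordinates near 8 distinct nodes: C(8,2) = 28 edges
  idx <- c(2L, 5L, 9L, 14L, 20L, 31L, 40L, 47L)
  sel8 <- theorySelection(cen[idx, ] + 0.01, at, name = "P-FIT")
  expect_identical(attr(sel8, "nodes"), idx)
  expect_equal(selectionSize(sel8), 28)
  expect_match(provenance(sel8), "theory:P-FIT")
  # duplicate nearest node is deduplicated
  dup <- theorySelection(rbind(cen[3, ], cen[3, ] + 0.01), at)
  expect_identical(attr(dup, "nodes"), 3L)
  # exact tie resolved towards the lowest node id
  atTie <- NodeAtlas(rep("A", 4),
                     centroids = rbind(c(0, 0, 0), c(2, 0, 0),
                                       c(0, 2, 0), c(0, 0, 2)))
  expect_message(selT <- theorySelection(matrix(c(1, 0, 0), 1), atTie),
                 "tie")
  expect_identical(attr(selT, "nodes"), 1L)
})

test_that("random selections are uniform, sized correctly, seed-stable", {
  at <- syntheticAtlas(30, seed = 3)
  s1 <- randomEdgeSelection(40, at, seed = 5)
  s2 <- randomEdgeSelection(40, at, seed = 5)
  expect_identical(selectionMask(s1), selectionMask(s2))
  expect_equal(selectionSize(s1), 40)
  expect_identical(selectionMask(randomEdgeSelection(nEdges(at), at, 1)),
                   selectionMask(wholeBrainSelection(at)))
  sn <- randomNodeSelection(10, at, seed = 6)
  expect_equal(selectionSize(sn), 45)
  expect_error(randomEdgeSelection(nEdges(at) + 1, at, 1), "out of range")
  expect_error(randomNodeSelection(31, at, 1), "out of range")
})

test_that("top-k selection ranks by magnitude with index tie-breaks", {
  rel <- c(0.1, -0.9, 0.5, 0.05, -0.5, 0.2, 0, 0.3, -0.05, 0.45)
  rm_ <- RelevanceMap(relevance = rel)
  expect_identical(which(selectionMask(topKSelection(rm_, 3))),
                   sort(c(2L, 3L, 5L)))  # |.| = 0.9, 0.5, 0.5
  expect_identical(which(selectionMask(topKSelection(rm_, 1))), 2L)
  expect_equal(selectionSize(topKSelection(rm_, 10)), 10)
  expect_error(topKSelection(rm_, 11), "exceeds")
  # signed ranking option
  expect_identical(which(selectionMask(topKSelection(rm_, 2,
                                                     by = "signed"))),
                   sort(c(3L, 10L)))
})

test_that("selections serialize round-trip through JSON", {
  at <- syntheticAtlas(20, seed = 4)
  sel <- randomEdgeSelection(15, at, seed = 9)
  path <- tempfile(fileext = ".json")
  writeSelection(sel, path)
  back <- readSelection(path)
  expect_identical(selectionMask(back), selectionMask(sel))
  expect_identical(provenance(back), provenance(sel))
})

test_that("node count for a matched edge budget is minimal", {
  expect_identical(nodesForEdgeCount(45), 10L)
  expect_identical(nodesForEdgeCount(190), 20L)
  expect_identical(nodesForEdgeCount(46), 11L)
})
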