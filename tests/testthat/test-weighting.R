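test_that("toy-network similarities reproduce the hand-worked rationals", {
  net <- toy_ppi_network()
  expect_equal(jaccard_similarity(net, "b", "d"), 2 / 9)
  expect_equal(jaccard_similarity(net, "b", "a"), 1 / 8)
  expect_equal(jaccard_similarity(net, "a", "d"), 1 / 9)
  expect_equal(jaccard_similarity(net, "b", "c"), 2 / 7)
  expect_equal(jaccard_similarity(net, "c", "d"), 2 / 8)
  expect_equal(common_neighbor_support(net, "b", "d"), 1 / 72 + 4 / 56)
  expect_equal(hocn_weight(net, "b", "d"), (2 / 9 + 1 / 72 + 4 / 56) / 3)
})

test_that("similarity is zero for disjoint neighbourhoods and errors on bad input", {
  net <- tibble::tibble(from = c("a", "c"), to = c("b", "d"))
  expect_equal(jaccard_similarity(net, "a", "c"), 0)
  expect_equal(common_neighbor_support(net, "a", "c"), 0)
  expect_error(jaccard_similarity(net, "a", "zz"), "unknown vertex")
  expect_error(hocn_weight(net, "a", "c"), "not an edge")
})

test_that("an unsupported edge is flagged unreliable and filtered", {
  # path a-b-c: no edge has a common neighbour
  net <- tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  expect_true(is.na(hocn_weight(net, "a", "b")))
  w <- weight_edges(net)
  expect_equal(nrow(w), 0)
  expect_setequal(attr(w, "vertices"), c("a", "b", "c")) # vertices preserved

  # pure star: every edge is discarded
  star <- tibble::tibble(from = rep("hub", 5), to = paste0("leaf", 1:5))
  expect_equal(nrow(weight_edges(star)), 0)
})

test_that("triangles keep all edges with the closed-form weight", {
  tri <- tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "c"))
  w <- weight_edges(tri)
  expect_equal(nrow(w), 3)
  # each edge: JCS = 1/3, CNS = (1/3)^2, |CN| = 1
  expect_equal(w$hocn, rep((1 / 3 + 1 / 9) / 2, 3))
})

test_that("HOCN is symmetric and bounded on random graphs", {
  withr::local_seed(11)
  for (rep in 1:20) {
    net <- random_edge_tbl(sample(5:10, 1), 0.5)
    if (!nrow(net)) next
    k <- sample(nrow(net), 1)
    expect_equal(hocn_weight(net, net$from[k], net$to[k]),
                 hocn_weight(net, net$to[k], net$from[k]))
    w <- weight_edges(net)
    expect_true(all(w$hocn > 0 & w$hocn <= 1))
  }
})

test_that("weighting matches the brute-force oracle on random graphs", {
  withr::local_seed(12)
  for (rep in 1:50) {
    net <- random_edge_tbl(sample(4:10, 1), stats::runif(1, 0.2, 0.7))
    w <- weight_edges(net)
    w <- w[order(w$from, w$to), ]
    o <- oracle_weight_network(net)
    expect_equal(w$from, o$from)
    expect_equal(w$to, o$to)
    expect_equal(w$hocn, o$hocn, tolerance = 1e-12)
  }
})

test_that("edits outside the involved neighbourhoods leave HOCN unchanged", {
  net <- toy_ppi_network()
  # edge (f, g) touches neither {b, d} nor CN(b, d) = {a, c} nor their
  # neighbourhoods' defining sets for the (b, d) terms
  before <- hocn_weight(net, "b", "d")
  after <- hocn_weight(dplyr::bind_rows(net, tibble::tibble(from = "f", to = "g")),
                       "b", "d")
  expect_equal(before, after)
})
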