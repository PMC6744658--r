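weighted_toy <- function() weight_edges(toy_ppi_network())

test_that("structural neighbourhood is the closed neighbourhood of the filtered net", {
  w <- weighted_toy()
  g_adj <- split(c(w$to, w$from), c(w$from, w$to))
  for (v in c("b", "d")) {
    expect_setequal(structural_neighborhood(w, v),
                    c(v, unique(g_adj[[v]])))
  }
  # |SN(v)| = degree + 1
  expect_length(structural_neighborhood(w, "b"),
                sum(w$from == "b" | w$to == "b") + 1)
  # vertex isolated by filtering keeps SN = {v}
  star <- weight_edges(tibble::tibble(from = rep("h", 3), to = c("x", "y", "z")))
  expect_equal(structural_neighborhood(star, "h"), "h")
})

test_that("structural similarity is symmetric, bounded and matches the oracle", {
  withr::local_seed(21)
  for (rep in 1:20) {
    net <- random_edge_tbl(10, 0.4)
    w <- weight_edges(net)
    A <- oracle_adj(w, attr(w, "vertices"))
    verts <- rownames(A)
    pairs <- utils::combn(verts, 2)[, sample(choose(length(verts), 2), 8)]
    for (k in seq_len(ncol(pairs))) {
      v <- pairs[1, k]; u <- pairs[2, k]
      s <- structural_similarity(w, v, u)
      expect_equal(s, structural_similarity(w, u, v))
      expect_gte(s, 0); expect_lte(s, 1)
      expect_equal(s, oracle_ss(A, v, u), tolerance = 1e-12)
    }
    expect_equal(structural_similarity(w, verts[1], verts[1]), 1)
  }
})

test_that("an isolated clique yields a single full core", {
  clique <- tibble::tibble(
    from = c("a", "a", "a", "b", "b", "c"),
    to = c("b", "c", "d", "c", "d", "d")
  )
  cores <- detect_cores(weight_edges(clique), ss = 0.4)
  expect_length(unique(cores$core), 1)
  expect_setequal(cores$member, c("a", "b", "c", "d"))
  # every pair in an isolated clique has SS = 1, so even ss = 1 keeps it
  cores1 <- detect_cores(weight_edges(clique), ss = 1)
  expect_setequal(cores1$member, c("a", "b", "c", "d"))
})

test_that("core list is deduplicated, seed-containing and seed-adjacent", {
  withr::local_seed(22)
  net <- random_edge_tbl(12, 0.4)
  w <- weight_edges(net)
  cores <- detect_cores(w, ss = 0.3)
  keys <- vapply(split(cores$member, cores$core),
                 function(m) paste(sort(m), collapse = ","), character(1))
  expect_false(any(duplicated(keys)))
  adj <- split(c(w$to, w$from), c(w$from, w$to))
  for (cid in unique(cores$core)) {
    rows <- cores[cores$core == cid, ]
    seed <- rows$seed[1]
    expect_true(seed %in% rows$member)
    expect_gte(nrow(rows), 2)
    expect_true(all(setdiff(rows$member, seed) %in% adj[[seed]]))
  }
})

test_that("raising ss never grows any seed's core", {
  withr::local_seed(23)
  net <- random_edge_tbl(10, 0.5)
  w <- weight_edges(net)
  verts <- attr(w, "vertices")
  adj <- split(c(w$to, w$from), c(w$from, w$to))
  for (v in verts) {
    prev <- NULL
    for (s in c(0.2, 0.4, 0.6, 0.8)) {
      nb <- unique(adj[[v]])
      memb <- c(v, nb[vapply(nb, function(u)
        structural_similarity(w, v, u) >= s, logical(1))])
      if (!is.null(prev)) expect_true(all(memb %in% prev))
      prev <- memb
    }
  }
})

test_that("degenerate inputs are handled", {
  w <- weighted_toy()
  expect_error(detect_cores(w, ss = 0), "0, 1")
  expect_error(detect_cores(w, ss = 1.2), "0, 1")
  # threshold no pair can reach (max SS on the weighted toy net is 0.8)
  expect_equal(nrow(detect_cores(w, ss = 0.999)), 0)
})
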