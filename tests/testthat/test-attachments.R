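# Small hand-built weighted networks: classification rules are pure
# arithmetic on the hocn column, so fixtures can set weights directly.

core2 <- function(members, seed = members[1]) {
  tibble::tibble(core = 1L, seed = seed, member = members)
}

test_that("core average weighted degree follows its definition", {
  w <- tibble::tibble(from = c("a", "x"), to = c("b", "y"),
                      hocn = c(0.6, 0.1))
  expect_equal(core_weight_avg(w, core2(c("a", "b")))$weight_avg, 0.6)
  # core with no internal edge
  expect_equal(core_weight_avg(w, core2(c("a", "y")))$weight_avg, 0)
})

test_that("candidates need at least two core neighbours; weights partition in/out", {
  w <- tibble::tibble(
    from = c("a", "a", "b", "p", "p", "p", "q"),
    to   = c("b", "c", "c", "a", "b", "z", "a"),
    hocn = c(0.5, 0.5, 0.5, 0.3, 0.2, 0.4, 0.9)
  )
  cap <- candidate_attachments(w, core2(c("a", "b", "c")))
  expect_equal(cap$member, "p") # q touches only one core member
  expect_equal(cap$weight_in, 0.5)
  expect_equal(cap$weight_out, 0.4)
})

test_that("overlapping rule: both boundaries inclusive, in-pull may not dominate", {
  core <- core2(c("a", "b"))
  # weight_avg = w(a,b) = 0.8 -> half = 0.4
  base <- tibble::tibble(from = "a", to = "b", hocn = 0.8)
  # p: weight_in exactly half the core average, weight_out exactly equal
  w1 <- dplyr::bind_rows(base, tibble::tibble(
    from = c("p", "p", "p"), to = c("a", "b", "z"),
    hocn = c(0.2, 0.2, 0.4)
  ))
  res <- classify_attachments(w1, core)
  expect_equal(res$role[res$member == "p"], "overlapping")
  # strong in-pull fails the overlapping rule but peripheral catches it
  w2 <- dplyr::bind_rows(base, tibble::tibble(
    from = c("p", "p", "p"), to = c("a", "b", "z"),
    hocn = c(0.4, 0.2, 0.2)
  ))
  res2 <- classify_attachments(w2, core)
  expect_equal(res2$role[res2$member == "p"], "peripheral")
})

test_that("peripheral rule: strict in-dominance and at-least-average in-weight", {
  core <- core2(c("a", "b", "c"))
  base <- tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "c"),
                         hocn = c(0.3, 0.3, 0.3))
  # two candidates, in-weights 0.9 and 0.1: only the 0.9 one reaches the mean
  w <- dplyr::bind_rows(base, tibble::tibble(
    from = c("p", "p", "q", "q"),
    to = c("a", "b", "a", "b"),
    hocn = c(0.5, 0.4, 0.06, 0.04)
  ))
  res <- classify_attachments(w, core)
  expect_equal(res$member[res$role == "peripheral"], "p")
  expect_false("q" %in% res$member)

  # a singleton candidate-peripheral set equals its own mean
  w1 <- dplyr::bind_rows(base, tibble::tibble(
    from = c("p", "p"), to = c("a", "b"), hocn = c(0.5, 0.4)
  ))
  res1 <- classify_attachments(w1, core)
  expect_equal(res1$role, "peripheral")
})

test_that("classification is invariant to rescaling all weights", {
  withr::local_seed(31)
  net <- random_edge_tbl(10, 0.5)
  w <- weight_edges(net)
  cores <- detect_cores(w, ss = 0.3)
  res <- classify_attachments(w, cores)
  w2 <- dplyr::mutate(w, hocn = hocn * 7.3)
  attr(w2, "vertices") <- attr(w, "vertices")
  res2 <- classify_attachments(w2, cores)
  expect_equal(res[, c("core", "member", "role")],
               res2[, c("core", "member", "role")])
})

test_that("attachment results satisfy their structural invariants", {
  withr::local_seed(32)
  for (rep in 1:10) {
    net <- random_edge_tbl(sample(8:12, 1), 0.45)
    w <- weight_edges(net)
    cores <- detect_cores(w, ss = 0.3)
    cap <- candidate_attachments(w, cores)
    res <- classify_attachments(w, cores)
    for (cid in unique(cores$core)) {
      members <- cores$member[cores$core == cid]
      cap_c <- cap$member[cap$core == cid]
      expect_length(intersect(cap_c, members), 0)
      roles <- res[res$core == cid, ]
      expect_true(all(roles$member %in% cap_c))
      expect_false(any(duplicated(roles$member)))
    }
  }
})

test_that("attachment classification matches the brute-force oracle", {
  withr::local_seed(33)
  for (rep in 1:30) {
    net <- random_edge_tbl(sample(6:11, 1), 0.5)
    w <- weight_edges(net)
    cores <- detect_cores(w, ss = 0.3)
    if (!nrow(cores)) next
    W <- oracle_weight_matrix(w, attr(w, "vertices"))
    res <- classify_attachments(w, cores)
    avg <- core_weight_avg(w, cores)
    cap <- candidate_attachments(w, cores)
    for (cid in unique(cores$core)) {
      o <- oracle_attach_one(W, cores$member[cores$core == cid])
      expect_setequal(cap$member[cap$core == cid], o$cap)
      expect_equal(avg$weight_avg[avg$core == cid], o$weight_avg,
                   tolerance = 1e-12)
      expect_setequal(res$member[res$core == cid & res$role == "overlapping"],
                      o$overlapping)
      expect_setequal(res$member[res$core == cid & res$role == "peripheral"],
                      o$peripheral)
    }
  }
})
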