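#' Toy 11-protein network for the weighting walk-through
#'
#' A small hypothetical PPI network of 11 proteins used throughout the
#' documentation and tests to illustrate the HOCN weighting scheme by hand.
#' Its adjacency gives the textbook intermediate values
#' `JCS(b,d) = 2/9`, `JCS(b,a) = 1/8`, `JCS(a,d) = 1/9`, `JCS(b,c) = 2/7`,
#' `JCS(c,d) = 2/8`, and hence an HOCN weight for the edge `(b, d)` of
#' `(2/9 + 1/72 + 4/56) / 3 = 0.1025...` (0.102 at three displayed decimals).
#'
#' The 14 edges listed here are exactly the adjacency those values pin down;
#' the hypothetical network this example is drawn from has one further edge
#' among the fringe vertices `{e, f, g, h, k, r, s}` whose placement cannot
#' be recovered from the printed neighbour sets and which cannot affect any
#' quantity of the walk-through (all terms involve only the neighbourhoods
#' of `a`, `b`, `c`, `d`), so it is deliberately omitted rather than guessed.
#'
#' @return An edge tibble with columns `from` and `to` (11 vertices,
#'   14 edges).
#' @examples
#' net <- toy_ppi_network()
#' jaccard_similarity(net, "b", "d")
#' hocn_weight(net, "b", "d")
#' @export
toy_ppi_network <- function() {
  tibble::tibble(
    from = c("a", "a", "a", "a", "b", "b", "b", "b", "c", "c", "c",
             "d", "d", "d"),
    to = c("b", "d", "h", "r", "c", "d", "k", "s", "d", "e", "k",
           "e", "f", "g")
  )
}
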