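# Reliability weighting of PPI edges.
#
# High-throughput interaction data carries many false positives, so before
# any clustering the network is re-weighted from its own topology: an edge is
# trusted in proportion to how strongly the neighbourhoods of its endpoints,
# and of their common neighbours, agree. Edges whose endpoints share no
# common neighbour at all are treated as unreliable and removed.

# JCS/CNS/HOCN on the integer graph structure; `i`, `j` are vertex ids.
jcs_ij <- function(g, i, j) {
  cn <- length(intersect(g$adj[[i]], g$adj[[j]]))
  if (cn < 1) return(0)
  cn / length(union(g$adj[[i]], g$adj[[j]]))
}

cns_ij <- function(g, i, j) {
  cn <- intersect(g$adj[[i]], g$adj[[j]])
  if (!length(cn)) return(0)
  sum(vapply(cn, function(w) jcs_ij(g, i, w) * jcs_ij(g, w, j), numeric(1)))
}

hocn_ij <- function(g, i, j) {
  cn <- length(intersect(g$adj[[i]], g$adj[[j]]))
  if (cn < 1) return(NA_real_)
  (jcs_ij(g, i, j) + cns_ij(g, i, j)) / (cn + 1)
}

#' Jaccard coefficient similarity between two proteins
#'
#' The Jaccard coefficient similarity (JCS) between proteins `v` and `u` is
#' the number of their common neighbours divided by the size of the union of
#' their (open) neighbourhoods, and 0 when they share no common neighbour.
#' When `v` and `u` are adjacent, each endpoint belongs to the other's
#' neighbourhood and so counts in the union — this is what makes the
#' worked-example values below come out as printed.
#'
#' @param edges A PPI edge tibble with columns `from` and `to` (see
#'   [read_ppi_edges()]).
#' @param v,u Protein identifiers; must be vertices of the network.
#' @return A number in `[0, 1]`.
#' @examples
#' net <- toy_ppi_network()
#' jaccard_similarity(net, "b", "d") # 2/9
#' jaccard_similarity(net, "b", "a") # 1/8
#' @export
jaccard_similarity <- function(edges, v, u) {
  check_edge_frame(edges)
  g <- edge_graph(edges)
  jcs_ij(g, vertex_id(g, v, "v"), vertex_id(g, u, "u"))
}

#' Common-neighbour support for a protein pair
#'
#' The common-neighbour support (CNS) of a pair `(v, u)` sums, over every
#' common neighbour `w`, the product `JCS(v, w) * JCS(w, u)`: each shared
#' partner "vouches" for the interaction in proportion to how similar it is
#' to both endpoints. Pairs without common neighbours score 0.
#'
#' @inheritParams jaccard_similarity
#' @return A non-negative number.
#' @examples
#' net <- toy_ppi_network()
#' common_neighbor_support(net, "b", "d") # 1/72 + 4/56
#' @export
common_neighbor_support <- function(edges, v, u) {
  check_edge_frame(edges)
  g <- edge_graph(edges)
  cns_ij(g, vertex_id(g, v, "v"), vertex_id(g, u, "u"))
}

#' High-order common-neighbour (HOCN) weight of an edge
#'
#' The HOCN reliability weight of an edge `(v, u)` is
#' `(JCS(v, u) + CNS(v, u)) / (|CN(v, u)| + 1)`, where `CN(v, u)` is the set
#' of common neighbours. When the endpoints share no common neighbour the
#' edge is considered unreliable and the weight is `NA`; [weight_edges()]
#' discards such edges.
#'
#' @inheritParams jaccard_similarity
#' @param v,u Protein identifiers; `(v, u)` must be an edge of the network.
#' @return A number in `(0, 1]`, or `NA` for an unsupported edge.
#' @examples
#' net <- toy_ppi_network()
#' hocn_weight(net, "b", "d") # ~0.1025, printed as 0.102
#' @export
hocn_weight <- function(edges, v, u) {
  check_edge_frame(edges)
  g <- edge_graph(edges)
  i <- vertex_id(g, v, "v")
  j <- vertex_id(g, u, "u")
  if (!j %in% g$adj[[i]]) {
    stop("(", v, ", ", u, ") is not an edge of the network", call. = FALSE)
  }
  hocn_ij(g, i, j)
}

#' Weight a PPI network and filter unreliable edges
#'
#' Computes the HOCN reliability weight of every edge from the *original*
#' neighbourhoods (a single pass — removals do not cascade) and drops edges
#' whose endpoints share no common neighbour. Vertices are never removed:
#' proteins isolated by the filter simply cannot enter any complex.
#'
#' @inheritParams jaccard_similarity
#' @return A tibble with columns `from`, `to` and `hocn`, carrying the
#'   retained edges. The full vertex set of the input network is kept in
#'   `attr(, "vertices")` and the input edge count in `attr(, "n_input_edges")`.
#' @examples
#' toy_ppi_network() |> weight_edges()
#' @export
weight_edges <- function(edges) {
  check_edge_frame(edges)
  g <- edge_graph(edges)
  w <- vapply(seq_along(g$from), function(k) hocn_ij(g, g$from[k], g$to[k]),
              numeric(1))
  keep <- !is.na(w)
  out <- tibble::tibble(
    from = g$vertices[g$from[keep]],
    to = g$vertices[g$to[keep]],
    hocn = w[keep]
  )
  attr(out, "vertices") <- g$vertices
  attr(out, "n_input_edges") <- length(g$from)
  out
}

# Vertex universe of a weighted edge table: the preserved attribute when
# present, otherwise the edge endpoints.
weighted_vertices <- function(weighted) {
  v <- attr(weighted, "vertices")
  if (is.null(v)) {
    v <- sort(unique(c(as.character(weighted$from), as.character(weighted$to))))
  }
  v
}
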