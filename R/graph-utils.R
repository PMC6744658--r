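# Internal helpers shared by the weighting / core / attachment stages.
# Vertices are mapped to integer ids once; all set arithmetic downstream is
# on sorted integer vectors, which keeps the hot loops allocation-light.

# Build an integer adjacency structure from an edge tibble.
# `extra_vertices` lets callers preserve vertices that lost all their edges
# (HOCN filtering never removes a protein from the network, only edges).
edge_graph <- function(edges, extra_vertices = character()) {
  from <- as.character(edges[["from"]])
  to <- as.character(edges[["to"]])
  verts <- sort(unique(c(from, to, as.character(extra_vertices))))
  from_i <- match(from, verts)
  to_i <- match(to, verts)
  adj <- rep(list(integer()), length(verts))
  if (length(from_i)) {
    ends <- c(from_i, to_i)
    other <- c(to_i, from_i)
    sp <- split(other, ends)
    adj[as.integer(names(sp))] <- lapply(sp, function(x) sort.int(unique(x)))
  }
  list(vertices = verts, adj = adj, from = from_i, to = to_i)
}

vertex_id <- function(g, v, arg = "v") {
  i <- match(as.character(v), g$vertices)
  if (anyNA(i)) {
    stop("unknown vertex in `", arg, "`: ",
         paste(setdiff(as.character(v), g$vertices), collapse = ", "),
         call. = FALSE)
  }
  i
}

# Unordered-pair key for O(1) edge-weight lookup.
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "|")
}

# Weight lookup table (named numeric vector keyed by pair_key).
edge_weight_table <- function(g, weights) {
  stats::setNames(as.numeric(weights), pair_key(g$from, g$to))
}

check_edge_frame <- function(edges, weight_col = NULL) {
  if (!is.data.frame(edges)) {
    stop("`edges` must be a data frame with columns `from` and `to`",
         call. = FALSE)
  }
  missing <- setdiff(c("from", "to", weight_col), names(edges))
  if (length(missing)) {
    stop("`edges` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(edges)
}

# Accept complexes as a `complex`/`member` tibble or a list of character
# vectors; return a plain list of unique member vectors (file/list order).
as_complex_list <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    if (!all(c("complex", "member") %in% names(x))) {
      stop("`", arg, "` must have columns `complex` and `member`",
           call. = FALSE)
    }
    ids <- x[["complex"]]
    split_ids <- factor(as.character(ids), levels = unique(as.character(ids)))
    out <- lapply(split(as.character(x[["member"]]), split_ids), unique)
    names(out) <- levels(split_ids)
    out
  } else if (is.list(x)) {
    out <- lapply(x, function(m) unique(as.character(m)))
    if (is.null(names(out)) && length(out)) {
      names(out) <- as.character(seq_along(out))
    }
    out
  } else {
    stop("`", arg, "` must be a data frame or a list of member vectors",
         call. = FALSE)
  }
}

complex_tibble <- function(members, roles = NULL, ids = NULL) {
  n <- lengths(members)
  if (is.null(ids)) ids <- seq_along(members)
  out <- tibble::tibble(
    complex = rep(ids, n),
    member = as.character(unlist(members, use.names = FALSE))
  )
  if (!is.null(roles)) {
    out$role <- as.character(unlist(roles, use.names = FALSE))
  }
  out
}
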