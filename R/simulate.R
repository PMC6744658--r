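#' Simulate a PPI network with planted core-attachment complexes
#'
#' Generates a sparse undirected network containing vertex-disjoint dense
#' cores, each dressed with peripheral proteins (attached to a majority of
#' one core), overlapping proteins (attached to a majority of two cores, so
#' their pull out of each core exceeds their pull into it), free background
#' vertices, and uniform noise edges. The planted assignment is returned as
#' ground truth, which makes the generator the oracle for end-to-end tests
#' of the detection pipeline.
#'
#' Structure emulated: complexes are internally dense but sparsely connected
#' to the rest of the network, the accepted modularity picture of protein
#' complexes. Peripheral proteins touch `ceil(0.6 k)` members of their core
#' (at least 2), overlapping proteins `ceil(0.8 k)` members of each of two
#' cores (at least 2) — strong enough attachment that their weighted degree
#' into a core is commensurate with the core's own average weighted degree,
#' as in the core-attachment model where attachments sit at complex
#' interfaces.
#'
#' @param n_complexes Number of planted complexes.
#' @param core_size Length-2 integer range of core sizes (inclusive).
#' @param p_core Probability of each core-internal edge (dense: >= 0.8).
#' @param n_peripheral Total number of peripheral proteins, dealt round-robin
#'   to the complexes.
#' @param n_overlap Number of overlapping proteins; each is shared by two
#'   cores. Requires `n_complexes >= 2` when positive.
#' @param n_background Number of free background vertices.
#' @param p_noise Probability of a noise edge between any unconnected pair
#'   not internal to a core.
#' @param seed Integer seed; the generator is fully reproducible from it and
#'   leaves the global RNG state untouched.
#' @return A list of class `planted_ppi` with elements `edges` (edge tibble)
#'   and `truth` (tibble `complex`, `member`, `role` with roles `core`,
#'   `peripheral`, `overlapping`; overlapping members appear under both of
#'   their complexes).
#' @examples
#' sim <- simulate_ppi(seed = 42)
#' dplyr::count(sim$truth, role)
#' @export
simulate_ppi <- function(n_complexes = 5, core_size = c(4L, 8L), p_core = 0.9,
                         n_peripheral = 10, n_overlap = 3, n_background = 20,
                         p_noise = 0.02, seed = NULL) {
  if (core_size[1] < 3) stop("core sizes must be >= 3", call. = FALSE)
  if (any(c(p_core, p_noise) < 0) || any(c(p_core, p_noise) > 1)) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  if (n_overlap > 0 && n_complexes < 2) {
    stop("overlapping proteins require at least two complexes", call. = FALSE)
  }
  if (!is.null(seed)) {
    withr::local_preserve_seed()
    set.seed(seed)
  }

  sizes <- sample(seq.int(core_size[1], core_size[2]), n_complexes,
                  replace = TRUE)
  core_members <- lapply(seq_len(n_complexes), function(i) {
    sprintf("c%d_%02d", i, seq_len(sizes[i]))
  })

  from <- character()
  to <- character()
  add_edges <- function(a, b) {
    from <<- c(from, a)
    to <<- c(to, b)
  }

  # dense cores: each internal pair with probability p_core
  for (cm in core_members) {
    pairs <- utils::combn(cm, 2)
    keep <- stats::runif(ncol(pairs)) < p_core
    add_edges(pairs[1, keep], pairs[2, keep])
  }

  # peripheral proteins: majority attachment to exactly one core
  truth_extra <- list()
  if (n_peripheral > 0) {
    host <- rep_len(seq_len(n_complexes), n_peripheral)
    for (i in seq_len(n_peripheral)) {
      id <- sprintf("per_%02d", i)
      cm <- core_members[[host[i]]]
      k <- max(2L, ceiling(0.6 * length(cm)))
      anchors <- sample(cm, k)
      add_edges(rep(id, k), anchors)
      truth_extra[[length(truth_extra) + 1]] <-
        tibble::tibble(complex = host[i], member = id, role = "peripheral")
    }
  }

  # overlapping proteins: majority attachment to two distinct cores
  if (n_overlap > 0) {
    for (i in seq_len(n_overlap)) {
      id <- sprintf("ovl_%02d", i)
      hosts <- sample(seq_len(n_complexes), 2)
      for (h in hosts) {
        cm <- core_members[[h]]
        k <- max(2L, ceiling(0.8 * length(cm)))
        anchors <- sample(cm, k)
        add_edges(rep(id, k), anchors)
        truth_extra[[length(truth_extra) + 1]] <-
          tibble::tibble(complex = h, member = id, role = "overlapping")
      }
    }
  }

  background <- if (n_background > 0) {
    sprintf("bg_%02d", seq_len(n_background))
  } else character()

  verts <- c(unlist(core_members, use.names = FALSE),
             if (n_peripheral > 0) sprintf("per_%02d", seq_len(n_peripheral)),
             if (n_overlap > 0) sprintf("ovl_%02d", seq_len(n_overlap)),
             background)

  # noise edges over pairs not already present and not core-internal
  if (p_noise > 0 && length(verts) > 1) {
    existing <- c(paste(pmin(from, to), pmax(from, to), sep = "\r"))
    intra <- unlist(lapply(core_members, function(cm) {
      pr <- utils::combn(cm, 2)
      paste(pmin(pr[1, ], pr[2, ]), pmax(pr[1, ], pr[2, ]), sep = "\r")
    }), use.names = FALSE)
    all_pairs <- utils::combn(sort(verts), 2)
    key <- paste(all_pairs[1, ], all_pairs[2, ], sep = "\r")
    open <- !(key %in% c(existing, intra))
    pick <- open & stats::runif(length(key)) < p_noise
    add_edges(all_pairs[1, pick], all_pairs[2, pick])
  }

  lo <- pmin(from, to)
  hi <- pmax(from, to)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  edges <- tibble::tibble(from = lo[!dup], to = hi[!dup])
  attr(edges, "vertices") <- sort(verts)

  truth_core <- tibble::tibble(
    complex = rep(seq_len(n_complexes), sizes),
    member = unlist(core_members, use.names = FALSE),
    role = "core"
  )
  truth <- dplyr::arrange(
    dplyr::bind_rows(truth_core, truth_extra),
    .data$complex, .data$role, .data$member
  )
  structure(list(edges = edges, truth = truth), class = "planted_ppi")
}
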