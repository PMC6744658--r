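# Attachment-protein detection.
#
# A candidate attachment protein must interact with at least two core members
# of a complex core. Candidates split into two roles from their weighted
# connectivity: overlapping proteins (shared between complexes) pull at least
# as strongly outward as inward and still reach half the core's average
# weighted degree; peripheral proteins pull strictly inward and at least as
# strongly as the average candidate. Classification is per-core and never
# consults other cores, so one protein may be overlapping for several
# complexes at once.

#' Average weighted degree of a complex core
#'
#' `weight_avg(Core) = 2 * sum(hocn over core-internal edges) / |V_core|` —
#' twice the total internal HOCN weight divided by the number of core
#' members, i.e. the mean weighted degree inside the core.
#'
#' @param weighted A weighted edge tibble from [weight_edges()].
#' @param cores A core tibble from [detect_cores()].
#' @return A tibble with columns `core` and `weight_avg`.
#' @export
core_weight_avg <- function(weighted, cores) {
  check_edge_frame(weighted, "hocn")
  g <- edge_graph(weighted, weighted_vertices(weighted))
  wt <- edge_weight_table(g, weighted$hocn)
  ids <- core_member_ids(g, cores)
  avg <- vapply(ids, function(m) {
    pairs <- utils::combn(sort.int(m), 2)
    w <- wt[pair_key(pairs[1, ], pairs[2, ])]
    2 * sum(w, na.rm = TRUE) / length(m)
  }, numeric(1))
  tibble::tibble(core = unique(cores$core), weight_avg = unname(avg))
}

# Internal workhorse: candidates with in/out weights for one core.
cap_for_core <- function(g, wt, core_ids) {
  in_core <- logical(length(g$vertices))
  in_core[core_ids] <- TRUE
  cand <- which(!in_core &
                  vapply(g$adj, function(nb) sum(in_core[nb]) >= 2L,
                         logical(1)))
  if (!length(cand)) {
    return(tibble::tibble(member_id = integer(), weight_in = numeric(),
                          weight_out = numeric()))
  }
  w_in <- numeric(length(cand))
  w_out <- numeric(length(cand))
  for (k in seq_along(cand)) {
    p <- cand[k]
    nb <- g$adj[[p]]
    w <- wt[pair_key(p, nb)]
    inside <- in_core[nb]
    w_in[k] <- sum(w[inside])
    w_out[k] <- sum(w[!inside])
  }
  tibble::tibble(member_id = cand, weight_in = w_in, weight_out = w_out)
}

#' Candidate attachment proteins of each core
#'
#' A protein `p` outside a core is a candidate attachment (member of the CAP
#' set) when it has at least two neighbours inside the core in the weighted
#' network. `weight_in` is `p`'s total HOCN weight into the core (the
#' quantity written `d_weight`), `weight_out` its total HOCN weight to all
#' vertices outside the core.
#'
#' @inheritParams core_weight_avg
#' @return A tibble with columns `core`, `member`, `weight_in`, `weight_out`.
#' @export
candidate_attachments <- function(weighted, cores) {
  check_edge_frame(weighted, "hocn")
  empty <- tibble::tibble(core = integer(), member = character(),
                          weight_in = numeric(), weight_out = numeric())
  if (!nrow(cores)) return(empty)
  g <- edge_graph(weighted, weighted_vertices(weighted))
  wt <- edge_weight_table(g, weighted$hocn)
  ids <- core_member_ids(g, cores)
  rows <- purrr::map2_dfr(unique(cores$core), ids, function(cid, m) {
    cap <- cap_for_core(g, wt, m)
    tibble::tibble(core = rep(cid, nrow(cap)),
                   member = g$vertices[cap$member_id],
                   weight_in = cap$weight_in,
                   weight_out = cap$weight_out)
  })
  if (!nrow(rows)) empty else rows
}

classify_cap <- function(cap, weight_avg) {
  overlapping <- cap$weight_out >= cap$weight_in &
    cap$weight_in >= 0.5 * weight_avg
  cp <- !overlapping
  peripheral <- logical(nrow(cap))
  if (any(cp)) {
    cp_mean <- mean(cap$weight_in[cp])
    peripheral <- cp & cap$weight_in > cap$weight_out &
      cap$weight_in >= cp_mean
  }
  dplyr::case_when(overlapping ~ "overlapping",
                   peripheral ~ "peripheral",
                   TRUE ~ NA_character_)
}

#' Classify attachment proteins as overlapping or peripheral
#'
#' Applies the two-stage rule to each core's candidate set. A candidate `p`
#' is **overlapping** when `weight_out >= weight_in` (ties go to overlapping)
#' and `weight_in >= weight_avg(core) / 2`. The remaining candidates form the
#' candidate-peripheral set CP; `p` in CP is **peripheral** when
#' `weight_in > weight_out` (strict) and `weight_in` is at least the mean
#' `weight_in` over all of CP. Candidates passing neither rule are dropped.
#' All comparisons are scale-covariant: rescaling every HOCN weight by a
#' positive constant changes no classification.
#'
#' @inheritParams core_weight_avg
#' @return A tibble with columns `core`, `member`, `role` (`"overlapping"` or
#'   `"peripheral"`), `weight_in`, `weight_out` — the attachment set of each
#'   core.
#' @examples
#' sim <- simulate_ppi(seed = 1)
#' w <- weight_edges(sim$edges)
#' cores <- detect_cores(w)
#' classify_attachments(w, cores)
#' @export
classify_attachments <- function(weighted, cores) {
  cap <- candidate_attachments(weighted, cores)
  if (!nrow(cap)) {
    return(tibble::tibble(core = cap$core, member = character(),
                          role = character(), weight_in = numeric(),
                          weight_out = numeric()))
  }
  avg <- core_weight_avg(weighted, cores)
  cap |>
    dplyr::left_join(avg, by = "core") |>
    dplyr::group_by(.data$core) |>
    dplyr::mutate(role = classify_cap(
      dplyr::pick(dplyr::everything()), .data$weight_avg[1]
    )) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$role)) |>
    dplyr::select("core", "member", "role", "weight_in", "weight_out")
}
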