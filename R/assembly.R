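# Final complex formation: core plus attachment, size filter, redundancy
# removal. "Redundant" means member sets that are exactly equal — a complex
# properly contained in another is genuine overlap and both are kept.

#' Assemble final complexes from cores and attachments
#'
#' Each predicted complex is the union of one core's members and its
#' attachment proteins. Complexes with fewer than `min_size` members are
#' discarded (default 3, the conventional minimum complex size), and
#' complexes whose member sets are identical collapse to the first in core
#' order. Core, peripheral and overlapping roles are pairwise disjoint within
#' a complex by construction: candidates never include core members, and the
#' two attachment roles are mutually exclusive.
#'
#' @param cores A core tibble from [detect_cores()].
#' @param attachments An attachment tibble from [classify_attachments()].
#' @param min_size Minimum complex size; smaller complexes are dropped.
#' @return A tibble with columns `complex` (integer id), `member` and `role`
#'   (`"core"`, `"peripheral"` or `"overlapping"`).
#' @export
assemble_complexes <- function(cores, attachments, min_size = 3) {
  check_edge_frame_cols(cores, c("core", "seed", "member"))
  check_edge_frame_cols(attachments, c("core", "member", "role"))
  core_ids <- unique(cores$core)
  members <- list()
  roles <- list()
  seen <- character()
  out_id <- 0L
  for (cid in core_ids) {
    cm <- sort(unique(cores$member[cores$core == cid]))
    at <- attachments[attachments$core == cid, , drop = FALSE]
    m <- c(cm, at$member)
    r <- c(rep("core", length(cm)), at$role)
    if (length(m) < min_size) next
    key <- paste(sort(m), collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    out_id <- out_id + 1L
    members[[out_id]] <- m
    roles[[out_id]] <- r
  }
  out <- complex_tibble(members, roles)
  out$complex <- as.integer(out$complex)
  out
}
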