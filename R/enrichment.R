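# Functional-enrichment testing of predicted complexes with the
# hypergeometric upper tail. No multiple-testing correction is applied and
# no ontology structure is consulted: annotations arrive as a flat
# protein-to-group table, matching how complex-detection methods are
# conventionally scored for biological significance.

#' Hypergeometric enrichment p-value
#'
#' Probability of observing `overlap` or more annotated proteins in a complex
#' by chance: the upper tail `P(X >= m)` of the hypergeometric distribution
#' with a universe of `universe_size` proteins of which `group_size` carry
#' the annotation, sampling `complex_size` proteins. Computed with the
#' numerically stable survival function and clamped to `[0, 1]`; `m = 0`
#' gives exactly 1.
#'
#' @param overlap Number of annotated proteins in the complex (`m`).
#' @param universe_size Total number of proteins (`N`).
#' @param complex_size Size of the complex (`C`).
#' @param group_size Size of the functional group (`F`).
#' @return A probability in `[0, 1]`. Vectorised over its arguments.
#' @examples
#' enrichment_pvalue(3, universe_size = 10, complex_size = 3, group_size = 5) # 10/120
#' @export
enrichment_pvalue <- function(overlap, universe_size, complex_size,
                              group_size) {
  n <- max(length(overlap), length(universe_size), length(complex_size),
           length(group_size))
  m <- rep_len(as.numeric(overlap), n)
  N <- rep_len(as.numeric(universe_size), n)
  C <- rep_len(as.numeric(complex_size), n)
  F_ <- rep_len(as.numeric(group_size), n)
  bad <- is.na(m) | is.na(N) | is.na(C) | is.na(F_) |
    m < 0 | C > N | F_ > N | m > pmin(C, F_)
  if (any(bad)) {
    stop("combinatorially impossible input: need 0 <= m <= min(C, F), ",
         "C <= N, F <= N", call. = FALSE)
  }
  pmin(1, pmax(0, stats::phyper(m - 1, F_, N - F_, C, lower.tail = FALSE)))
}

#' Functional enrichment of predicted complexes
#'
#' Scores each complex against every functional group it intersects and
#' reports the group with the smallest hypergeometric p-value. A complex is
#' called significant when that p-value is below `alpha` (conventionally
#' 0.01). Complex size `C` counts all members of the complex; proteins
#' missing from the annotation table simply belong to no group.
#'
#' @param complexes Complexes as a `complex`/`member` tibble or a list of
#'   member vectors.
#' @param annotations A data frame whose first two columns are protein
#'   identifier and functional-group label (one row per annotation).
#' @param universe_size Total number of proteins `N`; defaults to the number
#'   of distinct proteins in `annotations` union the complex members, with a
#'   message. Pass the PPI network's vertex count to reproduce the
#'   conventional setup.
#' @param alpha Significance cutoff on the smallest p-value; default 0.01.
#' @return A tibble with one row per complex: `complex`, `group` (best
#'   group, `NA` when the complex hits no group), `overlap`, `group_size`,
#'   `complex_size`, `p_value`, `significant`.
#' @export
enrich_complexes <- function(complexes, annotations, universe_size = NULL,
                             alpha = 0.01) {
  cl <- as_complex_list(complexes, "complexes")
  if (!is.data.frame(annotations) || ncol(annotations) < 2) {
    stop("`annotations` must be a data frame with protein and group columns",
         call. = FALSE)
  }
  prot <- as.character(annotations[[1]])
  grp <- as.character(annotations[[2]])
  groups <- split(prot, grp)
  groups <- lapply(groups, unique)
  if (is.null(universe_size)) {
    universe_size <- length(unique(c(prot, unlist(cl, use.names = FALSE))))
    message("universe_size not supplied; using ", universe_size,
            " (annotated proteins union complex members)")
  }
  purrr::imap_dfr(cl, function(members, id) {
    C <- length(members)
    ov <- vapply(groups, function(gm) length(intersect(members, gm)),
                 integer(1))
    hit <- which(ov >= 1)
    if (!length(hit)) {
      return(tibble::tibble(complex = id, group = NA_character_,
                            overlap = 0L, group_size = NA_integer_,
                            complex_size = C, p_value = 1,
                            significant = FALSE))
    }
    pv <- enrichment_pvalue(ov[hit], universe_size, C,
                            lengths(groups)[hit])
    best <- hit[which.min(pv)]
    tibble::tibble(
      complex = id,
      group = names(groups)[best],
      overlap = ov[best],
      group_size = length(groups[[best]]),
      complex_size = C,
      p_value = min(pv),
      significant = min(pv) < alpha
    )
  })
}
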