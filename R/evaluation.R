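# Evaluation of a predicted complex set against a reference catalogue:
# neighbourhood-affinity matching (recall / precision / F-measure), coverage
# rate, and the maximum matching ratio of ClusterONE. All metrics are
# permutation-invariant in both complex lists.

#' Neighbourhood affinity between two complexes
#'
#' `NA(A, B) = |A n B|^2 / (|A| * |B|)`: the squared overlap count divided by
#' the product of the sizes. Equal sets score 1, disjoint sets 0. Two
#' complexes are conventionally said to match when their affinity reaches a
#' threshold `t = 0.2`.
#'
#' @param a,b Character vectors of member identifiers (non-empty).
#' @return A number in `[0, 1]`.
#' @examples
#' neighborhood_affinity(c("p1", "p2", "p3", "p4"), c("p1", "p2", "p3", "x", "y")) # 9/20
#' @export
neighborhood_affinity <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (!length(a) || !length(b)) {
    stop("complexes must be non-empty", call. = FALSE)
  }
  length(intersect(a, b))^2 / (length(a) * length(b))
}

na_matrix <- function(pred, ref) {
  m <- matrix(0, nrow = length(ref), ncol = length(pred))
  for (i in seq_along(ref)) {
    for (j in seq_along(pred)) {
      m[i, j] <- neighborhood_affinity(ref[[i]], pred[[j]])
    }
  }
  m
}

#' Pairwise affinities between predicted and reference complexes
#'
#' @param pred,ref Complex sets: tibbles with `complex`/`member` columns, or
#'   lists of member vectors.
#' @return A tibble with columns `ref`, `pred` and `affinity`, one row per
#'   pair (zero-affinity pairs included).
#' @export
complex_affinities <- function(pred, ref) {
  p <- as_complex_list(pred, "pred")
  r <- as_complex_list(ref, "ref")
  m <- na_matrix(p, r)
  tibble::tibble(
    ref = rep(names(r), times = length(p)),
    pred = rep(names(p), each = length(r)),
    affinity = as.vector(m)
  )
}

#' Coverage rate of a reference set by predicted complexes
#'
#' For each reference complex, the largest number of its proteins found in a
#' single predicted complex; summed over the reference set and divided by the
#' total number of reference proteins (with multiplicity across complexes).
#'
#' @inheritParams complex_affinities
#' @return A number in `[0, 1]` (0 when `pred` is empty).
#' @export
coverage_rate <- function(pred, ref) {
  p <- as_complex_list(pred, "pred")
  r <- as_complex_list(ref, "ref")
  if (!length(r)) stop("`ref` must contain at least one complex", call. = FALSE)
  best <- vapply(r, function(ri) {
    if (!length(p)) return(0L)
    max(vapply(p, function(pj) length(intersect(ri, pj)), integer(1)))
  }, integer(1))
  sum(best) / sum(lengths(r))
}

#' Maximum matching ratio
#'
#' Builds the bipartite graph between reference and predicted complexes whose
#' edges are weighted by neighbourhood affinity, finds a maximum-weight
#' matching (each complex used at most once), and divides the total matched
#' weight by the number of reference complexes. The matching penalises
#' methods that fragment one reference complex into several predictions,
#' since only one fragment can be matched.
#'
#' @inheritParams complex_affinities
#' @param threshold Minimum affinity for a pair to enter the matching graph.
#'   Default 0: every positive-affinity pair participates, the convention of
#'   the original MMR definition (the recall/precision match threshold `t`
#'   plays no role here).
#' @return A number in `[0, 1]`.
#' @export
max_matching_ratio <- function(pred, ref, threshold = 0) {
  p <- as_complex_list(pred, "pred")
  r <- as_complex_list(ref, "ref")
  if (!length(r)) stop("`ref` must contain at least one complex", call. = FALSE)
  if (!length(p)) return(0)
  m <- na_matrix(p, r)
  keep <- which(m > threshold, arr.ind = TRUE)
  if (!nrow(keep)) return(0)
  nr <- length(r)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nr), rep(TRUE, length(p))),
    edges = as.vector(rbind(keep[, 1], nr + keep[, 2]))
  )
  match <- igraph::max_bipartite_match(g, weights = m[keep])
  match$matching_weight / nr
}

#' Evaluate predicted complexes against a reference set
#'
#' Computes the five standard quality metrics for a predicted complex set
#' `P` against a reference set `R`:
#' \describe{
#'   \item{recall}{fraction of reference complexes matched by at least one
#'     prediction at affinity `>= na_threshold`;}
#'   \item{precision}{fraction of predictions matching at least one reference
#'     complex at the same threshold;}
#'   \item{f_measure}{harmonic mean of recall and precision (0 when both
#'     are 0);}
#'   \item{coverage_rate}{see [coverage_rate()];}
#'   \item{mmr}{see [max_matching_ratio()].}
#' }
#'
#' @inheritParams complex_affinities
#' @param na_threshold Neighbourhood-affinity match threshold `t`; default
#'   0.2, the conventional value.
#' @param mmr_threshold Passed to [max_matching_ratio()].
#' @return A one-row tibble with the five metrics plus `n_pred`, `n_ref` and
#'   `na_threshold`. An empty `pred` yields zero metrics with a warning.
#' @examples
#' pred <- list(c("a", "b", "c"), c("d", "e", "f", "g"))
#' ref <- list(c("a", "b", "c", "x"), c("q", "r", "s"))
#' evaluate_complexes(pred, ref)
#' @export
evaluate_complexes <- function(pred, ref, na_threshold = 0.2,
                               mmr_threshold = 0) {
  if (!is.numeric(na_threshold) || na_threshold <= 0 || na_threshold > 1) {
    stop("`na_threshold` must be in (0, 1]", call. = FALSE)
  }
  p <- as_complex_list(pred, "pred")
  r <- as_complex_list(ref, "ref")
  if (!length(r)) stop("`ref` must contain at least one complex", call. = FALSE)
  if (!length(p)) {
    warning("empty prediction set: all metrics are 0", call. = FALSE)
    return(tibble::tibble(recall = 0, precision = 0, f_measure = 0,
                          coverage_rate = 0, mmr = 0, n_pred = 0L,
                          n_ref = length(r), na_threshold = na_threshold))
  }
  m <- na_matrix(p, r)
  matched <- m >= na_threshold
  recall <- sum(apply(matched, 1, any)) / length(r)
  precision <- sum(apply(matched, 2, any)) / length(p)
  f <- if (recall + precision > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(
    recall = recall,
    precision = precision,
    f_measure = f,
    coverage_rate = coverage_rate(p, r),
    mmr = max_matching_ratio(p, r, threshold = mmr_threshold),
    n_pred = length(p),
    n_ref = length(r),
    na_threshold = na_threshold
  )
}
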