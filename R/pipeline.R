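#' Detect protein complexes in a PPI network
#'
#' Runs the full core-attachment detection pipeline on an edge list:
#' \enumerate{
#'   \item weight every edge by HOCN reliability and drop unsupported edges
#'     ([weight_edges()]);
#'   \item mine a preliminary complex core around every seed vertex by
#'     structural-similarity expansion ([detect_cores()]);
#'   \item classify candidate attachment proteins of each core as
#'     overlapping or peripheral ([classify_attachments()]);
#'   \item assemble core plus attachment into final complexes, dropping
#'     complexes smaller than `min_size` and exact duplicates
#'     ([assemble_complexes()]).
#' }
#' The pipeline is fully deterministic: the same edge list and parameters
#' always produce the same complexes in the same order.
#'
#' @param edges A PPI edge tibble (see [read_ppi_edges()]). Any `weight`
#'   column is ignored; the method computes its own reliability weights.
#' @param ss Structural-similarity threshold for core membership, in
#'   `(0, 1]`; default 0.4.
#' @param min_size Minimum size of an emitted complex; default 3.
#' @param verbose Emit per-stage counts as messages.
#' @return A tibble of class `ppi_complexes` with columns `complex`, `member`
#'   and `role`, one row per complex membership. Stage statistics (input and
#'   retained edge counts, core count, parameters) are stored as attributes
#'   and summarised by [glance.ppi_complexes()].
#' @examples
#' sim <- simulate_ppi(seed = 7)
#' res <- detect_complexes(sim$edges)
#' glance(res)
#' @export
detect_complexes <- function(edges, ss = 0.4, min_size = 3, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  weighted <- weight_edges(edges)
  say("stage=weight edges_in=", attr(weighted, "n_input_edges"),
      " edges_retained=", nrow(weighted))
  cores <- detect_cores(weighted, ss = ss)
  n_cores <- length(unique(cores$core))
  say("stage=cores cores_found=", n_cores)
  attachments <- classify_attachments(weighted, cores)
  say("stage=attach attachments=", nrow(attachments))
  out <- assemble_complexes(cores, attachments, min_size = min_size)
  say("stage=assemble complexes_emitted=", length(unique(out$complex)))
  structure(
    out,
    class = c("ppi_complexes", class(out)),
    ss = ss,
    min_size = min_size,
    n_input_edges = attr(weighted, "n_input_edges"),
    n_retained_edges = nrow(weighted),
    n_cores = n_cores,
    n_vertices = length(weighted_vertices(weighted))
  )
}

#' Sweep the structural-similarity threshold
#'
#' Re-runs [detect_complexes()] over a grid of `ss` values and evaluates each
#' run against a reference complex set. As `ss` rises, every seed's core can
#' only shrink (member sets are nested across thresholds), so predicted
#' complexes become smaller and purer: precision tends upward and recall
#' downward, the classic trade-off this sweep exposes.
#'
#' @inheritParams detect_complexes
#' @param reference Reference complexes (tibble with `complex`/`member`, or a
#'   list of member vectors).
#' @param ss_grid Numeric vector of thresholds to try.
#' @param na_threshold Neighbourhood-affinity match threshold for
#'   recall/precision; default 0.2.
#' @param mmr_threshold Minimum affinity for an edge of the MMR matching
#'   graph; default 0.
#' @return A tibble of class `ss_sweep`: one row per `ss` with
#'   `n_complexes`, `recall`, `precision`, `f_measure`, `coverage_rate`,
#'   `mmr`.
#' @export
sweep_ss <- function(edges, reference, ss_grid = seq(0.1, 1, by = 0.1),
                     na_threshold = 0.2, min_size = 3, mmr_threshold = 0) {
  rows <- purrr::map_dfr(ss_grid, function(s) {
    pred <- detect_complexes(edges, ss = s, min_size = min_size)
    ev <- suppressWarnings(
      evaluate_complexes(pred, reference, na_threshold = na_threshold,
                         mmr_threshold = mmr_threshold)
    )
    dplyr::bind_cols(tibble::tibble(ss = s,
                                    n_complexes = length(unique(pred$complex))),
                     ev[, c("recall", "precision", "f_measure",
                            "coverage_rate", "mmr")])
  })
  structure(rows, class = c("ss_sweep", class(rows)))
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a detection run
#'
#' @param x A `ppi_complexes` object from [detect_complexes()].
#' @param ... Unused.
#' @return A one-row tibble: complex/protein counts, mean complex size,
#'   number of proteins assigned to more than one complex, edge retention and
#'   the parameters used.
#' @export
glance.ppi_complexes <- function(x, ...) {
  per <- tidy(x)
  tibble::tibble(
    n_complexes = nrow(per),
    n_proteins = length(unique(x$member)),
    mean_size = if (nrow(per)) mean(per$size) else NA_real_,
    n_multi_complex = sum(table(x$member) > 1),
    n_input_edges = attr(x, "n_input_edges"),
    n_retained_edges = attr(x, "n_retained_edges"),
    n_cores = attr(x, "n_cores"),
    ss = attr(x, "ss"),
    min_size = attr(x, "min_size")
  )
}

#' Per-complex summary of a detection run
#'
#' @param x A `ppi_complexes` object from [detect_complexes()].
#' @param ... Unused.
#' @return A tibble with one row per complex: `size` and the member counts in
#'   each role.
#' @export
tidy.ppi_complexes <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$complex) |>
    dplyr::summarise(
      size = dplyr::n(),
      n_core = sum(.data$role == "core"),
      n_peripheral = sum(.data$role == "peripheral"),
      n_overlapping = sum(.data$role == "overlapping"),
      .groups = "drop"
    )
}

#' Plot the composition of detected complexes
#'
#' Stacked bar chart of complex sizes split by member role.
#'
#' @param object A `ppi_complexes` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_complexes <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$complex),
    fill = factor(.data$role, levels = c("core", "peripheral", "overlapping"))
  )) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "complex", y = "members", fill = "role") +
    ggplot2::theme_minimal()
}

#' Plot an ss-threshold sweep
#'
#' Metric trajectories against the structural-similarity threshold,
#' mirroring the standard parameter-selection figure for this family of
#' methods.
#'
#' @param object An `ss_sweep` tibble from [sweep_ss()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ss_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)[, c("ss", "recall", "precision",
                                      "f_measure", "coverage_rate", "mmr")]
  long <- tibble::tibble(
    ss = rep(df$ss, 5),
    metric = rep(c("recall", "precision", "f_measure", "coverage_rate", "mmr"),
                 each = nrow(df)),
    value = c(df$recall, df$precision, df$f_measure, df$coverage_rate, df$mmr)
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$ss, .data$value, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "structural-similarity threshold (ss)", y = "value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
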