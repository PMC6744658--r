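#' Read a PPI network from a plain-text edge list
#'
#' Parses the flat edge-list format that DIP/BioGRID-derived interaction
#' networks are commonly distributed in: one interaction per line, two protein
#' identifiers separated by a tab or by runs of whitespace, with an optional
#' numeric third column carrying an externally supplied confidence weight.
#' Lines starting with `#` are comments. Identifiers are treated as opaque,
#' case-sensitive strings; no gene-name normalisation is attempted.
#'
#' Duplicate lines (including reversed duplicates, since the network is
#' undirected) collapse to a single edge and self-loop lines are dropped with
#' a warning. Input weights are preserved for round-tripping but are ignored
#' by the detection pipeline, which computes its own reliability weights with
#' [weight_edges()].
#'
#' @param path Path to the edge-list file.
#' @param delimiter `"auto"` (default) splits on any whitespace; `"tab"`
#'   splits on tab characters only; `"whitespace"` is an alias for `"auto"`.
#' @return A tibble with character columns `from` and `to` (one row per
#'   undirected edge) and, when the file has a third column, a numeric
#'   `weight` column.
#' @seealso [write_complexes()], [weight_edges()]
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "p1\tp2", "p2\tp1", "p2\tp3\t0.8"), f)
#' read_ppi_edges(f)
#' @export
read_ppi_edges <- function(path, delimiter = c("auto", "tab", "whitespace")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  split_re <- if (delimiter == "tab") "\t" else "[ \t]+"
  fields <- strsplit(trimws(lines[idx]), split_re)

  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop("line ", idx[which(nf < 2)[1]], ": expected at least 2 fields",
         call. = FALSE)
  }
  from <- vapply(fields, `[[`, character(1), 1)
  to <- vapply(fields, `[[`, character(1), 2)
  weight <- rep(NA_real_, length(fields))
  has_w <- nf >= 3
  if (any(has_w)) {
    wtxt <- vapply(fields[has_w], `[[`, character(1), 3)
    w <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(w)) {
      bad <- idx[has_w][which(is.na(w))[1]]
      stop("line ", bad, ": non-numeric weight field", call. = FALSE)
    }
    weight[has_w] <- w
  }

  self <- from == to
  if (any(self)) {
    warning(sum(self), " self-loop line(s) dropped", call. = FALSE)
  }
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  dup <- duplicated(paste(lo, hi, sep = "\r")) | self
  out <- tibble::tibble(from = lo[!dup], to = hi[!dup])
  if (any(has_w)) out$weight <- weight[!dup]
  out
}

#' Read a complex set from a flat file
#'
#' Reads a CYC2008-style complex catalogue: one complex per line, member
#' identifiers separated by tabs or whitespace. Lines starting with `#` are
#' comments; empty lines are skipped with a warning. Duplicate members within
#' a line are collapsed, but identical lines yield distinct complexes —
#' de-duplication of whole complexes is the assembly stage's job, not the
#' reader's.
#'
#' @param path Path to the complex-set file.
#' @return A tibble with columns `complex` (integer index in file order) and
#'   `member` (character).
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  blank <- !nzchar(trimws(lines))
  if (any(blank)) warning(sum(blank), " empty line(s) skipped", call. = FALSE)
  lines <- lines[!blank]
  members <- lapply(strsplit(trimws(lines), "[ \t]+"), unique)
  complex_tibble(members)
}

#' Write a complex set to a flat file
#'
#' Writes one complex per line with tab-separated members, the format
#' [read_complexes()] reads back. With `annotate_roles = TRUE` and a `role`
#' column present (as produced by [detect_complexes()]), each member is
#' written as `id::role` — a sidecar suffix that downstream plain-text tools
#' can strip on `::`.
#'
#' @param complexes A tibble with columns `complex` and `member` (optionally
#'   `role`), or a list of member vectors.
#' @param path Output file path.
#' @param annotate_roles Append `::role` to each member (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_complexes <- function(complexes, path, annotate_roles = FALSE) {
  if (is.data.frame(complexes) && annotate_roles &&
      "role" %in% names(complexes)) {
    complexes <- dplyr::mutate(
      complexes,
      member = paste(.data$member, .data$role, sep = "::")
    )
  }
  cl <- as_complex_list(complexes, "complexes")
  lines <- vapply(cl, paste, character(1), collapse = "\t")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}
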