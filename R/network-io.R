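#' Write a weighted gene network to disk
#'
#' Exports an edge list in one of the standard exchange formats so the
#' network can be laid out in Cytoscape/Gephi or re-imported elsewhere.
#' GraphML and the 3-column TSV edge list preserve edge weights exactly;
#' SIF is a topology-only format (no weight slot) and drops them.
#'
#' @param edges A data frame with columns `from`, `to`, `weight` (extra
#'   columns are ignored). Self-edges and non-finite weights are rejected.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("graphml", "sif", "tsv")) {
  if (length(format) != 1 || !format %in% c("graphml", "sif", "tsv")) {
    format <- tryCatch(match.arg(format),
                       error = function(e) stop("unknown network format: ",
                                                paste(format, collapse = ","),
                                                call. = FALSE))
  }
  edges <- tibble::as_tibble(edges)
  if (nrow(edges)) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    if (!"weight" %in% names(edges)) edges$weight <- 1
    if (any(!is.finite(edges$weight))) stop("edge weights must be finite", call. = FALSE)
    if (any(edges$from == edges$to)) stop("self-edges are not allowed", call. = FALSE)
  } else {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = numeric())
  }
  if (format == "tsv") {
    readr::write_tsv(edges[, c("from", "to", "weight")], path, progress = FALSE)
  } else if (format == "sif") {
    lines <- sprintf("%s\tco\t%s", edges$from, edges$to)
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("from", "to", "weight")], directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a weighted gene network written by [write_network()]
#'
#' @param path File path.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @return A tibble with columns `from`, `to`, `weight` (`weight` is `NA`
#'   for SIF input, which carries none).
#' @export
read_network <- function(path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  } else if (format == "sif") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- tibble::tibble(
      from = vapply(parts, `[`, "", 1),
      to = vapply(parts, `[`, "", 3),
      weight = NA_real_
    )
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    df <- igraph::as_data_frame(g, what = "edges")
    out <- tibble::tibble(from = df$from, to = df$to,
                          weight = if ("weight" %in% names(df)) df$weight else NA_real_)
  }
  out
}
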