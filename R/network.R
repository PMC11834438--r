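# Signed, weighted, undirected co-existence networks. Nodes are genera (with
# a prevalence attribute), edges carry a sign, an intensity (the Dev value
# for the co-detection model, the correlation coefficient for comparators)
# and a weight = |intensity| used to order removals during shearing.

#' Construct a co-existence network from node and edge tibbles
#'
#' Assembles a `coexist_network` directly, e.g. for networks imported from
#' elsewhere or constructed by hand. Edges are stored canonically
#' (`genus_a < genus_b`, lexicographic row order); self-loops and parallel
#' edges are rejected.
#'
#' @param nodes A data frame with a `genus` column and optionally
#'   `prevalence` (filled with `NA` when absent).
#' @param edges A data frame with columns `genus_a`, `genus_b`, `sign`
#'   (`"positive"`/`"negative"`), `intensity`; `weight` defaults to
#'   `abs(intensity)`.
#' @param method Method tag recorded on the network.
#' @param params Optional named list of build parameters.
#' @return A `coexist_network`.
#' @export
coexist_network <- function(nodes, edges, method = "manual", params = list()) {
  nodes <- tibble::as_tibble(nodes)
  if (!"prevalence" %in% names(nodes)) nodes$prevalence <- NA_real_
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) && !"weight" %in% names(edges)) edges$weight <- abs(edges$intensity)
  if (nrow(edges) && !all(c(edges$genus_a, edges$genus_b) %in% nodes$genus)) {
    abort("Every edge endpoint must appear in `nodes`.")
  }
  new_coexist_network(nodes, edges, method, params)
}

new_coexist_network <- function(nodes, edges, method, params = list()) {
  stopifnot(all(c("genus", "prevalence") %in% names(nodes)))
  edges <- canonical_edges(edges)
  structure(
    list(nodes = tibble::as_tibble(nodes), edges = edges,
         method = method, params = params),
    class = "coexist_network"
  )
}

# storage convention: genus_a < genus_b, rows sorted lexicographically
canonical_edges <- function(edges) {
  edges <- tibble::as_tibble(edges)
  if (!nrow(edges)) {
    return(tibble::tibble(genus_a = character(), genus_b = character(),
                          sign = character(), intensity = double(),
                          weight = double()))
  }
  flip <- edges$genus_a > edges$genus_b
  a <- ifelse(flip, edges$genus_b, edges$genus_a)
  b <- ifelse(flip, edges$genus_a, edges$genus_b)
  edges$genus_a <- a
  edges$genus_b <- b
  if (anyDuplicated(paste(edges$genus_a, edges$genus_b))) {
    abort("Parallel edges are not allowed.")
  }
  if (any(edges$genus_a == edges$genus_b)) abort("Self-loops are not allowed.")
  dplyr::arrange(edges, .data$genus_a, .data$genus_b)
}

#' Number of edges in a network
#' @param net A `coexist_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @export
print.coexist_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "<coexist_network: %s>\n  %d nodes, %d edges (avg links %.3g, P/N %s)\n",
    x$method, s$n_nodes, s$n_edges, s$avg_links,
    ifelse(is.na(s$pn_ratio), "undefined", format(s$pn_ratio, digits = 3))
  ))
  invisible(x)
}

#' @describeIn n_edges Tidy a network into its edge tibble.
#' @param x A `coexist_network`.
#' @param ... Unused.
#' @export
tidy.coexist_network <- function(x, ...) x$edges

#' @describeIn n_edges One-row network attribute summary (see
#'   [network_summary()]).
#' @export
glance.coexist_network <- function(x, ...) network_summary(x)

#' Convert a co-existence network to an igraph graph
#'
#' Node attribute `prevalence` and edge attributes `sign`, `intensity` and
#' `weight` are carried over. The graph is undirected; isolated genera are
#' kept as vertices.
#'
#' @param net A `coexist_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = net$edges, directed = FALSE,
    vertices = dplyr::select(net$nodes, "genus", dplyr::everything())
  )
}

#' Write a network as an edge-list TSV
#'
#' Columns `genus_a`, `genus_b`, `sign`, `intensity`, `weight`; the builder
#' method is recorded in a leading comment line.
#'
#' @param net A `coexist_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  writeLines(paste0("# method: ", net$method), path)
  readr::write_tsv(net$edges, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a network as GraphML
#'
#' @inheritParams write_edge_list
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read an edge-list TSV written by [write_edge_list()]
#'
#' @param path Edge-list file path.
#' @param nodes Optional node tibble (`genus`, `prevalence`); defaults to the
#'   genera appearing in edges, with prevalence `NA`.
#' @return A `coexist_network`.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  header <- readLines(path, n = 1L)
  method <- if (startsWith(header, "# method: ")) sub("^# method: ", "", header) else "unknown"
  edges <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    genus_a = readr::col_character(), genus_b = readr::col_character(),
    sign = readr::col_character(), intensity = readr::col_double(),
    weight = readr::col_double()
  ), progress = FALSE)
  if (is.null(nodes)) {
    nodes <- tibble::tibble(
      genus = sort(unique(c(edges$genus_a, edges$genus_b))),
      prevalence = NA_real_
    )
  }
  new_coexist_network(nodes, edges, method)
}

#' Drop isolated genera from a network (display helper)
#'
#' @param net A `coexist_network`.
#' @return The network restricted to genera with at least one edge.
#' @export
drop_isolates <- function(net) {
  connected <- unique(c(net$edges$genus_a, net$edges$genus_b))
  net$nodes <- dplyr::filter(net$nodes, .data$genus %in% connected)
  net
}
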