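# Node centralities and the centralized network scores
# Clo/Bet/Eig = sum_v (max(value) - value_v). Paths are unweighted: edge
# weights order removals during shearing but never enter path lengths.

#' Closeness centrality per node
#'
#' The inverse of the average shortest-path distance from a node to the
#' other nodes of its connected component; isolated nodes score 0.
#'
#' @param net A `coexist_network`.
#' @return A named numeric vector over all nodes.
#' @export
closeness_values <- function(net) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0L) abort("Network has no nodes.")
  clo <- suppressWarnings(igraph::closeness(g, weights = NA, normalized = TRUE))
  clo[!is.finite(clo)] <- 0 # isolated nodes / singleton components
  clo
}

#' Betweenness centrality per node
#'
#' The number of shortest paths between unordered node pairs that pass
#' through the node, each pair's contribution divided by its total number of
#' shortest paths. Unweighted; pairs in other components contribute nothing.
#'
#' @inheritParams closeness_values
#' @return A named numeric vector over all nodes.
#' @export
betweenness_values <- function(net) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0L) abort("Network has no nodes.")
  igraph::betweenness(g, weights = NA, directed = FALSE)
}

#' Eigenvector centrality per node
#'
#' Leading-eigenvector (Perron) scores of the unweighted adjacency, computed
#' per connected component with a dense symmetric eigendecomposition. Each
#' component's vector is scaled to unit maximum within the component and
#' then by the ratio of the component's spectral radius to the largest
#' spectral radius, so the globally dominant component peaks at exactly 1
#' and weaker components score proportionally less. This per-component rule
#' is deterministic even when several components tie spectrally (e.g. the
#' isolated edges that appear late in shearing). Isolated nodes score 0.
#'
#' @inheritParams closeness_values
#' @return A named numeric vector over all nodes, in \[0, 1\].
#' @export
eigenvector_values <- function(net) {
  nodes <- net$nodes$genus
  if (!length(nodes)) abort("Network has no nodes.")
  out <- stats::setNames(numeric(length(nodes)), nodes)
  if (!nrow(net$edges)) return(out)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  vecs <- list()
  lambdas <- numeric(0L)
  for (k in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == k]
    if (length(members) < 2L) next
    a <- igraph::as_adjacency_matrix(
      igraph::induced_subgraph(g, members), sparse = FALSE
    )
    a <- (a > 0) * 1 # ignore any weight semantics
    e <- eigen(a, symmetric = TRUE)
    v <- abs(e$vectors[, 1L])
    vecs[[length(vecs) + 1L]] <- stats::setNames(v / max(v), rownames(a))
    lambdas[length(lambdas) + 1L] <- e$values[1L]
  }
  lam_max <- max(lambdas)
  for (k in seq_along(vecs)) {
    out[names(vecs[[k]])] <- vecs[[k]] * (lambdas[k] / lam_max)
  }
  out
}

#' Centralize per-node values into a network score
#'
#' `sum_v (max(value) - value_v)`: zero when every node scores alike, large
#' when the distribution is star-like.
#'
#' @param values Numeric vector of per-node centralities.
#' @return A single non-negative number.
#' @export
centralize <- function(values) {
  if (!length(values)) abort("Cannot centralize an empty network.")
  sum(max(values) - values)
}

#' Per-node centrality report
#'
#' @inheritParams closeness_values
#' @return A tibble with columns `genus`, `closeness`, `betweenness`,
#'   `eigenvector`.
#' @export
centrality_report <- function(net) {
  clo <- closeness_values(net)
  tibble::tibble(
    genus = names(clo),
    closeness = unname(clo),
    betweenness = unname(betweenness_values(net)[names(clo)]),
    eigenvector = unname(eigenvector_values(net)[names(clo)])
  )
}

#' Centralized network scores
#'
#' @inheritParams closeness_values
#' @return A one-row tibble with columns `clo`, `bet`, `eig` (the
#'   centralized closeness, betweenness and eigenvector scores).
#' @export
network_centralization <- function(net) {
  tibble::tibble(
    clo = centralize(closeness_values(net)),
    bet = centralize(betweenness_values(net)),
    eig = centralize(eigenvector_values(net))
  )
}

#' Network attribute summary
#'
#' The three attributes tracked in the sample-size stability benchmark:
#' node count (isolates included), links per node, and the ratio of positive
#' to negative edge counts. The P/N ratio is `NA` when the network has no
#' negative edges (an undefined ratio, not infinity).
#'
#' @inheritParams closeness_values
#' @param links_per_node `"average_degree"` (default, `2E/N`) or
#'   `"edges_per_node"` (`E/N`).
#' @return A one-row tibble: `n_nodes`, `n_edges`, `avg_links`, `pn_ratio`.
#' @export
network_summary <- function(net, links_per_node = c("average_degree", "edges_per_node")) {
  links_per_node <- match.arg(links_per_node)
  n <- nrow(net$nodes)
  e <- nrow(net$edges)
  npos <- sum(net$edges$sign == "positive")
  nneg <- e - npos
  tibble::tibble(
    n_nodes = n,
    n_edges = e,
    avg_links = if (n == 0L) 0 else (if (links_per_node == "average_degree") 2 * e / n else e / n),
    pn_ratio = if (nneg == 0L) NA_real_ else npos / nneg
  )
}

#' Write a centrality report TSV
#'
#' Node rows (`genus`, `closeness`, `betweenness`, `eigenvector`) followed by
#' footer comment lines with the centralized scores and the attribute
#' summary.
#'
#' @inheritParams closeness_values
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_centrality_report <- function(net, path) {
  rep <- centrality_report(net)
  cz <- network_centralization(net)
  s <- network_summary(net)
  readr::write_tsv(rep, path)
  footer <- c(
    sprintf("# Clo\t%.10g", cz$clo),
    sprintf("# Bet\t%.10g", cz$bet),
    sprintf("# Eig\t%.10g", cz$eig),
    sprintf("# n_nodes\t%d", s$n_nodes),
    sprintf("# avg_links\t%.10g", s$avg_links),
    sprintf("# pn_ratio\t%s", ifelse(is.na(s$pn_ratio), "NA", format(s$pn_ratio, digits = 10)))
  )
  cat(footer, file = path, sep = "\n", append = TRUE)
  invisible(path)
}
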