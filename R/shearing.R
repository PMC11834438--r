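# Network shearing: a percolation-style pruning that, at each step, tries
# removing the least-weight edge and the biggest-weight edge, keeps whichever
# removal leaves the higher centralized eigenvector score, and repeats until
# a single edge remains. The stopping step trades betweenness against
# closeness centralization along the recorded trajectory; the network at the
# stop step is the core co-existence network.

edge_key <- function(edges) paste(edges$genus_a, edges$genus_b, sep = "\r")

# least/biggest weight; ties broken lexicographically on (genus_a, genus_b),
# which the canonical edge order already provides
pick_edge <- function(edges, kind) {
  w <- edges$weight
  idx <- if (kind == "least") which(w == min(w))[1L] else which(w == max(w))[1L]
  idx
}

remove_edge_at <- function(net, idx) {
  net$edges <- net$edges[-idx, , drop = FALSE]
  net
}

#' One shearing step
#'
#' Forms two candidate networks, one without the least-weight edge and one
#' without the biggest-weight edge (weight = |intensity|, sign ignored),
#' computes the centralized eigenvector score of each, and commits the
#' candidate with the larger score; exact ties keep the least-weight removal.
#' A `literal_three = TRUE` variant instead commits the least-weight removal
#' whenever its score exceeds the constant 3 (for auditing an alternative
#' reading of the rule; not the default).
#'
#' @param net A `coexist_network` with at least two edges.
#' @param literal_three Use the constant-3 decision variant (default `FALSE`).
#' @param tol Tolerance for declaring the two candidate scores tied.
#' @return A list: committed `network`, one-row `record` tibble
#'   (`removed_a`, `removed_b`, `kind`, `eig`, `eig_rejected`).
#' @export
shear_step <- function(net, literal_three = FALSE, tol = 1e-12) {
  if (nrow(net$edges) < 2L) {
    abort("Shearing needs at least two edges to form both candidates.")
  }
  i_min <- pick_edge(net$edges, "least")
  i_max <- pick_edge(net$edges, "biggest")
  cand_min <- remove_edge_at(net, i_min)
  cand_max <- remove_edge_at(net, i_max)
  eig_min <- centralize(eigenvector_values(cand_min))
  eig_max <- centralize(eigenvector_values(cand_max))
  take_least <- if (literal_three) {
    eig_min > 3
  } else {
    eig_min + tol * max(1, abs(eig_min), abs(eig_max)) >= eig_max
  }
  idx <- if (take_least) i_min else i_max
  removed <- net$edges[idx, ]
  list(
    network = if (take_least) cand_min else cand_max,
    record = tibble::tibble(
      removed_a = removed$genus_a, removed_b = removed$genus_b,
      kind = if (take_least) "least" else "biggest",
      eig = if (take_least) eig_min else eig_max,
      eig_rejected = if (take_least) eig_max else eig_min
    )
  )
}

#' Full shearing trajectory
#'
#' Repeats [shear_step()] until one edge remains, recording after each commit
#' the centralized eigenvector, betweenness and closeness scores of the
#' committed network. Deterministic: a given network always produces the
#' same removal sequence.
#'
#' @inheritParams shear_step
#' @return A `shear_trajectory` tibble with columns `step` (1-based; step t
#'   means t edges removed), `removed_a`, `removed_b`, `kind`, `eig`, `bet`,
#'   `clo`, `edges_remaining`; the initial network is kept in attribute
#'   `initial`.
#' @export
shear_trajectory <- function(net, literal_three = FALSE) {
  e0 <- nrow(net$edges)
  if (e0 < 2L) abort("Shearing needs at least two edges.")
  records <- vector("list", e0 - 1L)
  current <- net
  for (t in seq_len(e0 - 1L)) {
    step <- shear_step(current, literal_three = literal_three)
    current <- step$network
    records[[t]] <- dplyr::mutate(
      step$record,
      step = t,
      bet = centralize(betweenness_values(current)),
      clo = centralize(closeness_values(current)),
      edges_remaining = nrow(current$edges)
    )
  }
  out <- dplyr::bind_rows(records)
  out <- dplyr::select(out, "step", "removed_a", "removed_b", "kind",
                       "eig", "bet", "clo", "edges_remaining", "eig_rejected")
  attr(out, "initial") <- net
  class(out) <- c("shear_trajectory", class(out))
  out
}

norm01 <- function(x) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep(0.5, length(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Select the shearing stop step
#'
#' Scores the trade-off between betweenness and closeness centralization
#' along a trajectory and returns the best step (earliest on ties).
#' Rules: `"normalized-product"` (default) min-max normalizes both curves to
#' \[0, 1\] and maximizes their product; `"max-min"` maximizes the smaller of
#' the two normalized values; `"knee"` returns the step before the largest
#' one-step drop in normalized closeness.
#'
#' @param traj A `shear_trajectory`.
#' @param rule Stop rule name; recorded in the result's `rule` attribute.
#' @return The selected step (integer), with attribute `rule`.
#' @export
select_stop_step <- function(traj, rule = c("normalized-product", "max-min", "knee")) {
  rule <- match.arg(rule)
  if (!nrow(traj)) abort("Empty trajectory.")
  nb <- norm01(traj$bet)
  nc <- norm01(traj$clo)
  score <- switch(rule,
    "normalized-product" = nb * nc,
    "max-min" = pmin(nb, nc),
    "knee" = {
      if (nrow(traj) == 1L) 1 else c(-diff(nc), -Inf)
    }
  )
  if (max(score) == min(score)) {
    warn("Trade-off score is constant along the trajectory; returning the first step.")
  }
  structure(traj$step[which.max(score)], rule = rule)
}

#' Core network at a shearing stop step
#'
#' Replays the recorded removals up to and including `stop_step` against the
#' trajectory's initial network. Node prevalence attributes are preserved;
#' isolated nodes can optionally be dropped for display.
#'
#' @inheritParams select_stop_step
#' @param net The network the trajectory was computed from; defaults to the
#'   trajectory's `initial` attribute.
#' @param stop_step Step index in `1..nrow(traj)`.
#' @param drop_isolated Drop isolated nodes from the result (default `FALSE`).
#' @return A `coexist_network`.
#' @export
core_network <- function(traj, stop_step, net = NULL, drop_isolated = FALSE) {
  net <- net %||% attr(traj, "initial")
  if (is.null(net)) abort("No initial network available; pass `net`.")
  stop_step <- as.integer(stop_step)
  if (stop_step < 1L || stop_step > nrow(traj)) {
    abort(paste0("`stop_step` must be in 1..", nrow(traj), "."))
  }
  gone <- edge_key(tibble::tibble(
    genus_a = traj$removed_a[seq_len(stop_step)],
    genus_b = traj$removed_b[seq_len(stop_step)]
  ))
  net$edges <- net$edges[!edge_key(net$edges) %in% gone, , drop = FALSE]
  net$params$stop_step <- stop_step
  if (drop_isolated) net <- drop_isolates(net)
  net
}

#' Write a shearing trajectory TSV
#'
#' @inheritParams select_stop_step
#' @param path Output file path.
#' @param stop_step Optional selected stop step, recorded in a header
#'   comment together with its rule attribute.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, stop_step = NULL) {
  if (!is.null(stop_step)) {
    writeLines(sprintf("# stop_step: %d (rule: %s)", as.integer(stop_step),
                       attr(stop_step, "rule") %||% "unspecified"), path)
    readr::write_tsv(tibble::as_tibble(traj), path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(tibble::as_tibble(traj), path)
  }
  invisible(path)
}

#' @describeIn shear_trajectory One-row trajectory summary: initial and final
#'   edge counts, number of least/biggest removals.
#' @param x A `shear_trajectory`.
#' @param ... Unused.
#' @export
glance.shear_trajectory <- function(x, ...) {
  tibble::tibble(
    n_steps = nrow(x),
    initial_edges = nrow(x) + 1L,
    n_least = sum(x$kind == "least"),
    n_biggest = sum(x$kind == "biggest")
  )
}
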