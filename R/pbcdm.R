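# Probability-based co-detection model (PBCDM). Under independence the
# expected number of samples co-detecting genera i and j is
# Exp_ij = ns * p_i * p_j. The deviation Dev_ij = Exp_ij - Obs_ij is compared
# with the mean (MDev) and standard deviation (SDDev) of all pairwise
# deviations: pairs beyond k standard deviations of the mean become signed
# edges (Dev below the band = co-detected more than expected = positive).

#' Pairwise co-detection counts
#'
#' `Obs[i, j]` is the number of samples in which genera *i* and *j* are both
#' detected; the diagonal holds per-genus detection counts.
#'
#' @param presence A presence tibble (see [to_presence()]).
#' @return A symmetric integer matrix with genus dimnames.
#' @export
co_detection_counts <- function(presence) {
  p <- as_abundance_matrix(presence)
  if (!all(p %in% c(0, 1))) abort("`presence` must contain only 0/1 values.")
  obs <- p %*% t(p)
  storage.mode(obs) <- "integer"
  obs
}

#' Expected co-detection counts under independence
#'
#' `Exp[i, j] = ns * p_i * p_j`.
#'
#' @param prev A prevalence tibble (`genus`, `prevalence`) or named numeric
#'   vector of prevalences.
#' @param ns Number of samples.
#' @return A symmetric numeric matrix with genus dimnames.
#' @export
expected_counts <- function(prev, ns) {
  if (is.data.frame(prev)) {
    p <- stats::setNames(prev$prevalence, prev$genus)
  } else {
    p <- prev
  }
  if (ns < 1) abort("`ns` must be >= 1.")
  if (any(p < 0 | p > 1)) abort("Prevalences must lie in [0, 1].")
  ns * outer(p, p)
}

#' Pairwise deviation statistics
#'
#' `Dev = Exp - Obs` elementwise; `MDev` and `SDDev` are the mean and sample
#' (n - 1) standard deviation of Dev over the C(G, 2) unordered genus pairs.
#'
#' @param exp Expected count matrix from [expected_counts()].
#' @param obs Observed count matrix from [co_detection_counts()].
#' @param ns Number of samples (recorded for downstream checks).
#' @return A `dev_stats` object: matrices `obs`, `exp`, `dev` plus scalars
#'   `m_dev`, `sd_dev`, `ns` and the genus identifiers.
#' @export
deviation_stats <- function(exp, obs, ns = NULL) {
  if (!identical(dim(exp), dim(obs))) abort("`exp` and `obs` shapes differ.")
  g <- nrow(exp)
  if (g < 2L) abort("Deviation statistics need at least two genera (one pair).")
  dev <- exp - obs
  pair_dev <- dev[upper.tri(dev)]
  sd_dev <- if (length(pair_dev) > 1L) sd(pair_dev) else 0
  if (length(pair_dev) == 1L) {
    warn("Only one genus pair: SDDev is undefined and set to 0.")
  }
  structure(
    list(genus_ids = rownames(exp), obs = obs, exp = exp, dev = dev,
         m_dev = mean(pair_dev), sd_dev = sd_dev, ns = ns),
    class = "dev_stats"
  )
}

#' @export
print.dev_stats <- function(x, ...) {
  cat(sprintf("<dev_stats: %d genera, %d pairs; MDev = %.4g, SDDev = %.4g>\n",
              length(x$genus_ids), choose(length(x$genus_ids), 2L),
              x$m_dev, x$sd_dev))
  invisible(x)
}

#' @describeIn deviation_stats Per-pair tibble of observed, expected and
#'   deviation values (`genus_a < genus_b`).
#' @param x A `dev_stats` object.
#' @param ... Unused.
#' @export
tidy.dev_stats <- function(x, ...) {
  ut <- which(upper.tri(x$dev), arr.ind = TRUE)
  ids <- x$genus_ids
  out <- tibble::tibble(
    genus_a = ids[ut[, 1L]], genus_b = ids[ut[, 2L]],
    obs = x$obs[ut], exp = x$exp[ut], dev = x$dev[ut]
  )
  flip <- out$genus_a > out$genus_b
  tmp <- out$genus_a[flip]
  out$genus_a[flip] <- out$genus_b[flip]
  out$genus_b[flip] <- tmp
  dplyr::arrange(out, .data$genus_a, .data$genus_b)
}

#' @describeIn deviation_stats One-row summary (`n_genera`, `n_pairs`,
#'   `m_dev`, `sd_dev`, `ns`).
#' @export
glance.dev_stats <- function(x, ...) {
  tibble::tibble(
    n_genera = length(x$genus_ids),
    n_pairs = choose(length(x$genus_ids), 2L),
    m_dev = x$m_dev, sd_dev = x$sd_dev,
    ns = x$ns %||% NA_integer_
  )
}

#' Classify genus pairs into signed edges
#'
#' A pair is a positive connection when `Dev <= MDev - k_sd * SDDev`
#' (co-detected more than expected) and a negative connection when
#' `Dev >= MDev + k_sd * SDDev`; pairs inside the noise band are dropped.
#' Boundary values qualify. When `k_sd * SDDev` is zero the two thresholds
#' coincide; strict inequalities are then used (with a warning) so that no
#' pair is labelled both ways and an all-equal deviation set yields no edges.
#'
#' @param stats A `dev_stats` object.
#' @param k_sd Width of the noise band in standard deviations (default 1).
#' @return An edge tibble (`genus_a`, `genus_b`, `sign`, `intensity`,
#'   `weight`) where `intensity` is the Dev value and `weight` its absolute
#'   value.
#' @export
classify_edges <- function(stats, k_sd = 1) {
  if (k_sd < 0) abort("`k_sd` must be >= 0.")
  band <- k_sd * stats$sd_dev
  pairs <- tidy(stats)
  if (band == 0) {
    if (stats$sd_dev == 0) {
      warn("SDDev is 0: every off-mean pair qualifies as an edge.")
    }
    pos <- pairs$dev < stats$m_dev
    neg <- pairs$dev > stats$m_dev
  } else {
    pos <- pairs$dev <= stats$m_dev - band
    neg <- pairs$dev >= stats$m_dev + band
  }
  out <- dplyr::filter(pairs, pos | neg)
  out$sign <- ifelse(out$dev < stats$m_dev, "positive", "negative")
  tibble::tibble(
    genus_a = out$genus_a, genus_b = out$genus_b, sign = out$sign,
    intensity = out$dev, weight = abs(out$dev)
  )
}

#' Build a PBCDM co-existence network from an abundance table
#'
#' Pipeline: prevalence filter, detection calls, pairwise observed and
#' expected co-detection, deviation statistics, signed-edge classification.
#' All post-filter genera are kept as nodes (isolates included) with their
#' prevalence as a node attribute.
#'
#' @inheritParams to_presence
#' @inheritParams classify_edges
#' @param min_prev Prevalence filter threshold (default 0.10).
#' @return A `coexist_network` with `method = "pbcdm"`.
#' @export
build_pbcdm_network <- function(table, min_prev = 0.10, k_sd = 1,
                                detection_threshold = 0) {
  filtered <- filter_by_prevalence(table, min_prev, detection_threshold)
  if (nrow(filtered) < 2L) {
    abort("Fewer than two genera remain after the prevalence filter.")
  }
  pres <- to_presence(filtered, detection_threshold)
  prev <- prevalence(pres)
  obs <- co_detection_counts(pres)
  ns <- ncol(pres) - 1L
  expd <- expected_counts(prev, ns)
  stats <- deviation_stats(expd, obs, ns)
  edges <- classify_edges(stats, k_sd)
  new_coexist_network(
    nodes = prev, edges = edges, method = "pbcdm",
    params = list(min_prev = min_prev, k_sd = k_sd,
                  detection_threshold = detection_threshold,
                  m_dev = stats$m_dev, sd_dev = stats$sd_dev, ns = ns)
  )
}
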