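# Sample-size stability benchmark: subsample the pool without replacement at
# an incremental size grid (default 10..1,200, up to 20 replicates per size),
# rebuild the network on every subsample, track node count, links per node
# and the P/N ratio, and call the minimum stable sample size for an
# attribute as the smallest size showing no significant Student's t-test
# difference from every larger size.

#' The size grid used throughout the stability workflow
#' @export
default_size_grid <- c(10, 30, 50, 80, 100, 200, 300, 500, 700, 800, 1000, 1200)

#' Draw subsample index sets without replacement
#'
#' For each requested size, up to `max_iter` independent replicates of
#' distinct sample indices. Sizes exceeding the pool are skipped with a
#' warning (small cohorts cannot fill the upper grid).
#'
#' @param pool_size Number of samples available.
#' @param sizes Ascending subsample sizes (default [default_size_grid]).
#' @param max_iter Replicates per size (default 20).
#' @param seed Optional integer seed; a given seed always reproduces the
#'   same index sets.
#' @return A tibble with columns `size`, `replicate` and list-column
#'   `indices`.
#' @export
subsample_indices <- function(pool_size, sizes = default_size_grid,
                              max_iter = 20, seed = NULL) {
  sizes <- sort(unique(sizes))
  too_big <- sizes > pool_size
  if (any(too_big)) {
    warn(paste0("Skipping size(s) exceeding the pool of ", pool_size,
                " samples: ", toString(sizes[too_big]), "."))
    sizes <- sizes[!too_big]
  }
  draw <- function() {
    tidyr::expand_grid(size = sizes, replicate = seq_len(max_iter)) |>
      dplyr::mutate(indices = purrr::map(.data$size, ~ sample.int(pool_size, .x)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

build_network <- function(table, method, min_prev = 0.10, k_sd = 1, alpha = 0.05,
                          detection_threshold = 0, method_params = list()) {
  switch(method,
    pbcdm = build_pbcdm_network(table, min_prev = min_prev, k_sd = k_sd,
                                detection_threshold = detection_threshold),
    pearson = ,
    spearman = correlation_network(table, method = method, alpha = alpha,
                                   min_prev = min_prev,
                                   detection_threshold = detection_threshold),
    sparcc = do.call(sparcc_network, c(
      list(table = table, alpha = alpha, min_prev = min_prev,
           detection_threshold = detection_threshold), method_params
    )),
    abort(paste0("Unknown method: ", method))
  )
}

#' Network attributes across subsample sizes
#'
#' For every (size, replicate) subsample: subset the pool, re-apply the
#' prevalence filter within the subset, build the network with the chosen
#' method and record its [network_summary()]. A replicate on which the
#' builder fails (e.g. too few genera survive the filter) is recorded as an
#' NA triple with a warning rather than aborting the run.
#'
#' @inheritParams build_pbcdm_network
#' @inheritParams subsample_indices
#' @param method One of `"pbcdm"`, `"pearson"`, `"spearman"`, `"sparcc"`.
#' @param alpha Edge-retention p-value threshold for the comparator methods.
#' @param method_params Extra arguments for the SparCC builder.
#' @return A `stability_report` tibble with columns `method`, `size`,
#'   `replicate`, `n_nodes`, `avg_links`, `pn_ratio`; the grid and seed are
#'   kept as attributes.
#' @export
attribute_trajectories <- function(table, method = c("pbcdm", "pearson", "spearman", "sparcc"),
                                   sizes = default_size_grid, max_iter = 20,
                                   seed = NULL, min_prev = 0.10, k_sd = 1,
                                   alpha = 0.05, detection_threshold = 0,
                                   method_params = list()) {
  method <- match.arg(method)
  values <- as_abundance_matrix(table)
  pool <- ncol(values)
  idx <- subsample_indices(pool, sizes, max_iter, seed)
  one <- function(ind) {
    sub <- table[, c(1L, 1L + ind)]
    net <- tryCatch(
      suppressWarnings(build_network(sub, method, min_prev, k_sd, alpha,
                                     detection_threshold, method_params)),
      error = function(e) NULL
    )
    if (is.null(net)) {
      warn(paste0("Network build failed on a size-", length(ind),
                  " replicate; recorded as NA."))
      return(tibble::tibble(n_nodes = NA_integer_, avg_links = NA_real_,
                            pn_ratio = NA_real_))
    }
    dplyr::select(network_summary(net), "n_nodes", "avg_links", "pn_ratio")
  }
  out <- dplyr::bind_cols(
    tibble::tibble(method = method, size = idx$size, replicate = idx$replicate),
    dplyr::bind_rows(purrr::map(idx$indices, one))
  )
  attr(out, "sizes") <- sort(unique(idx$size))
  attr(out, "seed") <- seed
  class(out) <- c("stability_report", class(out))
  out
}

#' Pooled-variance Student's t-test p-value
#'
#' Two-sided, equal-variance. Degenerate cases follow the conventions of the
#' stability detector: `NA` with fewer than two finite values on either
#' side; p = 1 when both groups are constant and equal; p = 0 when the
#' pooled variance is zero but the means differ.
#'
#' @param a,b Numeric vectors (NAs dropped).
#' @param welch Use the Welch (unequal-variance) form instead.
#' @return The p-value, a single number or `NA`.
#' @export
students_t <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) return(NA_real_)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) return(if (mean(a) == mean(b)) 1 else 0)
  if (welch) {
    se2 <- va / na + vb / nb
    tt <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  2 * pt(-abs(tt), df)
}

#' Minimum stable sample size for a network attribute
#'
#' The smallest grid size whose attribute values show no significant
#' difference (p >= `alpha`) from those at **every** larger grid size;
#' `NA` when no size qualifies. Sizes with fewer than two finite replicate
#' values are excluded; the largest evaluable size is never a candidate
#' (stability against larger sizes would be vacuous).
#'
#' @param report A `stability_report` from [attribute_trajectories()].
#' @param attribute `"n_nodes"`, `"avg_links"` or `"pn_ratio"`.
#' @param alpha Significance level for the t-tests (default 0.05).
#' @param welch Use Welch's t-test instead of the pooled form.
#' @return The minimum stable size (numeric) or `NA`.
#' @export
min_stable_size <- function(report, attribute = c("avg_links", "n_nodes", "pn_ratio"),
                            alpha = 0.05, welch = FALSE) {
  attribute <- match.arg(attribute)
  vals <- split(report[[attribute]], report$size)
  vals <- lapply(vals, function(v) v[is.finite(v)])
  vals <- vals[vapply(vals, length, integer(1L)) >= 2L]
  if (!length(vals)) {
    warn(paste0("Attribute '", attribute, "' has no size with two finite replicates."))
    return(NA_real_)
  }
  sizes <- sort(as.numeric(names(vals)))
  if (length(sizes) < 2L) return(NA_real_)
  for (s in sizes[-length(sizes)]) {
    larger <- sizes[sizes > s]
    p <- vapply(larger, function(s2) {
      students_t(vals[[as.character(s)]], vals[[as.character(s2)]], welch = welch)
    }, numeric(1L))
    if (all(!is.na(p) & p >= alpha)) return(s)
  }
  NA_real_
}

#' Shapiro-Wilk normality screen per size and attribute
#'
#' Reported alongside the t-tests (which it never gates): W statistic and
#' p-value per (size, attribute) where at least three distinct finite values
#' exist, `NA` otherwise.
#'
#' @inheritParams min_stable_size
#' @return A tibble with columns `size`, `attribute`, `shapiro_w`,
#'   `shapiro_p`.
#' @export
normality_screen <- function(report) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(report),
    cols = c("n_nodes", "avg_links", "pn_ratio"),
    names_to = "attribute", values_to = "value"
  )
  dplyr::summarise(
    dplyr::group_by(long, .data$size, .data$attribute),
    shapiro_w = {
      v <- .data$value[is.finite(.data$value)]
      if (length(v) >= 3L && length(unique(v)) > 1L) shapiro.test(v)$statistic else NA_real_
    },
    shapiro_p = {
      v <- .data$value[is.finite(.data$value)]
      if (length(v) >= 3L && length(unique(v)) > 1L) shapiro.test(v)$p.value else NA_real_
    },
    .groups = "drop"
  )
}

#' @describeIn attribute_trajectories Minimum stable size per attribute,
#'   one row per (method, attribute).
#' @param x A `stability_report`.
#' @param alpha Significance level passed to [min_stable_size()].
#' @param ... Unused.
#' @export
glance.stability_report <- function(x, alpha = 0.05, ...) {
  attrs <- c("n_nodes", "avg_links", "pn_ratio")
  tibble::tibble(
    method = x$method[1L],
    attribute = attrs,
    min_stable_size = vapply(attrs, function(a) {
      suppressWarnings(min_stable_size(x, a, alpha = alpha))
    }, numeric(1L))
  )
}
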