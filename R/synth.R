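# Synthetic data with the statistical structure the methods assume:
# (i) Bernoulli presence/absence with specified marginal prevalences and
# planted pairwise dependencies expressed as joint-probability offsets, and
# (ii) compositional count tables drawn from a correlated log-normal basis
# closed to proportions and multinomially sampled at fixed depth.

default_genus_ids <- function(g) sprintf("g%03d", seq_len(g))
default_sample_ids <- function(n) sprintf("s%05d", seq_len(n))

#' Simulate presence/absence data with planted pairwise dependencies
#'
#' Unplanted genera are independent Bernoulli(p_i). Each planted pair (a, b)
#' is drawn per sample from the 2x2 joint table with
#' `P(both) = p_a * p_b + delta` and marginals preserved, so `delta > 0`
#' plants co-detection in excess of independence (a positive connection for
#' the co-detection model) and `delta < 0` plants avoidance. Planted pairs
#' must be disjoint and each joint probability must satisfy the Frechet
#' bounds `max(0, p_a + p_b - 1) <= P(both) <= min(p_a, p_b)`.
#'
#' @param n_samples Number of samples.
#' @param prevalence Numeric vector of marginal prevalences in (0, 1),
#'   optionally named with genus identifiers.
#' @param planted_pairs Optional data frame with columns `genus_a`,
#'   `genus_b`, `delta`.
#' @param seed Optional integer seed; the generator is a pure function of
#'   its arguments and the seed.
#' @return A presence tibble (`genus` column + 0/1 sample columns).
#' @export
simulate_presence <- function(n_samples, prevalence, planted_pairs = NULL,
                              seed = NULL) {
  g <- length(prevalence)
  ids <- names(prevalence) %||% default_genus_ids(g)
  if (any(prevalence <= 0 | prevalence >= 1)) {
    abort("Prevalences must lie strictly in (0, 1).")
  }
  p <- stats::setNames(as.numeric(prevalence), ids)
  if (!is.null(planted_pairs)) {
    planted_pairs <- tibble::as_tibble(planted_pairs)
    involved <- c(planted_pairs$genus_a, planted_pairs$genus_b)
    if (anyDuplicated(involved)) {
      abort("Planted pairs must be disjoint (no genus in two pairs).")
    }
    if (!all(involved %in% ids)) abort("Planted pair references an unknown genus.")
    for (r in seq_len(nrow(planted_pairs))) {
      pa <- p[planted_pairs$genus_a[r]]
      pb <- p[planted_pairs$genus_b[r]]
      p11 <- pa * pb + planted_pairs$delta[r]
      lo <- max(0, pa + pb - 1)
      hi <- min(pa, pb)
      if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
        abort(sprintf(
          "Infeasible delta for pair (%s, %s): joint probability %.4g outside the Frechet bounds [%.4g, %.4g].",
          planted_pairs$genus_a[r], planted_pairs$genus_b[r], p11, lo, hi
        ))
      }
    }
  }
  draw <- function() {
    m <- matrix(0, g, n_samples, dimnames = list(ids, default_sample_ids(n_samples)))
    planted_ids <- if (is.null(planted_pairs)) character() else
      c(planted_pairs$genus_a, planted_pairs$genus_b)
    free <- setdiff(ids, planted_ids)
    if (length(free)) {
      m[free, ] <- rbinom(length(free) * n_samples, 1L, rep(p[free], n_samples))
    }
    if (!is.null(planted_pairs)) {
      for (r in seq_len(nrow(planted_pairs))) {
        a <- planted_pairs$genus_a[r]; b <- planted_pairs$genus_b[r]
        p11 <- p[a] * p[b] + planted_pairs$delta[r]
        probs <- c(p11, p[a] - p11, p[b] - p11, 1 - p[a] - p[b] + p11)
        cell <- sample.int(4L, n_samples, replace = TRUE, prob = pmax(probs, 0))
        m[a, ] <- as.numeric(cell %in% c(1L, 2L))
        m[b, ] <- as.numeric(cell %in% c(1L, 3L))
      }
    }
    m
  }
  m <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  matrix_to_table(m)
}

#' Simulate compositional counts from a correlated log-normal basis
#'
#' Per sample, basis log-abundances are drawn from a multivariate normal
#' with the given mean, per-genus log scale and correlation structure,
#' exponentiated, closed to proportions, and sampled as multinomial counts
#' at the given sequencing depth. This is the generative model under which
#' SparCC's basis correlations are well defined.
#'
#' @param n_samples Number of samples.
#' @param log_mean Basis log-abundance mean vector (length = genus count),
#'   optionally named.
#' @param correlation Basis correlation matrix (symmetric positive-definite,
#'   unit diagonal); identity when `NULL`.
#' @param log_sd Per-genus log-scale standard deviation(s); default 1.
#' @param depth Reads per sample (default 20,000); every column sums to it.
#' @param seed Optional integer seed.
#' @return A counts tibble (`genus` column + integer sample columns).
#' @export
simulate_compositional <- function(n_samples, log_mean, correlation = NULL,
                                   log_sd = 1, depth = 20000, seed = NULL) {
  g <- length(log_mean)
  ids <- names(log_mean) %||% default_genus_ids(g)
  if (depth < 1) abort("`depth` must be >= 1.")
  correlation <- correlation %||% diag(g)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      !isTRUE(all.equal(unname(diag(correlation)), rep(1, g)))) {
    abort("`correlation` must be symmetric with unit diagonal.")
  }
  sds <- rep(log_sd, length.out = g)
  sigma <- diag(sds) %*% correlation %*% diag(sds)
  ch <- tryCatch(chol(sigma), error = function(e) {
    abort("`correlation` is not positive-definite.")
  })
  draw <- function() {
    z <- matrix(rnorm(n_samples * g), n_samples, g) %*% ch
    basis <- exp(sweep(z, 2L, as.numeric(log_mean), `+`))
    counts <- apply(basis, 1L, function(b) rmultinom(1L, depth, b / sum(b)))
    dimnames(counts) <- list(ids, default_sample_ids(n_samples))
    counts
  }
  m <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  matrix_to_table(m)
}

feasible_pair_prevalence <- function(delta, prev_range) {
  repeat {
    p <- runif(2, prev_range[1L], prev_range[2L])
    p11 <- p[1L] * p[2L] + delta
    # keep a small margin inside the Frechet bounds so the joint table is
    # well conditioned
    if (p11 >= max(0, sum(p) - 1) + 0.01 && p11 <= min(p) - 0.01) return(p)
  }
}

#' Simulate a benchmark pool with disjoint planted pairs
#'
#' The standard stability-benchmark scenario: `g` genera with marginal
#' prevalences uniform in `prev_range`, `n_pairs` planted co-detection pairs
#' (joint offset `+delta`) and `n_pairs` planted avoidance pairs (`-delta`).
#' Prevalences of planted pairs are redrawn within `prev_range` until the
#' offset is feasible under the Frechet bounds. With `abundances = TRUE` the
#' detection pattern is filled with log-normal abundances (log-mean 3,
#' log-sd 1) so that correlation-based methods can run on the same pool;
#' detection (presence/absence) structure is identical either way.
#'
#' @param n_samples Number of samples in the pool.
#' @param g Number of genera (default 50).
#' @param prev_range Marginal prevalence range (default \[0.3, 0.7\]).
#' @param n_pairs Planted pairs per sign (default 5).
#' @param delta Joint-probability offset magnitude (default 0.15).
#' @param abundances Fill detections with log-normal abundances instead of
#'   returning 0/1 (default `FALSE`).
#' @param seed Optional integer seed.
#' @return A list: `table` (abundance tibble) and `truth` (tibble
#'   `genus_a`, `genus_b`, `delta` of planted pairs).
#' @export
simulate_planted_pool <- function(n_samples, g = 50, prev_range = c(0.3, 0.7),
                                  n_pairs = 5, delta = 0.15,
                                  abundances = FALSE, seed = NULL) {
  if (4 * n_pairs > g) abort("Not enough genera for the requested planted pairs.")
  ids <- default_genus_ids(g)
  draw <- function() {
    prev <- stats::setNames(runif(g, prev_range[1L], prev_range[2L]), ids)
    pairs <- tibble::tibble(
      genus_a = ids[seq(1L, 4L * n_pairs, 2L)],
      genus_b = ids[seq(2L, 4L * n_pairs, 2L)],
      delta = rep(c(delta, -delta), each = n_pairs)
    )
    for (r in seq_len(nrow(pairs))) {
      p <- feasible_pair_prevalence(pairs$delta[r], prev_range)
      prev[pairs$genus_a[r]] <- p[1L]
      prev[pairs$genus_b[r]] <- p[2L]
    }
    pres <- simulate_presence(n_samples, prev, pairs)
    if (abundances) {
      m <- as_abundance_matrix(pres)
      ab <- m * exp(matrix(rnorm(length(m), mean = 3, sd = 1), nrow(m)))
      pres <- matrix_to_table(ab)
    }
    list(table = pres, truth = pairs)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

fixture_ids <- c("toy-6-genus", "independence-null",
                 "planted-pairs-pool-3000", "compositional-sparcc")

fixture_spec <- function(name) {
  switch(name,
    "toy-6-genus" = list(
      kind = "presence", n = 12,
      prevalence = stats::setNames(rep(0.5, 6),
                                   c("gA", "gB", "gC", "gD", "gE", "gF")),
      planted = tibble::tibble(
        genus_a = c("gA", "gC"), genus_b = c("gB", "gD"),
        delta = c(0.25, -0.25) # perfectly co-detected / perfectly exclusive
      )
    ),
    "independence-null" = list(
      kind = "presence", n = 500,
      prevalence = NULL, g = 30, prev_range = c(0.2, 0.8), planted = NULL
    ),
    "planted-pairs-pool-3000" = list(
      kind = "planted_pool", n = 3000, g = 50, prev_range = c(0.3, 0.7),
      n_pairs = 5, delta = 0.15
    ),
    "compositional-sparcc" = list(
      kind = "composition", n = 500, g = 22, depth = 20000,
      planted = list(pair = c(1L, 2L), rho = 0.8)
    ),
    abort(paste0("Unknown fixture '", name, "'. Known fixtures: ",
                 toString(fixture_ids), "."))
  )
}

build_fixture_table <- function(name, seed) {
  spec <- fixture_spec(name)
  if (spec$kind == "planted_pool") {
    pool <- simulate_planted_pool(spec$n, spec$g, spec$prev_range,
                                  spec$n_pairs, spec$delta, seed = seed + 1L)
    spec$planted <- pool$truth
    return(list(table = pool$table, spec = spec))
  }
  if (spec$kind == "presence") {
    prev <- spec$prevalence %||% withr::with_seed(
      seed,
      stats::setNames(runif(spec$g, spec$prev_range[1L], spec$prev_range[2L]),
                      default_genus_ids(spec$g))
    )
    table <- simulate_presence(spec$n, prev, spec$planted, seed = seed + 1L)
  } else {
    corr <- diag(spec$g)
    corr[spec$planted$pair[1L], spec$planted$pair[2L]] <- spec$planted$rho
    corr[spec$planted$pair[2L], spec$planted$pair[1L]] <- spec$planted$rho
    table <- simulate_compositional(spec$n, log_mean = rep(0, spec$g),
                                    correlation = corr, depth = spec$depth,
                                    seed = seed + 1L)
  }
  list(table = table, spec = spec)
}

#' Write a named synthetic fixture scenario to disk
#'
#' Known fixtures: `"toy-6-genus"` (6 genera, 12 samples, one perfectly
#' co-detected and one perfectly exclusive pair), `"independence-null"`
#' (30 independent genera, 500 samples), `"planted-pairs-pool-3000"`
#' (50 genera, 3,000 samples, 5 positive + 5 negative planted pairs at
#' |delta| = 0.15), `"compositional-sparcc"` (22 genera, 500 samples, depth
#' 20,000, one basis correlation of 0.8). Writes `<name>.tsv` plus a JSON
#' manifest recording the generating spec, seed and any planted truth;
#' rerunning with the same seed reproduces the files byte for byte.
#'
#' @param name Fixture identifier.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed (default 1).
#' @return Invisibly, a named character vector with the `table` and
#'   `manifest` paths.
#' @export
make_fixture <- function(name, out_dir, seed = 1L) {
  built <- build_fixture_table(name, as.integer(seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table_path <- file.path(out_dir, paste0(name, ".tsv"))
  manifest_path <- file.path(out_dir, paste0(name, "-manifest.json"))
  write_abundance_table(built$table, table_path)
  manifest <- list(
    fixture = name, seed = as.integer(seed),
    n_genera = nrow(built$table), n_samples = ncol(built$table) - 1L,
    planted = built$spec$planted
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(c(table = table_path, manifest = manifest_path))
}
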