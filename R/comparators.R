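# Comparator network builders used in the stability benchmark: Pearson on
# clr-transformed abundances, Spearman on relative abundances, and SparCC
# (log-ratio variance basis correlations with bootstrap pseudo p-values).

cor_pvalues <- function(rho, n) {
  p <- matrix(NA_real_, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  ok <- is.finite(rho)
  r <- pmin(pmax(rho[ok], -1), 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * pt(-tstat, df = n - 2)
  pv[abs(r) >= 1] <- 0
  p[ok] <- pv
  p
}

edges_from_correlation <- function(rho, p, alpha) {
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  ids <- rownames(rho)
  keep <- is.finite(p[ut]) & p[ut] < alpha
  ut <- ut[keep, , drop = FALSE]
  r <- rho[ut]
  tibble::tibble(
    genus_a = ids[ut[, 1L]], genus_b = ids[ut[, 2L]],
    sign = ifelse(r >= 0, "positive", "negative"),
    intensity = r, weight = abs(r)
  )
}

#' Correlation-based co-occurrence network (Pearson or Spearman)
#'
#' The Pearson variant first applies the centered log-ratio transform to
#' satisfy its normality assumption; the Spearman variant ranks relative
#' abundances directly. Pairs with two-sided p-value below `alpha` become
#' edges signed by the correlation coefficient.
#'
#' @inheritParams build_pbcdm_network
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha Retention threshold on the (raw) p-value; default 0.05.
#' @param p_adjust `"none"` (default, raw p-values) or `"BH"` for
#'   Benjamini-Hochberg adjustment across pairs.
#' @param zero_policy Passed to [clr_transform()] (Pearson only).
#' @return A `coexist_network` with `intensity` = correlation coefficient.
#' @export
correlation_network <- function(table, method = c("pearson", "spearman"),
                                alpha = 0.05, min_prev = 0.10,
                                detection_threshold = 0, p_adjust = c("none", "BH"),
                                zero_policy = "auto") {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  filtered <- filter_by_prevalence(table, min_prev, detection_threshold)
  if (nrow(filtered) < 2L) abort("Fewer than two genera remain after filtering.")
  values <- as_abundance_matrix(filtered)
  n <- ncol(values)
  if (n < 3L) abort("Correlation networks need at least three samples.")
  x <- if (method == "pearson") {
    as_abundance_matrix(clr_transform(filtered, zero_policy = zero_policy),
                        allow_negative = TRUE)
  } else {
    sweep(values, 2L, colSums(values), `/`) # relative abundances; rank-equivalent per sample
  }
  constant <- apply(x, 1L, function(r) max(r) == min(r))
  if (any(constant)) {
    warn(paste0("Correlation undefined for constant genus row(s): ",
                toString(head(rownames(x)[constant], 5L)), "; their pairs are skipped."))
  }
  rho <- suppressWarnings(cor(t(x), method = method))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  p <- cor_pvalues(rho, n)
  if (p_adjust == "BH") {
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  prev <- prevalence(filtered, detection_threshold)
  new_coexist_network(
    nodes = prev, edges = edges_from_correlation(rho, p, alpha), method = method,
    params = list(alpha = alpha, min_prev = min_prev, p_adjust = p_adjust)
  )
}

# one Dirichlet-resampled fraction matrix (genera x samples), +1 prior
resample_fractions <- function(counts) {
  g <- rgamma(length(counts), shape = counts + 1, rate = 1)
  f <- matrix(g, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  sweep(f, 2L, colSums(f), `/`)
}

# variation matrix t_ij = var over samples of log(x_i / x_j)
variation_matrix <- function(fracs) {
  l <- log(fracs)
  s <- cov(t(l))
  v <- diag(s)
  outer(v, v, `+`) - 2 * s
}

# solve basis variances from the variation matrix under the sparsity
# approximation, with iterative exclusion of strongly correlated pairs
basis_rho_once <- function(tmat, exclusion_threshold, exclusion_rounds) {
  g <- nrow(tmat)
  m <- matrix(1, g, g)
  diag(m) <- g - 1
  tmask <- tmat
  excluded <- matrix(FALSE, g, g)
  rho <- NULL
  for (round in 0:exclusion_rounds) {
    w <- tryCatch(solve(m, rowSums(tmask)), error = function(e) NULL)
    if (is.null(w)) {
      warn("SparCC basis system singular after exclusions; falling back to the no-exclusion estimate.")
      m0 <- matrix(1, g, g); diag(m0) <- g - 1
      w <- solve(m0, rowSums(tmat))
    }
    w <- pmax(w, .Machine$double.eps)
    rho <- (outer(w, w, `+`) - tmat) / (2 * sqrt(outer(w, w)))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (round == exclusion_rounds) break
    cand <- abs(rho)
    cand[excluded] <- -Inf
    diag(cand) <- -Inf
    top <- which.max(cand)
    if (cand[top] <= exclusion_threshold) break
    ij <- arrayInd(top, dim(cand))
    i <- ij[1L]; j <- ij[2L]
    excluded[i, j] <- excluded[j, i] <- TRUE
    tmask[i, j] <- tmask[j, i] <- 0
    m[i, j] <- m[j, i] <- 0
    m[i, i] <- m[i, i] - 1
    m[j, j] <- m[j, j] - 1
    rho <- NULL
  }
  if (is.null(rho)) { # loop exited at exclusion cap with a pending refit
    w <- tryCatch(solve(m, rowSums(tmask)), error = function(e) NULL)
    if (is.null(w)) {
      m0 <- matrix(1, g, g); diag(m0) <- g - 1
      w <- solve(m0, rowSums(tmat))
    }
    w <- pmax(w, .Machine$double.eps)
    rho <- pmin(pmax((outer(w, w, `+`) - tmat) / (2 * sqrt(outer(w, w))), -1), 1)
    diag(rho) <- 1
  }
  rho
}

#' SparCC basis correlations
#'
#' Estimates correlations between unobserved basis abundances from a
#' compositional count table: per inner resample, fractions are drawn from a
#' Dirichlet posterior (+1 prior), log-ratio variances
#' `t_ij = var(log(x_i/x_j))` are computed, basis variances are solved from
#' the sparsity-approximated linear system, and
#' `rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))` (clipped to \[-1, 1\]).
#' Pairs whose |rho| exceeds `exclusion_threshold` are iteratively removed
#' from the system; the reported rho is the entrywise median over resamples.
#'
#' @inheritParams as_abundance_matrix
#' @param exclusion_threshold Correlation magnitude above which a pair is
#'   excluded from the basis-variance system (default 0.1).
#' @param exclusion_rounds Maximum exclusion iterations (default 10).
#' @param inner_resamples Number of Dirichlet resamples to median over
#'   (default 20).
#' @param seed Optional integer seed for reproducibility.
#' @return A `sparcc_result`: genus ids and the symmetric `rho` matrix.
#' @export
sparcc_basis_correlations <- function(table, exclusion_threshold = 0.1,
                                      exclusion_rounds = 10, inner_resamples = 20,
                                      seed = NULL) {
  counts <- as_abundance_matrix(table)
  if (nrow(counts) < 4L) {
    abort("SparCC needs at least four genera for the basis-variance system.")
  }
  if (any(apply(counts, 2L, function(col) max(col) == min(col))) &&
      all(counts == counts[, 1L])) {
    warn("All sample columns are identical; SparCC estimates are degenerate.")
  }
  run <- function() {
    rhos <- lapply(seq_len(inner_resamples), function(b) {
      tmat <- variation_matrix(resample_fractions(counts))
      basis_rho_once(tmat, exclusion_threshold, exclusion_rounds)
    })
    arr <- array(unlist(rhos), dim = c(nrow(counts), nrow(counts), inner_resamples))
    apply(arr, c(1L, 2L), stats::median)
  }
  rho <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  dimnames(rho) <- dimnames(counts)[c(1L, 1L)]
  structure(list(genus_ids = rownames(counts), rho = rho, method = "sparcc"),
            class = "sparcc_result")
}

#' Bootstrap pseudo p-values for SparCC correlations
#'
#' Each bootstrap permutes every genus row independently across samples
#' (destroying all between-genus association while keeping marginals) and
#' recomputes the SparCC correlation matrix. The pseudo p-value is the
#' add-one proportion of bootstraps at least as extreme as the observed
#' correlation: `p = (1 + #{|rho_boot| >= |rho_obs|}) / (1 + n_boot)`.
#'
#' @inheritParams sparcc_basis_correlations
#' @param n_boot Number of bootstrap data sets (default 100).
#' @param rho_obs Optional precomputed observed `sparcc_result` to avoid
#'   refitting.
#' @return A list with matrices `rho` (observed) and `p`.
#' @export
sparcc_pseudo_p <- function(table, n_boot = 100, exclusion_threshold = 0.1,
                            exclusion_rounds = 10, inner_resamples = 20,
                            seed = NULL, rho_obs = NULL) {
  if (n_boot < 1) abort("`n_boot` must be >= 1.")
  counts <- as_abundance_matrix(table)
  run <- function() {
    obs <- rho_obs %||% sparcc_basis_correlations(
      table, exclusion_threshold, exclusion_rounds, inner_resamples
    )
    hits <- matrix(0L, nrow(counts), nrow(counts))
    for (b in seq_len(n_boot)) {
      perm <- t(apply(counts, 1L, sample))
      dimnames(perm) <- dimnames(counts)
      rb <- sparcc_basis_correlations(
        matrix_to_table(perm), exclusion_threshold, exclusion_rounds, inner_resamples
      )$rho
      hits <- hits + (abs(rb) >= abs(obs$rho))
    }
    p <- (1 + hits) / (1 + n_boot)
    diag(p) <- 1
    dimnames(p) <- dimnames(obs$rho)
    list(rho = obs$rho, p = p)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' SparCC co-occurrence network
#'
#' Composition of [sparcc_basis_correlations()] and [sparcc_pseudo_p()]:
#' pairs with pseudo p-value below `alpha` become edges signed and weighted
#' by the estimated basis correlation.
#'
#' @inheritParams sparcc_pseudo_p
#' @inheritParams correlation_network
#' @return A `coexist_network` with `method = "sparcc"`.
#' @export
sparcc_network <- function(table, alpha = 0.05, n_boot = 100, min_prev = 0.10,
                           detection_threshold = 0, exclusion_threshold = 0.1,
                           exclusion_rounds = 10, inner_resamples = 20,
                           seed = NULL) {
  filtered <- filter_by_prevalence(table, min_prev, detection_threshold)
  if (nrow(filtered) < 4L) {
    abort("SparCC needs at least four genera after filtering.")
  }
  res <- sparcc_pseudo_p(filtered, n_boot, exclusion_threshold,
                         exclusion_rounds, inner_resamples, seed = seed)
  prev <- prevalence(filtered, detection_threshold)
  new_coexist_network(
    nodes = prev, edges = edges_from_correlation(res$rho, res$p, alpha),
    method = "sparcc",
    params = list(alpha = alpha, n_boot = n_boot, min_prev = min_prev,
                  exclusion_threshold = exclusion_threshold,
                  exclusion_rounds = exclusion_rounds,
                  inner_resamples = inner_resamples, seed = seed)
  )
}
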