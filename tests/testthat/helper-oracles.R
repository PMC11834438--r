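# Independent brute-force implementations used as oracles. These stay
# deliberately naive (explicit loops, BFS by hand, power iteration) so they
# share no code path with the package.

# --- co-detection model, straight from the definitions ----------------------

oracle_pbcdm_edges <- function(presence_tbl, min_prev = 0.1, k_sd = 1) {
  m <- as.matrix(presence_tbl[-1])
  rownames(m) <- presence_tbl[[1]]
  ns <- ncol(m)
  p <- rowSums(m) / ns
  keep <- p >= min_prev
  m <- m[keep, , drop = FALSE]
  p <- p[keep]
  ids <- rownames(m)
  g <- nrow(m)
  rows <- list()
  devs <- numeric(0)
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      obs <- sum(m[i, ] == 1 & m[j, ] == 1)
      dev <- ns * p[i] * p[j] - obs
      devs <- c(devs, dev)
      rows[[length(rows) + 1]] <- data.frame(
        genus_a = min(ids[i], ids[j]), genus_b = max(ids[i], ids[j]), dev = dev
      )
    }
  }
  pairs <- do.call(rbind, rows)
  md <- mean(devs)
  sdd <- stats::sd(devs)
  pos <- pairs$dev <= md - k_sd * sdd
  neg <- pairs$dev >= md + k_sd * sdd
  out <- pairs[pos | neg, , drop = FALSE]
  out$sign <- ifelse(out$dev < md, "positive", "negative")
  out <- out[order(out$genus_a, out$genus_b), c("genus_a", "genus_b", "sign")]
  rownames(out) <- NULL
  out
}

edge_set <- function(net) {
  e <- tidy(net)[, c("genus_a", "genus_b", "sign")]
  e <- e[order(e$genus_a, e$genus_b), ]
  rownames(e) <- NULL
  as.data.frame(e)
}

# --- graph oracles: BFS distances, path counting, power iteration -----------

oracle_adjacency <- function(net) {
  ids <- net$nodes$genus
  a <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(net$edges))) {
    a[net$edges$genus_a[r], net$edges$genus_b[r]] <- 1L
    a[net$edges$genus_b[r], net$edges$genus_a[r]] <- 1L
  }
  a
}

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(a[v, ] == 1L)) {
          if (d[s, u] > depth) {
            d[s, u] <- depth
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

oracle_closeness <- function(net) {
  a <- oracle_adjacency(net)
  d <- oracle_distances(a)
  vapply(seq_len(nrow(a)), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(ncol(d)) != v)
    if (!length(reach)) 0 else 1 / mean(d[v, reach])
  }, numeric(1)) |> stats::setNames(rownames(a))
}

oracle_betweenness <- function(net) {
  a <- oracle_adjacency(net)
  d <- oracle_distances(a)
  n <- nrow(a)
  # sigma[s, v]: number of shortest s -> v paths, by dynamic programming in
  # order of increasing distance from s
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]))
    for (v in reach[order(d[s, reach])]) {
      if (v == s) next
      preds <- which(a[v, ] == 1L & d[s, ] == d[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  bet <- stats::setNames(numeric(n), rownames(a))
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          bet[v] <- bet[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bet
}

oracle_components <- function(a) {
  n <- nrow(a)
  comp <- integer(n)
  k <- 0
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    k <- k + 1
    frontier <- s
    comp[s] <- k
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(a[v, ] == 1L)) {
          if (comp[u] == 0) {
            comp[u] <- k
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  comp
}

oracle_eigenvector <- function(net, iter = 10000) {
  a <- oracle_adjacency(net)
  comp <- oracle_components(a)
  out <- stats::setNames(numeric(nrow(a)), rownames(a))
  lambdas <- numeric(0)
  vecs <- list()
  for (k in unique(comp)) {
    members <- which(comp == k)
    if (length(members) < 2) next
    sub <- a[members, members, drop = FALSE]
    # iterate on A + I: same Perron vector, but no oscillation on
    # bipartite components (whose spectrum is symmetric about 0)
    shifted <- sub + diag(length(members))
    v <- rep(1, length(members))
    for (i in seq_len(iter)) {
      v2 <- as.numeric(shifted %*% v)
      v <- v2 / sqrt(sum(v2^2))
    }
    lambda <- as.numeric(t(v) %*% sub %*% v)
    vecs[[length(vecs) + 1]] <- stats::setNames(abs(v) / max(abs(v)), rownames(sub))
    lambdas <- c(lambdas, lambda)
  }
  if (length(vecs)) {
    lam_max <- max(lambdas)
    for (k in seq_along(vecs)) {
      out[names(vecs[[k]])] <- vecs[[k]] * (lambdas[k] / lam_max)
    }
  }
  out
}

runif_seeded <- function(n, seed, min = 0, max = 1) {
  withr::with_seed(seed, runif(n, min, max))
}

matrix_to_table_for_test <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(genus = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

# --- random graph / network builders ----------------------------------------

random_presence_table <- function(seed, g = NULL, ns = NULL) {
  withr::with_seed(seed, {
    g <- g %||% sample(5:20, 1)
    ns <- ns %||% sample(50:300, 1)
    p <- runif(g, 0.1, 0.9)
    m <- matrix(rbinom(g * ns, 1, rep(p, ns)), g, ns,
                dimnames = list(sprintf("g%02d", seq_len(g)),
                                sprintf("s%03d", seq_len(ns))))
    dplyr::bind_cols(tibble::tibble(genus = rownames(m)), tibble::as_tibble(m))
  })
}

random_network <- function(seed, n_nodes = 8, n_edges = 12) {
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n_nodes))
    all_pairs <- t(utils::combn(ids, 2))
    pick <- sample(nrow(all_pairs), min(n_edges, nrow(all_pairs)))
    intensity <- round(runif(length(pick), -10, 10), 2)
    intensity[intensity == 0] <- 1
    coexist_network(
      nodes = tibble::tibble(genus = ids, prevalence = runif(n_nodes)),
      edges = tibble::tibble(
        genus_a = all_pairs[pick, 1], genus_b = all_pairs[pick, 2],
        sign = ifelse(intensity < 0, "positive", "negative"),
        intensity = intensity
      )
    )
  })
}

path_network <- function(ids = c("a", "b", "c"), weights = NULL) {
  k <- length(ids) - 1
  weights <- weights %||% rep(1, k)
  coexist_network(
    nodes = tibble::tibble(genus = ids, prevalence = 1),
    edges = tibble::tibble(
      genus_a = ids[seq_len(k)], genus_b = ids[seq_len(k) + 1],
      sign = "positive", intensity = -weights
    )
  )
}

star_network <- function(n_leaves = 3) {
  ids <- c("hub", sprintf("leaf%d", seq_len(n_leaves)))
  coexist_network(
    nodes = tibble::tibble(genus = ids, prevalence = 1),
    edges = tibble::tibble(
      genus_a = "hub", genus_b = ids[-1], sign = "positive",
      intensity = -seq_len(n_leaves)
    )
  )
}

complete_network <- function(n = 3) {
  ids <- sprintf("k%d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  coexist_network(
    nodes = tibble::tibble(genus = ids, prevalence = 1),
    edges = tibble::tibble(genus_a = pairs[, 1], genus_b = pairs[, 2],
                           sign = "positive", intensity = -1)
  )
}

cycle_network <- function(n = 5) {
  ids <- sprintf("c%d", seq_len(n))
  coexist_network(
    nodes = tibble::tibble(genus = ids, prevalence = 1),
    edges = tibble::tibble(genus_a = ids, genus_b = ids[c(2:n, 1)],
                           sign = "positive", intensity = -1)
  )
}

# --- independent shearing reimplementation -----------------------------------

oracle_shear_sequence <- function(net) {
  removed <- character(0)
  current <- net
  while (nrow(current$edges) > 1) {
    e <- current$edges
    e <- e[order(e$genus_a, e$genus_b), ]
    i_min <- which(e$weight == min(e$weight))[1]
    i_max <- which(e$weight == max(e$weight))[1]
    cand_min <- current; cand_min$edges <- e[-i_min, ]
    cand_max <- current; cand_max$edges <- e[-i_max, ]
    eig_min <- sum(max(oracle_eigenvector(cand_min)) - oracle_eigenvector(cand_min))
    eig_max <- sum(max(oracle_eigenvector(cand_max)) - oracle_eigenvector(cand_max))
    take_min <- eig_min >= eig_max - 1e-9
    idx <- if (take_min) i_min else i_max
    removed <- c(removed, paste(e$genus_a[idx], e$genus_b[idx]))
    current$edges <- e[-idx, ]
  }
  removed
}

# abundance pool with planted presence structure shared by all methods
planted_abundance_pool <- function(n_samples, seed, g = 50,
                                   prev_range = c(0.3, 0.7),
                                   n_pairs = 5, delta = 0.15) {
  simulate_planted_pool(n_samples, g = g, prev_range = prev_range,
                        n_pairs = n_pairs, delta = delta,
                        abundances = TRUE, seed = seed)
}

planted_truth_set <- function(truth) {
  data.frame(
    genus_a = pmin(truth$genus_a, truth$genus_b),
    genus_b = pmax(truth$genus_a, truth$genus_b),
    sign = ifelse(truth$delta > 0, "positive", "negative")
  )
}

# hand-built stability report from per-size value lists (avg_links slot)
fabricate_report <- function(values_by_size, method = "pbcdm") {
  rows <- purrr::imap(values_by_size, function(v, s) {
    tibble::tibble(method = method, size = as.numeric(s),
                   replicate = seq_along(v), n_nodes = NA_integer_,
                   avg_links = v, pn_ratio = NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stability_report", class(out))
  out
}

signed_precision_recall <- function(found, truth) {
  key <- function(d) paste(d$genus_a, d$genus_b, d$sign)
  tp <- sum(key(found) %in% key(truth))
  list(
    precision = if (nrow(found)) tp / nrow(found) else NA_real_,
    recall = tp / nrow(truth)
  )
}
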