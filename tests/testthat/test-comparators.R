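test_that("spearman networks respond to rank agreement and opposition", {
  base <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  tbl <- matrix_to_table_for_test(rbind(
    a = base, b = base * 2, c = 11 - base, d = runif_seeded(10, 30)
  ))
  net <- suppressWarnings(correlation_network(tbl, "spearman", min_prev = 0))
  e <- edge_set(net)
  expect_true(any(e$genus_a == "a" & e$genus_b == "b" & e$sign == "positive"))
  expect_true(any(e$genus_a == "a" & e$genus_b == "c" & e$sign == "negative"))
  ab <- tidy(net)[tidy(net)$genus_a == "a" & tidy(net)$genus_b == "b", ]
  expect_equal(ab$intensity, 1)
  ac <- tidy(net)[tidy(net)$genus_a == "a" & tidy(net)$genus_b == "c", ]
  expect_equal(ac$intensity, -1)
})

test_that("spearman edges are invariant under monotone per-genus transforms", {
  mu <- withr::with_seed(120, rnorm(8))
  tbl <- simulate_compositional(60, mu, depth = 5000, seed = 12)
  # spearman runs on per-sample relative abundances; per-genus transforms
  # commute with ranking only when closure is unchanged, so keep column
  # sums fixed by comparing tables that share the closure (equal depth)
  rel <- as_abundance_matrix(tbl)
  rel <- sweep(rel, 2, colSums(rel), `/`)
  warped <- rel
  warped[2, ] <- sqrt(warped[2, ])
  warped[5, ] <- warped[5, ]^3
  rho1 <- cor(t(rel), method = "spearman")
  rho2 <- cor(t(warped), method = "spearman")
  expect_equal(rho1, rho2, tolerance = 1e-12)

  # scaling a genus (a strictly monotone transform) never changes the network
  scaled <- tbl
  scaled[-1] <- as.matrix(tbl[-1]) * 1000
  expect_equal(edge_set(correlation_network(tbl, "spearman")),
               edge_set(correlation_network(scaled, "spearman")))
})

test_that("pearson-on-clr ignores per-sample scaling of abundances", {
  tbl <- simulate_compositional(50, rnorm(10), depth = 10000, seed = 13)
  scaled <- tbl
  scaled[-1] <- sweep(as.matrix(scaled[-1]), 2, runif_seeded(50, 5, 0.5, 3), `*`)
  n1 <- correlation_network(tbl, "pearson", zero_policy = "pseudocount")
  # pseudocount breaks exact scale invariance; compare on zero-free tables
  pos <- tbl; pos[-1] <- pos[-1] + 1
  pos_scaled <- pos
  pos_scaled[-1] <- sweep(as.matrix(pos_scaled[-1]), 2, runif_seeded(50, 5, 0.5, 3), `*`)
  expect_equal(
    edge_set(correlation_network(pos, "pearson", zero_policy = "none")),
    edge_set(correlation_network(pos_scaled, "pearson", zero_policy = "none"))
  )
  expect_s3_class(n1, "coexist_network")
})

test_that("constant genus rows are skipped with a warning, not an error", {
  # b + c is constant per column, so genus a stays constant after the
  # per-sample closure the spearman path applies
  tbl <- matrix_to_table_for_test(rbind(a = rep(5, 6), b = 1:6, c = 6:1))
  expect_warning(net <- correlation_network(tbl, "spearman", min_prev = 0),
                 "constant")
  e <- tidy(net)
  expect_false(any(e$genus_a == "a" | e$genus_b == "a"))
})

test_that("edge counts match a per-pair reimplementation on the same data", {
  m <- withr::with_seed(9, matrix(rnorm(10 * 100), 10))
  tbl <- matrix_to_table_for_test(exp(m))
  net <- correlation_network(tbl, "spearman", alpha = 0.05, min_prev = 0)
  # independent route: rank each closed row, then pearson cor.test per pair
  rel <- sweep(exp(m), 2, colSums(exp(m)), `/`)
  ranks <- t(apply(rel, 1, rank))
  manual <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    if (stats::cor.test(ranks[i, ], ranks[j, ])$p.value < 0.05) manual <- manual + 1
  }
  expect_equal(nrow(net$edges), manual)
})

test_that("edge retention is calibrated near alpha under independence", {
  # 10 seeds x C(30,2) pair tests at alpha = 0.05; G is large enough that
  # the compositional closure bias (~ -1/(G-1)) is negligible
  hits <- 0; pairs <- 0
  for (seed in 1:10) {
    m <- withr::with_seed(seed + 100, matrix(rnorm(30 * 100), 30))
    tbl <- matrix_to_table_for_test(exp(m))
    net <- correlation_network(tbl, "spearman", alpha = 0.05, min_prev = 0)
    hits <- hits + nrow(net$edges)
    pairs <- pairs + choose(30, 2)
  }
  rate <- hits / pairs
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("sparcc recovers zero correlation in the exact-t limit", {
  w <- c(0.5, 1, 2, 4, 0.25)
  tmat <- outer(w, w, `+`)
  diag(tmat) <- 0
  rho <- codetect:::basis_rho_once(tmat, exclusion_threshold = 0.1,
                                  exclusion_rounds = 10)
  expect_equal(rho[upper.tri(rho)], rep(0, 10), tolerance = 1e-10)
})

test_that("sparcc recovers a planted basis correlation", {
  corr <- diag(22)
  corr[1, 2] <- corr[2, 1] <- 0.8
  tbl <- simulate_compositional(500, rep(0, 22), corr, depth = 20000, seed = 21)
  res <- sparcc_basis_correlations(tbl, seed = 22)
  expect_equal(res$rho[1, 2], 0.8, tolerance = 0.1)
  off <- abs(res$rho[upper.tri(res$rho)])
  expect_lt(mean(off[-1]), 0.1) # unplanted pairs stay near zero
  expect_true(all(res$rho >= -1 & res$rho <= 1))
  expect_true(isSymmetric(res$rho))
  expect_equal(unname(diag(res$rho)), rep(1, 22))
  expect_error(sparcc_basis_correlations(tbl[1:3, ]), "four genera")
})

test_that("pseudo p-values follow the add-one permutation convention", {
  corr <- diag(8)
  corr[1, 2] <- corr[2, 1] <- 0.8
  tbl <- simulate_compositional(300, rep(0, 8), corr, depth = 5000, seed = 31)
  res <- sparcc_pseudo_p(tbl, n_boot = 24, inner_resamples = 8, seed = 32)
  expect_equal(res$p[1, 2], 1 / 25) # minimum attainable with 24 bootstraps
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_error(sparcc_pseudo_p(tbl, n_boot = 0), "n_boot")
})

test_that("the sparcc network keeps the planted edge and stays calibrated", {
  corr <- diag(10)
  corr[1, 2] <- corr[2, 1] <- 0.8
  tbl <- simulate_compositional(300, rep(0, 10), corr, depth = 5000, seed = 33)
  net <- sparcc_network(tbl, n_boot = 24, inner_resamples = 8, seed = 34,
                        min_prev = 0)
  e <- edge_set(net)
  expect_true(any(e$genus_a == "g001" & e$genus_b == "g002" & e$sign == "positive"))
  expect_error(sparcc_network(tbl[1:3, ], min_prev = 0), "four genera")
})
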