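test_that("co-detection counts match direct tallies", {
  tbl <- matrix_to_table_for_test(rbind(g1 = c(1, 1, 0), g2 = c(1, 0, 1)))
  obs <- co_detection_counts(tbl)
  expect_equal(obs["g1", "g2"], 1L)
  expect_equal(diag(obs), c(g1 = 2L, g2 = 2L))

  same <- matrix_to_table_for_test(rbind(a = c(1, 1, 0, 1), b = c(1, 1, 0, 1)))
  expect_equal(co_detection_counts(same)["a", "b"], 3L)

  tbl2 <- random_presence_table(7, g = 15, ns = 300)
  obs2 <- co_detection_counts(tbl2)
  m <- as.matrix(tbl2[-1])
  for (i in 1:14) for (j in (i + 1):15) {
    expect_equal(obs2[i, j], sum(m[i, ] == 1 & m[j, ] == 1))
  }
  expect_true(isSymmetric(obs2))
})

test_that("expected counts follow ns * p_i * p_j", {
  prev <- tibble::tibble(genus = c("a", "b", "c"), prevalence = c(0.5, 0.4, 0))
  e <- expected_counts(prev, 100)
  expect_equal(e["a", "b"], 20)
  expect_equal(e["c", ], c(a = 0, b = 0, c = 0))
  ones <- expected_counts(c(a = 1, b = 1), 57)
  expect_equal(ones["a", "b"], 57)
  expect_error(expected_counts(prev, 0), ">= 1")
})

sym_from_upper <- function(ids, upper) {
  g <- length(ids)
  m <- matrix(0, g, g, dimnames = list(ids, ids))
  m[upper.tri(m)] <- upper
  m + t(m)
}

test_that("deviation statistics use the sample SD over unordered pairs", {
  # 3-sample toy: p1 = p2 = 2/3, Exp = 3 * 4/9 = 4/3, Obs = 1, Dev = 1/3
  tbl <- matrix_to_table_for_test(rbind(g1 = c(1, 1, 0), g2 = c(1, 0, 1)))
  st <- deviation_stats(expected_counts(prevalence(tbl), 3), co_detection_counts(tbl), 3)
  expect_equal(st$dev["g1", "g2"], 1 / 3)

  # hand-computed: devs {-10, 0, 2, 12, 1, 1} -> mean 1,
  # squared deviations {121, 1, 1, 121, 0, 0} -> sd = sqrt(244 / 5)
  exp_m <- sym_from_upper(letters[1:4], c(-10, 0, 2, 12, 1, 1))
  st2 <- deviation_stats(exp_m, exp_m * 0)
  expect_equal(st2$m_dev, 1)
  expect_equal(st2$sd_dev, sqrt(244 / 5))
  expect_equal(sort(tidy(st2)$dev), sort(c(-10, 0, 2, 12, 1, 1)))

  same <- deviation_stats(exp_m, exp_m)
  expect_equal(same$m_dev, 0)
  expect_equal(same$sd_dev, 0)

  expect_error(deviation_stats(matrix(1), matrix(1)), "two genera")
})

test_that("edge classification honours the +-k SD band with inclusive bounds", {
  # devs {-10, 0, 2, 12, 1, 1}: thresholds 1 -+ sqrt(48.8) ~= -5.985 / 7.985
  exp_m <- sym_from_upper(letters[1:4], c(-10, 0, 2, 12, 1, 1))
  edges <- classify_edges(deviation_stats(exp_m, exp_m * 0))
  expect_equal(nrow(edges), 2L)
  expect_equal(edges$sign[edges$intensity == -10], "positive")
  expect_equal(edges$sign[edges$intensity == 12], "negative")
  expect_equal(edges$weight, abs(edges$intensity))

  # devs {-1, 0, 1}: mean 0, sd 1; both extremes sit exactly on the
  # boundary and must be kept (non-strict inequalities as printed)
  b <- sym_from_upper(letters[1:3], c(-1, 0, 1))
  edges_b <- classify_edges(deviation_stats(b, b * 0))
  expect_equal(nrow(edges_b), 2L)
  expect_setequal(edges_b$sign, c("positive", "negative"))

  # all deviations equal: SDDev = 0, no pair strictly beyond the mean
  flat <- sym_from_upper(letters[1:3], c(2, 2, 2))
  expect_warning(none <- classify_edges(deviation_stats(flat, flat * 0)), "SDDev")
  expect_equal(nrow(none), 0L)

  # off-mean pairs all qualify once the band is degenerate
  two <- sym_from_upper(letters[1:3], c(0, 5, 5))
  st <- deviation_stats(two, two * 0)
  st$sd_dev <- 0 # force the degenerate band
  expect_warning(all_off <- classify_edges(st), "SDDev")
  expect_equal(nrow(all_off), 3L)
})

test_that("the full pipeline equals the brute-force oracle on seeded data", {
  for (seed in 1:20) {
    tbl <- random_presence_table(seed)
    net <- suppressWarnings(build_pbcdm_network(tbl))
    expect_equal(edge_set(net), oracle_pbcdm_edges(tbl), info = paste("seed", seed))
  }
})

test_that("perfectly coupled and exclusive pairs are the extreme deviations", {
  paths <- make_fixture("toy-6-genus", withr::local_tempdir(), seed = 3)
  tbl <- read_abundance_table(paths[["table"]])
  net <- build_pbcdm_network(tbl, min_prev = 0.10)
  st <- deviation_stats(
    expected_counts(prevalence(tbl), 12),
    co_detection_counts(to_presence(tbl)), 12
  )
  pairs <- tidy(st)
  key <- paste(pairs$genus_a, pairs$genus_b)
  expect_equal(key[which.min(pairs$dev)], "gA gB") # co-detected: Obs >> Exp
  expect_equal(key[which.max(pairs$dev)], "gC gD") # exclusive: Obs << Exp
  found <- edge_set(net)
  expect_true(any(found$genus_a == "gA" & found$genus_b == "gB" & found$sign == "positive"))
  expect_true(any(found$genus_a == "gC" & found$genus_b == "gD" & found$sign == "negative"))
})

test_that("planted dependencies are recovered with the right signs", {
  truth <- tibble::tibble(genus_a = c("g001", "g003"), genus_b = c("g002", "g004"),
                          delta = c(0.15, -0.15))
  prev <- stats::setNames(rep(0.5, 20), sprintf("g%03d", 1:20))
  tbl <- simulate_presence(1000, prev, truth, seed = 41)
  found <- edge_set(build_pbcdm_network(tbl))
  expect_true(any(found$genus_a == "g001" & found$sign == "positive"))
  expect_true(any(found$genus_a == "g003" & found$sign == "negative"))
})

test_that("the network only sees the detection pattern, not abundances", {
  tbl <- random_presence_table(9, g = 12, ns = 120)
  scaled <- tbl
  scaled[-1] <- withr::with_seed(2, scaled[-1] * matrix(exp(rnorm(12 * 120, 2)), 12))
  expect_equal(tidy(suppressWarnings(build_pbcdm_network(tbl))),
               tidy(suppressWarnings(build_pbcdm_network(scaled))))
})

test_that("degenerate tables are rejected", {
  one <- matrix_to_table_for_test(rbind(g1 = c(1, 1, 1, 0), g2 = c(1, 0, 0, 0)))
  expect_error(build_pbcdm_network(one, min_prev = 0.5), "Fewer than two genera")
})
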