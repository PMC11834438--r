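test_that("subsampling draws distinct indices reproducibly", {
  idx <- subsample_indices(2000, seed = 5)
  again <- subsample_indices(2000, seed = 5)
  expect_identical(idx, again)
  expect_equal(nrow(idx), 12 * 20)
  expect_true(all(vapply(idx$indices, anyDuplicated, integer(1)) == 0))
  expect_equal(idx$size[1], 10)

  # at size == pool every replicate is a permutation of the full pool
  full <- subsample_indices(100, sizes = 100, max_iter = 5, seed = 2)
  expect_true(all(vapply(full$indices, function(i) setequal(i, 1:100), logical(1))))

  expect_warning(skip <- subsample_indices(50, sizes = c(10, 80), max_iter = 3, seed = 1),
                 "Skipping")
  expect_equal(unique(skip$size), 10)
})

test_that("a single subsample equals a direct manual build", {
  tbl <- random_presence_table(61, g = 20, ns = 200)
  rep1 <- attribute_trajectories(tbl, "pbcdm", sizes = 50, max_iter = 1, seed = 9)
  idx <- subsample_indices(200, sizes = 50, max_iter = 1, seed = 9)
  manual <- network_summary(build_pbcdm_network(tbl[, c(1, 1 + idx$indices[[1]])]))
  expect_equal(rep1$n_nodes, manual$n_nodes)
  expect_equal(rep1$avg_links, manual$avg_links)
  expect_equal(rep1$pn_ratio, manual$pn_ratio)
})

test_that("replicate-level failures are recorded as NA, not fatal", {
  # one common genus plus one ultra-rare: small subsets keep a single genus
  # after the filter, so the builder fails on those replicates
  m <- rbind(common = rep(1, 60), rare = c(1, rep(0, 59)))
  tbl <- matrix_to_table_for_test(m)
  expect_warning(
    rep <- attribute_trajectories(tbl, "pbcdm", sizes = c(10, 30), max_iter = 4,
                                  seed = 3, min_prev = 0.1),
    "NA"
  )
  expect_true(any(is.na(rep$n_nodes)))
  expect_equal(nrow(rep), 8)
})

test_that("stability reports are reproducible from the seed", {
  pool <- random_presence_table(71, g = 15, ns = 400)
  r1 <- suppressWarnings(attribute_trajectories(pool, "pbcdm", sizes = c(20, 50, 100),
                                                max_iter = 5, seed = 11))
  r2 <- suppressWarnings(attribute_trajectories(pool, "pbcdm", sizes = c(20, 50, 100),
                                                max_iter = 5, seed = 11))
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
})

test_that("node counts grow with sample size on planted pools", {
  pool <- planted_abundance_pool(1500, seed = 81, g = 30, n_pairs = 3)
  rep <- suppressWarnings(attribute_trajectories(
    pool$table, "pbcdm", sizes = c(10, 100, 1000), max_iter = 5, seed = 8
  ))
  med <- tapply(rep$n_nodes, rep$size, stats::median, na.rm = TRUE)
  expect_true(med["10"] <= med["100"] && med["100"] <= med["1000"])
  expect_equal(nrow(rep), 15)
})

test_that("the pooled t-test matches its closed form and guards", {
  # {1,2,3} vs {2,3,4}: t = -1.2247, df = 4
  p <- students_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(p, 2 * pt(-sqrt(1.5), 4))
  expect_equal(p, 0.2879, tolerance = 1e-3)
  expect_equal(p, stats::t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)$p.value)

  expect_equal(students_t(c(5, 6, 7), c(5, 6, 7)), 1)
  expect_equal(students_t(c(0, 0), c(0, 0)), 1)
  expect_lt(students_t(c(0, 0), c(10, 10)), 1e-6)
  expect_true(is.na(students_t(1, c(1, 2))))
  expect_true(is.na(students_t(c(1, NA), c(1, 2))))

  w <- students_t(c(1, 2, 3, 9), c(2, 3, 4), welch = TRUE)
  expect_equal(w, stats::t.test(c(1, 2, 3, 9), c(2, 3, 4))$p.value)
})

test_that("the change-point detector finds the stabilisation size", {
  frozen <- withr::with_seed(100, rnorm(20))
  vals <- list(`10` = frozen + 10, `30` = frozen + 10, `50` = frozen + 10,
               `100` = frozen + 10, `200` = frozen, `300` = frozen,
               `500` = frozen, `700` = frozen)
  expect_equal(min_stable_size(fabricate_report(vals), "avg_links"), 200)

  # identically drawn everywhere: the smallest size already qualifies
  same <- list(`10` = frozen, `30` = frozen, `50` = frozen, `100` = frozen)
  expect_equal(min_stable_size(fabricate_report(same), "avg_links"), 10)

  # strict drift at every size: nothing stabilises
  drift <- withr::with_seed(7, lapply(stats::setNames(1:6, c(10, 30, 50, 100, 200, 300)),
                                      function(k) rnorm(20, mean = 3 * k, sd = 0.1)))
  expect_true(is.na(min_stable_size(fabricate_report(drift), "avg_links")))

  # sizes with < 2 finite replicates are excluded from the grid
  holes <- list(`10` = frozen, `30` = c(NA_real_, NA_real_), `50` = frozen)
  expect_equal(min_stable_size(fabricate_report(holes), "avg_links"), 10)

  all_na <- list(`10` = rep(NA_real_, 3), `30` = rep(NA_real_, 3))
  expect_warning(out <- min_stable_size(fabricate_report(all_na), "avg_links"),
                 "finite")
  expect_true(is.na(out))
})

test_that("the normality screen reports W per size without gating", {
  pool <- random_presence_table(91, g = 15, ns = 300)
  rep <- suppressWarnings(attribute_trajectories(pool, "pbcdm", sizes = c(30, 100),
                                                 max_iter = 10, seed = 14))
  screen <- normality_screen(rep)
  expect_setequal(unique(screen$attribute), c("n_nodes", "avg_links", "pn_ratio"))
  ok <- screen[!is.na(screen$shapiro_w), ]
  expect_true(all(ok$shapiro_w > 0 & ok$shapiro_w <= 1))

  g <- glance(rep)
  expect_equal(g$attribute, c("n_nodes", "avg_links", "pn_ratio"))
})
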