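region_row <- function(cond, state, region, count, len, area) {
  data.frame(
    region_id = region, condition = cond, actin_state = state,
    fls_count = count, mean_length_um = len, mean_base_area_um2 = area,
    mean_straightness = 0.9
  )
}

both_states <- function(cond, counts, lens = rep(5, length(counts)),
                        areas = rep(1, length(counts))) {
  rbind(
    do.call(rbind, Map(
      region_row, cond, "none_added",
      paste0(cond, "_n", seq_along(counts)), counts, lens, areas
    )),
    do.call(rbind, Map(
      region_row, cond, "actin_added",
      paste0(cond, "_a", seq_along(counts)), counts, lens, areas
    ))
  )
}

test_that("feature medians follow the sort-based definition", {
  tab <- both_states("C", counts = c(10, 20, 30))
  m <- build_feature_matrix(tab)
  expect_equal(unname(m["C", "count_none_added"]), 20)

  # even number of regions: midpoint of the central pair
  tab2 <- both_states("C", counts = c(4, 8, 10, 40))
  m2 <- build_feature_matrix(tab2)
  sorted <- sort(c(4, 8, 10, 40))
  expect_equal(unname(m2["C", "count_none_added"]), mean(sorted[2:3]))
})

test_that("the matrix has six fixed columns and one row per condition", {
  tab <- generate_phenotype_conditions(23, n_regions_per_condition = 12, seed = 10)
  m <- build_feature_matrix(tab)
  expect_equal(dim(m), c(23L, 6L))
  expect_equal(colnames(m), c(
    "count_none_added", "count_actin_added",
    "length_none_added", "length_actin_added",
    "area_none_added", "area_actin_added"
  ))
  expect_equal(rownames(m), sort(unique(tab$condition)))
})

test_that("a condition missing an actin state is rejected by name", {
  tab <- both_states("C", c(10, 12))
  lonely <- region_row("scFv9", "none_added", "x1", 5, 4, 1)
  expect_error(build_feature_matrix(rbind(tab, lonely)), "scFv9")
})

test_that("features are the median over regions of the per-region mean", {
  # per-region FLS lengths chosen so median-of-means differs from
  # mean-of-medians: means are (6, 5, 7), medians are (6, 1, 7)
  regions <- list(c(0, 12), c(1, 1, 13), c(7, 7))
  summaries <- do.call(rbind, lapply(seq_along(regions), function(i) {
    meas <- data.frame(
      trace_id = seq_along(regions[[i]]),
      path_length_um = regions[[i]],
      straightness = 0.9, base_area_um2 = 1,
      n_nodes = 3L
    )
    summarize_region(meas, paste0("r", i), "C", "none_added")
  }))
  summaries <- rbind(summaries, both_states("C", c(1, 1))[3:4, ])
  m <- build_feature_matrix(summaries)
  med_of_means <- stats::median(c(6, 5, 7))
  mean_of_medians <- mean(c(6, 1, 7))
  expect_equal(unname(m["C", "length_none_added"]), med_of_means)
  expect_false(isTRUE(all.equal(med_of_means, mean_of_medians)))
})

test_that("scaling standardises columns to zero mean and unit population sd", {
  expect_equal(unname(scale_features(cbind(a = c(1, 3), b = c(0, 2)))[, "a"]), c(-1, 1))

  expect_warning(
    z <- scale_features(cbind(a = c(5, 5, 5), b = c(1, 2, 3))),
    "constant"
  )
  expect_equal(unname(z[, "a"]), c(0, 0, 0))

  set.seed(2)
  m <- matrix(rnorm(23 * 6, 50, 20), 23, 6)
  s <- scale_features(m)
  for (j in 1:6) {
    expect_lt(abs(mean(s[, j])), 1e-12)
    expect_lt(abs(sqrt(mean((s[, j] - mean(s[, j]))^2)) - 1), 1e-12)
  }
  expect_error(scale_features(m[1, , drop = FALSE]), "2 rows")
})

test_that("scaling is idempotent", {
  set.seed(3)
  m <- matrix(rnorm(60, 10, 4), 10, 6)
  once <- scale_features(m)
  twice <- scale_features(once)
  expect_lt(max(abs(twice - once)), 1e-9)
})

test_that("embedding returns one 2D coordinate per condition, reproducibly", {
  tab <- generate_phenotype_conditions(23, n_regions_per_condition = 12, seed = 20)
  s <- scale_features(build_feature_matrix(tab))
  e1 <- embed_2d(s, seed = 42)
  e2 <- embed_2d(s, seed = 42)
  expect_equal(dim(e1$coordinates), c(23L, 2L))
  expect_identical(e1$coordinates, e2$coordinates)
  expect_equal(e1$perplexity, 2.49)
  expect_equal(e1$early_exaggeration, 12)
})

test_that("row order of the input does not change per-condition coordinates", {
  tab <- generate_phenotype_conditions(12, n_regions_per_condition = 10, seed = 30)
  s <- scale_features(build_feature_matrix(tab))
  perm <- s[sample(nrow(s)), , drop = FALSE]
  a <- embed_2d(s, seed = 7)
  b <- embed_2d(perm, seed = 7)
  expect_identical(a$coordinates, b$coordinates)
})

test_that("perplexity infeasible for the row count is rejected", {
  m <- matrix(rnorm(5 * 6), 5, 6)
  expect_error(embed_2d(m, perplexity = 2.49), "infeasible")
  expect_error(embed_2d(m[1:3, ]), ">= 4 rows")
})
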