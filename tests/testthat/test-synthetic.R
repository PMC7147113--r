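test_that("identical config and seed give bit-identical stacks, truth and linescans", {
  cfg <- fls_stack_config(n_filaments = 4, seed = 7)
  a <- generate_fls_stack(cfg)
  b <- generate_fls_stack(cfg)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth, b$truth)

  lcfg <- fls_linescan_config(n_filopodia = 25, seed = 3)
  la <- generate_linescan_dataset(lcfg)
  lb <- generate_linescan_dataset(lcfg)
  expect_identical(la$linescans, lb$linescans)
  expect_identical(la$labels, lb$labels)
})

test_that("zero filaments give a pure-background stack and empty truth", {
  cfg <- fls_stack_config(n_filaments = 0, seed = 2)
  g <- generate_fls_stack(cfg)
  expect_equal(nrow(g$truth), 0)
  # no painted structure: intensities stay near background
  expect_lt(max(g$stack$voxels), cfg$background_level + 8 * cfg$noise_sd)
  expect_equal(dim(g$stack$voxels), cfg$image_shape)
})

test_that("a straight vertical filament has the stated truth morphometrics", {
  cfg <- fls_stack_config(n_filaments = 1, seed = 1)
  poly <- cbind(x = 5, y = 5, z = 0:10) # 10 um tall, perfectly straight
  g <- generate_fls_stack(cfg, filaments = list(list(polyline = poly)))
  expect_equal(g$truth$arc_length_um, 10.0)
  expect_equal(g$truth$straightness_true, 1.0)
  expect_equal(g$truth$base_area_um2, pi * cfg$base_radius_um^2)
})

test_that("helical polyline arc length matches hand summation of segment lengths", {
  t <- 0:12
  poly <- cbind(
    x = 6 + 0.4 * cos(t / 2),
    y = 6 + 0.4 * sin(t / 2),
    z = t * 1.0
  )
  cfg <- fls_stack_config(
    n_filaments = 1, seed = 5, image_shape = c(13, 128, 128),
    length_range = c(3, 12)
  )
  g <- generate_fls_stack(cfg, filaments = list(list(polyline = poly)))
  # independent summation of consecutive point distances
  by_hand <- 0
  for (i in 2:nrow(poly)) {
    by_hand <- by_hand + sqrt(sum((poly[i, ] - poly[i - 1, ])^2))
  }
  expect_equal(g$truth$arc_length_um, by_hand, tolerance = 1e-12)
  expect_true(g$truth$straightness_true > 0 && g$truth$straightness_true <= 1)
})

test_that("generated truth always satisfies the straightness and arc-length bounds", {
  for (seed in 1:5) {
    g <- generate_fls_stack(fls_stack_config(n_filaments = 8, seed = seed))
    expect_true(all(g$truth$straightness_true > 0))
    expect_true(all(g$truth$straightness_true <= 1))
    for (p in g$polylines) {
      e2e <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
      arc <- sum(sqrt(rowSums(diff(p)^2)))
      expect_gte(arc, e2e - 1e-12)
    }
  }
})

test_that("with zero noise and blur the brightest base pixel sits within the base radius", {
  for (seed in 1:5) {
    cfg <- fls_stack_config(
      n_filaments = 3, seed = seed,
      psf_sigma_xy = 0, noise_sd = 0, background_level = 0
    )
    g <- generate_fls_stack(cfg)
    base <- g$stack$voxels[1, , ]
    idx <- which(base == max(base), arr.ind = TRUE)
    r_px <- cfg$base_radius_um / cfg$pixel_size_xy
    # every maximal pixel belongs to some filament's base disk
    for (row in seq_len(nrow(idx))) {
      d <- sqrt((idx[row, 2] - 1 - g$truth$base_x_px)^2 +
        (idx[row, 1] - 1 - g$truth$base_y_px)^2)
      expect_lte(min(d), r_px + 1e-9)
    }
  }
})

test_that("generator rejects infeasible configurations", {
  expect_error(
    fls_stack_config(length_range = c(3, 30), image_shape = c(10, 64, 64)),
    "axial extent"
  )
  expect_error(fls_stack_config(pixel_size_xy = 0), "positive")
  expect_error(fls_linescan_config(positive_fraction = 1.2), "\\[0, 1\\]")
  # 30 bases at >= 3 um separation cannot fit a 3.2 um field
  expect_error(
    generate_fls_stack(fls_stack_config(
      n_filaments = 30, image_shape = c(10, 32, 32), seed = 1,
      length_range = c(3, 9)
    )),
    "could not place|too small"
  )
})

test_that("linescan labels reproduce the underlying Bernoulli draw and edge fractions", {
  cfg <- fls_linescan_config(n_filopodia = 400, positive_fraction = 0.7, seed = 99)
  d <- generate_linescan_dataset(cfg)
  redraw <- withr::with_seed(99L, stats::runif(400) < 0.7)
  expect_identical(d$labels$positive, redraw)
  expect_equal(sum(d$labels$positive), sum(redraw))

  all_pos <- generate_linescan_dataset(
    fls_linescan_config(n_filopodia = 50, positive_fraction = 1, seed = 1)
  )
  expect_true(all(all_pos$labels$positive))
  all_neg <- generate_linescan_dataset(
    fls_linescan_config(n_filopodia = 50, positive_fraction = 0, seed = 1)
  )
  expect_false(any(all_neg$labels$positive))
})

test_that("positive linescans carry the planted peak", {
  cfg <- fls_linescan_config(
    n_filopodia = 60, positive_fraction = 0.5,
    positive_delta = 200, background_sd = 5, seed = 12
  )
  d <- generate_linescan_dataset(cfg)
  maxima <- tapply(
    d$linescans$intensity[d$linescans$role == "filopodium"],
    d$linescans$filopodium_id[d$linescans$role == "filopodium"], max
  )
  maxima <- maxima[d$labels$filopodium_id]
  expect_true(all(maxima[d$labels$positive] > cfg$background_mean + 100))
  expect_true(all(maxima[!d$labels$positive] < cfg$background_mean + 100))
})

test_that("phenotype table has one row per condition, state and region", {
  tab <- generate_phenotype_conditions(
    n_conditions = 23, n_regions_per_condition = 12, seed = 4
  )
  expect_equal(nrow(tab), 23 * 2 * 12)
  expect_setequal(unique(tab$actin_state), c("none_added", "actin_added"))
  expect_equal(length(unique(tab$condition)), 23)
  expect_true("C" %in% tab$condition)
})

test_that("with no effects all conditions are exchangeable; a planted length deficit is recovered", {
  tab0 <- generate_phenotype_conditions(
    n_conditions = 6, n_regions_per_condition = 14, seed = 8
  )
  grand <- mean(tab0$mean_length_um[tab0$actin_state == "none_added"])
  per_cond <- tapply(
    tab0$mean_length_um[tab0$actin_state == "none_added"],
    tab0$condition[tab0$actin_state == "none_added"], mean
  )
  expect_true(all(abs(per_cond - grand) < 1)) # sampling noise only (sd 0.75/sqrt(14))

  # planted shortening: condition cluster 2 gets a -60% length shift and
  # should have the minimal median length in the clear majority of seeds
  hits <- 0
  for (seed in 1:100) {
    tab <- generate_phenotype_conditions(
      n_conditions = 5, n_regions_per_condition = 12,
      cluster_assignments = c(1, 1, 2, 1, 1),
      effect_sizes = rbind(c(0, 0, 0), c(0, -0.6, 0)),
      seed = seed
    )
    med <- tapply(tab$mean_length_um, tab$condition, median)
    if (names(which.min(med)) == "scFv2") hits <- hits + 1
  }
  expect_gte(hits, 99)
})
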