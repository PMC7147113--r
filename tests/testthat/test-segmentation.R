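test_that("difference of Gaussians maps constants to zero and is linear", {
  const <- matrix(7.3, 40, 40)
  expect_lt(max(abs(dog_filter(const, 1.5, 3))), 1e-10)

  set.seed(21)
  img <- matrix(runif(64 * 64), 64, 64)
  a <- dog_filter(img * 3.7, 1.5, 3)
  b <- 3.7 * dog_filter(img, 1.5, 3)
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-9)
})

test_that("impulse response matches dense direct convolution", {
  img <- matrix(0, 41, 41)
  img[21, 21] <- 1
  got <- dog_filter(img, 2, 4)
  want <- oracle_dog(img, 2, 4)
  expect_equal(got[21, 21], want[21, 21], tolerance = 1e-10)
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("filter output equals the dense oracle on random images, borders included", {
  set.seed(5)
  for (i in 1:5) {
    img <- matrix(runif(48 * 40, 0, 10), 48, 40)
    expect_lt(max(abs(dog_filter(img, 1.5, 3) - oracle_dog(img, 1.5, 3))), 1e-6)
  }
})

test_that("filter rejects invalid sigmas and non-2D input", {
  img <- matrix(0, 8, 8)
  expect_error(dog_filter(img, 3, 1.5), "sigma")
  expect_error(dog_filter(img, 0, 2), "sigma")
  expect_error(dog_filter(array(0, c(2, 2, 2)), 1, 2), "matrix")
})

test_that("thresholding picks exactly a bright block and is monotone in k", {
  img <- matrix(0, 10, 10)
  img[3:4, 5:6] <- 10
  # mean = 0.4; population sd = sqrt(4 - 0.16) = 1.9596; mean + 2 sd = 4.319
  mask <- threshold_slice(img, k = 2)
  expect_equal(sum(mask), 4)
  expect_true(all(mask[3:4, 5:6]))

  expect_equal(sum(threshold_slice(matrix(0, 6, 6), 3)), 0)

  set.seed(9)
  for (i in 1:10) {
    r <- matrix(rnorm(400), 20, 20)
    m2 <- threshold_slice(r, 2)
    m4 <- threshold_slice(r, 4)
    expect_true(all(m2[m4])) # k = 4 mask is a subset of k = 2 mask
  }
})

test_that("component extraction follows 8-connectivity and the area filter", {
  m <- matrix(0, 12, 12)
  m[2:4, 2:4] <- 1
  m[8:10, 8:10] <- 1
  comps <- extract_components(m, slice_index = 0, min_area_px = 1)
  expect_equal(nrow(comps), 2)
  expect_equal(comps$area_px, c(9L, 9L))
  # ordered by (cy, cx); 0-based centroids
  expect_equal(comps$cy, c(2, 8))
  expect_equal(comps$cx, c(2, 8))

  single <- matrix(0, 5, 5)
  single[3, 3] <- 1
  expect_equal(nrow(extract_components(single, 0, min_area_px = 2)), 0)

  diag2 <- matrix(0, 5, 5)
  diag2[2, 2] <- 1
  diag2[3, 3] <- 1
  got <- extract_components(diag2, 0, min_area_px = 1)
  expect_equal(nrow(got), 1) # touching only diagonally: one 8-connected piece
  expect_equal(got$area_px, 2L)
})

test_that("centroids are intensity-weighted when the original slice is given", {
  mask <- matrix(0, 5, 5)
  mask[2, 2:3] <- 1
  inten <- matrix(1, 5, 5)
  inten[2, 3] <- 3 # pulls centroid toward x = 2 (0-based)
  comps <- extract_components(mask, 0, 1, intensity_image = inten)
  expect_equal(comps$cx, (1 * 1 + 3 * 2) / 4)
  expect_equal(comps$cy, 1)
  expect_equal(comps$mean_intensity, 2)
})

test_that("segmenting a noise-free vertical filament finds one component per occupied slice", {
  cfg <- fls_stack_config(
    n_filaments = 1, seed = 3, noise_sd = 0,
    curvature_scale = 0, image_shape = c(12, 96, 96), length_range = c(3, 10)
  )
  poly <- cbind(x = 4.8, y = 4.8, z = 0:9)
  g <- generate_fls_stack(cfg, filaments = list(list(polyline = poly)))
  comps <- segment_stack(g$stack)
  counts <- vapply(comps, nrow, integer(1))
  expect_equal(unname(counts[1:10]), rep(1L, 10))
  expect_equal(unname(counts[11:12]), rep(0L, 2))
  # repeat segmentation is identical
  expect_identical(comps, segment_stack(g$stack))
})

test_that("pure-background stacks are almost always free of components", {
  nonempty <- 0L
  total <- 0L
  for (seed in 1:50) {
    g <- generate_fls_stack(fls_stack_config(
      n_filaments = 0, seed = seed, image_shape = c(1, 128, 128),
      length_range = c(0.5, 1)
    ))
    comps <- segment_stack(g$stack, seg_config(k = 3))
    total <- total + 1L
    if (nrow(comps[[1]]) > 0L) nonempty <- nonempty + 1L
  }
  expect_lte(nonempty / total, 0.05)
})

test_that("whole-pixel translation shifts centroids by the same amount", {
  img <- matrix(100, 64, 64)
  img[20:24, 30:34] <- 2000
  shifted <- matrix(100, 64, 64)
  shifted[(20:24) + 7, (30:34) + 5] <- 2000
  seg <- function(im) {
    extract_components(
      threshold_slice(dog_filter(im, 1.5, 3), 3), 0, 12,
      intensity_image = im
    )
  }
  a <- seg(img)
  b <- seg(shifted)
  expect_equal(nrow(a), 1)
  expect_equal(nrow(b), 1)
  expect_equal(b$cx - a$cx, 5, tolerance = 1e-9)
  expect_equal(b$cy - a$cy, 7, tolerance = 1e-9)
})
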