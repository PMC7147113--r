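# Shared fixtures and independent oracle implementations.

# --- dense direct convolution oracle (independent of the FFT path) --------

# Reflect an out-of-range 1-based index back into 1..n, mirroring at the
# edges with the edge sample duplicated. Written as an explicit fold loop.
oracle_reflect <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

oracle_gauss_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  g <- dnorm((-r):r, sd = sigma)
  g / sum(g)
}

# Direct spatial convolution with a separable Gaussian, accumulating one
# kernel offset at a time over explicitly reflected index vectors.
oracle_blur <- function(img, sigma) {
  k <- oracle_gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(img)
  m <- ncol(img)
  K <- outer(k, k)
  out <- matrix(0, n, m)
  for (di in -r:r) {
    ri <- vapply(seq_len(n) + di, oracle_reflect, integer(1), n = n)
    for (dj in -r:r) {
      ci <- vapply(seq_len(m) + dj, oracle_reflect, integer(1), n = m)
      out <- out + K[di + r + 1L, dj + r + 1L] * img[ri, ci]
    }
  }
  out
}

oracle_dog <- function(img, sigma_small, sigma_large) {
  oracle_blur(img, sigma_small) - oracle_blur(img, sigma_large)
}

# --- component fixtures ----------------------------------------------------

# Build a component data.frame by hand from vectors of centroids/areas.
make_comps <- function(slice, cx, cy, area = rep(10L, length(cx))) {
  if (length(cx) == 0L) {
    d <- data.frame(
      slice = integer(0), cx = numeric(0), cy = numeric(0),
      area_px = integer(0), mean_intensity = numeric(0)
    )
    d$pixels <- list()
    return(d)
  }
  d <- data.frame(
    slice = as.integer(slice), cx = cx, cy = cy,
    area_px = as.integer(area), mean_intensity = NA_real_
  )
  d$pixels <- replicate(length(cx), cbind(x = 0, y = 0), simplify = FALSE)
  d
}

# Random small tracing instance; grid = TRUE snaps centroids to integers to
# provoke distance ties.
random_instance <- function(seed, grid = FALSE) {
  set.seed(seed)
  nz <- sample(2:8, 1)
  comps <- lapply(seq_len(nz) - 1L, function(z) {
    nc <- sample(0:5, 1)
    if (nc == 0L) {
      return(make_comps(z, numeric(0), numeric(0)))
    }
    if (grid) {
      make_comps(z, sample(0:5, nc, TRUE), sample(0:5, nc, TRUE),
        area = sample(1:30, nc, TRUE)
      )
    } else {
      make_comps(z, runif(nc, 0, 10), runif(nc, 0, 10),
        area = sample(1:30, nc, TRUE)
      )
    }
  })
  cfg <- trace_config(
    max_link_um = runif(1, 0.2, 1.2),
    gap_tolerance = sample(0:2, 1),
    min_nodes = sample(1:3, 1)
  )
  list(comps = comps, cfg = cfg, pixel_size = 0.1)
}

# Canonical signature of a trace set for equality comparison.
trace_signature <- function(traces) {
  lapply(traces, function(tr) {
    unname(as.matrix(tr$nodes[, c("slice", "cx", "cy", "area_px")]))
  })
}

# Mean silhouette width of 2D points against integer labels.
mean_silhouette <- function(coords, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(coords))
  mean(sil[, "sil_width"])
}

# Planted three-cluster screen used by the embedding tests.
planted_screen <- function(seed, n_regions = 12L) {
  effects <- rbind(
    c(0, 0, 0),
    c(-0.5, 0.9, -0.4),
    c(0.9, -0.5, 0.6)
  )
  assignments <- rep(1:3, each = 4L)
  tab <- generate_phenotype_conditions(
    n_conditions = 12L, n_regions_per_condition = n_regions,
    cluster_assignments = assignments, effect_sizes = effects,
    noise_sd = 0.1, seed = seed
  )
  list(table = tab, clusters = attr(tab, "cluster_assignments"))
}

# Empirical two-sample KS statistic by brute-force ECDF enumeration.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}
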