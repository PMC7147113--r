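# Synthetic-data generators. These define the study conditions used for all
# validation: bright filaments rooted on a base plane and sampled once per
# z-slice, linescan sets with planted positives, and phenotype tables with
# planted cluster structure.

#' Configuration for the synthetic FLS stack generator
#'
#' Defaults emulate the reconstituted FLS assay as imaged on a spinning-disk
#' confocal with a 100x objective: 0.1 um/px laterally, 1 um z-spacing,
#' filaments 3-15 um long with base radius 0.5 um and shaft radius 0.25 um,
#' a ~1 px lateral PSF blur, constant background with additive Gaussian
#' camera noise, and gentle curvature produced by a lateral Gaussian random
#' walk (one step per slice, step sd = `curvature_scale` um per axis).
#'
#' @param image_shape integer c(n_slices, height_px, width_px).
#' @param pixel_size_xy um per pixel (> 0).
#' @param z_step um per z-slice (> 0).
#' @param n_filaments number of filaments to seed (>= 0).
#' @param length_range c(min, max) target arc length in um; the maximum must
#'   fit in the axial extent `n_slices * z_step`.
#' @param curvature_scale um; sd of the per-slice lateral random-walk step.
#'   0 gives perfectly straight (straightness 1) filaments.
#' @param base_radius_um radius of the disk painted on the base slice.
#' @param shaft_radius_um radius of the disks painted above the base.
#' @param peak_intensity filament intensity in counts before blur/noise.
#' @param psf_sigma_xy Gaussian blur sd applied per slice, in px (>= 0).
#' @param background_level constant background, counts (>= 0).
#' @param noise_sd sd of additive zero-mean Gaussian noise, counts (>= 0).
#' @param min_separation_um minimum pairwise distance between base centers.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated list of class `fls_stack_config`.
#' @export
fls_stack_config <- function(image_shape = c(18L, 128L, 128L),
                             pixel_size_xy = 0.1,
                             z_step = 1.0,
                             n_filaments = 10L,
                             length_range = c(3, 15),
                             curvature_scale = 0.1,
                             base_radius_um = 0.5,
                             shaft_radius_um = 0.25,
                             peak_intensity = 2000,
                             psf_sigma_xy = 1,
                             background_level = 100,
                             noise_sd = 20,
                             min_separation_um = 3,
                             seed = 1L) {
  cfg <- list(
    image_shape = as.integer(image_shape), pixel_size_xy = pixel_size_xy,
    z_step = z_step, n_filaments = as.integer(n_filaments),
    length_range = length_range, curvature_scale = curvature_scale,
    base_radius_um = base_radius_um, shaft_radius_um = shaft_radius_um,
    peak_intensity = peak_intensity, psf_sigma_xy = psf_sigma_xy,
    background_level = background_level, noise_sd = noise_sd,
    min_separation_um = min_separation_um, seed = as.integer(seed)
  )
  if (length(cfg$image_shape) != 3L || any(cfg$image_shape < 1L)) {
    stop("'image_shape' must be c(n_slices, height_px, width_px), all >= 1")
  }
  if (cfg$pixel_size_xy <= 0 || cfg$z_step <= 0) {
    stop("calibrations 'pixel_size_xy' and 'z_step' must be positive")
  }
  if (cfg$n_filaments < 0L) stop("'n_filaments' must be >= 0")
  if (length(cfg$length_range) != 2L || any(cfg$length_range <= 0) ||
    diff(cfg$length_range) < 0) {
    stop("'length_range' must be c(min, max) with 0 < min <= max")
  }
  if (cfg$length_range[2] > cfg$image_shape[1] * cfg$z_step) {
    stop("maximum filament length exceeds the axial extent n_slices * z_step")
  }
  if (cfg$curvature_scale < 0) stop("'curvature_scale' must be >= 0")
  if (cfg$base_radius_um <= 0 || cfg$shaft_radius_um <= 0) {
    stop("base and shaft radii must be positive")
  }
  if (cfg$psf_sigma_xy < 0) stop("'psf_sigma_xy' must be >= 0")
  if (cfg$background_level < 0 || cfg$noise_sd < 0) {
    stop("'background_level' and 'noise_sd' must be >= 0")
  }
  if (cfg$min_separation_um < 0) stop("'min_separation_um' must be >= 0")
  structure(cfg, class = "fls_stack_config")
}

# Arc length of a polyline given as an n x 3 matrix (um).
polyline_arc_length <- function(polyline) {
  if (nrow(polyline) < 2L) {
    return(0)
  }
  sum(sqrt(rowSums(diff(polyline)^2)))
}

# Ground-truth morphometrics of one filament polyline.
filament_truth <- function(polyline, base_radius_um, pixel_size_xy) {
  arc <- polyline_arc_length(polyline)
  e2e <- sqrt(sum((polyline[nrow(polyline), ] - polyline[1, ])^2))
  data.frame(
    arc_length_um = arc,
    straightness_true = e2e / arc,
    base_area_um2 = pi * base_radius_um^2,
    base_x_px = polyline[1, 1] / pixel_size_xy,
    base_y_px = polyline[1, 2] / pixel_size_xy
  )
}

# Sample base centers with pairwise separation >= min_sep inside
# [margin, extent - margin]^2 (um) by rejection sampling.
sample_base_centers <- function(n, extent_x, extent_y, margin, min_sep) {
  if (n == 0L) {
    return(matrix(numeric(0), ncol = 2))
  }
  if (extent_x - 2 * margin <= 0 || extent_y - 2 * margin <= 0) {
    stop("field of view too small for the configured filament radii/margins")
  }
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 5000L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "could not place %d filament bases with separation >= %.3g um in a %.3g x %.3g um field",
        n, min_sep, extent_x, extent_y
      ))
    }
    cand <- c(
      stats::runif(1, margin, extent_x - margin),
      stats::runif(1, margin, extent_y - margin)
    )
    ok <- placed == 0L ||
      all(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
        matrix(cand, placed, 2, byrow = TRUE))^2)) >= min_sep)
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  centers
}

# Grow one polyline: nodes at z = 0, z_step, 2*z_step, ... until the arc
# length reaches target_len or the top of the stack is hit.
grow_polyline <- function(base_xy, target_len, z_step, n_slices, curvature_scale) {
  pts <- matrix(c(base_xy, 0), 1, 3)
  arc <- 0
  s <- 0L
  while (arc < target_len && s < n_slices - 1L) {
    step_xy <- if (curvature_scale > 0) stats::rnorm(2, 0, curvature_scale) else c(0, 0)
    nxt <- pts[nrow(pts), ] + c(step_xy, z_step)
    arc <- arc + sqrt(sum((nxt - pts[nrow(pts), ])^2))
    pts <- rbind(pts, nxt)
    s <- s + 1L
  }
  pts
}

paint_disk <- function(img, cx_px, cy_px, r_px, value) {
  ny <- nrow(img)
  nx <- ncol(img)
  x0 <- max(0L, floor(cx_px - r_px))
  x1 <- min(nx - 1L, ceiling(cx_px + r_px))
  y0 <- max(0L, floor(cy_px - r_px))
  y1 <- min(ny - 1L, ceiling(cy_px + r_px))
  if (x0 > x1 || y0 > y1) {
    return(img)
  }
  xs <- x0:x1
  ys <- y0:y1
  d2 <- outer((ys - cy_px)^2, (xs - cx_px)^2, `+`)
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  sub[d2 <= r_px^2] <- pmax(sub[d2 <= r_px^2], value)
  img[ys + 1L, xs + 1L] <- sub
  img
}

#' Generate a synthetic FLS image stack with ground truth
#'
#' Filament base centers are drawn uniformly with pairwise separation at
#' least `min_separation_um`, target arc lengths uniformly from
#' `length_range`, and each filament grows as a polyline with one node per
#' z-slice (lateral Gaussian random-walk steps of sd `curvature_scale`).
#' Rendering paints, per slice, a filled disk at the polyline position for
#' that z (base radius on slice 0, shaft radius above), blurs each slice
#' with a Gaussian of `psf_sigma_xy`, then adds `background_level` plus
#' zero-mean Gaussian noise and rounds to integer counts clipped to
#' 0..65535. Ground-truth arc length, straightness and base area are
#' computed from the polylines before rasterization.
#'
#' @param config an [fls_stack_config()].
#' @param filaments optional list overriding random placement; each element
#'   is a list with `polyline` (n x 3 matrix of (x, y, z) um, z starting at 0
#'   and strictly increasing) and optionally `base_radius_um`. When supplied,
#'   `n_filaments` and the placement/length/curvature parameters are ignored.
#' @return A list with elements `stack` (an [fls_stack()]), `truth` (a
#'   data.frame with one row per filament: `filament_id`, `arc_length_um`,
#'   `straightness_true`, `base_area_um2`, `base_x_px`, `base_y_px`) and
#'   `polylines` (list of the generating polylines, um).
#' @export
generate_fls_stack <- function(config, filaments = NULL) {
  stopifnot(inherits(config, "fls_stack_config"))
  nz <- config$image_shape[1]
  ny <- config$image_shape[2]
  nx <- config$image_shape[3]
  px <- config$pixel_size_xy
  extent_x <- nx * px
  extent_y <- ny * px

  build <- function() {
    if (is.null(filaments)) {
      # margin keeps base disks and the expected lateral wander in-field
      margin <- config$base_radius_um +
        2 * config$curvature_scale * sqrt(nz) + 2 * px
      centers <- sample_base_centers(
        config$n_filaments, extent_x, extent_y,
        margin, config$min_separation_um
      )
      targets <- if (config$n_filaments > 0) {
        stats::runif(config$n_filaments, config$length_range[1], config$length_range[2])
      } else {
        numeric(0)
      }
      fil <- lapply(seq_len(config$n_filaments), function(i) {
        list(
          polyline = grow_polyline(
            centers[i, ], targets[i], config$z_step,
            nz, config$curvature_scale
          ),
          base_radius_um = config$base_radius_um
        )
      })
    } else {
      fil <- lapply(filaments, function(f) {
        p <- f$polyline
        if (!is.matrix(p) || ncol(p) != 3L || nrow(p) < 2L) {
          stop("each filament polyline must be an n x 3 matrix with n >= 2")
        }
        if (p[1, 3] != 0 || any(diff(p[, 3]) <= 0)) {
          stop("polyline z values must start at 0 and increase strictly")
        }
        list(
          polyline = p,
          base_radius_um = f$base_radius_um %||% config$base_radius_um
        )
      })
    }

    truth <- if (length(fil) > 0) {
      cbind(
        data.frame(filament_id = seq_along(fil)),
        do.call(rbind, lapply(fil, function(f) {
          filament_truth(f$polyline, f$base_radius_um, px)
        }))
      )
    } else {
      data.frame(
        filament_id = integer(0), arc_length_um = numeric(0),
        straightness_true = numeric(0), base_area_um2 = numeric(0),
        base_x_px = numeric(0), base_y_px = numeric(0)
      )
    }

    vox <- array(0, dim = c(nz, ny, nx))
    for (z in 0:(nz - 1L)) {
      sl <- vox[z + 1L, , , drop = TRUE]
      for (f in fil) {
        p <- f$polyline
        row <- which(abs(p[, 3] - z * config$z_step) < config$z_step / 2)
        if (length(row) == 0L) next
        row <- row[1]
        r_um <- if (z == 0L) f$base_radius_um else config$shaft_radius_um
        sl <- paint_disk(sl, p[row, 1] / px, p[row, 2] / px, r_um / px,
          value = config$peak_intensity
        )
      }
      if (config$psf_sigma_xy > 0) sl <- blur_reflect(sl, config$psf_sigma_xy)
      sl <- sl + config$background_level
      if (config$noise_sd > 0) sl <- sl + stats::rnorm(length(sl), 0, config$noise_sd)
      vox[z + 1L, , ] <- pmin(pmax(round(sl), 0), 65535)
    }

    list(
      stack = fls_stack(vox, px, config$z_step),
      truth = truth,
      polylines = lapply(fil, `[[`, "polyline")
    )
  }

  withr::with_seed(config$seed, build())
}

#' Configuration for the synthetic linescan generator
#'
#' @param n_filopodia number of filopodium linescans.
#' @param positive_fraction probability that a filopodium truly carries the
#'   marker, in `[0, 1]`.
#' @param background_mean,background_sd Gaussian background intensity model
#'   (arbitrary units); values are clipped at 0 so intensities stay
#'   non-negative.
#' @param positive_delta peak height added at the centre sample of true
#'   positives (>= 0).
#' @param samples_per_linescan samples per profile (>= 2).
#' @param n_images number of images the filopodia are split across;
#'   background linescans are pooled per image when thresholds are computed.
#' @param seed integer RNG seed.
#' @return A validated list of class `fls_linescan_config`.
#' @export
fls_linescan_config <- function(n_filopodia = 400L,
                                positive_fraction = 0.5,
                                background_mean = 100,
                                background_sd = 10,
                                positive_delta = 100,
                                samples_per_linescan = 30L,
                                n_images = 1L,
                                seed = 1L) {
  cfg <- list(
    n_filopodia = as.integer(n_filopodia),
    positive_fraction = positive_fraction,
    background_mean = background_mean, background_sd = background_sd,
    positive_delta = positive_delta,
    samples_per_linescan = as.integer(samples_per_linescan),
    n_images = as.integer(n_images), seed = as.integer(seed)
  )
  if (cfg$n_filopodia < 1L) stop("'n_filopodia' must be >= 1")
  if (cfg$positive_fraction < 0 || cfg$positive_fraction > 1) {
    stop("'positive_fraction' must lie in [0, 1]")
  }
  if (cfg$background_sd < 0) stop("'background_sd' must be >= 0")
  if (cfg$positive_delta < 0) stop("'positive_delta' must be >= 0")
  if (cfg$samples_per_linescan < 2L) stop("'samples_per_linescan' must be >= 2")
  if (cfg$n_images < 1L) stop("'n_images' must be >= 1")
  structure(cfg, class = "fls_linescan_config")
}

#' Generate a synthetic linescan dataset with known marker labels
#'
#' Labels are drawn first as one Bernoulli block
#' (`runif(n) < positive_fraction`), then for each filopodium in order a
#' filopodium linescan (background noise, plus `positive_delta` added to the
#' centre sample for true positives) and a paired pure-noise background
#' linescan are drawn. Filopodia are assigned to `n_images` images in
#' contiguous blocks.
#'
#' @param config an [fls_linescan_config()].
#' @return A list with `linescans`, a long-format data.frame with columns
#'   `image_id`, `filopodium_id`, `role` (`"filopodium"`/`"background"`),
#'   `sample_index` (0-based) and `intensity`; and `labels`, a data.frame
#'   with `filopodium_id`, `image_id` and logical `positive`.
#' @export
generate_linescan_dataset <- function(config) {
  stopifnot(inherits(config, "fls_linescan_config"))
  n <- config$n_filopodia
  k <- config$samples_per_linescan
  build <- function() {
    labels <- stats::runif(n) < config$positive_fraction
    image_id <- paste0("img", rep(seq_len(config$n_images),
      each = ceiling(n / config$n_images)
    )[seq_len(n)])
    rows <- vector("list", 2L * n)
    centre <- ceiling(k / 2)
    for (i in seq_len(n)) {
      fil <- stats::rnorm(k, config$background_mean, config$background_sd)
      if (labels[i]) fil[centre] <- fil[centre] + config$positive_delta
      bg <- stats::rnorm(k, config$background_mean, config$background_sd)
      rows[[2L * i - 1L]] <- data.frame(
        image_id = image_id[i], filopodium_id = paste0("fp", i),
        role = "filopodium", sample_index = 0:(k - 1L),
        intensity = pmax(fil, 0)
      )
      rows[[2L * i]] <- data.frame(
        image_id = image_id[i], filopodium_id = paste0("fp", i),
        role = "background", sample_index = 0:(k - 1L),
        intensity = pmax(bg, 0)
      )
    }
    list(
      linescans = do.call(rbind, rows),
      labels = data.frame(
        filopodium_id = paste0("fp", seq_len(n)),
        image_id = image_id, positive = labels
      )
    )
  }
  withr::with_seed(config$seed, build())
}

# Baseline per-region phenotype used by generate_phenotype_conditions().
# Added actin lengthens FLS, so the length baseline doubles in that state.
phenotype_baselines <- function() {
  list(
    none_added = c(fls_count = 60, mean_length_um = 5, mean_base_area_um2 = 1.0),
    actin_added = c(fls_count = 50, mean_length_um = 10, mean_base_area_um2 = 1.0)
  )
}

#' Generate a synthetic perturbation-screen phenotype table
#'
#' Produces per-region summaries (one row per imaging region) for
#' `n_conditions` conditions in both actin states, with planted cluster
#' structure. The first condition is the control, labelled `"C"`; the rest
#' are labelled `"scFv1"`, `"scFv2"`, ... Effects are fractional mean
#' shifts: a region value is
#' `baseline * (1 + effect) + N(0, noise_sd * baseline)`, so
#' `effect_sizes[k, "mean_length_um"] = -0.5` halves mean length for
#' conditions in cluster `k`. Counts are rounded and truncated at 0.
#'
#' @param n_conditions number of conditions (>= 1), control included.
#' @param n_regions_per_condition regions per condition and actin state; if
#'   `NULL`, each condition/state draws its region count uniformly from
#'   10..17 (typical replication of an FLS screen).
#' @param cluster_assignments integer vector of length `n_conditions` giving
#'   each condition's cluster (row of `effect_sizes`).
#' @param effect_sizes numeric matrix `n_clusters x 3` with columns
#'   `fls_count`, `mean_length_um`, `mean_base_area_um2`; fractional shifts.
#' @param noise_sd coefficient of variation of regional sampling noise.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `region_id`, `condition`,
#'   `actin_state`, `fls_count`, `mean_length_um`, `mean_base_area_um2`,
#'   `mean_straightness`.
#' @export
generate_phenotype_conditions <- function(n_conditions,
                                          n_regions_per_condition = NULL,
                                          cluster_assignments = rep(1L, n_conditions),
                                          effect_sizes = matrix(0, 1, 3),
                                          noise_sd = 0.15,
                                          seed = 1L) {
  stopifnot(n_conditions >= 1L)
  if (length(cluster_assignments) != n_conditions) {
    stop("'cluster_assignments' must have one entry per condition")
  }
  effect_sizes <- as.matrix(effect_sizes)
  if (ncol(effect_sizes) != 3L) {
    stop("'effect_sizes' must have 3 columns: fls_count, mean_length_um, mean_base_area_um2")
  }
  if (any(cluster_assignments < 1L) || any(cluster_assignments > nrow(effect_sizes))) {
    stop("'cluster_assignments' must index rows of 'effect_sizes'")
  }
  colnames(effect_sizes) <- c("fls_count", "mean_length_um", "mean_base_area_um2")
  conditions <- c("C", if (n_conditions > 1L) paste0("scFv", seq_len(n_conditions - 1L)))
  base <- phenotype_baselines()

  build <- function() {
    out <- list()
    for (ci in seq_len(n_conditions)) {
      eff <- effect_sizes[cluster_assignments[ci], ]
      for (state in c("none_added", "actin_added")) {
        nr <- if (is.null(n_regions_per_condition)) {
          sample(10:17, 1L)
        } else {
          n_regions_per_condition
        }
        b <- base[[state]]
        mu <- b * (1 + eff)
        count <- pmax(0, round(stats::rnorm(nr, mu["fls_count"], noise_sd * b["fls_count"])))
        len <- pmax(0.1, stats::rnorm(nr, mu["mean_length_um"], noise_sd * b["mean_length_um"]))
        area <- pmax(0.01, stats::rnorm(nr, mu["mean_base_area_um2"], noise_sd * b["mean_base_area_um2"]))
        straight <- pmin(1, pmax(0.1, stats::rnorm(nr, 0.9, 0.05)))
        out[[length(out) + 1L]] <- data.frame(
          region_id = sprintf("%s_%s_r%02d", conditions[ci], state, seq_len(nr)),
          condition = conditions[ci], actin_state = state,
          fls_count = as.integer(count), mean_length_um = len,
          mean_base_area_um2 = area, mean_straightness = straight
        )
      }
    }
    do.call(rbind, out)
  }
  res <- withr::with_seed(as.integer(seed), build())
  rownames(res) <- NULL
  attr(res, "cluster_assignments") <- stats::setNames(cluster_assignments, conditions)
  res
}
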