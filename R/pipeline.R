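# End-to-end orchestration: configuration, CSV I/O, run manifests.

#' Full pipeline configuration
#'
#' Bundles the per-stage parameters with the calibration and the analysis
#' constants of the screen (perplexity 2.49, early exaggeration 12,
#' 1-SD presence scoring). Round-trips losslessly through YAML via
#' [write_fls_config()] / [read_fls_config()].
#'
#' @param pixel_size_xy,z_step calibration, um/px and um/slice.
#' @param segmentation a [seg_config()].
#' @param tracing a [trace_config()].
#' @param perplexity,early_exaggeration,embed_seed t-SNE settings for
#'   [embed_2d()].
#' @param sd_multiplier stringency of the presence score
#'   ([background_threshold()]).
#' @param seed default RNG seed for synthetic stages.
#' @return A list of class `fls_config`.
#' @export
fls_config <- function(pixel_size_xy = 0.1, z_step = 1.0,
                       segmentation = seg_config(), tracing = trace_config(),
                       perplexity = 2.49, early_exaggeration = 12,
                       embed_seed = 0L, sd_multiplier = 1, seed = 1L) {
  if (pixel_size_xy <= 0 || z_step <= 0) stop("calibrations must be positive")
  stopifnot(inherits(segmentation, "fls_seg_config"), inherits(tracing, "fls_trace_config"))
  if (perplexity <= 0) stop("'perplexity' must be > 0")
  if (sd_multiplier < 0) stop("'sd_multiplier' must be >= 0")
  structure(
    list(
      pixel_size_xy = pixel_size_xy, z_step = z_step,
      segmentation = segmentation, tracing = tracing,
      perplexity = perplexity, early_exaggeration = early_exaggeration,
      embed_seed = as.integer(embed_seed), sd_multiplier = sd_multiplier,
      seed = as.integer(seed), schema_version = 1L
    ),
    class = "fls_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config an [fls_config()].
#' @param path YAML file path.
#' @return `write_fls_config` returns `path` invisibly; `read_fls_config`
#'   returns the reconstructed [fls_config()].
#' @export
write_fls_config <- function(config, path) {
  stopifnot(inherits(config, "fls_config"))
  flat <- list(
    schema_version = config$schema_version,
    pixel_size_xy = config$pixel_size_xy, z_step = config$z_step,
    segmentation = unclass(config$segmentation),
    tracing = unclass(config$tracing),
    perplexity = config$perplexity,
    early_exaggeration = config$early_exaggeration,
    embed_seed = config$embed_seed, sd_multiplier = config$sd_multiplier,
    seed = config$seed
  )
  yaml::write_yaml(flat, path, precision = 17L)
  invisible(path)
}

#' @rdname write_fls_config
#' @export
read_fls_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$schema_version) || y$schema_version != 1L) {
    stop("unsupported or missing config schema_version")
  }
  fls_config(
    pixel_size_xy = y$pixel_size_xy, z_step = y$z_step,
    segmentation = do.call(seg_config, y$segmentation),
    tracing = do.call(trace_config, y$tracing),
    perplexity = y$perplexity, early_exaggeration = y$early_exaggeration,
    embed_seed = y$embed_seed, sd_multiplier = y$sd_multiplier, seed = y$seed
  )
}

# Round-trip-exact CSV helpers (readr writes shortest-round-trip doubles).
write_table_csv <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

read_table_csv <- function(path) {
  as.data.frame(readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE
  ))
}

# Deterministic JSON run manifest: configuration, seeds, input hashes and
# package version -- everything needed to reproduce the outputs bit for bit.
write_manifest <- function(path, config, inputs = character(0), extra = list()) {
  manifest <- c(
    list(
      package = "flsquant",
      package_version = as.character(utils::packageVersion("flsquant")),
      config = yaml::as.yaml(list(
        pixel_size_xy = config$pixel_size_xy, z_step = config$z_step,
        segmentation = unclass(config$segmentation),
        tracing = unclass(config$tracing),
        perplexity = config$perplexity,
        early_exaggeration = config$early_exaggeration,
        embed_seed = config$embed_seed,
        sd_multiplier = config$sd_multiplier, seed = config$seed
      )),
      input_md5 = as.list(tools::md5sum(inputs))
    ),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Quantify a directory of stacks into measurement and summary tables
#'
#' For every row of the metadata table the stack is read, segmented, traced
#' and measured, and a per-region summary appended. Writes
#' `measurements.csv`, `region_summaries.csv` and `manifest.json` to
#' `out_dir`.
#'
#' @param input_dir directory holding the TIFF stacks.
#' @param config an [fls_config()].
#' @param metadata data.frame (or CSV path) with columns `stack_path`
#'   (relative to `input_dir`), `region_id`, `condition`, `actin_state`.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with `measurements` and `region_summaries`.
#' @export
run_quantify <- function(input_dir, config = fls_config(),
                         metadata = file.path(input_dir, "metadata.csv"),
                         out_dir = file.path(input_dir, "out")) {
  stopifnot(inherits(config, "fls_config"))
  meta_path <- NULL
  if (is.character(metadata)) {
    meta_path <- metadata
    if (!file.exists(metadata)) stop(sprintf("metadata file '%s' not found", metadata))
    metadata <- read_table_csv(metadata)
  }
  req <- c("stack_path", "region_id", "condition", "actin_state")
  if (!all(req %in% names(metadata))) {
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(metadata) == 0L) stop("metadata lists no stacks")
  paths <- file.path(input_dir, metadata$stack_path)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop(
      "stacks listed in metadata but not found: ",
      paste(metadata$stack_path[missing], collapse = ", ")
    )
  }
  measurements <- list()
  summaries <- list()
  for (i in seq_len(nrow(metadata))) {
    stack <- read_stack(paths[i],
      pixel_size_xy = config$pixel_size_xy, z_step = config$z_step,
      region_id = metadata$region_id[i], condition = metadata$condition[i],
      actin_state = metadata$actin_state[i]
    )
    res <- quantify_stack(stack, config$segmentation, config$tracing)
    if (nrow(res$measures) > 0L) {
      measurements[[i]] <- cbind(
        data.frame(
          region_id = metadata$region_id[i],
          condition = metadata$condition[i],
          actin_state = metadata$actin_state[i]
        ),
        res$measures
      )
    }
    summaries[[i]] <- res$summary
  }
  measurements <- if (length(measurements)) {
    do.call(rbind, measurements)
  } else {
    data.frame(
      region_id = character(0), condition = character(0),
      actin_state = character(0), trace_id = integer(0),
      path_length_um = numeric(0), straightness = numeric(0),
      base_area_um2 = numeric(0), n_nodes = integer(0)
    )
  }
  summaries <- do.call(rbind, summaries)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(measurements, file.path(out_dir, "measurements.csv"))
  write_table_csv(summaries, file.path(out_dir, "region_summaries.csv"))
  write_manifest(
    file.path(out_dir, "manifest.json"), config,
    inputs = c(paths, meta_path),
    extra = list(stage = "quantify", n_stacks = nrow(metadata))
  )
  invisible(list(measurements = measurements, region_summaries = summaries))
}

#' Embed a screen's region summaries in 2D
#'
#' Runs [build_feature_matrix()], [scale_features()] and [embed_2d()] and
#' writes `phenotype_matrix.csv`, `embedding.csv` (condition, x, y) and
#' `manifest.json` to `out_dir`.
#'
#' @param region_summaries data.frame or CSV path of per-region summaries.
#' @param config an [fls_config()].
#' @param out_dir output directory.
#' @return Invisibly, the [embed_2d()] result.
#' @export
run_embed <- function(region_summaries, config = fls_config(),
                      out_dir = "embed_out") {
  stopifnot(inherits(config, "fls_config"))
  in_path <- NULL
  if (is.character(region_summaries)) {
    in_path <- region_summaries
    region_summaries <- read_table_csv(region_summaries)
  }
  features <- build_feature_matrix(region_summaries)
  scaled <- scale_features(features)
  emb <- embed_2d(scaled,
    perplexity = config$perplexity,
    early_exaggeration = config$early_exaggeration,
    seed = config$embed_seed
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(
    data.frame(condition = rownames(features), unclass(features), row.names = NULL),
    file.path(out_dir, "phenotype_matrix.csv")
  )
  write_table_csv(
    data.frame(
      condition = rownames(emb$coordinates),
      x = emb$coordinates[, "x"], y = emb$coordinates[, "y"],
      row.names = NULL
    ),
    file.path(out_dir, "embedding.csv")
  )
  write_manifest(
    file.path(out_dir, "manifest.json"), config,
    inputs = in_path %||% character(0),
    extra = list(stage = "embed", n_conditions = nrow(features))
  )
  invisible(emb)
}

#' Score a linescan table for marker presence
#'
#' Computes a per-image threshold from that image's background linescans
#' ([background_threshold()]), scores every filopodium against it
#' ([score_filopodia()]) and aggregates positive fractions per image and
#' overall. Writes `presence_scores.csv`, `fractions.csv` and
#' `manifest.json` to `out_dir`.
#'
#' @param linescans data.frame or CSV path in long format with columns
#'   `image_id`, `filopodium_id`, `role` (`"filopodium"`/`"background"`),
#'   `sample_index`, `intensity` (as produced by
#'   [generate_linescan_dataset()]).
#' @param config an [fls_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with `scores` (per-filopodium data.frame with
#'   `image_id`) and `fractions` (see [fraction_positive()]).
#' @export
run_score <- function(linescans, config = fls_config(), out_dir = "score_out") {
  stopifnot(inherits(config, "fls_config"))
  in_path <- NULL
  if (is.character(linescans)) {
    in_path <- linescans
    linescans <- read_table_csv(linescans)
  }
  req <- c("image_id", "filopodium_id", "role", "sample_index", "intensity")
  if (!all(req %in% names(linescans))) {
    stop("linescan table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(linescans) == 0L) stop("linescan table is empty")
  scores <- list()
  for (img in sort(unique(linescans$image_id))) {
    sub <- linescans[linescans$image_id == img, , drop = FALSE]
    bg <- sub[sub$role == "background", , drop = FALSE]
    fp <- sub[sub$role == "filopodium", , drop = FALSE]
    if (nrow(bg) == 0L) {
      stop(sprintf("image '%s' has no background linescans", img))
    }
    bg_list <- lapply(split(bg, bg$filopodium_id), function(d) {
      d$intensity[order(d$sample_index)]
    })
    thr <- background_threshold(bg_list, sd_multiplier = config$sd_multiplier)
    fp_split <- split(fp, fp$filopodium_id)
    fp_list <- lapply(fp_split, function(d) d$intensity[order(d$sample_index)])
    sc <- score_filopodia(fp_list, thr)
    sc <- cbind(data.frame(image_id = img), sc)
    scores[[length(scores) + 1L]] <- sc
  }
  scores <- do.call(rbind, scores)
  rownames(scores) <- NULL
  fractions <- fraction_positive(scores, groups = scores$image_id)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(scores, file.path(out_dir, "presence_scores.csv"))
  frac_tab <- rbind(
    fractions$per_group,
    data.frame(
      group = "overall", n = nrow(scores),
      n_positive = sum(scores$positive), fraction = fractions$overall
    )
  )
  write_table_csv(frac_tab, file.path(out_dir, "fractions.csv"))
  write_manifest(
    file.path(out_dir, "manifest.json"), config,
    inputs = in_path %||% character(0),
    extra = list(stage = "score", n_filopodia = nrow(scores))
  )
  invisible(list(scores = scores, fractions = fractions))
}
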