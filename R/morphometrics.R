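# Per-trace morphology and per-region aggregation.

trace_nodes_um <- function(trace, pixel_size_xy, z_step) {
  n <- trace$nodes
  cbind(
    x = n$cx * pixel_size_xy,
    y = n$cy * pixel_size_xy,
    z = n$slice * z_step
  )
}

#' Path length of a trace
#'
#' Cumulative 3D Euclidean distance through the node centroids with
#' anisotropic scaling: each step contributes
#' `sqrt((dx * pixel_size_xy)^2 + (dy * pixel_size_xy)^2 + (dslice * z_step)^2)`.
#' Gap slices bridged during tracing contribute their full straight-line
#' distance. A single-node trace has length 0.
#'
#' @param trace one element of an [trace_fls()] result.
#' @param pixel_size_xy,z_step calibration, um/px and um/slice (> 0).
#' @return Path length in um.
#' @export
path_length <- function(trace, pixel_size_xy, z_step) {
  if (pixel_size_xy <= 0 || z_step <= 0) stop("calibrations must be positive")
  if (nrow(trace$nodes) < 1L) stop("trace has no nodes")
  polyline_arc_length(trace_nodes_um(trace, pixel_size_xy, z_step))
}

#' Straightness of a trace
#'
#' 3D end-to-end distance (first to last node) divided by [path_length()].
#' 1 for collinear traces, < 1 otherwise; always in (0, 1] by the triangle
#' inequality.
#'
#' @inheritParams path_length
#' @return Unitless straightness in (0, 1].
#' @export
straightness <- function(trace, pixel_size_xy, z_step) {
  if (nrow(trace$nodes) < 2L) stop("straightness needs >= 2 nodes")
  pts <- trace_nodes_um(trace, pixel_size_xy, z_step)
  pl <- polyline_arc_length(pts)
  if (pl == 0) stop("degenerate trace: zero path length")
  sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)) / pl
}

#' Base area of a trace
#'
#' Pixel area of the slice-0 (base) component scaled to um^2.
#'
#' @inheritParams path_length
#' @return Base area in um^2.
#' @export
base_area <- function(trace, pixel_size_xy) {
  base <- trace$nodes[trace$nodes$slice == min(trace$nodes$slice), , drop = FALSE]
  base$area_px[1] * pixel_size_xy^2
}

#' Morphometrics for a set of traces
#'
#' @param traces an [trace_fls()] result.
#' @param pixel_size_xy,z_step calibration, um/px and um/slice.
#' @return A data.frame with one row per trace: `trace_id`,
#'   `path_length_um`, `straightness`, `base_area_um2`, `n_nodes`.
#' @export
measure_traces <- function(traces, pixel_size_xy, z_step) {
  if (length(traces) == 0L) {
    return(data.frame(
      trace_id = integer(0), path_length_um = numeric(0),
      straightness = numeric(0), base_area_um2 = numeric(0),
      n_nodes = integer(0)
    ))
  }
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(
      trace_id = tr$trace_id,
      path_length_um = path_length(tr, pixel_size_xy, z_step),
      straightness = straightness(tr, pixel_size_xy, z_step),
      base_area_um2 = base_area(tr, pixel_size_xy),
      n_nodes = nrow(tr$nodes)
    )
  }))
}

#' Summarise the FLS of one imaging region
#'
#' Count plus arithmetic means of length, base area and straightness across
#' the structures of a region. An empty region yields count 0 with `NA`
#' means.
#'
#' @param measures data.frame from [measure_traces()].
#' @param region_id,condition,actin_state region metadata.
#' @return One-row data.frame: `region_id`, `condition`, `actin_state`,
#'   `fls_count`, `mean_length_um`, `mean_base_area_um2`,
#'   `mean_straightness`.
#' @export
summarize_region <- function(measures, region_id = "region",
                             condition = "C", actin_state = "none_added") {
  n <- nrow(measures)
  data.frame(
    region_id = region_id, condition = condition, actin_state = actin_state,
    fls_count = n,
    mean_length_um = if (n > 0) mean(measures$path_length_um) else NA_real_,
    mean_base_area_um2 = if (n > 0) mean(measures$base_area_um2) else NA_real_,
    mean_straightness = if (n > 0) mean(measures$straightness) else NA_real_
  )
}

#' Segment, trace and measure one stack
#'
#' Convenience wrapper running [segment_stack()], [trace_fls()] and
#' [measure_traces()] with the stack's own calibration.
#'
#' @param stack an [fls_stack()].
#' @param seg a [seg_config()].
#' @param trc a [trace_config()].
#' @return A list with `measures` (per-FLS data.frame), `summary` (one-row
#'   region summary) and `traces`.
#' @export
quantify_stack <- function(stack, seg = seg_config(), trc = trace_config()) {
  comps <- segment_stack(stack, seg)
  traces <- trace_fls(comps, trc, stack$pixel_size_xy)
  measures <- measure_traces(traces, stack$pixel_size_xy, stack$z_step)
  list(
    measures = measures,
    summary = summarize_region(
      measures, stack$region_id, stack$condition, stack$actin_state
    ),
    traces = traces
  )
}
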