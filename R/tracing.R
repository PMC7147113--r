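# Greedy base-to-tip linking of per-slice components into FLS traces.
#
# Normative rule (frozen by trace_oracle() and the test suite):
#   1. Seed one trace per slice-0 component, processed in descending base
#      area; ties broken by ascending (centroid y, centroid x).
#   2. Complete each trace before starting the next. From the current node
#      at slice s, scan slices s+1 .. s+1+gap_tolerance in order; the first
#      slice holding at least one unclaimed component whose lateral centroid
#      distance (Euclidean, um) is <= max_link_um supplies the next node:
#      the nearest such component, ties broken by ascending (y, x).
#   3. A claimed component is never reused. When no slice in the window
#      offers a candidate, the trace terminates.
#   4. Traces with fewer than min_nodes nodes are discarded.

#' Tracing parameters
#'
#' @param max_link_um maximum lateral centroid displacement per link, um.
#' @param gap_tolerance number of consecutive empty/unlinkable slices a
#'   trace may bridge (gaps still contribute their full z-distance to path
#'   length).
#' @param min_nodes minimum nodes for a trace to count as an FLS; the
#'   default 2 requires persistence across at least two slices.
#' @return A validated list of class `fls_trace_config`.
#' @export
trace_config <- function(max_link_um = 0.5, gap_tolerance = 1L, min_nodes = 2L) {
  if (max_link_um <= 0) stop("'max_link_um' must be > 0")
  if (gap_tolerance < 0L) stop("'gap_tolerance' must be >= 0")
  if (min_nodes < 1L) stop("'min_nodes' must be >= 1")
  structure(
    list(
      max_link_um = max_link_um,
      gap_tolerance = as.integer(gap_tolerance),
      min_nodes = as.integer(min_nodes)
    ),
    class = "fls_trace_config"
  )
}

# Canonicalize a per-slice component list: required columns present, rows
# sorted by (cy, cx) so results are independent of input ordering.
canonical_components <- function(per_slice_components) {
  if (!is.list(per_slice_components) || length(per_slice_components) == 0L) {
    stop("'per_slice_components' must be a non-empty list indexed by slice (slice 0 first)")
  }
  lapply(per_slice_components, function(df) {
    if (is.null(df) || nrow(df) == 0L) {
      return(df)
    }
    if (!all(c("cx", "cy", "area_px") %in% names(df))) {
      stop("components need columns 'cx', 'cy', 'area_px'")
    }
    df <- df[order(df$cy, df$cx), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

#' Trace FLS through a segmented stack with a greedy algorithm
#'
#' Components are linked from the base slice (index 0) upward according to
#' the deterministic greedy rule documented above; every FLS is anchored at
#' a slice-0 component and each component is used at most once.
#'
#' @param per_slice_components list of component data.frames as returned by
#'   [segment_stack()]; element 1 is slice 0 (may be empty).
#' @param config a [trace_config()].
#' @param pixel_size_xy lateral calibration, um/px (> 0).
#' @return A list of traces of class `fls_traces`; each trace is a list with
#'   `trace_id` and `nodes`, a data.frame of the linked component rows in
#'   base-to-tip order.
#' @export
trace_fls <- function(per_slice_components, config = trace_config(),
                      pixel_size_xy) {
  stopifnot(inherits(config, "fls_trace_config"))
  if (missing(pixel_size_xy) || !is.numeric(pixel_size_xy) || pixel_size_xy <= 0) {
    stop("'pixel_size_xy' must be a positive calibration (um/px)")
  }
  comps <- canonical_components(per_slice_components)
  nz <- length(comps)
  claimed <- lapply(comps, function(df) {
    rep(FALSE, if (is.null(df)) 0L else nrow(df))
  })

  base <- comps[[1]]
  traces <- list()
  if (!is.null(base) && nrow(base) > 0L) {
    seed_order <- order(-base$area_px, base$cy, base$cx)
    for (b in seed_order) {
      claimed[[1]][b] <- TRUE
      node_rows <- list(base[b, , drop = FALSE])
      cur <- c(base$cx[b], base$cy[b])
      cur_slice <- 0L
      repeat {
        nxt <- NULL
        for (s in (cur_slice + 1L):(cur_slice + 1L + config$gap_tolerance)) {
          if (s > nz - 1L) break
          df <- comps[[s + 1L]]
          if (is.null(df) || nrow(df) == 0L) next
          open <- which(!claimed[[s + 1L]])
          if (length(open) == 0L) next
          d_um <- pixel_size_xy *
            sqrt((df$cx[open] - cur[1])^2 + (df$cy[open] - cur[2])^2)
          ok <- which(d_um <= config$max_link_um)
          if (length(ok) == 0L) next
          # nearest; rows are in (cy, cx) order so which.min's first-match
          # tie-break is the (y, x) rule
          pick <- open[ok[which.min(d_um[ok])]]
          nxt <- list(slice = s, row = pick)
          break
        }
        if (is.null(nxt)) break
        claimed[[nxt$slice + 1L]][nxt$row] <- TRUE
        node_rows[[length(node_rows) + 1L]] <-
          comps[[nxt$slice + 1L]][nxt$row, , drop = FALSE]
        cur <- c(
          comps[[nxt$slice + 1L]]$cx[nxt$row],
          comps[[nxt$slice + 1L]]$cy[nxt$row]
        )
        cur_slice <- nxt$slice
        if (cur_slice >= nz - 1L) break
      }
      nodes <- do.call(rbind, node_rows)
      rownames(nodes) <- NULL
      traces[[length(traces) + 1L]] <- list(trace_id = NA_integer_, nodes = nodes)
    }
  }
  traces <- Filter(function(tr) nrow(tr$nodes) >= config$min_nodes, traces)
  for (i in seq_along(traces)) traces[[i]]$trace_id <- i
  structure(traces, class = "fls_traces")
}

#' Literal reference implementation of the greedy tracer
#'
#' An unoptimised transcription of the same linking rules as [trace_fls()],
#' written with explicit scalar loops and kept deliberately independent of
#' the production code path. Intended for equivalence testing on small
#' instances only.
#'
#' @inheritParams trace_fls
#' @return Same structure as [trace_fls()].
#' @export
trace_oracle <- function(per_slice_components, config = trace_config(),
                         pixel_size_xy) {
  stopifnot(inherits(config, "fls_trace_config"))
  nz <- length(per_slice_components)
  if (nz > 8L || any(vapply(per_slice_components, function(d) {
    if (is.null(d)) 0L else nrow(d)
  }, integer(1)) > 5L)) {
    stop("trace_oracle is guarded to instances with <= 8 slices and <= 5 components per slice")
  }
  # flatten into plain records
  slices <- vector("list", nz)
  for (z in seq_len(nz)) {
    df <- per_slice_components[[z]]
    recs <- list()
    if (!is.null(df) && nrow(df) > 0L) {
      for (i in seq_len(nrow(df))) {
        recs[[i]] <- list(
          cx = df$cx[i], cy = df$cy[i], area = df$area_px[i],
          row = df[i, , drop = FALSE], used = FALSE
        )
      }
      # sort by (cy, cx)
      ord <- order(
        vapply(recs, `[[`, numeric(1), "cy"),
        vapply(recs, `[[`, numeric(1), "cx")
      )
      recs <- recs[ord]
    }
    slices[[z]] <- recs
  }

  # seed order: descending area, ties by (cy, cx) (already sorted by (cy, cx))
  base <- slices[[1]]
  seed_idx <- seq_along(base)
  if (length(seed_idx) > 1L) {
    areas <- vapply(base, `[[`, numeric(1), "area")
    seed_idx <- seed_idx[order(-areas, seed_idx)]
  }

  traces <- list()
  for (b in seed_idx) {
    slices[[1]][[b]]$used <- TRUE
    chain <- list(slices[[1]][[b]]$row)
    cx <- slices[[1]][[b]]$cx
    cy <- slices[[1]][[b]]$cy
    z <- 0L
    repeat {
      found_slice <- -1L
      found_idx <- -1L
      found_d <- Inf
      for (s in (z + 1L):(z + 1L + config$gap_tolerance)) {
        if (s > nz - 1L) break
        cands <- slices[[s + 1L]]
        for (i in seq_along(cands)) {
          if (cands[[i]]$used) next
          d <- pixel_size_xy * sqrt((cands[[i]]$cx - cx)^2 + (cands[[i]]$cy - cy)^2)
          if (d <= config$max_link_um && d < found_d) {
            found_slice <- s
            found_idx <- i
            found_d <- d
          }
        }
        if (found_idx > 0L) break
      }
      if (found_idx < 0L) break
      slices[[found_slice + 1L]][[found_idx]]$used <- TRUE
      chain[[length(chain) + 1L]] <- slices[[found_slice + 1L]][[found_idx]]$row
      cx <- slices[[found_slice + 1L]][[found_idx]]$cx
      cy <- slices[[found_slice + 1L]][[found_idx]]$cy
      z <- found_slice
      if (z >= nz - 1L) break
    }
    if (length(chain) >= config$min_nodes) {
      nodes <- do.call(rbind, chain)
      rownames(nodes) <- NULL
      traces[[length(traces) + 1L]] <- list(trace_id = length(traces) + 1L, nodes = nodes)
    }
  }
  structure(traces, class = "fls_traces")
}

#' @export
print.fls_traces <- function(x, ...) {
  cat(sprintf("<fls_traces> %d trace(s)\n", length(x)))
  for (tr in x) {
    cat(sprintf(
      "  #%d: %d nodes, slices %d..%d\n", tr$trace_id,
      nrow(tr$nodes), min(tr$nodes$slice), max(tr$nodes$slice)
    ))
  }
  invisible(x)
}
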