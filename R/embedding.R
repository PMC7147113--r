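# Per-condition phenotype vectors and their 2D t-SNE embedding.

feature_columns <- c(
  "count_none_added", "count_actin_added",
  "length_none_added", "length_actin_added",
  "area_none_added", "area_actin_added"
)

#' Build the six-feature phenotype matrix of a screen
#'
#' For every condition and actin state, takes the median across imaging
#' regions of the per-region FLS count, the per-region mean path length and
#' the per-region mean base area ("median average": median over regions of
#' the mean over structures). Columns, in fixed order: median count (no
#' added actin), median count (actin added), median mean length (no actin,
#' actin added), median mean base area (no actin, actin added). Rows are
#' sorted by condition label so the matrix is independent of input order.
#' Regions with zero FLS contribute their count but no length/area value.
#'
#' @param region_summaries data.frame with columns `condition`,
#'   `actin_state` (`"none_added"`/`"actin_added"`), `fls_count`,
#'   `mean_length_um`, `mean_base_area_um2` (one row per region), e.g. from
#'   [summarize_region()] or [generate_phenotype_conditions()].
#' @return Numeric matrix, one row per condition, six columns; class
#'   `phenotype_matrix`.
#' @export
build_feature_matrix <- function(region_summaries) {
  req <- c("condition", "actin_state", "fls_count", "mean_length_um", "mean_base_area_um2")
  if (!all(req %in% names(region_summaries))) {
    stop(
      "region summaries must contain columns: ",
      paste(setdiff(req, names(region_summaries)), collapse = ", ")
    )
  }
  conditions <- sort(unique(region_summaries$condition))
  for (cond in conditions) {
    states <- unique(region_summaries$actin_state[region_summaries$condition == cond])
    if (!all(c("none_added", "actin_added") %in% states)) {
      stop(sprintf("condition '%s' is missing an actin state", cond))
    }
  }
  m <- matrix(NA_real_, length(conditions), 6L,
    dimnames = list(conditions, feature_columns)
  )
  for (cond in conditions) {
    for (state in c("none_added", "actin_added")) {
      sub <- region_summaries[
        region_summaries$condition == cond &
          region_summaries$actin_state == state, ,
        drop = FALSE
      ]
      suffix <- state
      m[cond, paste0("count_", suffix)] <- stats::median(sub$fls_count)
      m[cond, paste0("length_", suffix)] <- stats::median(sub$mean_length_um, na.rm = TRUE)
      m[cond, paste0("area_", suffix)] <- stats::median(sub$mean_base_area_um2, na.rm = TRUE)
    }
  }
  if (anyNA(m)) stop("phenotype matrix has missing entries")
  class(m) <- c("phenotype_matrix", class(m))
  m
}

#' Standardise phenotype features
#'
#' Centres each column to mean 0 and scales it to unit population sd
#' (divisor n). A constant column carries no information and is mapped to
#' zero with a warning.
#'
#' @param matrix numeric matrix with >= 2 rows (e.g. a
#'   [build_feature_matrix()] result).
#' @return Matrix of the same shape, column means 0 and sds 1 (0 for
#'   degenerate columns).
#' @export
scale_features <- function(matrix) {
  m <- unclass(matrix)
  if (!is.matrix(m) || nrow(m) < 2L) {
    stop("feature scaling needs a matrix with at least 2 rows")
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    s <- sd_pop(m[, j])
    if (s == 0) {
      warning(sprintf(
        "column %s is constant and was mapped to 0",
        colnames(m)[j] %||% as.character(j)
      ))
      out[, j] <- 0
    } else {
      out[, j] <- (m[, j] - mean(m[, j])) / s
    }
  }
  out
}

#' Embed scaled phenotype vectors in 2D with t-SNE
#'
#' Exact (theta = 0) t-SNE with the screen's analysis settings: perplexity
#' 2.49 and early exaggeration 12 by default. Rows are sorted by rowname
#' (condition label) before embedding, and the optimiser is initialised
#' from the given seed, so identical input and seed give bitwise-identical
#' coordinates. t-SNE requires `n_rows - 1 >= 3 * perplexity`.
#'
#' @param scaled numeric matrix, rows = conditions (rownames = labels),
#'   typically from [scale_features()].
#' @param perplexity t-SNE perplexity (may be fractional).
#' @param early_exaggeration early exaggeration factor.
#' @param seed integer RNG seed for the random initialisation.
#' @param max_iter optimisation iterations.
#' @return An object of class `fls_embedding`: list with `coordinates`
#'   (n x 2 matrix, rownames = condition), `perplexity`,
#'   `early_exaggeration`, `seed` and `scaled_input`.
#' @export
embed_2d <- function(scaled, perplexity = 2.49, early_exaggeration = 12,
                     seed = 0L, max_iter = 1000L) {
  m <- unclass(scaled)
  if (!is.matrix(m) || nrow(m) < 4L) stop("embedding needs >= 4 rows")
  if (perplexity <= 0 || 3 * perplexity > nrow(m) - 1) {
    stop(sprintf(
      "perplexity %.3g infeasible for %d rows (need n - 1 >= 3 * perplexity)",
      perplexity, nrow(m)
    ))
  }
  if (!is.null(rownames(m))) {
    m <- m[order(rownames(m)), , drop = FALSE]
  }
  fit <- withr::with_seed(
    as.integer(seed),
    Rtsne::Rtsne(m,
      dims = 2L, perplexity = perplexity, theta = 0,
      exaggeration_factor = early_exaggeration, max_iter = as.integer(max_iter),
      pca = FALSE, normalize = FALSE, verbose = FALSE
    )
  )
  coords <- fit$Y
  rownames(coords) <- rownames(m)
  colnames(coords) <- c("x", "y")
  structure(
    list(
      coordinates = coords, perplexity = perplexity,
      early_exaggeration = early_exaggeration, seed = as.integer(seed),
      scaled_input = m
    ),
    class = "fls_embedding"
  )
}

#' @export
print.fls_embedding <- function(x, ...) {
  cat(sprintf(
    "<fls_embedding> %d conditions, perplexity %.3g, early exaggeration %g, seed %d\n",
    nrow(x$coordinates), x$perplexity, x$early_exaggeration, x$seed
  ))
  invisible(x)
}
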