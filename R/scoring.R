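# Linescan marker-presence scoring and KS comparisons with
# Bonferroni-corrected significance tiers.

#' Bonferroni-corrected significance tiers for a four-way comparison
#'
#' The family-wise levels 0.05, 0.01 and 0.001 divided by the number of
#' comparisons (4) give per-comparison thresholds 0.0125, 0.0025 and
#' 0.00025 for the *, ** and *** tiers.
#'
#' @param n_comparisons number of comparisons in the family.
#' @return A data.frame with columns `label`, `family_alpha`, `threshold`
#'   (ordered most stringent first), with `n_comparisons` as an attribute.
#' @export
tier_thresholds <- function(n_comparisons = 4L) {
  stopifnot(n_comparisons >= 1L)
  out <- data.frame(
    label = c("***", "**", "*"),
    family_alpha = c(0.001, 0.01, 0.05)
  )
  out$threshold <- out$family_alpha / n_comparisons
  attr(out, "n_comparisons") <- as.integer(n_comparisons)
  out
}

#' Marker-presence threshold from background linescans
#'
#' Collects the maximum of each background linescan of one image and
#' returns `mean(maxima) + 1 * sd(maxima)` (sample sd, divisor n - 1).
#' With a single background linescan the spread of maxima is not estimable,
#' so the fallback `mean(samples) + 1 * sd(samples)` of that linescan is
#' used instead.
#'
#' @param background_linescans list of numeric vectors, one per background
#'   linescan of the image.
#' @param sd_multiplier stringency multiplier on the sd term (default 1,
#'   i.e. "1 SD above background").
#' @return Threshold intensity (arbitrary units).
#' @export
background_threshold <- function(background_linescans, sd_multiplier = 1) {
  if (!is.list(background_linescans) || length(background_linescans) == 0L) {
    stop("need at least one background linescan")
  }
  lapply(background_linescans, function(v) {
    if (!is.numeric(v) || length(v) < 2L) {
      stop("each linescan needs >= 2 numeric samples")
    }
  })
  if (length(background_linescans) == 1L) {
    v <- background_linescans[[1]]
    return(mean(v) + sd_multiplier * stats::sd(v))
  }
  maxima <- vapply(background_linescans, max, numeric(1))
  mean(maxima) + sd_multiplier * stats::sd(maxima)
}

#' Score filopodia for marker presence
#'
#' A filopodium is positive when the maximum of its linescan strictly
#' exceeds the threshold.
#'
#' @param filopodium_linescans named list of numeric vectors (names are
#'   filopodium ids).
#' @param threshold intensity threshold, e.g. from [background_threshold()].
#' @return A data.frame with one row per filopodium: `filopodium_id`,
#'   `max_intensity`, `threshold`, `positive`, `margin`
#'   (`max_intensity - threshold`; positive iff margin > 0).
#' @export
score_filopodia <- function(filopodium_linescans, threshold) {
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  if (length(filopodium_linescans) == 0L) stop("no filopodium linescans supplied")
  ids <- names(filopodium_linescans) %||% paste0("fp", seq_along(filopodium_linescans))
  maxima <- vapply(seq_along(filopodium_linescans), function(i) {
    v <- filopodium_linescans[[i]]
    if (!is.numeric(v) || length(v) == 0L) {
      stop(sprintf("filopodium linescan '%s' is empty", ids[i]))
    }
    max(v)
  }, numeric(1))
  data.frame(
    filopodium_id = ids,
    max_intensity = maxima,
    threshold = threshold,
    positive = maxima > threshold,
    margin = maxima - threshold
  )
}

#' Fraction of marker-positive filopodia per group and overall
#'
#' @param scores data.frame with a logical `positive` column (e.g. from
#'   [score_filopodia()]).
#' @param groups vector of group labels (image or region ids), one per row
#'   of `scores`.
#' @return A list with `per_group` (data.frame `group`, `n`, `n_positive`,
#'   `fraction`) and `overall` (pooled positives / total).
#' @export
fraction_positive <- function(scores, groups = rep("all", nrow(scores))) {
  if (nrow(scores) == 0L) stop("no scores supplied")
  if (length(groups) != nrow(scores)) {
    stop("'groups' must have one label per score")
  }
  per <- do.call(rbind, lapply(split(seq_len(nrow(scores)), groups), function(ix) {
    data.frame(
      n = length(ix),
      n_positive = sum(scores$positive[ix]),
      fraction = mean(scores$positive[ix])
    )
  }))
  per <- data.frame(group = rownames(per), per, row.names = NULL)
  list(per_group = per, overall = mean(scores$positive))
}

#' Two-sample KS test with Bonferroni significance tiers
#'
#' Standard two-sample Kolmogorov-Smirnov statistic with the asymptotic
#' p-value, labelled with the most stringent tier whose per-comparison
#' threshold exceeds p; p at or above the loosest threshold is "n.s.".
#'
#' @param sample_a,sample_b numeric vectors with >= 2 values each.
#' @param thresholds a [tier_thresholds()] data.frame.
#' @return A list with `statistic` (D), `p_value` and `tier`
#'   (`"***"`, `"**"`, `"*"` or `"n.s."`).
#' @export
ks_compare_with_tiers <- function(sample_a, sample_b,
                                  thresholds = tier_thresholds()) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("both samples need >= 2 values")
  }
  fit <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(
    statistic = unname(fit$statistic),
    p_value = fit$p.value,
    tier = assign_tier(fit$p.value, thresholds)
  )
}

#' Map a p-value to its significance tier
#'
#' @param p p-value.
#' @param thresholds a [tier_thresholds()] data.frame.
#' @return Tier label, `"n.s."` when no threshold exceeds `p`.
#' @export
assign_tier <- function(p, thresholds = tier_thresholds()) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  thr <- thresholds[order(thresholds$threshold), , drop = FALSE] # stringent first
  for (i in seq_len(nrow(thr))) {
    if (p < thr$threshold[i]) {
      return(thr$label[i])
    }
  }
  "n.s."
}
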