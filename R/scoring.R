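#' Split a metric plot into equal stack regions
#'
#' The slice axis `1..n` is divided into `parts` contiguous regions
#' (top, middle, bottom for the default 3), with boundaries at
#' `round(p * n / parts)`; region `p` covers slices
#' `round((p-1) n / parts) + 1` through `round(p n / parts)`. For a
#' 10-slice stack and 3 parts this gives slices 1-3 / 4-7 / 8-10.
#'
#' @param plot a metric-plot tibble (needs a `slice` column), e.g. from
#'   [evaluate_stack()]; several stacks may be present, each is split on its
#'   own slice count.
#' @param parts number of regions (default 3).
#' @return The input tibble with a `region` factor column prepended to the
#'   grouping; for `parts = 3` the levels are top/middle/bottom, otherwise
#'   `region_1..region_parts`.
#' @export
split_regions <- function(plot, parts = 3L) {
  stopifnot(parts >= 1L)
  labels <- if (parts == 3L) region_levels() else paste0("region_", seq_len(parts))
  keys <- intersect(c("stack_id", "metric", "masking"), names(plot))
  out <- plot |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(region = region_of(.data$slice, dplyr::n(), parts, labels)) |>
    dplyr::ungroup()
  out
}

region_of <- function(slice, n, parts, labels) {
  if (n < parts) {
    stop("cannot split ", n, " slices into ", parts, " regions", call. = FALSE)
  }
  bounds <- round(seq_len(parts) * n / parts)
  factor(labels[findInterval(slice, c(0, bounds[-parts]) + 1L)], levels = labels)
}

#' Single-value score of jointly assessed metric plots
#'
#' Reduces each metric plot of an assessment set to one number in \[0, 1\].
#' With \eqn{\alpha} the maximum and \eqn{\beta} the minimum metric value
#' over *all* plots of the set, the score of plot \eqn{g_i} over its n
#' slices is
#' \deqn{score_i = \frac{1}{(\alpha-\beta)\,n} \sum_{j=1}^{n} (g_i(j) - \beta).}
#' A plot pinned at the set maximum on every slice scores exactly 1 (a
#' "perfect rectangle" of height \eqn{\alpha-\beta}); one pinned at the set
#' minimum scores exactly 0. Because \eqn{\alpha} and \eqn{\beta} are shared,
#' scores are comparable only within the set they were normalized in —
#' pooling across protocols vs. across cell lines changes the scale, so the
#' set membership is always an explicit choice of the caller.
#'
#' Slices with undefined metric values (`NA`) are excluded from the
#' \eqn{\alpha}/\eqn{\beta} pool and from that plot's sum and its n. If
#' \eqn{\alpha = \beta} the set is degenerate: all scores are 0 and
#' `degenerate` is set.
#'
#' @param plots a tibble of per-slice metric values with a `value` column;
#'   one plot per combination of the `by` columns (default all of
#'   `stack_id`, `metric`, `masking`, `region` that are present).
#' @param by character vector of columns identifying a plot.
#' @return An object of class `sqm_scoreset`: a tibble with the `by`
#'   columns, `n_slices` (non-NA slices) and `score01`, carrying the
#'   attributes `alpha`, `beta` and `degenerate`.
#' @export
score_plots <- function(plots, by = NULL) {
  stopifnot("value" %in% names(plots), nrow(plots) > 0L)
  if (is.null(by)) {
    by <- intersect(c("stack_id", "metric", "masking", "region"), names(plots))
  }
  if (!length(by)) stop("no plot-identifying columns found; pass `by`", call. = FALSE)
  vals <- plots$value[!is.na(plots$value)]
  if (!length(vals)) stop("all metric values are NA", call. = FALSE)
  alpha <- max(vals)
  beta <- min(vals)
  degenerate <- (alpha == beta)
  out <- plots |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_slices = sum(!is.na(.data$value)),
      # (mean - beta)/(alpha - beta): same algebra as the per-slice sum,
      # but exact at the extremes in floating point
      score01 = if (degenerate) 0 else
        (mean(.data$value, na.rm = TRUE) - beta) / (alpha - beta),
      .groups = "drop")
  if (any(out$n_slices == 0L)) {
    out$score01[out$n_slices == 0L] <- NA_real_
  }
  structure(out, class = c("sqm_scoreset", class(out)),
            alpha = alpha, beta = beta, degenerate = degenerate)
}

#' @export
print.sqm_scoreset <- function(x, ...) {
  cat(sprintf("<sqm_scoreset> alpha = %.6g, beta = %.6g%s\n",
              attr(x, "alpha"), attr(x, "beta"),
              if (attr(x, "degenerate")) " (degenerate: alpha == beta)" else ""))
  NextMethod()
}

#' Rescale 0-1 scores onto the 1-5 expert scale
#'
#' Linear min-max map of a score set's `score01` values onto \[1, 5\], so
#' that the metric scores share the range of the experts' 1-5 scoring. The
#' map is monotone, so rank order (and Pearson correlation against any
#' reference) is unchanged; the rescale is presentational. If all scores are
#' equal the map is undefined and every score is placed at the midpoint 3,
#' with a warning.
#'
#' @param scores an `sqm_scoreset` (or any tibble with `score01`).
#' @return The input with a `score15` column appended.
#' @export
rescale_1_5 <- function(scores) {
  s <- scores$score01
  lo <- min(s, na.rm = TRUE)
  hi <- max(s, na.rm = TRUE)
  if (hi == lo) {
    warning("all scores equal; mapping to the 1-5 midpoint", call. = FALSE)
    scores$score15 <- ifelse(is.na(s), NA_real_, 3)
  } else {
    scores$score15 <- 1 + 4 * (s - lo) / (hi - lo)
  }
  scores
}

#' Region scores for a set of stacks
#'
#' The full pipeline from per-slice metric values to per-region scores:
#' each plot is split into `parts` regions ([split_regions()]) and the
#' region sub-plots are scored with [score_plots()], then rescaled to the
#' 1-5 scale per [rescale_1_5()].
#'
#' `pool` controls the normalization set for \eqn{\alpha}/\eqn{\beta}:
#' `"by_region"` (default) normalizes each region across all stacks —
#' top-region plots are compared with top-region plots — while `"global"`
#' uses one \eqn{\alpha}/\eqn{\beta} pair for everything. Scores are only
#' comparable within their pool.
#'
#' @param plots per-slice metric tibble from [evaluate_stack()] (rows for
#'   several stacks can be bound together).
#' @param parts number of regions (default 3: top/middle/bottom).
#' @param pool `"by_region"` or `"global"`.
#' @return A tibble with `stack_id`, `region`, `n_slices`, `score01`,
#'   `score15` (plus `metric`, `masking` when present).
#' @export
score_regions <- function(plots, parts = 3L, pool = c("by_region", "global")) {
  pool <- match.arg(pool)
  reg <- split_regions(plots, parts = parts)
  by <- intersect(c("stack_id", "metric", "masking", "region"), names(reg))
  if (pool == "global") {
    out <- rescale_1_5(score_plots(reg, by = by))
  } else {
    out <- reg |>
      dplyr::group_split(.data$region) |>
      purrr::map(\(r) rescale_1_5(score_plots(r, by = by))) |>
      purrr::list_rbind()
  }
  dplyr::arrange(out, dplyr::across(dplyr::all_of(by)))
}

#' Pearson correlation between two score vectors
#'
#' Thin wrapper around the product-moment correlation with the
#' degenerate-input checks the scoring pipeline needs.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite, with nonzero
#'   variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Pearson correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}
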